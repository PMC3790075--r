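#' Read and write mono PCM16 WAV files
#'
#' A minimal RIFF/WAVE codec for 16-bit mono PCM, sufficient for
#' persisting and reloading the synthetic stimuli.
#'
#' @param w An [waveform()].
#' @param path File path.
#' @return `write_wav` invisibly returns `path`; `read_wav` returns an
#'   `hpp_waveform`.
#' @export
write_wav <- function(w, path) {
  if (!inherits(w, "hpp_waveform")) stop_param("w must be an hpp_waveform")
  pcm <- as.integer(pmax(-32768, pmin(32767, round(w$samples * 32767))))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  wr_int <- function(x, size) writeBin(as.integer(x), con, size = size,
                                       endian = "little")
  writeChar("RIFF", con, eos = NULL)
  wr_int(36 + 2 * n, 4)
  writeChar("WAVEfmt ", con, eos = NULL)
  wr_int(16, 4)                    # fmt chunk size
  wr_int(1, 2)                     # PCM
  wr_int(1, 2)                     # mono
  wr_int(w$sample_rate_hz, 4)
  wr_int(w$sample_rate_hz * 2, 4)  # byte rate
  wr_int(2, 2)                     # block align
  wr_int(16, 2)                    # bits per sample
  writeChar("data", con, eos = NULL)
  wr_int(2 * n, 4)
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_int <- function(size, signed = TRUE) {
    readBin(con, "integer", 1L, size = size, signed = signed,
            endian = "little")
  }
  if (readChar(con, 4) != "RIFF") stop_data("not a RIFF file: ", path)
  invisible(rd_int(4))
  if (readChar(con, 4) != "WAVE") stop_data("not a WAVE file: ", path)
  sr <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || nchar(id) < 4) stop_data("no data chunk in ", path)
    sz <- rd_int(4)
    if (id == "fmt ") {
      fmt <- rd_int(2)
      nch <- rd_int(2)
      sr <- rd_int(4)
      invisible(rd_int(4)); invisible(rd_int(2))
      bits <- rd_int(2)
      if (fmt != 1L || nch != 1L || bits != 16L) {
        stop_data("only mono 16-bit PCM is supported")
      }
      if (sz > 16) invisible(readBin(con, "raw", sz - 16L))
    } else if (id == "data") {
      pcm <- readBin(con, "integer", sz %/% 2L, size = 2, signed = TRUE,
                     endian = "little")
      return(waveform(pcm / 32767, sr))
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
}

#' Write a stimulus set to WAV files with a manifest
#'
#' Writes every waveform of an audio stimulus set to `out_dir` and a
#' `manifest.csv` describing each file (`file`, `role`, `word_id`,
#' `speaker_id`, `duration_s`, `word_onset_s`, `word_offset_s`).
#'
#' @param set An `hpp_stimulus_set`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_stimulus_set <- function(set, out_dir) {
  if (!inherits(set, "hpp_stimulus_set")) {
    stop_param("set must be an hpp_stimulus_set (audio)")
  }
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create ", out_dir)
  }
  sid <- set$speaker$speaker_id
  rows <- list()
  add <- function(w, file, role, wid = NA, on = NA, off = NA) {
    write_wav(w, file.path(out_dir, file))
    rows[[length(rows) + 1L]] <<- data.frame(
      file = file, role = role, word_id = wid, speaker_id = sid,
      duration_s = wave_duration_s(w), word_onset_s = on,
      word_offset_s = off, stringsAsFactors = FALSE)
  }
  for (wid in names(set$isolated_tokens)) {
    for (ti in seq_along(set$isolated_tokens[[wid]])) {
      add(set$isolated_tokens[[wid]][[ti]],
          sprintf("%s_token_%s_%02d.wav", sid, wid, ti), "token", wid)
    }
  }
  for (wid in names(set$sentences)) {
    for (si in seq_along(set$sentences[[wid]])) {
      s <- set$sentences[[wid]][[si]]
      add(s$wave, sprintf("%s_sentence_%s_%02d.wav", sid, wid, si),
          "sentence", wid, s$word_onset_s, s$word_offset_s)
    }
  }
  for (bi in seq_along(set$background)) {
    add(set$background[[bi]], sprintf("%s_background_%03d.wav", sid, bi),
        "background")
  }
  add(set$noise, sprintf("%s_noise.wav", sid), "noise")
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
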