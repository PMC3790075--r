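#' Generate a symbolic (label-stream) stimulus directly
#'
#' Fast-test mode that bypasses audio synthesis, feature extraction and
#' vector quantization: it emits the three parallel prototype-label
#' sequences that the acoustic front end would produce, at the nominal
#' 10 ms frame hop.  Background frames are uniform random labels; if a
#' word is given, a contiguous word-specific label pattern (a deterministic
#' function of the word identity) is embedded at a seeded position.
#' Speaker effects are emulated as seeded label noise: each label of the
#' stream is replaced by a random label with probability
#' `min(0.4, abs(spectral_shift))`, and the embedded pattern length is
#' scaled by the speaker's `rate_factor`.
#'
#' @param word An [word_spec()] or `NULL` for a background stream.
#' @param speaker An [speaker_profile()].
#' @param n_frames Number of 10 ms frames (at least 1).
#' @param codebook_sizes Integer triple `(K1, K2, K3)` of prototype
#'   inventory sizes.
#' @param seed Integer seed; identical arguments give identical streams.
#' @return An `hpp_label_stream` (see [label_stream()]); when a word is
#'   embedded, attributes `word_onset_frame` / `word_offset_frame` record
#'   its position and the stream carries `duration_s = n_frames / 100`.
#' @export
generate_symbolic_stream <- function(word = NULL, speaker, n_frames,
                                     codebook_sizes = c(150L, 150L, 100L),
                                     seed = 1L) {
  if (!is.numeric(n_frames) || n_frames < 1) {
    stop_param("n_frames must be >= 1")
  }
  n_frames <- as.integer(n_frames)
  sizes <- as.integer(codebook_sizes)
  if (length(sizes) != 3L || any(sizes < 1L)) {
    stop_param("codebook_sizes must be three positive integers")
  }
  p_noise <- min(0.4, abs(speaker$spectral_shift))
  streams <- with_seed(seed, {
    base <- lapply(sizes, function(K) sample.int(K, n_frames, replace = TRUE))
    onset <- NA_integer_
    offset <- NA_integer_
    if (!is.null(word)) {
      pat <- symbolic_word_pattern(word, sizes, speaker$rate_factor)
      L <- length(pat[[1]])
      if (L > n_frames) {
        stop_param("stream of ", n_frames,
                   " frames cannot hold a word pattern of ", L, " frames")
      }
      onset <- sample.int(n_frames - L + 1L, 1L)
      offset <- onset + L - 1L
      for (c_ in 1:3) base[[c_]][onset:offset] <- pat[[c_]]
    }
    if (p_noise > 0) {
      for (c_ in 1:3) {
        flip <- stats::runif(n_frames) < p_noise
        base[[c_]][flip] <- sample.int(sizes[c_], sum(flip), replace = TRUE)
      }
    }
    list(base = base, onset = onset, offset = offset)
  })
  ls <- label_stream(streams$base[[1]], streams$base[[2]], streams$base[[3]],
                     sizes)
  attr(ls, "word_onset_frame") <- streams$onset
  attr(ls, "word_offset_frame") <- streams$offset
  attr(ls, "duration_s") <- n_frames / 100
  ls
}

# The label pattern of a word: deterministic in the word identity and the
# codebook sizes; length = template duration at 10 ms per frame, scaled by
# the speaker's rate factor.
symbolic_word_pattern <- function(word, sizes, rate_factor = 1.0) {
  L <- max(2L, as.integer(round(word_duration_ms(word) / 10 * rate_factor)))
  h <- sum(utf8ToInt(word$word_id) * seq_along(utf8ToInt(word$word_id)))
  with_seed(1e6 + h, {
    lapply(sizes, function(K) sample.int(K, L, replace = TRUE))
  })
}

#' Generate a symbolic stimulus set for one speaker
#'
#' The label-stream counterpart of [generate_stimulus_set()]: per word,
#' `n_tokens` isolated-token streams (just the word pattern plus a short
#' silence margin) and `n_sentences` sentence streams with one embedded
#' word pattern each, plus `n_background` background streams without any
#' target pattern and one constant-label noise stream.
#'
#' @inheritParams generate_stimulus_set
#' @param codebook_sizes Label inventory sizes `(K1, K2, K3)`.
#' @return An object of class `hpp_symbolic_set` with the same structure as
#'   an `hpp_stimulus_set` but holding `hpp_label_stream`s.
#' @export
generate_symbolic_set <- function(words, speaker,
                                  design = default_stimulus_design(),
                                  codebook_sizes = c(150L, 150L, 100L),
                                  seed = 1L) {
  if (length(words) < design$n_words) {
    stop_param("need ", design$n_words, " word specs, got ", length(words))
  }
  words <- words[seq_len(design$n_words)]
  wids <- vapply(words, function(w) w$word_id, character(1))
  names(words) <- wids
  dur <- design$sentence_duration_s
  sen_frames <- function(s) {
    as.integer(round(with_seed(s, stats::runif(1, dur[1], dur[2])) * 100))
  }
  tok_seed <- derive_seed(seed, "tokens")
  sen_seed <- derive_seed(seed, "sentences")
  bg_seed <- derive_seed(seed, "background")

  tokens <- lapply(seq_along(words), function(wi) {
    lapply(seq_len(design$n_tokens), function(ti) {
      L <- length(symbolic_word_pattern(words[[wi]], codebook_sizes,
                                        speaker$rate_factor)[[1]])
      generate_symbolic_stream(words[[wi]], speaker, n_frames = L + 10L,
                               codebook_sizes = codebook_sizes,
                               seed = tok_seed + wi * 1000L + ti)
    })
  })
  names(tokens) <- wids

  sentences <- lapply(seq_along(words), function(wi) {
    lapply(seq_len(design$n_sentences), function(si) {
      nf <- sen_frames(sen_seed + wi * 100000L + si * 7L)
      st <- generate_symbolic_stream(words[[wi]], speaker, n_frames = nf,
                                     codebook_sizes = codebook_sizes,
                                     seed = sen_seed + wi * 1000L + si)
      list(stream = st, duration_s = attr(st, "duration_s"),
           word_onset_s = (attr(st, "word_onset_frame") - 1L) / 100,
           word_offset_s = attr(st, "word_offset_frame") / 100)
    })
  })
  names(sentences) <- wids

  background <- lapply(seq_len(design$n_background), function(bi) {
    nf <- sen_frames(bg_seed + 77L * bi)
    generate_symbolic_stream(NULL, speaker, n_frames = nf,
                             codebook_sizes = codebook_sizes,
                             seed = bg_seed + bi)
  })

  noise <- label_stream(rep(1L, 100L), rep(1L, 100L), rep(1L, 100L),
                        codebook_sizes)

  structure(list(isolated_tokens = tokens, sentences = sentences,
                 background = background, noise = noise, speaker = speaker,
                 design = design, words = words,
                 codebook_sizes = as.integer(codebook_sizes),
                 seed = as.integer(seed)),
            class = "hpp_symbolic_set")
}

#' @export
print.hpp_symbolic_set <- function(x, ...) {
  cat(sprintf(paste0("<hpp_symbolic_set: %d words x %d tokens, ",
                     "%d words x %d sentences, %d background; ",
                     "codebooks %s; speaker %s>\n"),
              length(x$isolated_tokens), x$design$n_tokens,
              length(x$sentences), x$design$n_sentences,
              length(x$background),
              paste(x$codebook_sizes, collapse = "/"),
              x$speaker$speaker_id))
  invisible(x)
}
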