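#' Speaker profile for the synthetic stimulus generator
#'
#' A speaker is modeled by the two signal properties the downstream
#' encoding is sensitive to: speech rate (the co-occurrence histograms use
#' fixed time lags, so a rate change alters every lagged count) and a warp
#' of the spectral envelope (a crude stand-in for vocal-tract differences).
#' Voice pitch is deliberately absent: the cepstral front end does not
#' represent it.
#'
#' @param speaker_id Character label, e.g. `"F1"`.
#' @param rate_factor Time-scale multiplier in `[0.5, 2]`; 1 is nominal.
#'   Values above 1 mean slower speech (longer utterances).
#' @param spectral_shift Relative formant/envelope warp; 0 is nominal. In
#'   symbolic (label-stream) mode its magnitude sets the label-noise
#'   probability instead.
#' @param seed Integer seed owned by this speaker; all per-speaker random
#'   variation is derived from it.
#' @return An object of class `hpp_speaker`.
#' @examples
#' speaker_profile("F1", rate_factor = 0.93, spectral_shift = 0.1, seed = 7)
#' @export
speaker_profile <- function(speaker_id, rate_factor = 1.0,
                            spectral_shift = 0.0, seed = 1L) {
  if (!is.character(speaker_id) || length(speaker_id) != 1L) {
    stop_param("speaker_id must be a single character label")
  }
  if (!is.numeric(rate_factor) || length(rate_factor) != 1L ||
      !is.finite(rate_factor) || rate_factor < 0.5 || rate_factor > 2.0) {
    stop_param("rate_factor must lie in [0.5, 2.0], got ", rate_factor)
  }
  if (!is.numeric(spectral_shift) || length(spectral_shift) != 1L ||
      !is.finite(spectral_shift)) {
    stop_param("spectral_shift must be a finite number")
  }
  structure(
    list(speaker_id = speaker_id,
         rate_factor = as.numeric(rate_factor),
         spectral_shift = as.numeric(spectral_shift),
         seed = as.integer(seed)),
    class = "hpp_speaker")
}

#' @export
print.hpp_speaker <- function(x, ...) {
  cat(sprintf("<hpp_speaker %s: rate %.2f, spectral shift %+.2f, seed %d>\n",
              x$speaker_id, x$rate_factor, x$spectral_shift, x$seed))
  invisible(x)
}

#' Pseudo-word template
#'
#' A word is a short sequence of pseudo-syllable segments, each described by
#' a duration and a coarse spectral envelope (two resonance frequencies and
#' a voicing proportion).  No phonetic content is intended: the model only
#' consumes spectral envelopes, so pseudo-syllables with distinct envelopes
#' play the role of distinct monosyllabic words.
#'
#' @param word_id Character label, e.g. `"frog"`.
#' @param template Data frame with columns `duration_ms`, `f1`, `f2`
#'   (resonance frequencies, Hz) and `voicing` in `[0, 1]` (harmonic vs.
#'   noise excitation mix).
#' @return An object of class `hpp_word`.
#' @details Total template duration must lie in 300--700 ms at nominal
#'   speech rate, matching the short stop-consonant words used in headturn
#'   studies.
#' @examples
#' word_spec("frog", data.frame(duration_ms = c(60, 240, 80),
#'                              f1 = c(300, 650, 400), f2 = c(1800, 1100, 1500),
#'                              voicing = c(0.1, 1, 0.4)))
#' @export
word_spec <- function(word_id, template) {
  if (!is.character(word_id) || length(word_id) != 1L) {
    stop_param("word_id must be a single character label")
  }
  need <- c("duration_ms", "f1", "f2", "voicing")
  if (!is.data.frame(template) || !all(need %in% names(template))) {
    stop_param("template must be a data frame with columns ",
               paste(need, collapse = ", "))
  }
  if (any(!is.finite(as.matrix(template[need])))) {
    stop_param("template descriptors must be finite")
  }
  tot <- sum(template$duration_ms)
  if (tot < 300 || tot > 700) {
    stop_param("template duration must be 300-700 ms at nominal rate, got ",
               tot, " ms")
  }
  if (any(template$voicing < 0 | template$voicing > 1)) {
    stop_param("voicing must lie in [0, 1]")
  }
  structure(list(word_id = word_id, template = template[need]),
            class = "hpp_word")
}

word_duration_ms <- function(word) sum(word$template$duration_ms)

#' Default inventory of four target pseudo-words
#'
#' Four consonant-vowel-consonant style templates with pairwise distinct
#' segment descriptors, mirroring the two familiarization pairs used in
#' classic headturn experiments (two words familiarized, two novel).
#'
#' @return A named list of four [word_spec()] objects.
#' @export
default_word_specs <- function() {
  mk <- function(id, f1v, f2v, d) {
    word_spec(id, data.frame(
      duration_ms = d,
      f1 = c(350, f1v, 420),
      f2 = c(1900, f2v, 1400),
      voicing = c(0.15, 1.0, 0.35)))
  }
  list(
    frog = mk("frog", 620, 1150, c(70, 260, 90)),
    doll = mk("doll", 540, 950,  c(60, 300, 80)),
    duck = mk("duck", 700, 1300, c(60, 220, 100)),
    ball = mk("ball", 480, 850,  c(80, 280, 70)))
}

#' Mono waveform container
#'
#' @param samples Numeric vector of samples, peak magnitude at most 1.
#' @param sample_rate_hz Positive integer sampling rate.
#' @return An object of class `hpp_waveform`.
#' @export
waveform <- function(samples, sample_rate_hz = 16000L) {
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    stop_data("samples must be finite numerics")
  }
  if (length(samples) && max(abs(samples)) > 1 + 1e-9) {
    stop_data("peak amplitude must not exceed 1")
  }
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    stop_param("sample_rate_hz must be positive")
  }
  structure(list(samples = as.numeric(samples),
                 sample_rate_hz = as.integer(sample_rate_hz)),
            class = "hpp_waveform")
}

#' @export
print.hpp_waveform <- function(x, ...) {
  cat(sprintf("<hpp_waveform: %.3f s at %d Hz>\n",
              length(x$samples) / x$sample_rate_hz, x$sample_rate_hz))
  invisible(x)
}

wave_duration_s <- function(w) length(w$samples) / w$sample_rate_hz

# --- low-level synthesis -----------------------------------------------

# One pseudo-syllable segment: additive harmonics of a fixed fundamental,
# amplitude-shaped by Gaussian bumps at the two (warped) resonances, mixed
# with resonator-filtered white noise, under a raised-cosine edge envelope.
synth_segment <- function(duration_ms, f1, f2, voicing, spectral_shift,
                          sample_rate) {
  n <- max(1L, round(duration_ms / 1000 * sample_rate))
  t <- seq_len(n) / sample_rate
  warp <- 1 + spectral_shift
  f1w <- min(f1 * warp, sample_rate / 2 * 0.9)
  f2w <- min(f2 * warp, sample_rate / 2 * 0.9)
  f0 <- 160
  nh <- floor(sample_rate / 2 / f0) - 1L
  hfreq <- f0 * seq_len(nh)
  amp <- exp(-((hfreq - f1w) / 220)^2) + 0.7 * exp(-((hfreq - f2w) / 350)^2)
  amp <- amp / sum(amp)
  voiced <- colSums(amp * sin(2 * pi * outer(hfreq, t)))
  # two-pole resonators excited by white noise
  resonate <- function(x, f, r = 0.97) {
    a <- c(2 * r * cos(2 * pi * f / sample_rate), -r^2)
    as.numeric(stats::filter(x, a, method = "recursive"))
  }
  e <- stats::rnorm(n)
  noise <- resonate(e, f1w) + 0.7 * resonate(e, f2w)
  noise <- noise / (stats::sd(noise) + 1e-12) * 0.3
  seg <- voicing * voiced / (max(abs(voiced)) + 1e-12) +
    (1 - voicing) * noise
  # 10 ms raised-cosine ramps (shorter for very short segments)
  nr <- min(round(0.01 * sample_rate), floor(n / 2))
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    seg[seq_len(nr)] <- seg[seq_len(nr)] * ramp
    seg[n - nr + seq_len(nr)] <- seg[n - nr + seq_len(nr)] * rev(ramp)
  }
  seg
}

normalize_peak <- function(x, peak = 0.95) {
  m <- max(abs(x))
  if (m > 0) x * (peak / m) else x
}

# Fixed filler-syllable inventory, shared across speakers so that carrier
# sentences differ between speakers only through rate and spectral warp.
filler_inventory <- function() {
  data.frame(
    duration_ms = c(140, 180, 120, 200, 160, 220, 130, 170),
    f1 = c(420, 560, 700, 380, 640, 500, 330, 590),
    f2 = c(2100, 1700, 1200, 2400, 1000, 1500, 2600, 1850),
    voicing = c(0.9, 0.7, 1.0, 0.5, 0.8, 0.6, 0.95, 0.75))
}

synth_template <- function(template, speaker, sample_rate) {
  segs <- lapply(seq_len(nrow(template)), function(i) {
    synth_segment(template$duration_ms[i] * speaker$rate_factor,
                  template$f1[i], template$f2[i], template$voicing[i],
                  speaker$spectral_shift, sample_rate)
  })
  unlist(segs, use.names = FALSE)
}

#' Synthesize one isolated token of a word
#'
#' Duration equals the template duration scaled by the speaker's rate
#' factor and a seeded token-level jitter (default up to +/-10%), emulating
#' natural token-to-token variation among the isolated familiarization
#' tokens.
#'
#' @param word An [word_spec()] object.
#' @param speaker An [speaker_profile()] object.
#' @param jitter_seed Integer; tokens with different seeds differ.
#' @param jitter Maximum relative duration jitter (default 0.1).
#' @param sample_rate Sampling rate in Hz.
#' @return An `hpp_waveform`.
#' @export
synthesize_word_token <- function(word, speaker, jitter_seed,
                                  jitter = 0.1, sample_rate = 16000L) {
  if (!inherits(word, "hpp_word")) stop_param("word must be an hpp_word")
  if (!inherits(speaker, "hpp_speaker")) {
    stop_param("speaker must be an hpp_speaker")
  }
  with_seed(jitter_seed, {
    j <- if (jitter > 0) stats::runif(1, -jitter, jitter) else 0
    tpl <- word$template
    tpl$duration_ms <- tpl$duration_ms * (1 + j)
    waveform(normalize_peak(synth_template(tpl, speaker, sample_rate)),
             sample_rate)
  })
}

#' Synthesize a carrier sentence with one embedded word
#'
#' Filler pseudo-syllables drawn from a fixed shared inventory surround a
#' single realization of the target word at a seeded position.  The
#' realized total duration falls within +/-10% of the target and the word
#' onset/offset are returned as an annotation.
#'
#' @param word An [word_spec()] (the embedded target).
#' @param speaker An [speaker_profile()].
#' @param target_duration_s Requested sentence duration in seconds.
#' @param seed Integer seed controlling filler choice and word position.
#' @param sample_rate Sampling rate in Hz.
#' @return A list with elements `wave` (`hpp_waveform`), `word_onset_s`,
#'   `word_offset_s`.
#' @export
synthesize_sentence <- function(word, speaker, target_duration_s,
                                seed, sample_rate = 16000L) {
  if (!inherits(word, "hpp_word")) stop_param("word must be an hpp_word")
  word_s <- word_duration_ms(word) / 1000 * speaker$rate_factor
  if (target_duration_s < word_s) {
    stop_param("target duration ", target_duration_s,
               " s is shorter than the embedded word (", round(word_s, 3),
               " s)")
  }
  inv <- filler_inventory()
  with_seed(seed, {
    filler_s <- target_duration_s - word_s
    idx <- integer(0)
    acc <- 0
    while (acc < filler_s - 0.05) {
      k <- sample.int(nrow(inv), 1L)
      idx <- c(idx, k)
      acc <- acc + inv$duration_ms[k] / 1000 * speaker$rate_factor
    }
    pos <- if (length(idx)) sample.int(length(idx) + 1L, 1L) - 1L else 0L
    pre <- idx[seq_len(pos)]
    post <- if (pos < length(idx)) idx[(pos + 1L):length(idx)] else integer(0)
    synth_fill <- function(ii) {
      if (!length(ii)) return(numeric(0))
      synth_template(inv[ii, , drop = FALSE], speaker, sample_rate)
    }
    a <- synth_fill(pre)
    b <- synth_template(word$template, speaker, sample_rate)
    c_ <- synth_fill(post)
    onset <- length(a) / sample_rate
    offset <- onset + length(b) / sample_rate
    list(wave = waveform(normalize_peak(c(a, b, c_)), sample_rate),
         word_onset_s = onset, word_offset_s = offset)
  })
}

#' Generate a complete synthetic stimulus set for one speaker
#'
#' Emulates the material of a two-phase headturn experiment: isolated
#' familiarization tokens for each target word, carrier sentences embedding
#' each word once, background utterances that contain no target word, and a
#' single low-level noise recording.  Defaults: 5 tokens and 24 sentences
#' per word, 100 background utterances, 1 noise recording, mean sentence
#' duration drawn uniformly from 2.7--3.0 s.
#'
#' @param words List of exactly `design$n_words` [word_spec()] objects.
#' @param speaker An [speaker_profile()].
#' @param design List of counts and durations; see
#'   [default_stimulus_design()].
#' @param seed Master seed for the set; fixed seed gives a bit-identical
#'   set.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `hpp_stimulus_set` with fields
#'   `isolated_tokens` (per word, list of waveforms), `sentences` (per
#'   word, list of annotated sentences), `background`, `noise`, `speaker`.
#' @export
generate_stimulus_set <- function(words, speaker,
                                  design = default_stimulus_design(),
                                  seed = 1L, sample_rate = 16000L) {
  if (length(words) < design$n_words) {
    stop_param("need ", design$n_words, " word specs, got ", length(words))
  }
  words <- words[seq_len(design$n_words)]
  if (any(unlist(lapply(design[c("n_tokens", "n_sentences", "n_background",
                                 "n_noise")], function(x) x < 0)))) {
    stop_param("design counts must be non-negative")
  }
  wids <- vapply(words, function(w) w$word_id, character(1))
  names(words) <- wids
  tok_seed <- derive_seed(seed, "tokens")
  sen_seed <- derive_seed(seed, "sentences")
  bg_seed <- derive_seed(seed, "background")

  tokens <- lapply(seq_along(words), function(wi) {
    lapply(seq_len(design$n_tokens), function(ti) {
      synthesize_word_token(words[[wi]], speaker,
                            jitter_seed = tok_seed + wi * 1000L + ti,
                            sample_rate = sample_rate)
    })
  })
  names(tokens) <- wids

  dur_range <- design$sentence_duration_s
  sentences <- lapply(seq_along(words), function(wi) {
    lapply(seq_len(design$n_sentences), function(si) {
      d <- with_seed(sen_seed + wi * 100000L + si * 7L,
                     stats::runif(1, dur_range[1], dur_range[2]))
      synthesize_sentence(words[[wi]], speaker, d,
                          seed = sen_seed + wi * 1000L + si,
                          sample_rate = sample_rate)
    })
  })
  names(sentences) <- wids

  inv <- filler_inventory()
  background <- lapply(seq_len(design$n_background), function(bi) {
    with_seed(bg_seed + bi, {
      d <- stats::runif(1, dur_range[1], dur_range[2])
      n_syl <- max(1L, round(d * 1000 / mean(inv$duration_ms) /
                               speaker$rate_factor))
      idx <- sample.int(nrow(inv), n_syl, replace = TRUE)
      waveform(normalize_peak(
        synth_template(inv[idx, , drop = FALSE], speaker, sample_rate)),
        sample_rate)
    })
  })

  noise <- with_seed(derive_seed(seed, "noise"), {
    n <- round(1.0 * sample_rate)
    waveform(normalize_peak(stats::rnorm(n), peak = 0.02), sample_rate)
  })

  structure(list(isolated_tokens = tokens, sentences = sentences,
                 background = background, noise = noise, speaker = speaker,
                 design = design, words = words, seed = as.integer(seed)),
            class = "hpp_stimulus_set")
}

#' Default stimulus design (counts and durations)
#'
#' @param n_words Number of target words (4).
#' @param n_tokens Isolated tokens per word (5).
#' @param n_sentences Carrier sentences per word (24).
#' @param n_background Background utterances (100).
#' @param n_noise Noise recordings (1).
#' @param sentence_duration_s Range the per-sentence target duration is
#'   drawn from (2.7--3.0 s).
#' @return A list of design constants.
#' @export
default_stimulus_design <- function(n_words = 4L, n_tokens = 5L,
                                    n_sentences = 24L, n_background = 100L,
                                    n_noise = 1L,
                                    sentence_duration_s = c(2.7, 3.0)) {
  list(n_words = as.integer(n_words), n_tokens = as.integer(n_tokens),
       n_sentences = as.integer(n_sentences),
       n_background = as.integer(n_background), n_noise = as.integer(n_noise),
       sentence_duration_s = sentence_duration_s)
}

#' @export
print.hpp_stimulus_set <- function(x, ...) {
  cat(sprintf(paste0("<hpp_stimulus_set: %d words x %d tokens, ",
                     "%d words x %d sentences, %d background, %d noise; ",
                     "speaker %s>\n"),
              length(x$isolated_tokens), x$design$n_tokens,
              length(x$sentences), x$design$n_sentences,
              length(x$background), x$design$n_noise,
              x$speaker$speaker_id))
  invisible(x)
}
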