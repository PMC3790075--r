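#' Number of analysis frames for a given duration
#'
#' The front end uses 20 ms windows with a 10 ms hop, i.e. 100 short-time
#' spectra per second in the long run.
#'
#' @param duration_ms Utterance duration in milliseconds (at least 20).
#' @return Integer frame count `floor((duration_ms - 20) / 10) + 1`.
#' @examples
#' frame_count(1000)  # 99
#' @export
frame_count <- function(duration_ms) {
  if (!is.numeric(duration_ms) || any(duration_ms < 20)) {
    stop_data("input shorter than one 20 ms analysis window")
  }
  as.integer(floor((duration_ms - 20) / 10) + 1)
}

# Triangular mel filterbank, `n_mel` filters from 0 Hz to Nyquist.
mel_filterbank <- function(n_mel, n_fft, sample_rate) {
  hz2mel <- function(f) 2595 * log10(1 + f / 700)
  mel2hz <- function(m) 700 * (10^(m / 2595) - 1)
  mel_pts <- seq(hz2mel(0), hz2mel(sample_rate / 2), length.out = n_mel + 2)
  hz_pts <- mel2hz(mel_pts)
  bins <- floor((n_fft + 1) * hz_pts / sample_rate)
  fb <- matrix(0, n_mel, n_fft %/% 2 + 1)
  for (m in seq_len(n_mel)) {
    lo <- bins[m]; ce <- bins[m + 1]; hi <- bins[m + 2]
    for (k in seq(lo, hi)) {
      if (k < 0 || k > n_fft %/% 2) next
      v <- if (k < ce) (k - lo) / max(1, ce - lo) else
        (hi - k) / max(1, hi - ce)
      fb[m, k + 1] <- max(0, v)
    }
  }
  fb
}

# DCT-II matrix (orthogonal), rows = cepstral indices 0..n_cep-1.
dct_matrix <- function(n_cep, n_mel) {
  d <- sqrt(2 / n_mel) *
    cos(pi / n_mel * outer(0:(n_cep - 1), (1:n_mel) - 0.5))
  d[1, ] <- d[1, ] / sqrt(2)
  d
}

#' Cepstral features: 13 MFCCs with first and second differences
#'
#' Converts a mono waveform into per-frame static mel-frequency cepstral
#' coefficients plus their first (delta) and second (delta-delta) temporal
#' differences -- 3 x 13 = 39 numbers per frame.  Framing is 20 ms windows
#' with 10 ms hop (Hamming window, pre-emphasis 0.97, 26-filter mel bank to
#' Nyquist, log floor 1e-10 for silence robustness, DCT-II cepstra 0--12).
#' Deltas are backward first differences with a zero-padded first frame;
#' delta-deltas repeat the scheme on the deltas.
#'
#' @param w An [waveform()] of at least 20 ms.
#' @param n_mel Number of mel filters (26).
#' @param n_cep Number of cepstra kept (13, including the 0th).
#' @param preemph Pre-emphasis coefficient (0.97).
#' @return An object of class `hpp_features`: list of three `13 x T`
#'   matrices `static`, `delta`, `deltadelta` plus frame timing metadata.
#' @export
compute_features <- function(w, n_mel = 26L, n_cep = 13L, preemph = 0.97) {
  if (!inherits(w, "hpp_waveform")) stop_param("w must be an hpp_waveform")
  x <- w$samples
  if (any(!is.finite(x))) stop_data("waveform contains non-finite samples")
  sr <- w$sample_rate_hz
  dur_ms <- length(x) / sr * 1000
  if (dur_ms < 20) stop_data("input shorter than one 20 ms analysis window")
  n_win <- round(0.020 * sr)
  n_hop <- round(0.010 * sr)
  n_frames <- frame_count(dur_ms)
  n_fft <- 2^ceiling(log2(n_win))
  fb <- mel_filterbank(n_mel, n_fft, sr)
  dct <- dct_matrix(n_cep, n_mel)
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(n_win - 1)) / (n_win - 1))

  # frame matrix with per-frame pre-emphasis (first sample of each frame
  # emphasized against the sample preceding the frame)
  xp <- c(0, x)
  frames <- vapply(seq_len(n_frames), function(i) {
    s <- (i - 1) * n_hop + 1
    seg <- x[s:(s + n_win - 1)] - preemph * xp[s:(s + n_win - 1)]
    seg * ham
  }, numeric(n_win))
  spec <- stats::mvfft(rbind(frames, matrix(0, n_fft - n_win, n_frames)))
  power <- abs(spec[seq_len(n_fft %/% 2 + 1), , drop = FALSE])^2
  logE <- log(pmax(fb %*% power, 1e-10))
  static <- dct %*% logE
  delta <- cbind(0, static[, -1, drop = FALSE] -
                   static[, -ncol(static), drop = FALSE])
  deltadelta <- cbind(0, delta[, -1, drop = FALSE] -
                        delta[, -ncol(delta), drop = FALSE])
  if (ncol(static) == 1L) {
    delta <- matrix(0, n_cep, 1L)
    deltadelta <- matrix(0, n_cep, 1L)
  }
  structure(list(static = static, delta = delta, deltadelta = deltadelta,
                 frame_hop_ms = 10, frame_len_ms = 20),
            class = "hpp_features")
}

#' @export
print.hpp_features <- function(x, ...) {
  cat(sprintf("<hpp_features: %d frames x (13 + 13 + 13) coefficients>\n",
              ncol(x$static)))
  invisible(x)
}
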