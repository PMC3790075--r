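#' Behavior-generation parameters
#'
#' @param alpha Exponential decay rate of attention per second (> 0);
#'   interpretable as the inverse of the attention span.  Small values
#'   mean long attention spans.
#' @param theta Experimenter threshold (> 0): the attention level above
#'   which the head counts as sufficiently turned.
#' @param rho Onset offset (default 0.4): attention at trial start is
#'   `theta + rho`, guaranteeing an initial headturn.
#' @param away_limit_s The abort rule (default 2 s): a below-threshold
#'   interval longer than this terminates the trial.
#' @param mode `"superpose"` (default): pulses add to the decayed
#'   attention, the literal impulse-train-through-exponential reading;
#'   `"reset"`: each pulse replaces the attention level ("attention is
#'   renewed").  Both readings are supported.
#' @return An object of class `hpp_behavior_params`.
#' @export
behavior_params <- function(alpha = 0.1, theta = 0.4, rho = 0.4,
                            away_limit_s = 2.0,
                            mode = c("superpose", "reset")) {
  mode <- match.arg(mode)
  if (!is.numeric(alpha) || alpha <= 0) stop_param("alpha must be > 0")
  if (!is.numeric(theta) || theta <= 0) stop_param("theta must be > 0")
  if (!is.numeric(rho) || rho <= 0) stop_param("rho must be > 0")
  if (!is.numeric(away_limit_s) || away_limit_s <= 0) {
    stop_param("away_limit_s must be > 0")
  }
  structure(list(alpha = alpha, theta = theta, rho = rho,
                 away_limit_s = away_limit_s, mode = mode),
            class = "hpp_behavior_params")
}

#' Build the familiarity pulse train of a test passage
#'
#' The discrete familiarity scores, available at the end of each sentence,
#' become pulses at the cumulative sentence-end times; an onset pulse of
#' amplitude `theta + rho` at `t = 0` models the initial interest in the
#' flashing lamp.  Sentence scores are taken on the proportion scale
#' (`score_pct / 100`), commensurate with the threshold grid.
#'
#' @param scores_pct Familiarity scores (percent) of the `N` sentences.
#' @param durations_s Their durations in seconds (all > 0).
#' @param params An [behavior_params()].
#' @return An object of class `hpp_pulse_train` with `pulse_times_s`
#'   `(0, d1, d1+d2, ...)`, `amplitudes` `(theta+rho, s1/100, ...)` and
#'   `passage_duration_s`.
#' @export
build_pulse_train <- function(scores_pct, durations_s, params) {
  if (!inherits(params, "hpp_behavior_params")) {
    stop_param("params must be hpp_behavior_params")
  }
  if (!length(scores_pct) || !length(durations_s)) {
    stop_param("scores and durations must be non-empty")
  }
  if (length(scores_pct) != length(durations_s)) {
    stop_param("scores and durations differ in length")
  }
  if (any(durations_s <= 0)) stop_param("durations must be positive")
  if (any(scores_pct < 0)) stop_param("scores must be non-negative")
  structure(list(
    pulse_times_s = c(0, cumsum(durations_s)),
    amplitudes = c(params$theta + params$rho, scores_pct / 100),
    passage_duration_s = sum(durations_s),
    theta = params$theta, rho = params$rho),
    class = "hpp_pulse_train")
}

#' @export
print.hpp_pulse_train <- function(x, ...) {
  cat(sprintf(paste0("<hpp_pulse_train: onset %.2f + %d sentence pulses ",
                     "over %.2f s>\n"),
              x$amplitudes[1], length(x$amplitudes) - 1L,
              x$passage_duration_s))
  invisible(x)
}

#' Evaluate the attention function
#'
#' In superpose mode the attention at `t` is
#' `sum_\{i : t_i <= t\} a_i exp(-alpha (t - t_i))`; in reset mode it is
#' `a_k exp(-alpha (t - t_k))` for the last pulse at or before `t`.
#'
#' @param pt An [build_pulse_train()] result.
#' @param alpha Decay rate (> 0).
#' @param t Time(s) in `[0, passage_duration_s]` (vectorized).
#' @param mode `"superpose"` or `"reset"`.
#' @return Attention value(s) at `t`.
#' @export
attention_at <- function(pt, alpha, t, mode = c("superpose", "reset")) {
  mode <- match.arg(mode)
  if (!inherits(pt, "hpp_pulse_train")) {
    stop_param("pt must be an hpp_pulse_train")
  }
  if (any(t < 0 | t > pt$passage_duration_s + 1e-12)) {
    stop_param("t outside [0, passage duration]")
  }
  vapply(t, function(tt) {
    on <- pt$pulse_times_s <= tt + 1e-12
    if (mode == "superpose") {
      sum(pt$amplitudes[on] * exp(-alpha * (tt - pt$pulse_times_s[on])))
    } else {
      k <- max(which(on))
      pt$amplitudes[k] * exp(-alpha * (tt - pt$pulse_times_s[k]))
    }
  }, numeric(1))
}

#' Simulated listening time of a test passage
#'
#' Walks the attention trace segment by segment (between pulses attention
#' is a single decaying exponential in both modes, so threshold crossings
#' have closed forms), accumulating the time attention is at or above
#' `theta`.  If attention stays below `theta` for more than
#' `away_limit_s` consecutive seconds the trial is terminated: listening
#' stops and later pulses are ignored.  A pulse arriving before the limit
#' elapses takes effect and can rescue the trial, as the audio keeps
#' playing while the head is briefly turned away.  Time below threshold is
#' never counted.
#'
#' @param pt An [build_pulse_train()] result.
#' @param params An [behavior_params()] (its `theta`, `alpha`, `mode` and
#'   `away_limit_s` are used).
#' @return List with `listening_s` (in `[0, passage_duration_s]`) and
#'   `terminated_at_s` (start of the fatal below-threshold interval, or
#'   `NA` if the passage ran to its end).
#' @export
listening_time <- function(pt, params) {
  if (!inherits(pt, "hpp_pulse_train")) {
    stop_param("pt must be an hpp_pulse_train")
  }
  if (!inherits(params, "hpp_behavior_params")) {
    stop_param("params must be hpp_behavior_params")
  }
  listening_core(pt$pulse_times_s, pt$amplitudes, pt$passage_duration_s,
                 params$alpha, params$theta, params$away_limit_s,
                 params$mode == "superpose")
}

# The segment walk shared by listening_time() and the grid sweep; between
# pulses attention is a single exponential in both modes, so the theta
# crossing per segment is closed-form.
listening_core <- function(times, amps, t_end, alpha, theta, away,
                           superpose) {
  n <- length(times)
  listening <- 0
  below_start <- NA_real_
  terminated <- NA_real_
  a_end <- 0  # attention at the end of the previous segment
  for (i in seq_len(n)) {
    t_i <- times[i]
    if (!is.na(below_start) && t_i - below_start > away) {
      terminated <- below_start
      break
    }
    a <- if (superpose) a_end + amps[i] else amps[i]
    if (a >= theta) {
      below_start <- NA_real_
    } else if (is.na(below_start)) {
      below_start <- t_i
    }
    t_next <- if (i < n) times[i + 1L] else t_end
    seg <- t_next - t_i
    if (a >= theta) {
      t_above <- min(seg, log(a / theta) / alpha)
      listening <- listening + max(0, t_above)
      if (t_above < seg) below_start <- t_i + t_above
    }
    a_end <- a * exp(-alpha * seg)
    if (i == n && is.na(terminated) && !is.na(below_start) &&
        t_end - below_start > away) {
      terminated <- below_start
    }
  }
  list(listening_s = listening, terminated_at_s = terminated)
}
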