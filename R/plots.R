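#' Hinton-style plot of a significance grid
#'
#' One rectangle per significant `(alpha, theta)` cell; rectangle size
#' encodes the significance level (larger = smaller p), black rectangles a
#' familiarity preference, grey a novelty preference.
#'
#' @param x An [run_grid()] result.
#' @param max_cex Rectangle size of the most significant cell, as a
#'   fraction of the grid step (default 0.95).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.hpp_grid <- function(x, max_cex = 0.95, ...) {
  da <- diff(sort(unique(x$alpha)))
  dt <- diff(sort(unique(x$theta)))
  da <- if (length(da)) min(da) else 0.01
  dt <- if (length(dt)) min(dt) else 0.01
  graphics::plot(NA, xlim = range(x$alpha) + c(-da, da),
                 ylim = range(x$theta) + c(-dt, dt),
                 xlab = expression(alpha ~ "(attention decay rate / s)"),
                 ylab = expression(theta ~ "(experimenter threshold)"),
                 main = sprintf("Listening-time preference (%s scores)",
                                attr(x, "score_mode")), ...)
  sig <- x[x$sign != "none", , drop = FALSE]
  if (nrow(sig)) {
    # size from p: p = 0.05 -> small, p -> 0 -> max
    sz <- (1 - sig$p / 0.05)
    w <- da * max_cex * (0.25 + 0.75 * sz) / 2
    h <- dt * max_cex * (0.25 + 0.75 * sz) / 2
    graphics::rect(sig$alpha - w, sig$theta - h, sig$alpha + w,
                   sig$theta + h,
                   col = ifelse(sig$sign == "familiar", "black", "grey60"),
                   border = NA)
  }
  graphics::legend("topright", legend = c("familiar", "novel"),
                   fill = c("black", "grey60"), bty = "n")
  invisible(x)
}

#' Plot an attention function with its threshold
#'
#' Draws the continuous attention trace of a pulse train for one or more
#' decay rates, with the experimenter threshold as a dashed line --- the
#' standard way to visualize how familiarity pulses and attention decay
#' turn into listening time.
#'
#' @param x An [build_pulse_train()] result.
#' @param alpha Decay rate(s) to draw.
#' @param theta Threshold to draw (defaults to the train's).
#' @param mode `"superpose"` or `"reset"`.
#' @param dt Time resolution in seconds (0.001).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.hpp_pulse_train <- function(x, alpha = c(0.1, 0.25), theta = x$theta,
                                 mode = "superpose", dt = 0.001, ...) {
  tt <- seq(0, x$passage_duration_s, by = dt)
  traces <- lapply(alpha, function(a) attention_at(x, a, tt, mode = mode))
  graphics::plot(NA, xlim = c(0, x$passage_duration_s),
                 ylim = c(0, max(unlist(traces), theta) * 1.05),
                 xlab = "time (s)", ylab = "attention", ...)
  for (i in seq_along(traces)) {
    graphics::lines(tt, traces[[i]], lty = i)
  }
  graphics::abline(h = theta, lty = 3, col = "grey40")
  graphics::legend("topright", bty = "n", lty = seq_along(alpha),
                   legend = sprintf("alpha = %.2f", alpha))
  invisible(x)
}

#' Attention trace of a passage as a data frame
#'
#' @param pt An [build_pulse_train()] result.
#' @param alpha Decay rate.
#' @param mode `"superpose"` or `"reset"`.
#' @param dt Time step in seconds (0.001).
#' @return Data frame with columns `t` and `attention`, suitable for CSV
#'   export.
#' @export
attention_trace <- function(pt, alpha, mode = "superpose", dt = 0.001) {
  tt <- seq(0, pt$passage_duration_s, by = dt)
  data.frame(t = tt, attention = attention_at(pt, alpha, tt, mode = mode))
}
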