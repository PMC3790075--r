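#' Generalized Kullback--Leibler divergence between count vectors
#'
#' `D(v || a) = sum_d [ v_d log(v_d / a_d) - v_d + a_d ]`, with `v_d = 0`
#' terms contributing `a_d`.  Non-negative, and zero iff the vectors are
#' equal.  Where `a_d` underflows to zero against a positive `v_d`, the
#' divergence is kept finite by an epsilon floor on `a_d`.
#'
#' @param v,approx Non-negative numeric vectors of equal length (`v` may be
#'   an `hpp_hac`).
#' @param eps Floor applied to `approx` where `v > 0` (default 1e-12).
#' @return A single non-negative number.
#' @export
kl_divergence <- function(v, approx, eps = 1e-12) {
  if (inherits(v, "hpp_hac")) v <- as.numeric(v$counts)
  v <- as.numeric(v); approx <- as.numeric(approx)
  if (length(v) != length(approx)) stop_param("dimension mismatch")
  if (any(v < 0) || any(approx < 0)) {
    stop_param("vectors must be entrywise non-negative")
  }
  pos <- v > 0
  a <- pmax(approx[pos], eps)
  sum(v[pos] * log(v[pos] / a) - v[pos]) + sum(approx)
}

#' Decompose a test utterance over the episodic memory
#'
#' Approximates a HAC-encoded test stimulus `v` as a non-negative weighted
#' sum of all memory entries, `v ~ W h`, by minimizing the generalized
#' Kullback--Leibler divergence with the dictionary `W` held fixed (no
#' learning): only the weights are updated, with the standard
#' multiplicative rule
#' `h <- h * (W' (v / (W h))) / (W' 1)`.
#' The resulting weight of an entry measures its contribution to
#' explaining the test stimulus.
#'
#' Weights are initialized uniformly at `1/M` (deterministic), dictionary
#' columns are normalized to unit sum by default so that weights are
#' comparable across entries of different utterance lengths, and iteration
#' stops when the relative divergence decrease falls below `tol`.
#'
#' @param v An [encode_hac()] vector (or non-negative numeric vector) with
#'   positive total count.
#' @param bank An [build_memory()] memory (usually after [familiarize()]).
#' @param tol Relative divergence-decrease stopping tolerance (1e-6).
#' @param max_iter Iteration cap (500).
#' @param normalize_columns Normalize dictionary columns to unit sum
#'   (default `TRUE`).
#' @param eps Epsilon floor used in divisions (1e-12).
#' @return An object of class `hpp_decomposition`: `weights` (length-`M`
#'   non-negative vector), `divergence_trace` (non-increasing), `n_iter`,
#'   `converged`.
#' @export
decompose <- function(v, bank, tol = 1e-6, max_iter = 500L,
                      normalize_columns = TRUE, eps = 1e-12) {
  if (!inherits(bank, "hpp_memory")) stop_param("bank must be an hpp_memory")
  if (inherits(v, "hpp_hac")) {
    if (length(v$counts) != bank$dimension) {
      stop_param("HAC dimension ", length(v$counts),
                 " does not match memory dimension ", bank$dimension)
    }
    sup <- v$counts@i
    vs <- v$counts@x
  } else {
    v <- as.numeric(v)
    if (length(v) != bank$dimension) stop_param("dimension mismatch")
    if (any(v < 0)) stop_param("v must be non-negative")
    sup <- which(v > 0)
    vs <- v[sup]
  }
  if (!length(sup)) stop_data("cannot decompose an all-zero vector")
  W <- memory_dictionary(bank)
  csum <- Matrix::colSums(W)
  if (normalize_columns) {
    W <- W %*% Matrix::Diagonal(x = 1 / csum)
    denom <- rep(1, ncol(W))
  } else {
    denom <- csum
  }
  M <- ncol(W)
  Ws <- as.matrix(W[sup, , drop = FALSE])
  tWs <- t(Ws)
  h <- rep(1 / M, M)
  # constant part of the divergence outside the support of v is sum(W h)
  # = sum(denom * h); inside the support it is evaluated directly
  trace <- numeric(0)
  div <- function(ap) {
    sum(vs * log(vs / pmax(ap, eps)) - vs) + sum(denom * h)
  }
  prev <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ap <- as.numeric(Ws %*% h)
    d <- div(ap)
    trace <- c(trace, d)
    if (is.finite(prev) && abs(prev - d) <= tol * max(abs(prev), eps)) {
      converged <- TRUE
      break
    }
    prev <- d
    h <- h * as.numeric(tWs %*% (vs / pmax(ap, eps))) / pmax(denom, eps)
  }
  structure(list(weights = h, divergence_trace = trace,
                 converged = converged, n_iter = it),
            class = "hpp_decomposition")
}

#' @export
print.hpp_decomposition <- function(x, ...) {
  cat(sprintf(paste0("<hpp_decomposition: %d weights, %d iterations ",
                     "(%sconverged), final divergence %.6g>\n"),
              length(x$weights), x$n_iter, if (x$converged) "" else "not ",
              utils::tail(x$divergence_trace, 1)))
  invisible(x)
}
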