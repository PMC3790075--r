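# Shared fixtures and independent oracles for the test suite.

# A random label stream of length n over small inventories.
random_stream <- function(n, sizes = c(5L, 4L, 3L), seed = 1L) {
  set.seed(seed)
  label_stream(sample.int(sizes[1], n, replace = TRUE),
               sample.int(sizes[2], n, replace = TRUE),
               sample.int(sizes[3], n, replace = TRUE),
               sizes)
}

# A small HAC vector built from explicit counts at explicit indices.
hac_from_counts <- function(idx, cnt, dim_total, sizes = c(2L, 2L, 2L),
                            lags_ms = c(20, 50)) {
  o <- order(idx)
  structure(list(counts = Matrix::sparseVector(x = as.numeric(cnt[o]),
                                               i = as.integer(idx[o]),
                                               length = dim_total),
                 sizes = sizes, lags_ms = lags_ms, n_frames = NA_integer_,
                 duration_s = 1),
            class = "hpp_hac")
}

# A tiny memory bank from a dense non-negative dictionary matrix; the last
# column is the noise entry, columns `fam_cols` are familiarization
# entries for word "w1".
toy_memory <- function(W, fam_cols = integer(0)) {
  stopifnot(is.matrix(W), all(W >= 0))
  mk <- function(j) hac_from_counts(which(W[, j] > 0), W[W[, j] > 0, j],
                                    nrow(W))
  plain <- setdiff(seq_len(ncol(W)), fam_cols)
  bank <- build_memory(lapply(plain[-length(plain)], mk),
                       mk(plain[length(plain)]))
  if (length(fam_cols)) {
    bank <- familiarize(bank, list(w1 = lapply(fam_cols, mk)))
  }
  bank
}

# Brute-force KL-NMF oracle: coarse-to-fine grid search over the weight
# box, independent of the multiplicative-update path.
brute_force_kl <- function(v, W, rounds = 4L, pts = 13L) {
  M <- ncol(W)
  lo <- rep(0, M)
  hi <- rep(2 * sum(v) / min(colSums(W)), M)
  best <- NULL
  for (r in seq_len(rounds)) {
    axes <- lapply(seq_len(M), function(j) seq(lo[j], hi[j], length.out = pts))
    grid <- as.matrix(expand.grid(axes))
    dv <- apply(grid, 1, function(h) kl_divergence(v, as.numeric(W %*% h)))
    k <- which.min(dv)
    best <- list(h = grid[k, ], div = dv[k])
    step <- vapply(axes, function(a) a[2] - a[1], numeric(1))
    lo <- pmax(0, best$h - step)
    hi <- best$h + step
  }
  best
}

# 1 ms-grid listening-time oracle: evaluates the attention function on a
# fine time grid and applies the threshold and the abort rule directly.
listening_time_grid <- function(pt, params, dt = 0.001) {
  tt <- seq(0, pt$passage_duration_s, by = dt)
  a <- attention_at(pt, params$alpha, tt, mode = params$mode)
  above <- a >= params$theta
  r <- rle(!above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  term <- NA_real_
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && r$lengths[k] * dt > params$away_limit_s) {
      term <- tt[starts[k]]
      break
    }
  }
  keep <- if (is.na(term)) above else above & tt < term
  list(listening_s = sum(keep) * dt, terminated_at_s = term)
}

# A random pulse train resembling reduced passages (N sentences of 2-4 s,
# proportion-scale scores).
random_pulse_train <- function(seed, n = 6L, params = behavior_params()) {
  set.seed(seed)
  build_pulse_train(runif(n, 0, 60), runif(n, 2, 4), params)
}

toy_words <- function() default_word_specs()
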