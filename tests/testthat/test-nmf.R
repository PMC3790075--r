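test_that("generalized KL divergence has its closed-form values", {
  expect_equal(kl_divergence(c(1, 2, 3), c(1, 2, 3)), 0)
  # (2,0) vs (1,1): 2 ln 2 - 2 + 1 + 1
  expect_equal(kl_divergence(c(2, 0), c(1, 1)), 2 * log(2), tolerance = 1e-12)
  expect_gte(kl_divergence(c(1, 0), c(0.5, 0.7)), 0)
  # epsilon floor keeps a zero under positive mass finite (and large)
  d <- kl_divergence(c(2, 1), c(1, 0))
  expect_true(is.finite(d) && d > 10)
  expect_error(kl_divergence(c(-1, 0), c(1, 1)), class = "hpp_param_error")
  expect_error(kl_divergence(c(1, 0), c(1, 1, 1)), class = "hpp_param_error")
})

test_that("an exact memory member is recovered with > 99% weight share", {
  # disjoint supports so that column 2 is the only explanation of v
  W <- cbind(c(4, 2, 0, 0, 0, 0), c(0, 0, 3, 5, 0, 0), c(0, 0, 0, 0, 2, 2))
  bank <- toy_memory(W, fam_cols = 2L)
  v <- hac_from_counts(c(3, 4), c(3, 5), 6L)
  w <- decompose(v, bank)
  share <- w$weights / sum(w$weights)
  expect_gt(share[3], 0.99)  # fam entry appended last
  expect_true(all(w$weights >= 0))
})

test_that("disjoint-support mixtures split their weight as mixed", {
  W <- cbind(c(1, 1, 0, 0, 0, 0), c(0, 0, 1, 1, 0, 0), c(0, 0, 0, 0, 1, 1))
  bank <- toy_memory(W)
  v <- hac_from_counts(1:4, c(2, 2, 2, 2), 6L)  # 0.5 col1 + 0.5 col2
  w <- decompose(v, bank)
  share <- w$weights / sum(w$weights)
  expect_equal(share[1], 0.5, tolerance = 0.01)
  expect_equal(share[2], 0.5, tolerance = 0.01)
  expect_lt(share[3], 0.01)
})

test_that("divergence traces are monotone non-increasing on random input", {
  for (s in 1:100) {
    set.seed(s)
    dim_t <- 12L
    M <- sample(3:6, 1)
    W <- matrix(rpois(dim_t * M, 2), dim_t, M)
    W[, colSums(W) == 0] <- 1  # keep columns non-empty
    bank <- toy_memory(W)
    nz <- sort(sample.int(dim_t, sample(2:dim_t, 1)))
    v <- hac_from_counts(nz, rpois(length(nz), 3) + 1, dim_t)
    w <- decompose(v, bank, max_iter = 60)
    expect_true(all(diff(w$divergence_trace) <= 1e-8 *
                      max(1, w$divergence_trace[1])))
    expect_true(all(w$weights >= 0))
  }
})

test_that("decomposition is scale covariant in the input", {
  set.seed(9)
  W <- matrix(rpois(8 * 4, 3) + 1, 8, 4)
  bank <- toy_memory(W)
  v1 <- hac_from_counts(1:8, rpois(8, 4) + 1, 8L)
  v3 <- hac_from_counts(1:8, 3 * v1$counts@x, 8L)
  w1 <- decompose(v1, bank)
  w3 <- decompose(v3, bank)
  expect_equal(w3$weights, 3 * w1$weights, tolerance = 1e-8)
})

test_that("multiplicative updates reach the brute-force KL optimum", {
  for (s in 1:5) {
    set.seed(s)
    dim_t <- sample(4:6, 1)
    M <- sample(2:3, 1)
    W <- matrix(rpois(dim_t * M, 3) + 1, dim_t, M)
    v_counts <- rpois(dim_t, 4) + 1
    bank <- toy_memory(W)
    v <- hac_from_counts(seq_len(dim_t), v_counts, dim_t)
    w <- decompose(v, bank, tol = 1e-10, max_iter = 2000)
    # oracle searches the weight box over the column-normalized dictionary
    Wn <- sweep(W, 2, colSums(W), "/")
    oracle <- brute_force_kl(v_counts, Wn, rounds = 6L, pts = 15L)
    ours <- utils::tail(w$divergence_trace, 1)
    expect_lt(abs(ours - oracle$div), 1e-3)
  }
})

test_that("decomposition contracts reject bad input", {
  W <- matrix(1, 4, 2)
  bank <- toy_memory(W)
  expect_error(decompose(hac_from_counts(integer(0), numeric(0), 4L), bank),
               class = "hpp_data_error")
  expect_error(decompose(hac_from_counts(1L, 2, 9L), bank),
               class = "hpp_param_error")
})
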