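test_that("pulse trains place scores at sentence ends with the onset pulse", {
  p <- behavior_params(alpha = 0.1, theta = 0.4, rho = 0.4)
  pt <- build_pulse_train(c(50, 20, 10, 5, 2, 1), rep(3, 6), p)
  expect_equal(pt$amplitudes[1], 0.8)  # theta + rho
  expect_equal(pt$pulse_times_s, c(0, 3, 6, 9, 12, 15, 18))
  expect_equal(pt$passage_duration_s, 18)
  expect_equal(pt$amplitudes[-1], c(50, 20, 10, 5, 2, 1) / 100)
  pt0 <- build_pulse_train(rep(0, 3), rep(2, 3), p)
  expect_equal(pt0$amplitudes, c(0.8, 0, 0, 0))
  expect_error(build_pulse_train(numeric(0), numeric(0), p),
               class = "hpp_param_error")
  expect_error(build_pulse_train(c(1, 2), c(3, -1), p),
               class = "hpp_param_error")
})

test_that("attention evaluates its closed forms", {
  p <- behavior_params(alpha = 0.1, theta = 0.4, rho = 0.4)
  pt <- build_pulse_train(30, 10, p)
  expect_equal(attention_at(pt, 0.1, 0), 0.8)
  expect_equal(attention_at(pt, 0.1, 2), 0.8 * exp(-0.2), tolerance = 1e-12)
  # alpha -> 0 limit: cumulative sum (superpose) / last amplitude (reset)
  pt2 <- build_pulse_train(c(30, 20), c(2, 2), p)
  expect_equal(attention_at(pt2, 1e-12, 3), 0.8 + 0.3, tolerance = 1e-6)
  expect_equal(attention_at(pt2, 1e-12, 3, mode = "reset"), 0.3,
               tolerance = 1e-6)
  expect_error(attention_at(pt, 0.1, 11), class = "hpp_param_error")
})

test_that("single-pulse listening time equals ln(a0/theta)/alpha", {
  set.seed(20)
  for (i in 1:1000) {
    theta <- runif(1, 0.05, 1.2)
    rho <- runif(1, 0.05, 1.0)
    alpha <- runif(1, 0.02, 0.5)
    cross <- log((theta + rho) / theta) / alpha
    p <- behavior_params(alpha = alpha, theta = theta, rho = rho)
    # one long silent sentence: no further pulse before cross + 2 s
    pt <- build_pulse_train(0, cross + 5, p)
    lt <- listening_time(pt, p)
    expect_lt(abs(lt$listening_s - cross), 1e-3)
    expect_equal(lt$terminated_at_s, cross, tolerance = 1e-9)
  }
})

test_that("the piecewise walk agrees with the 1 ms grid evaluator", {
  for (s in 1:40) {
    p <- behavior_params(alpha = runif(1, 0.02, 0.4),
                         theta = runif(1, 0.1, 1.2),
                         mode = sample(c("superpose", "reset"), 1))
    pt <- random_pulse_train(s, params = p)
    exact <- listening_time(pt, p)
    grid <- listening_time_grid(pt, p)
    expect_lt(abs(exact$listening_s - grid$listening_s), 5e-3)
    if (!is.na(exact$terminated_at_s) && !is.na(grid$terminated_at_s)) {
      expect_lt(abs(exact$terminated_at_s - grid$terminated_at_s), 5e-3)
    }
  }
})

test_that("listening time is monotone in theta and in alpha", {
  thetas <- seq(0.1, 1.4, by = 0.1)
  alphas <- seq(0.02, 0.4, by = 0.02)
  for (s in 1:100) {
    base <- behavior_params()
    pt <- random_pulse_train(s, params = base)
    lt_th <- vapply(thetas, function(th) {
      pr <- behavior_params(alpha = 0.15, theta = th, rho = base$rho)
      ptt <- build_pulse_train(pt$amplitudes[-1] * 100,
                               diff(pt$pulse_times_s), pr)
      listening_time(ptt, pr)$listening_s
    }, numeric(1))
    expect_true(all(diff(lt_th) <= 1e-9))
    lt_al <- vapply(alphas, function(al) {
      pr <- behavior_params(alpha = al, theta = 0.4, rho = base$rho)
      listening_time(pt, pr)$listening_s
    }, numeric(1))
    expect_true(all(diff(lt_al) <= 1e-9))
  }
})

test_that("extreme thresholds hit the paper's qualitative regimes", {
  for (s in 1:10) {
    p_lo <- behavior_params(alpha = 0.2, theta = 1e-6)
    pt <- random_pulse_train(s, params = p_lo)
    lt <- listening_time(pt, p_lo)
    expect_equal(lt$listening_s, pt$passage_duration_s, tolerance = 1e-6)
    expect_true(is.na(lt$terminated_at_s))
    # theta > 1.5 with typical percent-scale scores: near-zero listening
    # (the onset pulse alone crosses theta, then nothing rescues)
    p_hi <- behavior_params(alpha = 0.2, theta = 1.6)
    set.seed(s)
    pt_hi <- build_pulse_train(runif(6, 0, 20), runif(6, 2, 4), p_hi)
    lt_hi <- listening_time(pt_hi, p_hi)
    expect_lt(lt_hi$listening_s, log((1.6 + 0.4) / 1.6) / 0.2 + 1e-9)
    expect_lt(lt_hi$listening_s, 0.1 * pt_hi$passage_duration_s)
  }
})

test_that("bounds hold and a pulse can rescue a trial before 2 s elapse", {
  p <- behavior_params(alpha = 0.5, theta = 0.4, rho = 0.4)
  # onset decays below theta at ln(2)/0.5 = 1.386; first sentence ends at
  # 3.0 s, i.e. 1.61 s below threshold -- under the 2 s limit, so the
  # strong first-sentence score rescues the trial
  pt <- build_pulse_train(c(90, 90), c(3, 3), p)
  lt <- listening_time(pt, p)
  expect_true(is.na(lt$terminated_at_s) || lt$terminated_at_s > 3)
  expect_gt(lt$listening_s, log(2) / 0.5 + log(0.9 / 0.4) / 0.5 - 1e-6)
  # with a 4 s first sentence the below interval exceeds 2 s: terminated
  p2 <- behavior_params(alpha = 0.5, theta = 0.4, rho = 0.4)
  pt2 <- build_pulse_train(c(90, 90), c(4, 4), p2)
  lt2 <- listening_time(pt2, p2)
  expect_equal(lt2$terminated_at_s, log(2) / 0.5, tolerance = 1e-9)
  expect_equal(lt2$listening_s, log(2) / 0.5, tolerance = 1e-9)
  for (s in 1:30) {
    pr <- behavior_params(alpha = runif(1, 0.05, 0.4),
                          theta = runif(1, 0.1, 1.3))
    ptr <- random_pulse_train(s + 500, params = pr)
    ltr <- listening_time(ptr, pr)$listening_s
    expect_gte(ltr, 0)
    expect_lte(ltr, ptr$passage_duration_s + 1e-9)
  }
})
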