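test_that("speaker profiles validate and are deterministic value objects", {
  p <- speaker_profile("F1", 0.93, +0.1, 7)
  expect_equal(p$rate_factor, 0.93)
  expect_identical(p, speaker_profile("F1", 0.93, +0.1, 7))
  expect_error(speaker_profile("X", 3.0), class = "hpp_param_error")
  expect_error(speaker_profile("X", 0.4), class = "hpp_param_error")
})

test_that("word templates respect the duration and descriptor contracts", {
  words <- toy_words()
  expect_length(words, 4L)
  for (w in words) {
    d <- sum(w$template$duration_ms)
    expect_gte(d, 300)
    expect_lte(d, 700)
  }
  # all pairs differ in at least one descriptor
  for (i in 1:3) for (j in (i + 1):4) {
    expect_false(identical(words[[i]]$template, words[[j]]$template))
  }
  expect_error(word_spec("x", data.frame(duration_ms = 100, f1 = 1, f2 = 2,
                                         voicing = 0.5)),
               class = "hpp_param_error")
})

test_that("token duration scales with rate factor and jitter is seeded", {
  w <- word_spec("w", data.frame(duration_ms = c(200, 300), f1 = c(400, 600),
                                 f2 = c(1500, 1100), voicing = c(1, 1)))
  sp1 <- speaker_profile("a", 1.0)
  tk <- synthesize_word_token(w, sp1, 1, jitter = 0)
  expect_equal(length(tk$samples) / tk$sample_rate_hz, 0.5, tolerance = 1e-3)
  sp2 <- speaker_profile("b", 1.2)
  tk2 <- synthesize_word_token(w, sp2, 1, jitter = 0)
  expect_equal(length(tk2$samples) / tk2$sample_rate_hz, 0.6,
               tolerance = 1e-3)
  # same seed -> identical; different seeds -> different realizations
  expect_identical(synthesize_word_token(w, sp1, 5)$samples,
                   synthesize_word_token(w, sp1, 5)$samples)
  expect_false(identical(synthesize_word_token(w, sp1, 5)$samples,
                         synthesize_word_token(w, sp1, 6)$samples))
})

test_that("sentences embed the word once with a consistent annotation", {
  w <- toy_words()$frog
  sp <- speaker_profile("a", 1.0)
  s <- synthesize_sentence(w, sp, 2.8, seed = 3)
  dur <- length(s$wave$samples) / s$wave$sample_rate_hz
  expect_lt(abs(dur - 2.8) / 2.8, 0.10)
  expect_equal(s$word_offset_s - s$word_onset_s,
               sum(w$template$duration_ms) / 1000, tolerance = 1e-2)
  expect_gte(s$word_onset_s, 0)
  expect_lte(s$word_offset_s, dur + 1e-9)
  s2 <- synthesize_sentence(w, sp, 2.8, seed = 3)
  expect_identical(s$wave$samples, s2$wave$samples)
  expect_identical(s$word_onset_s, s2$word_onset_s)
  expect_error(synthesize_sentence(w, sp, 0.3, seed = 1),
               class = "hpp_param_error")
})

test_that("stimulus sets have exactly the configured counts", {
  sp <- speaker_profile("a", 1.0)
  des <- default_stimulus_design(n_tokens = 2, n_sentences = 3,
                                 n_background = 4)
  st <- generate_stimulus_set(toy_words(), sp, des, seed = 9)
  expect_length(st$isolated_tokens, 4L)
  expect_true(all(lengths(st$isolated_tokens) == 2L))
  expect_true(all(lengths(st$sentences) == 3L))
  expect_length(st$background, 4L)
  expect_s3_class(st$noise, "hpp_waveform")
  st2 <- generate_stimulus_set(toy_words(), sp, des, seed = 9)
  expect_identical(st$sentences[["frog"]][[1]]$wave$samples,
                   st2$sentences[["frog"]][[1]]$wave$samples)
  expect_error(generate_stimulus_set(toy_words()[1:2], sp, des, seed = 1),
               class = "hpp_param_error")
})

test_that("symbolic streams embed a detectable word pattern", {
  sp <- speaker_profile("clean", 1.0, 0.0)
  st <- generate_symbolic_stream(NULL, sp, 100, c(10, 10, 8), seed = 2)
  expect_length(st, 100L)
  expect_lte(max(st$labels_static), 10L)
  expect_lte(max(st$labels_deltadelta), 8L)
  w <- toy_words()$frog
  ws <- generate_symbolic_stream(w, sp, 120, c(10, 10, 8), seed = 4)
  on <- attr(ws, "word_onset_frame")
  off <- attr(ws, "word_offset_frame")
  pat <- hppsim:::symbolic_word_pattern(w, c(10L, 10L, 8L), 1.0)
  expect_identical(ws$labels_static[on:off], pat[[1]])
  expect_identical(generate_symbolic_stream(w, sp, 120, c(10, 10, 8), 4),
                   generate_symbolic_stream(w, sp, 120, c(10, 10, 8), 4))
})

test_that("same-word tokens are closer in HAC space than cross-word", {
  sp <- speaker_profile("clean", 1.0, 0.0)
  sizes <- c(10L, 10L, 8L)
  words <- toy_words()
  hacs <- lapply(words[c("frog", "doll")], function(w) {
    lapply(1:3, function(k) {
      encode_hac(generate_symbolic_stream(w, sp, 60, sizes, seed = 100 + k))
    })
  })
  cosine <- function(a, b) {
    x <- as.numeric(a$counts); y <- as.numeric(b$counts)
    sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  }
  within_ <- c(cosine(hacs[[1]][[1]], hacs[[1]][[2]]),
               cosine(hacs[[2]][[1]], hacs[[2]][[3]]))
  across <- c(cosine(hacs[[1]][[1]], hacs[[2]][[1]]),
              cosine(hacs[[1]][[2]], hacs[[2]][[3]]))
  expect_gt(min(within_), max(across))
})
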