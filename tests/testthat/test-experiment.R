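# Reduced-scale symbolic fixture shared by the experiment tests: one clean
# speaker, 2 sentences per word, small label inventories.
small_symbolic <- function(seed = 5, n_sentences = 2L, n_background = 10L) {
  sp <- speaker_profile("S1", 1.0, 0.0, seed = 1)
  des <- default_stimulus_design(n_tokens = 2L, n_sentences = n_sentences,
                                 n_background = n_background)
  set <- generate_symbolic_set(toy_words(), sp, des,
                               codebook_sizes = c(10L, 10L, 8L), seed = seed)
  encode_stimuli(set)
}

small_design <- function(n_sentences = 2L, n_passages = 3L) {
  hpp_design(n_tokens = 2L, n_sentences_per_word = n_sentences,
             n_passages_per_word = n_passages, passage_len = 6L)
}

test_that("designs must partition the word list", {
  expect_error(hpp_design(familiarization_sets = list(c("frog", "doll"),
                                                      c("duck", "frog"))),
               class = "hpp_param_error")
  expect_error(hpp_design(passage_len = 0), class = "hpp_param_error")
  d <- hpp_design()
  expect_equal(d$n_sentences_per_word * length(d$words), 96L)
})

test_that("every sentence is scored once per familiarization set", {
  enc <- small_symbolic()
  des <- small_design()
  scores <- score_all_sentences(enc, enc, des)
  # 2 sentences x 4 words x 2 familiarization sets
  expect_equal(nrow(scores), 16L)
  expect_equal(length(unique(scores$sentence_id)), 8L)
  # partition: each sentence is familiar in exactly one set
  tab <- table(scores$sentence_id, scores$condition)
  expect_true(all(tab == 1L))
  expect_true(all(scores$cluster_score_pct >= scores$single_score_pct - 1e-9))
  expect_true(all(scores$single_score_pct >= 0 &
                    scores$cluster_score_pct <= 100))
  expect_error(score_all_sentences(list(), enc, des),
               class = "hpp_state_error")
})

test_that("passages sample the configured counts with replacement", {
  enc <- small_symbolic()
  scores <- score_all_sentences(enc, enc, small_design())
  des <- small_design(n_passages = 30L)
  p <- assemble_passages(scores, des, seed = 4)
  expect_equal(nrow(p), 120L)  # 30 per word, two sets of 120 in the t-test
  expect_true(all(lengths(p$sentence_ids) == 6L))
  expect_true(all(table(p$word_id) == 30L))
  p2 <- assemble_passages(scores, des, seed = 4)
  expect_identical(p$sentence_ids, p2$sentence_ids)
  p3 <- assemble_passages(scores, des, seed = 5)
  expect_false(identical(p$sentence_ids, p3$sentence_ids))
  # with-replacement sampling: some passage repeats a sentence
  expect_true(any(vapply(p$sentence_ids, anyDuplicated, integer(1)) > 0))
})

test_that("the significance grid has coherent shape and signs", {
  enc <- small_symbolic(seed = 7)
  des <- small_design(n_passages = 8L)
  scores <- score_all_sentences(enc, enc, des)
  passages <- assemble_passages(scores, des, seed = 1)
  alphas <- seq(0.05, 0.25, 0.05)
  thetas <- seq(0.2, 1.0, 0.2)
  g <- run_grid(passages, scores, "cluster", alphas, thetas)
  expect_equal(nrow(g), length(alphas) * length(thetas))
  expect_true(all(g$sign %in% c("familiar", "novel", "none")))
  expect_true(all(g$p[g$sign != "none"] < 0.05))
  expect_true(all(g$sign[g$p >= 0.05] == "none"))
  fam_rows <- g$sign == "familiar"
  expect_true(all(g$mean_fam[fam_rows] > g$mean_nov[fam_rows]))
  # near-zero threshold: listening = passage duration in both conditions
  g0 <- run_grid(passages, scores, "cluster", c(0.1), c(1e-6))
  expect_equal(g0$mean_fam, g0$mean_nov)
  expect_equal(g0$p, 1)
  expect_identical(g0$sign, "none")
  expect_error(run_grid(passages, scores, "cluster", numeric(0), 0.4),
               class = "hpp_param_error")
})

test_that("results export as readable CSV tables", {
  enc <- small_symbolic()
  des <- small_design()
  scores <- score_all_sentences(enc, enc, des)
  passages <- assemble_passages(scores, des, seed = 2)
  g <- run_grid(passages, scores, "cluster", c(0.1, 0.2), c(0.3, 0.6))
  out <- tempfile("hppexport")
  paths <- export_results(g, scores, out)
  expect_true(all(file.exists(paths)))
  grid_back <- read.csv(file.path(out, "grid_cluster.csv"))
  expect_equal(nrow(grid_back), 4L)
  expect_true(all(c("alpha", "theta", "t", "p", "sign") %in%
                    names(grid_back)))
  summ <- read.csv(file.path(out, "score_summary.csv"))
  expect_equal(nrow(summ), 4L)  # 2 modes x 2 conditions
  unlink(out, recursive = TRUE)
})

test_that("a full symbolic experiment recovers the familiarity preference", {
  sp <- speaker_profile("S1", 1.0, 0.0, seed = 2)
  ex <- hpp_experiment(
    sp, words = toy_words(),
    design = small_design(n_sentences = 4L, n_passages = 6L),
    stimulus_design = default_stimulus_design(n_tokens = 2L,
                                              n_sentences = 4L,
                                              n_background = 15L),
    mode = "symbolic", codebook_sizes = c(10L, 10L, 8L),
    alpha_values = seq(0.05, 0.25, 0.1), theta_values = seq(0.2, 0.8, 0.3),
    seed = 21)
  expect_s3_class(ex, "hpp_experiment")
  expect_lt(ex$sentence_tests$cluster$p_two_sided, 0.05)
  expect_gt(ex$sentence_tests$cluster$mean[["familiar"]],
            ex$sentence_tests$cluster$mean[["novel"]])
  expect_identical(ex, local({set.seed(99); ex2 <- hpp_experiment(
    sp, words = toy_words(),
    design = small_design(n_sentences = 4L, n_passages = 6L),
    stimulus_design = default_stimulus_design(n_tokens = 2L,
                                              n_sentences = 4L,
                                              n_background = 15L),
    mode = "symbolic", codebook_sizes = c(10L, 10L, 8L),
    alpha_values = seq(0.05, 0.25, 0.1), theta_values = seq(0.2, 0.8, 0.3),
    seed = 21); ex2}))
})

test_that("speaker rate mismatch degrades the score separation", {
  des <- small_design(n_sentences = 4L)
  sdes <- default_stimulus_design(n_tokens = 2L, n_sentences = 4L,
                                  n_background = 10L)
  gap_sep <- vapply(c(1.0, 1.6), function(rate) {
    seps <- vapply(1:4, function(s) {
      fam_sp <- speaker_profile("fam", 1.0, 0.0, seed = s)
      test_sp <- speaker_profile("test", rate, 0.0, seed = s + 50)
      fam_set <- generate_symbolic_set(toy_words(), fam_sp, sdes,
                                       codebook_sizes = c(10L, 10L, 8L),
                                       seed = s)
      test_set <- generate_symbolic_set(toy_words(), test_sp, sdes,
                                        codebook_sizes = c(10L, 10L, 8L),
                                        seed = s + 100)
      sc <- score_all_sentences(encode_stimuli(fam_set),
                                encode_stimuli(test_set), des)
      mean(sc$cluster_score_pct[sc$condition == "familiar"]) -
        mean(sc$cluster_score_pct[sc$condition == "novel"])
    }, numeric(1))
    median(seps)
  }, numeric(1))
  expect_gt(gap_sep[1], gap_sep[2])
})
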