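#' Experiment design constants
#'
#' The standard two-phase design: four target words split into two
#' familiarization pairs; 5 isolated tokens per word are familiarized; all
#' 24 carrier sentences per word (96 per speaker) are scored in both the
#' familiar and novel condition; 30 six-sentence passages per word enter
#' the listening-time comparison (two sets of 120 passages).
#'
#' @param words Four word ids.
#' @param familiarization_sets List of two character vectors partitioning
#'   `words`.
#' @param n_tokens Isolated tokens familiarized per word (5).
#' @param n_sentences_per_word Carrier sentences per word (24).
#' @param n_passages_per_word Test passages built per word (30).
#' @param passage_len Sentences per passage (6).
#' @return An object of class `hpp_design`.
#' @export
hpp_design <- function(words = c("frog", "doll", "duck", "ball"),
                       familiarization_sets = list(words[1:2], words[3:4]),
                       n_tokens = 5L, n_sentences_per_word = 24L,
                       n_passages_per_word = 30L, passage_len = 6L) {
  sets <- lapply(familiarization_sets, as.character)
  if (length(sets) != 2L ||
      !setequal(unlist(sets), words) ||
      length(unlist(sets)) != length(words)) {
    stop_param("familiarization_sets must partition the word list")
  }
  if (any(c(n_tokens, n_sentences_per_word, n_passages_per_word,
            passage_len) < 1L)) {
    stop_param("design counts must be positive")
  }
  structure(list(words = as.character(words), familiarization_sets = sets,
                 n_tokens = as.integer(n_tokens),
                 n_sentences_per_word = as.integer(n_sentences_per_word),
                 n_passages_per_word = as.integer(n_passages_per_word),
                 passage_len = as.integer(passage_len)),
            class = "hpp_design")
}

#' Encode a stimulus set as HAC vectors
#'
#' For an audio set the waveforms run through [compute_features()] and
#' [quantize()] against the supplied codebooks; a symbolic set already
#' carries label streams and is encoded directly.
#'
#' @param set An `hpp_stimulus_set` or `hpp_symbolic_set`.
#' @param codebooks An [train_codebooks()] result (audio sets only).
#' @param lags_ms Co-occurrence lags, default `c(20, 50)`.
#' @return An object of class `hpp_encoded_set`: per-word token HACs, a
#'   sentence table with HACs and durations, background HACs and the noise
#'   HAC.
#' @export
encode_stimuli <- function(set, codebooks = NULL, lags_ms = c(20, 50)) {
  symbolic <- inherits(set, "hpp_symbolic_set")
  if (!symbolic && !inherits(set, "hpp_stimulus_set")) {
    stop_param("set must be an hpp_stimulus_set or hpp_symbolic_set")
  }
  if (!symbolic && is.null(codebooks)) {
    stop_param("audio sets need trained codebooks")
  }
  enc_wave <- function(w) encode_hac(quantize(compute_features(w), codebooks),
                                     lags_ms)
  enc_stream <- function(s) encode_hac(s, lags_ms)

  tokens <- lapply(set$isolated_tokens, function(tks) {
    lapply(tks, function(tk) if (symbolic) enc_stream(tk) else enc_wave(tk))
  })
  sent_rows <- list()
  sent_hacs <- list()
  k <- 0L
  for (wid in names(set$sentences)) {
    for (si in seq_along(set$sentences[[wid]])) {
      k <- k + 1L
      s <- set$sentences[[wid]][[si]]
      h <- if (symbolic) enc_stream(s$stream) else enc_wave(s$wave)
      dur <- if (symbolic) s$duration_s else wave_duration_s(s$wave)
      sent_rows[[k]] <- data.frame(sentence_id = paste0(wid, "_s", si),
                                   word_id = wid, duration_s = dur,
                                   stringsAsFactors = FALSE)
      sent_hacs[[k]] <- h
    }
  }
  background <- lapply(set$background,
                       function(b) if (symbolic) enc_stream(b) else enc_wave(b))
  noise <- if (symbolic) enc_stream(set$noise) else enc_wave(set$noise)
  structure(list(tokens = tokens,
                 sentence_table = do.call(rbind, sent_rows),
                 sentence_hacs = sent_hacs,
                 background = background, noise = noise,
                 speaker_id = set$speaker$speaker_id),
            class = "hpp_encoded_set")
}

#' @export
print.hpp_encoded_set <- function(x, ...) {
  cat(sprintf(paste0("<hpp_encoded_set: speaker %s, %d token words, ",
                     "%d sentences, %d background>\n"),
              x$speaker_id, length(x$tokens), nrow(x$sentence_table),
              length(x$background)))
  invisible(x)
}

#' Score every test sentence under both familiarization sets
#'
#' For each familiarization set, the memory is built from the
#' familiarization speaker's background experience and noise entry, the
#' set's word tokens are familiarized into it, and every test-speaker
#' sentence is decomposed against it.  Each sentence therefore yields two
#' score records, one per familiarization set; its condition is familiar
#' exactly when its word belongs to that set.  Both the single-episode and
#' the cluster familiarity scores are recorded, in percent.
#'
#' @param fam_enc [encode_stimuli()] result for the familiarization
#'   speaker (supplies background, noise and word tokens).
#' @param test_enc [encode_stimuli()] result for the test speaker
#'   (supplies the test sentences).
#' @param design An [hpp_design()].
#' @param ... Passed to [decompose()] (`tol`, `max_iter`, ...).
#' @return A data frame with one row per sentence x familiarization set:
#'   `sentence_id`, `word_id`, `fam_set`, `condition`,
#'   `single_score_pct`, `cluster_score_pct`, `duration_s`.
#' @export
score_all_sentences <- function(fam_enc, test_enc, design = hpp_design(),
                                ...) {
  for (e in list(fam_enc, test_enc)) {
    if (!inherits(e, "hpp_encoded_set")) {
      stop_state("both stimulus sets must be encoded (encode_stimuli)")
    }
  }
  missing_words <- setdiff(design$words, names(fam_enc$tokens))
  if (length(missing_words)) {
    stop_state("familiarization tokens missing for: ",
               paste(missing_words, collapse = ", "))
  }
  out <- list()
  for (f in 1:2) {
    fam_words <- design$familiarization_sets[[f]]
    bank <- build_memory(fam_enc$background, fam_enc$noise)
    bank <- familiarize(bank, fam_enc$tokens[fam_words])
    st <- test_enc$sentence_table
    single <- numeric(nrow(st))
    cluster <- numeric(nrow(st))
    for (i in seq_len(nrow(st))) {
      w <- decompose(test_enc$sentence_hacs[[i]], bank, ...)
      single[i] <- single_episode_score(w, bank)
      cluster[i] <- cluster_score(w, bank)
    }
    out[[f]] <- data.frame(
      sentence_id = st$sentence_id, word_id = st$word_id,
      fam_set = f,
      condition = ifelse(st$word_id %in% fam_words, "familiar", "novel"),
      single_score_pct = single, cluster_score_pct = cluster,
      duration_s = st$duration_s, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("hpp_scores", class(res))
  res
}

#' Sentence-level familiarity-score comparison
#'
#' Mann-Whitney U test of familiar against novel sentence scores (each
#' sentence contributes once to each condition, via its two
#' familiarization-set runs).
#'
#' @param scores A [score_all_sentences()] table.
#' @param mode `"single"` or `"cluster"`.
#' @return List with per-condition `mean` and `sd`, the `U` statistic and
#'   the two-sided `p`.
#' @export
sentence_score_test <- function(scores, mode = c("cluster", "single")) {
  mode <- match.arg(mode)
  col <- paste0(mode, "_score_pct")
  fam <- scores[[col]][scores$condition == "familiar"]
  nov <- scores[[col]][scores$condition == "novel"]
  mw <- mann_whitney_u(fam, nov)
  list(mode = mode,
       mean = c(familiar = mean(fam), novel = mean(nov)),
       sd = c(familiar = stats::sd(fam), novel = stats::sd(nov)),
       U = mw$U, p_two_sided = mw$p_two_sided)
}

#' Assemble six-sentence test passages
#'
#' Per word, `n_passages_per_word` passages of `passage_len` sentences are
#' sampled with replacement under the seed.  Every passage is later scored
#' in both conditions (familiar and novel), which removes duration biases:
#' the familiar and novel listening-time samples are built from the very
#' same passages.
#'
#' @param sentence_table Data frame with `sentence_id`, `word_id`,
#'   `duration_s` (one row per distinct sentence; e.g. the deduplicated
#'   [score_all_sentences()] table).
#' @param design An [hpp_design()].
#' @param seed Integer seed for the passage sampling.
#' @return An object of class `hpp_passage_set`: data frame with
#'   `passage_id`, `word_id` and the list column `sentence_ids`.
#' @export
assemble_passages <- function(sentence_table, design = hpp_design(),
                              seed = 1L) {
  need <- c("sentence_id", "word_id", "duration_s")
  if (!all(need %in% names(sentence_table))) {
    stop_param("sentence_table needs columns ", paste(need, collapse = ", "))
  }
  sentence_table <- unique(sentence_table[need])
  rows <- list()
  k <- 0L
  for (wid in design$words) {
    ids <- sentence_table$sentence_id[sentence_table$word_id == wid]
    if (!length(ids)) stop_param("no sentences available for word ", wid)
    picks <- with_seed(derive_seed(seed, paste0("passages_", wid)), {
      lapply(seq_len(design$n_passages_per_word), function(p) {
        sample(ids, design$passage_len, replace = TRUE)
      })
    })
    for (p in seq_along(picks)) {
      k <- k + 1L
      rows[[k]] <- data.frame(passage_id = paste0(wid, "_p", p),
                              word_id = wid, stringsAsFactors = FALSE)
      rows[[k]]$sentence_ids <- list(picks[[p]])
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("hpp_passage_set", class(out))
  out
}

#' Sweep attention span and experimenter threshold into a significance grid
#'
#' For every `(alpha, theta)` combination, listening times are simulated
#' for all passages in both conditions (the familiar sample takes each
#' passage's scores from the familiarization set containing its word, the
#' novel sample from the other set), compared by a two-sample t-test
#' (Welch by default), and summarized as mean/SD per condition, the t and
#' p values, and a preference sign: `"familiar"` or `"novel"` when
#' `p < 0.05` in the respective direction, `"none"` otherwise.  No
#' multiple-comparison correction is applied.
#'
#' @param passages An [assemble_passages()] result.
#' @param scores A [score_all_sentences()] table covering all referenced
#'   sentences.
#' @param score_mode `"cluster"` or `"single"`.
#' @param alpha_values Decay-rate grid; default `seq(0.01, 0.30, 0.01)`.
#' @param theta_values Threshold grid; default `seq(0.10, 1.50, 0.01)`.
#' @param rho Onset offset (0.4).
#' @param away_limit_s Abort rule (2 s).
#' @param mode Attention mode, `"superpose"` (default) or `"reset"`.
#' @param pooled Use the pooled-variance t-test instead of Welch.
#' @return An object of class `hpp_grid`: data frame with one row per
#'   grid cell (`alpha`, `theta`, `mean_fam`, `sd_fam`, `mean_nov`,
#'   `sd_nov`, `t`, `p`, `sign`).
#' @export
run_grid <- function(passages, scores, score_mode = c("cluster", "single"),
                     alpha_values = seq(0.01, 0.30, by = 0.01),
                     theta_values = seq(0.10, 1.50, by = 0.01),
                     rho = 0.4, away_limit_s = 2.0,
                     mode = c("superpose", "reset"), pooled = FALSE) {
  score_mode <- match.arg(score_mode)
  mode <- match.arg(mode)
  if (!length(alpha_values) || !length(theta_values)) {
    stop_param("parameter grids must be non-empty")
  }
  if (!inherits(passages, "hpp_passage_set")) {
    stop_param("passages must come from assemble_passages()")
  }
  col <- paste0(score_mode, "_score_pct")
  # the familiarization set in which a given word is the familiar one
  word_set <- function(wid) {
    fs <- unique(scores$fam_set[scores$word_id == wid &
                                scores$condition == "familiar"])
    if (length(fs) != 1L) {
      stop_state("word ", wid, " is not familiar in exactly one set")
    }
    fs
  }
  # per-sentence lookup keyed by (sentence_id, fam_set)
  key <- paste(scores$sentence_id, scores$fam_set)
  score_of <- function(ids, fs) {
    scores[[col]][match(paste(ids, fs), key)]
  }
  dur_of <- function(ids) {
    scores$duration_s[match(paste(ids, 1L), key)]
  }
  # precompute pulse ingredients per passage x condition
  n_p <- nrow(passages)
  prep <- vector("list", n_p)
  for (i in seq_len(n_p)) {
    ids <- passages$sentence_ids[[i]]
    fs_fam <- word_set(passages$word_id[i])
    fs_nov <- 3L - fs_fam
    durs <- dur_of(ids)
    s_fam <- score_of(ids, fs_fam)
    s_nov <- score_of(ids, fs_nov)
    if (any(is.na(durs)) || any(is.na(s_fam)) || any(is.na(s_nov))) {
      stop_state("scores table does not cover all passage sentences")
    }
    prep[[i]] <- list(times = c(0, cumsum(durs)), t_end = sum(durs),
                      a_fam = s_fam / 100, a_nov = s_nov / 100)
  }
  superpose <- mode == "superpose"
  cells <- expand.grid(alpha = alpha_values, theta = theta_values,
                       KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    al <- cells$alpha[ci]
    th <- cells$theta[ci]
    a0 <- th + rho
    lt_fam <- numeric(n_p)
    lt_nov <- numeric(n_p)
    for (i in seq_len(n_p)) {
      p <- prep[[i]]
      lt_fam[i] <- listening_core(p$times, c(a0, p$a_fam), p$t_end, al, th,
                                  away_limit_s, superpose)$listening_s
      lt_nov[i] <- listening_core(p$times, c(a0, p$a_nov), p$t_end, al, th,
                                  away_limit_s, superpose)$listening_s
    }
    if (stats::var(lt_fam) == 0 && stats::var(lt_nov) == 0) {
      tt <- list(t = 0, p_two_sided = if (mean(lt_fam) == mean(lt_nov)) 1
                 else 0)
    } else {
      tt <- welch_t(lt_fam, lt_nov, pooled = pooled)
    }
    sgn <- if (tt$p_two_sided < 0.05 && mean(lt_fam) > mean(lt_nov)) {
      "familiar"
    } else if (tt$p_two_sided < 0.05 && mean(lt_nov) > mean(lt_fam)) {
      "novel"
    } else "none"
    res[[ci]] <- data.frame(alpha = al, theta = th,
                            mean_fam = mean(lt_fam),
                            sd_fam = stats::sd(lt_fam),
                            mean_nov = mean(lt_nov),
                            sd_nov = stats::sd(lt_nov),
                            t = tt$t, p = tt$p_two_sided, sign = sgn,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  attr(out, "score_mode") <- score_mode
  attr(out, "rho") <- rho
  attr(out, "mode") <- mode
  class(out) <- c("hpp_grid", class(out))
  out
}

#' @export
print.hpp_grid <- function(x, ...) {
  tb <- table(factor(x$sign, levels = c("familiar", "novel", "none")))
  cat(sprintf(paste0("<hpp_grid (%s scores): %d cells (%d alpha x %d ",
                     "theta); %d familiar, %d novel, %d n.s.>\n"),
              attr(x, "score_mode"), nrow(x), length(unique(x$alpha)),
              length(unique(x$theta)), tb[["familiar"]], tb[["novel"]],
              tb[["none"]]))
  invisible(x)
}

#' Export scores and significance grids as CSV files
#'
#' @param grid An [run_grid()] result (or a named list of them).
#' @param scores A [score_all_sentences()] table.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
export_results <- function(grid, scores, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory ", out_dir)
  }
  grids <- if (inherits(grid, "hpp_grid")) {
    stats::setNames(list(grid), attr(grid, "score_mode"))
  } else grid
  paths <- character(0)
  for (nm in names(grids)) {
    p <- file.path(out_dir, paste0("grid_", nm, ".csv"))
    utils::write.csv(as.data.frame(grids[[nm]]), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  sp <- file.path(out_dir, "sentence_scores.csv")
  utils::write.csv(as.data.frame(scores), sp, row.names = FALSE)
  paths <- c(paths, sp)
  summ <- do.call(rbind, lapply(c("single", "cluster"), function(m) {
    s <- sentence_score_test(scores, m)
    data.frame(mode = m, condition = c("familiar", "novel"),
               mean = s$mean, sd = s$sd, U = s$U, p = s$p_two_sided,
               stringsAsFactors = FALSE)
  }))
  pp <- file.path(out_dir, "score_summary.csv")
  utils::write.csv(summ, pp, row.names = FALSE)
  invisible(c(paths, pp))
}

#' Run a complete simulated headturn experiment
#'
#' End-to-end orchestration: generate (or accept) stimulus sets for the
#' familiarization and test speakers, encode them as HAC vectors (training
#' prototype codebooks on the familiarization speaker's background when in
#' audio mode), score all test sentences under both familiarization sets,
#' run the sentence-level Mann-Whitney tests, assemble test passages and
#' sweep the `(alpha, theta)` grid for both definitions of recognition.
#'
#' @param fam_speaker,test_speaker [speaker_profile()]s (may be
#'   identical).
#' @param words List of word specs; defaults to [default_word_specs()].
#' @param design An [hpp_design()].
#' @param stimulus_design A [default_stimulus_design()]; its counts should
#'   agree with `design`.
#' @param mode `"symbolic"` (fast, label streams) or `"audio"` (full
#'   waveform front end).
#' @param codebook_sizes Prototype inventory sizes (150/150/100).
#' @param alpha_values,theta_values Sweep grids.
#' @param seed Master seed; all stage seeds are derived from it.
#' @param ... Passed to [decompose()].
#' @return An object of class `hpp_experiment` holding the score table,
#'   sentence-level test results, passage set and the two significance
#'   grids.
#' @export
hpp_experiment <- function(fam_speaker, test_speaker = fam_speaker,
                           words = default_word_specs(),
                           design = hpp_design(),
                           stimulus_design = default_stimulus_design(
                             n_tokens = design$n_tokens,
                             n_sentences = design$n_sentences_per_word),
                           mode = c("symbolic", "audio"),
                           codebook_sizes = c(150L, 150L, 100L),
                           alpha_values = seq(0.01, 0.30, by = 0.01),
                           theta_values = seq(0.10, 1.50, by = 0.01),
                           seed = 1L, ...) {
  mode <- match.arg(mode)
  gen <- function(speaker, s) {
    if (mode == "symbolic") {
      generate_symbolic_set(words, speaker, stimulus_design,
                            codebook_sizes = codebook_sizes, seed = s)
    } else {
      generate_stimulus_set(words, speaker, stimulus_design, seed = s)
    }
  }
  same <- identical(fam_speaker, test_speaker)
  fam_set <- gen(fam_speaker, derive_seed(seed, "fam_stimuli"))
  test_set <- if (same) fam_set else
    gen(test_speaker, derive_seed(seed, "test_stimuli"))
  cb <- NULL
  if (mode == "audio") {
    feats <- lapply(fam_set$background, compute_features)
    cb <- train_codebooks(feats, sizes = codebook_sizes,
                          seed = derive_seed(seed, "codebooks"))
  }
  fam_enc <- encode_stimuli(fam_set, cb)
  test_enc <- if (same) fam_enc else encode_stimuli(test_set, cb)
  scores <- score_all_sentences(fam_enc, test_enc, design, ...)
  passages <- assemble_passages(scores, design,
                                seed = derive_seed(seed, "passages"))
  grids <- lapply(c(single = "single", cluster = "cluster"), function(m) {
    run_grid(passages, scores, score_mode = m,
             alpha_values = alpha_values, theta_values = theta_values)
  })
  structure(list(
    scores = scores,
    sentence_tests = list(single = sentence_score_test(scores, "single"),
                          cluster = sentence_score_test(scores, "cluster")),
    passages = passages, grids = grids,
    speaker_pair = c(fam_speaker$speaker_id, test_speaker$speaker_id),
    design = design, mode = mode, seed = as.integer(seed)),
    class = "hpp_experiment")
}

#' @export
print.hpp_experiment <- function(x, ...) {
  cat(sprintf("Simulated HPP experiment (%s mode, seed %d)\n", x$mode,
              x$seed))
  cat(sprintf("  speakers: familiarization %s, test %s\n",
              x$speaker_pair[1], x$speaker_pair[2]))
  cat(sprintf("  %d score records over %d sentences\n", nrow(x$scores),
              length(unique(x$scores$sentence_id))))
  for (m in names(x$sentence_tests)) {
    st <- x$sentence_tests[[m]]
    cat(sprintf(paste0("  %s scores: familiar %.2f%% (SD %.2f), novel ",
                       "%.2f%% (SD %.2f), Mann-Whitney p = %.3g\n"),
                m, st$mean[["familiar"]], st$sd[["familiar"]],
                st$mean[["novel"]], st$sd[["novel"]], st$p_two_sided))
  }
  for (m in names(x$grids)) {
    g <- x$grids[[m]]
    cat(sprintf("  %s grid: %d/%d cells familiar-signed, %d novel-signed\n",
                m, sum(g$sign == "familiar"), nrow(g),
                sum(g$sign == "novel")))
  }
  invisible(x)
}

#' @export
summary.hpp_experiment <- function(object, ...) {
  list(sentence_tests = object$sentence_tests,
       grid_cells = lapply(object$grids, function(g) table(g$sign)),
       speaker_pair = object$speaker_pair)
}
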