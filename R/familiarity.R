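#' Familiarity scores from a memory decomposition
#'
#' Two notions of recognition are supported, both expressed as a
#' percentage of the total weight mass over all memory entries (noise
#' included):
#'
#' * *single episode activation* ([single_episode_score()]): the maximum
#'   weight among the familiarization entries -- the familiarized tokens
#'   are treated as independent episodes;
#' * *cluster activation* ([cluster_score()]): the summed weight of all
#'   familiarization entries -- the tokens are treated as one cluster of
#'   related experiences.
#'
#' The cluster score is always at least the single-episode score, and both
#' are invariant to positive rescaling of the weight vector.  Scores are
#' computed once per test sentence: the decomposition weights only become
#' available at sentence end.
#'
#' @param w An [decompose()] result over `bank`.
#' @param bank The `hpp_memory` the decomposition was run against; must
#'   contain at least one familiarization entry.
#' @return A percentage in `[0, 100]`.
#' @name familiarity_scores
NULL

score_shares <- function(w, bank) {
  if (!inherits(w, "hpp_decomposition")) {
    stop_param("w must be an hpp_decomposition")
  }
  fam <- familiarization_index(bank)
  if (!length(fam)) {
    stop_state("memory holds no familiarization entries; familiarize() first")
  }
  if (length(w$weights) != memory_size(bank)) {
    stop_param("weight vector length does not match the memory size")
  }
  tot <- sum(w$weights)
  if (tot <= 0) stop_data("weight vector sums to zero")
  list(fam = w$weights[fam], tot = tot)
}

#' @rdname familiarity_scores
#' @export
single_episode_score <- function(w, bank) {
  s <- score_shares(w, bank)
  100 * max(s$fam) / s$tot
}

#' @rdname familiarity_scores
#' @export
cluster_score <- function(w, bank) {
  s <- score_shares(w, bank)
  100 * sum(s$fam) / s$tot
}
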