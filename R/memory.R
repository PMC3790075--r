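#' Build the episodic memory from background experience and noise
#'
#' The memory models what the infant brings to the experiment: HAC
#' representations of previously heard utterances (the background), plus a
#' single entry holding recording-session background noise.  The
#' familiarized word tokens are appended later by [familiarize()]; under
#' the defaults (100 background + 2 words x 5 tokens + 1 noise) the memory
#' holds 111 entries.
#'
#' @param background List of [encode_hac()] vectors (may be empty, with a
#'   warning).
#' @param noise A single [encode_hac()] vector (or a list of one).
#' @return An object of class `hpp_memory`: an entry metadata data frame
#'   (`role`, `word_id`, `token_id`) and a sparse dictionary matrix whose
#'   column `j` holds entry `j`'s counts.
#' @export
build_memory <- function(background, noise) {
  if (inherits(noise, "hpp_hac")) noise <- list(noise)
  entries <- c(background, noise)
  if (!length(background)) {
    warning("memory built without background experience (noise entry only)")
  }
  dims <- vapply(entries, function(h) length(h$counts), numeric(1))
  if (length(unique(dims)) != 1L) {
    stop_param("all HAC vectors must share one dimension")
  }
  totals <- vapply(entries, hac_total, numeric(1))
  if (any(totals <= 0)) {
    stop_data("memory entries must have positive total count (entry ",
              which(totals <= 0)[1], " is empty)")
  }
  meta <- data.frame(
    role = c(rep("background", length(background)),
             rep("noise", length(noise))),
    word_id = NA_character_, token_id = NA_integer_,
    stringsAsFactors = FALSE)
  structure(list(entries = entries, meta = meta,
                 dimension = as.integer(dims[1]), familiarized = FALSE),
            class = "hpp_memory")
}

#' Add familiarization word tokens to the memory
#'
#' Simulates the familiarization phase under full attention and error-free
#' storage: the HAC representations of the isolated word tokens are
#' appended verbatim as tagged episodes.  Can only be applied once per
#' memory.
#'
#' @param bank An [build_memory()] result.
#' @param tokens Named list: per familiarized word, a list of
#'   [encode_hac()] vectors (default design: 2 words x 5 tokens).
#' @return The augmented `hpp_memory`.
#' @export
familiarize <- function(bank, tokens) {
  if (!inherits(bank, "hpp_memory")) stop_param("bank must be an hpp_memory")
  if (isTRUE(bank$familiarized)) {
    stop_state("memory has already been familiarized")
  }
  if (!is.list(tokens) || is.null(names(tokens)) || any(names(tokens) == "")) {
    stop_param("tokens must be a named list (one element per word)")
  }
  flat <- unlist(tokens, recursive = FALSE)
  dims <- vapply(flat, function(h) length(h$counts), numeric(1))
  if (any(dims != bank$dimension)) {
    stop_param("familiarization HAC dimension does not match the memory")
  }
  wlab <- rep(names(tokens), times = lengths(tokens))
  tlab <- unlist(lapply(tokens, function(tk) seq_along(tk)))
  meta <- rbind(bank$meta,
                data.frame(role = "familiarization", word_id = wlab,
                           token_id = as.integer(tlab),
                           stringsAsFactors = FALSE))
  bank$entries <- c(bank$entries, flat)
  bank$meta <- meta
  bank$familiarized <- TRUE
  bank
}

#' Indices of the familiarization entries in a memory
#'
#' @param bank An `hpp_memory`.
#' @return Integer vector of entry indices (order-preserving).
#' @export
familiarization_index <- function(bank) {
  which(bank$meta$role == "familiarization")
}

memory_size <- function(bank) length(bank$entries)

# Sparse dictionary matrix view: dimension x M, column j = entry j.
memory_dictionary <- function(bank) {
  ii <- unlist(lapply(bank$entries, function(h) h$counts@i))
  jj <- rep(seq_along(bank$entries),
            times = vapply(bank$entries, function(h) length(h$counts@i),
                           integer(1)))
  xx <- unlist(lapply(bank$entries, function(h) h$counts@x))
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(bank$dimension, length(bank$entries)))
}

#' @export
print.hpp_memory <- function(x, ...) {
  tb <- table(x$meta$role)
  cat(sprintf("<hpp_memory: %d entries (%s)%s>\n", memory_size(x),
              paste(sprintf("%s %d", names(tb), tb), collapse = ", "),
              if (x$familiarized) "" else ", not yet familiarized"))
  invisible(x)
}

#' @export
summary.hpp_memory <- function(object, ...) {
  m <- object$meta
  m$total_count <- vapply(object$entries, hac_total, numeric(1))
  m
}
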