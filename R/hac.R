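#' Dimension of a histogram of acoustic co-occurrences
#'
#' Each of the three label classes contributes one `K_c x K_c` block of
#' ordered label-pair counts per time lag, so the total dimension is
#' `n_lags * (K1^2 + K2^2 + K3^2)`.  Under the default inventories
#' (150/150/100) and the two lags (20 and 50 ms) this is 110,000.
#'
#' @param sizes Integer triple `(K1, K2, K3)`.
#' @param n_lags Number of co-occurrence lags (default 2).
#' @return Integer vector dimension.
#' @examples
#' hac_dimension(c(150, 150, 100), 2)  # 110000
#' @export
hac_dimension <- function(sizes, n_lags = 2L) {
  sizes <- as.integer(sizes)
  if (length(sizes) != 3L || any(sizes < 1L)) {
    stop_param("sizes must be three positive integers")
  }
  if (n_lags < 1L) stop_param("n_lags must be >= 1")
  d <- as.numeric(n_lags) * sum(as.numeric(sizes)^2)
  if (d <= .Machine$integer.max) as.integer(d) else d
}

#' Encode a label stream as a histogram of acoustic co-occurrences
#'
#' Counts, for each label class and each lag `L` (in frames: 20 ms -> 2,
#' 50 ms -> 5 at the 10 ms hop), the ordered pairs
#' `(label_t, label_\{t+L\})` for `t = 1 .. T - L`, into a fixed-dimension
#' sparse non-negative count vector.  Any-length utterance therefore maps
#' to the same dimension; streams shorter than a lag contribute zero to
#' that lag's blocks.
#'
#' Layout: blocks ordered lag-major then class
#' (`lag1/static, lag1/delta, lag1/deltadelta, lag2/static, ...`), each
#' block in column-major `(i, j)` order with `i` the earlier label.
#'
#' @param ls An [label_stream()].
#' @param lags_ms Co-occurrence lags in milliseconds; each must be a
#'   multiple of the 10 ms frame hop.  Default `c(20, 50)`.
#' @return An object of class `hpp_hac`: a [Matrix::sparseVector()] of
#'   counts plus layout metadata (`sizes`, `lags_ms`, `duration_s` when
#'   the stream carries one).
#' @export
encode_hac <- function(ls, lags_ms = c(20, 50)) {
  if (!inherits(ls, "hpp_label_stream")) {
    stop_param("ls must be an hpp_label_stream")
  }
  if (any(lags_ms %% ls$frame_hop_ms != 0)) {
    stop_param("lags must be multiples of the ", ls$frame_hop_ms,
               " ms frame hop")
  }
  lags <- as.integer(lags_ms / ls$frame_hop_ms)
  sizes <- ls$sizes
  labs <- list(ls$labels_static, ls$labels_delta, ls$labels_deltadelta)
  T_ <- length(ls)
  dim_total <- hac_dimension(sizes, length(lags))
  block_sizes <- rep(sizes^2, times = length(lags))
  offsets <- cumsum(c(0L, block_sizes[-length(block_sizes)]))
  idx_all <- integer(0)
  cnt_all <- integer(0)
  b <- 0L
  for (l in seq_along(lags)) {
    L <- lags[l]
    for (c_ in 1:3) {
      b <- b + 1L
      if (T_ > L) {
        i <- labs[[c_]][1:(T_ - L)]
        j <- labs[[c_]][(1L + L):T_]
        cell <- (j - 1L) * sizes[c_] + i  # column-major within the block
        tab <- table(cell)
        idx_all <- c(idx_all, offsets[b] + as.integer(names(tab)))
        cnt_all <- c(cnt_all, as.integer(tab))
      }
    }
  }
  o <- order(idx_all)
  v <- Matrix::sparseVector(x = as.numeric(cnt_all[o]), i = idx_all[o],
                            length = dim_total)
  structure(list(counts = v, sizes = sizes, lags_ms = lags_ms,
                 n_frames = T_,
                 duration_s = attr(ls, "duration_s") %||% (T_ / 100)),
            class = "hpp_hac")
}

hac_total <- function(h) sum(h$counts@x)

#' @export
print.hpp_hac <- function(x, ...) {
  cat(sprintf("<hpp_hac: dimension %d, %d nonzero cells, total count %d>\n",
              length(x$counts), length(x$counts@i), as.integer(hac_total(x))))
  invisible(x)
}
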