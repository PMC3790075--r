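#' Prototype label streams
#'
#' The quantized form of an utterance: three parallel integer sequences of
#' equal length, one label per 10 ms frame per feature class (static,
#' delta, delta-delta).
#'
#' @param labels_static,labels_delta,labels_deltadelta Integer vectors of
#'   equal length `T`; class-`c` labels must lie in `[1, sizes[c]]`.
#' @param sizes Integer triple of prototype inventory sizes.
#' @return An object of class `hpp_label_stream`.
#' @export
label_stream <- function(labels_static, labels_delta, labels_deltadelta,
                         sizes) {
  sizes <- as.integer(sizes)
  lab <- list(as.integer(labels_static), as.integer(labels_delta),
              as.integer(labels_deltadelta))
  n <- unique(lengths(lab))
  if (length(n) != 1L) stop_param("the three label sequences differ in length")
  for (c_ in 1:3) {
    if (length(lab[[c_]]) && (min(lab[[c_]]) < 1L || max(lab[[c_]]) > sizes[c_])) {
      stop_param("class ", c_, " labels outside [1, ", sizes[c_], "]")
    }
  }
  structure(list(labels_static = lab[[1]], labels_delta = lab[[2]],
                 labels_deltadelta = lab[[3]], sizes = sizes,
                 frame_hop_ms = 10),
            class = "hpp_label_stream")
}

#' @export
print.hpp_label_stream <- function(x, ...) {
  cat(sprintf("<hpp_label_stream: %d frames, inventories %s>\n",
              length(x$labels_static), paste(x$sizes, collapse = "/")))
  invisible(x)
}

#' @export
length.hpp_label_stream <- function(x) length(x$labels_static)

# --- k-means internals --------------------------------------------------

# k-means++ seeding (Arthur & Vassilvitskii) on the rows of X.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(n, 1L)
  centers[1, ] <- X[idx, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = p)
    }
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

# Squared Euclidean distances between rows of X and rows of C.
dist2_mat <- function(X, C) {
  # |x - c|^2 = |x|^2 - 2 x.c + |c|^2 ; clamp tiny negatives from roundoff
  d <- outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
  pmax(d, 0)
}

# Lloyd iterations with k-means++ seeding, a relative-distortion stopping
# rule and empty-cluster repair (respawn on the worst-fit point of the
# highest-distortion cluster), returning the per-iteration distortion
# trace.  The trace and the repair rule are part of the training contract,
# which is why this is not a call to stats::kmeans.
kmeans_lloyd <- function(X, k, max_iter = 50L, tol = 1e-4) {
  if (nrow(X) < k) stop_data("fewer frames (", nrow(X), ") than prototypes (",
                             k, ")")
  C <- kmeanspp_init(X, k)
  trace <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    d2 <- dist2_mat(X, C)
    assign <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: move the empty center onto the point farthest
    # from its center within the highest-distortion cluster
    repeat {
      empty <- setdiff(seq_len(k), unique(assign))
      if (!length(empty)) break
      per_cl <- vapply(seq_len(k), function(j) {
        m <- assign == j
        if (any(m)) sum(d2[cbind(which(m), j)]) else 0
      }, numeric(1))
      sizes_cl <- tabulate(assign, k)
      per_cl[sizes_cl <= 1L] <- -Inf  # avoid emptying a singleton in turn
      worst <- which.max(per_cl)
      members <- which(assign == worst)
      far <- members[which.max(d2[cbind(members, worst)])]
      C[empty[1], ] <- X[far, ]
      assign[far] <- empty[1]
      d2[, empty[1]] <- rowSums(sweep(X, 2, C[empty[1], ])^2)
    }
    distortion <- mean(d2[cbind(seq_len(nrow(X)), assign)])
    for (j in seq_len(k)) {
      C[j, ] <- colMeans(X[assign == j, , drop = FALSE])
    }
    trace <- c(trace, distortion)
    if (distortion == 0) break
    if (is.finite(prev) && prev > 0 &&
        (prev - distortion) / prev < tol) break
    prev <- distortion
  }
  list(centers = C, distortion_trace = trace, assign = assign)
}

#' Learn the acoustic prototype codebooks
#'
#' Trains three independent codebooks (static, delta, delta-delta) by
#' seeded k-means over the pooled frames of a feature collection.
#' Defaults follow the model configuration: 150, 150 and 100 prototypes.
#'
#' @param features List of [compute_features()] results (the training
#'   material; typically the background utterances of the experiment's
#'   speaker).
#' @param sizes Integer triple `(K1, K2, K3)` of codebook sizes.
#' @param seed Integer seed; training is reproducible under it.
#' @param max_iter,tol Lloyd iteration cap (50) and relative-distortion
#'   stopping tolerance (1e-4).
#' @return An object of class `hpp_codebooks` with fields
#'   `prototypes_static`, `prototypes_delta`, `prototypes_deltadelta`
#'   (`K x 13` matrices), per-class `distortion_trace`s and the training
#'   seed.
#' @export
train_codebooks <- function(features, sizes = c(150L, 150L, 100L),
                            seed = 1L, max_iter = 50L, tol = 1e-4) {
  sizes <- as.integer(sizes)
  if (length(sizes) != 3L || any(sizes < 1L)) {
    stop_param("sizes must be three positive integers")
  }
  pool <- function(block) {
    t(do.call(cbind, lapply(features, function(f) f[[block]])))
  }
  blocks <- c("static", "delta", "deltadelta")
  out <- vector("list", 3L)
  traces <- vector("list", 3L)
  for (c_ in 1:3) {
    X <- pool(blocks[c_])
    if (nrow(X) < sizes[c_]) {
      stop_data("pooled frame count ", nrow(X),
                " is below codebook size ", sizes[c_])
    }
    fit <- with_seed(derive_seed(seed, blocks[c_]),
                     kmeans_lloyd(X, sizes[c_], max_iter, tol))
    out[[c_]] <- fit$centers
    traces[[c_]] <- fit$distortion_trace
  }
  structure(list(prototypes_static = out[[1]], prototypes_delta = out[[2]],
                 prototypes_deltadelta = out[[3]], sizes = sizes,
                 distortion_trace = stats::setNames(traces, blocks),
                 train_seed = as.integer(seed)),
            class = "hpp_codebooks")
}

#' @export
print.hpp_codebooks <- function(x, ...) {
  cat(sprintf("<hpp_codebooks: %s prototypes (static/delta/deltadelta)>\n",
              paste(x$sizes, collapse = "/")))
  invisible(x)
}

#' Quantize features against the prototype codebooks
#'
#' Replaces each frame's static, delta and delta-delta vectors by the index
#' of their nearest prototype (Euclidean distance; ties broken by the
#' lowest index), yielding three parallel label streams.
#'
#' @param f An [compute_features()] result.
#' @param cb An [train_codebooks()] result of matching dimension.
#' @return An `hpp_label_stream` of the same length as `f`.
#' @export
quantize <- function(f, cb) {
  if (!inherits(f, "hpp_features")) stop_param("f must be hpp_features")
  if (!inherits(cb, "hpp_codebooks")) stop_param("cb must be hpp_codebooks")
  qc <- function(block, protos) {
    X <- t(f[[block]])
    if (ncol(X) != ncol(protos)) {
      stop_param("feature dimension ", ncol(X),
                 " does not match codebook dimension ", ncol(protos))
    }
    max.col(-dist2_mat(X, protos), ties.method = "first")
  }
  label_stream(qc("static", cb$prototypes_static),
               qc("delta", cb$prototypes_delta),
               qc("deltadelta", cb$prototypes_deltadelta),
               cb$sizes)
}
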