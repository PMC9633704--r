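#' Vectorize the strict upper triangle of a symmetric matrix
#'
#' Returns the strict upper-triangle entries in R's native column-major
#' order: (1,2), (1,3), (2,3), (1,4), ... This ordering is used consistently
#' wherever connectivity matrices are compared, so any fixed ordering yields
#' identical similarities.
#'
#' @param m Square matrix.
#' @return Numeric vector of length `R*(R-1)/2`.
#' @export
vectorize_upper <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("vectorize_upper: input must be square")
  m[upper.tri(m)]
}

# Rebuild a symmetric matrix (unit diagonal by default) from its strict
# upper triangle; inverse of vectorize_upper up to the diagonal.
unvectorize_upper <- function(v, R, diag_value = 1) {
  stopifnot(length(v) == R * (R - 1) / 2)
  m <- matrix(0, R, R)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Build the meta-matrix of pairwise connectivity-pattern similarities
#'
#' The meta-matrix (also called functional connectivity dynamics) holds, at
#' entry (i, j), the similarity between the vectorized upper triangles of
#' connectivity matrices i and j, with windows ordered in time. The primary
#' metric is Pearson correlation (a similarity, diagonal 1); Manhattan and
#' cosine distances are provided as alternatives (distances, diagonal 0).
#'
#' @param cs A `connectivity_series` with at least 2 unflagged windows.
#' @param metric One of "pearson", "manhattan", "cosine".
#' @return Object of class `"meta_matrix"`: the N x N matrix with
#'   attributes `metric`, `orientation` ("similarity" or "distance") and
#'   `n_windows`.
#' @export
build_meta_matrix <- function(cs, metric = c("pearson", "manhattan", "cosine")) {
  metric <- match.arg(metric)
  stopifnot(inherits(cs, "connectivity_series"))
  if (length(cs$flagged))
    stop("build_meta_matrix: flagged (degenerate) windows present: ",
         paste(cs$flagged, collapse = ", "))
  N <- n_windows(cs)
  if (N < 2) stop("build_meta_matrix: need at least 2 windows")
  R_ <- dim(cs$matrices)[1]
  V <- apply(cs$matrices, 3, vectorize_upper)  # (R(R-1)/2) x N
  V <- matrix(V, ncol = N)
  if (metric == "pearson") {
    mm <- stats::cor(V)
    orientation <- "similarity"
  } else if (metric == "manhattan") {
    mm <- as.matrix(stats::dist(t(V), method = "manhattan"))
    orientation <- "distance"
  } else {
    nrm <- sqrt(colSums(V^2))
    cos_sim <- crossprod(V) / tcrossprod(nrm)
    mm <- 1 - cos_sim
    mm[mm < 0] <- 0  # numerical guard
    diag(mm) <- 0
    orientation <- "distance"
  }
  dimnames(mm) <- NULL
  structure(mm, metric = metric, orientation = orientation, n_windows = N,
            class = c("meta_matrix", "matrix", "array"))
}

#' @export
print.meta_matrix <- function(x, ...) {
  cat("Meta-matrix: ", attr(x, "n_windows"), " windows, metric = ",
      attr(x, "metric"), " (", attr(x, "orientation"), ")\n", sep = "")
  invisible(x)
}

#' Heatmap of a meta-matrix
#'
#' @param x A `meta_matrix`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.meta_matrix <- function(x, ...) {
  N <- attr(x, "n_windows")
  graphics::image(seq_len(N), seq_len(N), unclass(x)[, N:1],
                  xlab = "window", ylab = "window",
                  main = paste0("Meta-matrix (", attr(x, "metric"), ")"), ...)
  invisible(x)
}

#' Temporal decay of similarity model (TDSM)
#'
#' A synthetic meta-matrix whose entries decay monotonically with the lag
#' between windows: the model of a state trajectory that never revisits past
#' states. Three profiles are available. The exponential kinds use the lag
#' profile `u = exp(l/c)` where `l` is the arithmetic sequence from
#' `log(0.0001)` to `log(1)` over n points, with decay constant `c = 3`
#' (slow) or `c = 1.5` (fast); the linear kind uses `u[i] = i/(n-1)`. The
#' model matrix is `M[i, j] = u[(n-1) - |i-j|]` (1 on the diagonal, smallest
#' at the largest lag).
#'
#' @param n Matrix side (number of windows), n >= 2.
#' @param kind One of "exp_slow", "exp_fast", "linear".
#' @return Object of class `"tdsm"`: the n x n model matrix with attributes
#'   `kind`, `profile` (the length-n lag profile u) and `n_windows`.
#' @export
build_tdsm <- function(n, kind = c("exp_slow", "exp_fast", "linear")) {
  kind <- match.arg(kind)
  stopifnot(n >= 2)
  if (kind == "linear") {
    u <- seq(0, 1, length.out = n)
  } else {
    c_ <- if (kind == "exp_slow") 3 else 1.5
    u <- exp(seq(log(0.0001), log(1), length.out = n) / c_)
  }
  lag <- abs(outer(seq_len(n), seq_len(n), "-"))
  M <- matrix(u[n - lag], n, n)
  structure(M, kind = kind, profile = u, n_windows = n,
            class = c("tdsm", "matrix", "array"))
}

#' Fit of a meta-matrix to a temporal decay model
#'
#' Pearson correlation between the strict upper triangles of the meta-matrix
#' and the model matrix (the trivially-1 diagonal is excluded). Distance-
#' oriented meta-matrices are negated before fitting so that "higher = more
#' similar" holds in both operands; the fit is then on the same footing as
#' for similarity matrices.
#'
#' @param mm A `meta_matrix`.
#' @param model A `tdsm` of matching size (or the kind name, in which case
#'   the model is built to match).
#' @return Correlation in `[-1, 1]`.
#' @export
tdsm_fit <- function(mm, model = "exp_slow") {
  stopifnot(inherits(mm, "meta_matrix"))
  if (is.character(model)) model <- build_tdsm(attr(mm, "n_windows"), model)
  if (attr(mm, "n_windows") != attr(model, "n_windows"))
    stop("tdsm_fit: meta-matrix and model sizes differ")
  v <- vectorize_upper(unclass(mm))
  if (identical(attr(mm, "orientation"), "distance")) v <- -v
  stats::cor(v, vectorize_upper(unclass(model)))
}

#' 2-D embedding of a meta-matrix
#'
#' Classical metric multidimensional scaling on the pairwise Euclidean
#' distances between meta-matrix columns: each window is placed in a
#' low-dimensional plane so nearby points have similar intrinsic
#' relationships to all other windows. Coordinates are centred at the
#' origin.
#'
#' @param mm A `meta_matrix`.
#' @param dims Embedding dimension (default 2), must be < N.
#' @return N x dims coordinate matrix of class `"mm_embedding"`.
#' @export
embed_mm <- function(mm, dims = 2) {
  stopifnot(inherits(mm, "meta_matrix"))
  N <- attr(mm, "n_windows")
  if (dims >= N) stop("embed_mm: dims must be smaller than the number of windows")
  D <- stats::dist(t(unclass(mm)))
  xy <- stats::cmdscale(D, k = dims)
  if (is.null(dim(xy))) xy <- matrix(xy, nrow = N)
  if (ncol(xy) < dims) {
    # degenerate geometry (e.g. identical columns): pad with zero axes
    xy <- cbind(xy, matrix(0, N, dims - ncol(xy)))
  }
  structure(xy, class = c("mm_embedding", "matrix", "array"))
}

#' @export
plot.mm_embedding <- function(x, ...) {
  N <- nrow(x)
  graphics::plot(x[, 1], x[, 2], col = grDevices::hcl.colors(N, "Zissou 1"),
                 pch = 16, xlab = "dim 1", ylab = "dim 2",
                 main = "Meta-matrix embedding (time as colour)", ...)
  invisible(x)
}
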