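#' Extract one sub-diagonal of a meta-matrix
#'
#' The lag-`lag` sub-diagonal holds the similarity between windows `i` and
#' `i + lag` in temporal order: the series of connectivity-pattern
#' transitions `lag` window-steps apart (1 step = 1 TR at the default
#' step of 1).
#'
#' @param mm A `meta_matrix` (or plain square matrix).
#' @param lag Lag in window steps, `1 <= lag <= N - 1`.
#' @return Numeric vector of length `N - lag`.
#' @export
subdiagonal_series <- function(mm, lag = 1) {
  m <- unclass(as.matrix(mm))
  N <- nrow(m)
  if (lag < 1 || lag > N - 1)
    stop("subdiagonal_series: lag must be in 1..N-1")
  i <- seq_len(N - lag)
  m[cbind(i, i + lag)]
}

#' Proximal transition series of a meta-matrix
#'
#' The short-range transition profile: for `max_lag = 1`, the first
#' sub-diagonal (similarity between successive connectivity patterns); for
#' `max_lag = L > 1`, the element-wise mean over sub-diagonals 1..L aligned
#' on their start index and truncated to the common length `N - L`.
#'
#' @param mm A `meta_matrix`.
#' @param max_lag Largest sub-diagonal averaged in (default 1; 6 and 13 are
#'   the usual multi-lag choices, i.e. 12 s and 26 s at TR = 2 s).
#' @return Object of class `"proximal_series"`: numeric vector of length
#'   `N - max_lag` with attributes `max_lag`, `metric`, `orientation`.
#' @export
proximal_series <- function(mm, max_lag = 1) {
  m <- unclass(as.matrix(mm))
  N <- nrow(m)
  if (max_lag < 1 || max_lag > N - 1)
    stop("proximal_series: max_lag must be in 1..N-1")
  len <- N - max_lag
  acc <- numeric(len)
  for (l in seq_len(max_lag)) acc <- acc + subdiagonal_series(m, l)[seq_len(len)]
  structure(acc / max_lag, max_lag = max_lag,
            metric = attr(mm, "metric"), orientation = attr(mm, "orientation"),
            class = "proximal_series")
}

#' @export
print.proximal_series <- function(x, ...) {
  cat("Proximal transition series: length", length(unclass(x)),
      ", lags 1..", attr(x, "max_lag"), "\n", sep = "")
  invisible(x)
}

#' Summary measures of a scalar series
#'
#' Central tendency (mean, median), breadth (standard deviation, Shannon
#' entropy of the binned values), temporal complexity (sample entropy,
#' normalized effort-to-compress) and the mean absolute first difference
#' (how much the series' level changes per step).
#'
#' For a constant series the entropies are defined as 0 and the result is
#' flagged `degenerate`.
#'
#' @param x Numeric vector, length >= 4 for the entropy measures.
#' @param bins Bins for Shannon entropy and ETC symbolization (default 10).
#' @param sampen_m,sampen_r Sample-entropy template length and tolerance
#'   coefficient (defaults 1 and 0.2).
#' @return Object of class `"measure_set"`: named list with elements
#'   `mean`, `median`, `sd`, `shannon_entropy`, `sample_entropy`,
#'   `effort_to_compress_norm`, `mean_abs_derivative`, and a logical
#'   `degenerate` flag.
#' @export
summarize_series <- function(x, bins = 10, sampen_m = 1, sampen_r = 0.2) {
  x <- as.numeric(x)
  if (length(x) < 4) stop("summarize_series: need at least 4 values")
  if (anyNA(x)) stop("summarize_series: input contains missing values")
  degenerate <- stats::sd(x) == 0
  se <- if (degenerate) 0 else {
    v <- sample_entropy(x, m = sampen_m, r_coeff = sampen_r)
    as.numeric(v)
  }
  structure(list(
    mean = mean(x),
    median = stats::median(x),
    sd = stats::sd(x),
    shannon_entropy = shannon_entropy(x, bins = bins),
    sample_entropy = se,
    effort_to_compress_norm = etc_norm(x, bins = bins),
    mean_abs_derivative = mean(abs(diff(x))),
    degenerate = degenerate
  ), class = "measure_set")
}

#' @export
print.measure_set <- function(x, ...) {
  vals <- unlist(x[c("mean", "median", "sd", "shannon_entropy",
                     "sample_entropy", "effort_to_compress_norm",
                     "mean_abs_derivative")])
  print(round(vals, 4))
  if (isTRUE(x$degenerate)) cat("(degenerate: constant series)\n")
  invisible(x)
}

#' Distal meta-matrix
#'
#' Removes the `k` lags closest to the diagonal and mirrors the remaining
#' off-diagonal triangle across its new diagonal:
#' `D[a, b] = MM[min(a, b), max(a, b) + k]` for `a != b`, with the diagonal
#' left undefined (`NA`). Every defined cell corresponds to a meta-matrix
#' cell of source lag `k + 1 .. N - 1`, so distal relations are isolated
#' from window-overlap autocorrelation.
#'
#' @param mm A `meta_matrix` with N windows.
#' @param k Exclusion lag, `1 <= k <= N - 3` (defaults: 13 primary — just
#'   over half a 24-point window, 26 s at TR 2 s; 24 as sensitivity —
#'   fully non-overlapping windows).
#' @return Object of class `"distal_matrix"`: M x M matrix (M = N - k) with
#'   `NA` diagonal and attributes `k`, `metric`, `orientation`.
#' @export
build_distal_matrix <- function(mm, k = 13) {
  m <- unclass(as.matrix(mm))
  N <- nrow(m)
  if (k < 1 || k > N - 3)
    stop("build_distal_matrix: fewer than 2 distal lags remain")
  M <- N - k
  a <- as.vector(matrix(seq_len(M), M, M))
  b <- as.vector(t(matrix(seq_len(M), M, M)))
  D <- matrix(m[cbind(pmin(a, b), pmax(a, b) + k)], M, M)
  diag(D) <- NA_real_
  structure(D, k = k, metric = attr(mm, "metric"),
            orientation = attr(mm, "orientation"),
            class = c("distal_matrix", "matrix", "array"))
}

#' Complexity measures of the distal meta-matrix
#'
#' In `per_column` mode each column's defined cells (ordered by ascending
#' row index, i.e. the temporal order of the partner windows) form one
#' sequence; the sequences are summarized with [summarize_series()] and the
#' measures averaged over columns. In `vectorized` mode all defined strict
#' upper-triangle cells form a single column-major sequence. Both modes also
#' report `mean_max_similarity`, the mean over columns of each column's
#' maximum — the average best match a state finds among its temporally
#' distant alternatives.
#'
#' @param mm A `meta_matrix`.
#' @param k Exclusion lag passed to [build_distal_matrix()].
#' @param mode "per_column" (default) or "vectorized".
#' @inheritParams summarize_series
#' @return A `measure_set` with an extra element `mean_max_similarity`.
#'   Columns with fewer than 4 defined cells are skipped (with a message).
#' @export
distal_measures <- function(mm, k = 13, mode = c("per_column", "vectorized"),
                            bins = 10, sampen_m = 1, sampen_r = 0.2) {
  mode <- match.arg(mode)
  D <- build_distal_matrix(mm, k)
  Dm <- unclass(D)
  M <- nrow(Dm)
  col_seqs <- lapply(seq_len(M), function(b) Dm[!is.na(Dm[, b]), b])
  mean_max <- mean(vapply(col_seqs, max, numeric(1)))
  fields <- c("mean", "median", "sd", "shannon_entropy", "sample_entropy",
              "effort_to_compress_norm", "mean_abs_derivative")
  if (mode == "vectorized") {
    v <- Dm[upper.tri(Dm)]
    ms <- summarize_series(v, bins = bins, sampen_m = sampen_m,
                           sampen_r = sampen_r)
    out <- ms[fields]
    degenerate <- isTRUE(ms$degenerate)
  } else {
    usable <- vapply(col_seqs, length, integer(1)) >= 4
    if (!all(usable))
      message("distal_measures: skipping ", sum(!usable),
              " column(s) with < 4 defined cells")
    if (!any(usable)) stop("distal_measures: no usable columns")
    per_col <- lapply(col_seqs[usable], summarize_series, bins = bins,
                      sampen_m = sampen_m, sampen_r = sampen_r)
    out <- lapply(fields, function(f)
      mean(vapply(per_col, function(m) as.numeric(m[[f]]), numeric(1)),
           na.rm = TRUE))
    names(out) <- fields
    degenerate <- all(vapply(per_col, function(m) isTRUE(m$degenerate),
                             logical(1)))
  }
  out$mean_max_similarity <- mean_max
  out$degenerate <- degenerate
  class(out) <- "measure_set"
  out
}
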