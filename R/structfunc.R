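#' Construct a structural connectome object
#'
#' @param weights Symmetric nonnegative R x R matrix with zero diagonal
#'   (e.g. streamline counts from tractography).
#' @return Object of class `"structural_connectome"` with attribute
#'   `n_edges` (count of nonzero strict upper-triangle cells).
#' @export
structural_connectome <- function(weights) {
  w <- as.matrix(weights)
  if (nrow(w) != ncol(w)) stop("structural_connectome: matrix must be square")
  if (any(w < 0)) stop("structural_connectome: weights must be nonnegative")
  if (any(abs(w - t(w)) > 1e-10)) stop("structural_connectome: matrix must be symmetric")
  if (any(diag(w) != 0)) stop("structural_connectome: diagonal must be zero")
  E <- sum(w[upper.tri(w)] > 0)
  if (E < 1) stop("empty connectome")
  structure(w, n_edges = E,
            class = c("structural_connectome", "matrix", "array"))
}

#' @export
print.structural_connectome <- function(x, ...) {
  cat("Structural connectome:", nrow(x), "regions,", attr(x, "n_edges"),
      "edges\n")
  invisible(x)
}

#' Proportionally threshold a functional connectivity matrix
#'
#' Retains exactly `target_edges` strict upper-triangle cells — the largest
#' by signed value (or by absolute value with `rank = "absolute"`) — and
#' zeroes the rest, then symmetrizes and zeroes the diagonal. Used to match
#' a functional matrix's density to a structural connectome's edge count
#' before comparing the two. Ties straddling the cutoff are resolved
#' deterministically by (value, row, column) ordering.
#'
#' @param fc Symmetric R x R functional connectivity matrix.
#' @param target_edges Number of edges E to retain,
#'   `1 <= E <= R*(R-1)/2`.
#' @param rank "signed" (default; most-positive correlations retained) or
#'   "absolute".
#' @return R x R matrix with exactly E nonzero strict upper-triangle cells
#'   (fewer only if retained values are themselves 0).
#' @export
threshold_fc_to_density <- function(fc, target_edges,
                                    rank = c("signed", "absolute")) {
  rank <- match.arg(rank)
  fc <- as.matrix(fc)
  R_ <- nrow(fc)
  if (R_ != ncol(fc)) stop("threshold_fc_to_density: matrix must be square")
  n_up <- R_ * (R_ - 1) / 2
  if (target_edges < 1 || target_edges > n_up)
    stop("threshold_fc_to_density: target_edges out of range")
  up <- which(upper.tri(fc))
  vals <- fc[up]
  key <- if (rank == "signed") vals else abs(vals)
  rc <- arrayInd(up, dim(fc))
  ord <- order(-key, rc[, 1], rc[, 2])
  keep <- up[ord[seq_len(target_edges)]]
  out <- matrix(0, R_, R_)
  out[keep] <- fc[keep]
  out <- out + t(out)
  out
}

#' Structure-function dynamic similarity series
#'
#' For each window of a connectivity series: threshold the functional
#' matrix to the structural connectome's edge count, then compute the
#' similarity (Pearson by default) between the vectorized upper triangles
#' of the thresholded functional matrix and the structural weights. The
#' result is one similarity value per window — the timecourse of how
#' closely moment-to-moment functional patterns track the anatomical
#' backbone.
#'
#' @param cs A `connectivity_series`.
#' @param sc A [structural_connectome()] on the same regions.
#' @param metric "pearson" (default), "cosine" or "manhattan" ("manhattan"
#'   is a distance; the others are similarities).
#' @param rank Threshold ranking rule, see [threshold_fc_to_density()].
#' @param log_weights If TRUE, compare against `log1p` of the structural
#'   weights instead of the raw weights.
#' @return Object of class `"struct_func_series"`: numeric vector of length
#'   N with attributes `metric` and `flagged` (windows with undefined
#'   similarity, recorded as `NA`).
#' @export
struct_func_series <- function(cs, sc, metric = c("pearson", "cosine",
                                                  "manhattan"),
                               rank = "signed", log_weights = FALSE) {
  metric <- match.arg(metric)
  stopifnot(inherits(cs, "connectivity_series"),
            inherits(sc, "structural_connectome"))
  R_ <- dim(cs$matrices)[1]
  if (nrow(sc) != R_)
    stop("struct_func_series: region counts differ between series and connectome")
  E <- attr(sc, "n_edges")
  sv <- vectorize_upper(unclass(sc))
  if (log_weights) sv <- log1p(sv)
  N <- n_windows(cs)
  out <- numeric(N)
  flagged <- integer(0)
  for (n in seq_len(N)) {
    fcn <- cs$matrices[, , n]
    if (anyNA(fcn)) {
      out[n] <- NA_real_; flagged <- c(flagged, n); next
    }
    fv <- vectorize_upper(threshold_fc_to_density(fcn, E, rank = rank))
    val <- switch(metric,
      pearson = if (stats::sd(fv) == 0 || stats::sd(sv) == 0) NA_real_
                else stats::cor(fv, sv),
      cosine = {
        d <- sqrt(sum(fv^2)) * sqrt(sum(sv^2))
        if (d == 0) NA_real_ else sum(fv * sv) / d
      },
      manhattan = sum(abs(fv - sv)))
    if (is.na(val)) flagged <- c(flagged, n)
    out[n] <- val
  }
  structure(out, metric = metric, flagged = flagged,
            class = "struct_func_series")
}

#' @export
print.struct_func_series <- function(x, ...) {
  cat("Structure-function series: length", length(unclass(x)),
      ", metric =", attr(x, "metric"), "\n")
  if (length(attr(x, "flagged")))
    cat("  flagged windows:", paste(attr(x, "flagged"), collapse = ", "), "\n")
  invisible(x)
}

#' Complexity summary of a structure-function series
#'
#' Sample entropy and normalized effort-to-compress of the similarity
#' timecourse, plus its maximum (the best structural match any functional
#' window achieves). Flagged (undefined) windows are dropped before
#' computation.
#'
#' @param series A [struct_func_series()] result (or plain numeric vector).
#' @inheritParams summarize_series
#' @return Named list: `sample_entropy`, `effort_to_compress_norm`,
#'   `max_similarity`, `n_used`.
#' @export
struct_func_summary <- function(series, bins = 10, sampen_m = 1,
                                sampen_r = 0.2) {
  x <- as.numeric(series)
  dropped <- sum(is.na(x))
  if (dropped > 0) {
    message("struct_func_summary: dropping ", dropped, " undefined window(s)")
    x <- x[!is.na(x)]
  }
  if (length(x) < 4) stop("struct_func_summary: need at least 4 usable values")
  se <- if (stats::sd(x) == 0) 0 else
    as.numeric(sample_entropy(x, m = sampen_m, r_coeff = sampen_r))
  list(sample_entropy = se,
       effort_to_compress_norm = etc_norm(x, bins = bins),
       max_similarity = max(x),
       n_used = length(x))
}
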