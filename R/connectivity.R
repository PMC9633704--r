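#' Construct a parcellated region timeseries object
#'
#' @param values T x R numeric matrix, timepoints in rows, regions in columns.
#' @param tr_seconds Repetition time in seconds (default 2).
#' @param region_ids Optional character vector of R unique region labels.
#' @return Object of class `"region_ts"`: the matrix with `tr_seconds` and
#'   `region_ids` attributes.
#' @export
region_ts <- function(values, tr_seconds = 2, region_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("region_ts: values must be numeric")
  if (anyNA(values)) stop("region_ts: missing values not allowed")
  stopifnot(tr_seconds > 0)
  if (is.null(region_ids)) {
    region_ids <- colnames(values)
    if (is.null(region_ids)) region_ids <- paste0("R", seq_len(ncol(values)))
  }
  if (anyDuplicated(region_ids)) stop("region_ts: duplicate region ids")
  if (length(region_ids) != ncol(values))
    stop("region_ts: region_ids length must match the number of regions")
  colnames(values) <- region_ids
  structure(values, tr_seconds = tr_seconds, region_ids = region_ids,
            class = c("region_ts", "matrix", "array"))
}

#' @export
print.region_ts <- function(x, ...) {
  cat("Region timeseries:", nrow(x), "timepoints x", ncol(x),
      "regions, TR =", attr(x, "tr_seconds"), "s\n")
  invisible(x)
}

#' Gaussian taper weights for a sliding window
#'
#' Symmetric Gaussian weights centred on the window midpoint, de-weighting
#' timepoints near the window extremities; normalized to sum to 1.
#'
#' @param window_length Window length W >= 2 (timepoints).
#' @param sigma Gaussian standard deviation in timepoints; defaults to W/6.
#' @return Length-W vector of strictly positive weights summing to 1.
#' @export
gaussian_taper <- function(window_length, sigma = window_length / 6) {
  stopifnot(window_length >= 2)
  if (sigma <= 0) stop("gaussian_taper: sigma must be positive")
  centre <- (window_length + 1) / 2
  w <- exp(-0.5 * ((seq_len(window_length) - centre) / sigma)^2)
  w / sum(w)
}

#' Weighted Pearson correlation
#'
#' Correlation of two vectors under observation weights: the weighted
#' covariance divided by the product of weighted standard deviations. With
#' uniform weights this reduces to the ordinary Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length.
#' @param w Nonnegative weights summing to 1 (e.g. from [gaussian_taper()]).
#' @return Correlation in `[-1, 1]`, or `NA` (with a warning) if either
#'   input has zero weighted variance.
#' @export
weighted_pearson <- function(x, y, w) {
  n <- length(x)
  if (length(y) != n || length(w) != n)
    stop("weighted_pearson: x, y, w must have equal length")
  if (abs(sum(w) - 1) > 1e-8) stop("weighted_pearson: weights must sum to 1")
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) {
    warning("weighted_pearson: zero weighted variance; result undefined")
    return(NA_real_)
  }
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

# Weighted correlation matrix of the columns of X (weights sum to 1).
# Zero-variance columns give NA rows/columns.
weighted_cor_matrix <- function(X, w) {
  mu <- colSums(w * X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc, w * Xc)
  v <- diag(C)
  bad <- v <= 0
  s <- sqrt(ifelse(bad, NA_real_, v))
  R <- C / tcrossprod(s)
  if (!any(bad)) diag(R) <- 1
  list(cor = R, degenerate = any(bad))
}

#' Tapered sliding-window dynamic connectivity
#'
#' Computes, for each window of `window` consecutive timepoints advanced by
#' `step`, the taper-weighted Pearson correlation matrix between all region
#' pairs. The number of windows is `floor((T - W)/step) + 1`; window `n`
#' (1-based) covers timepoints `(n-1)*step + 1 .. (n-1)*step + W`.
#'
#' @param ts A [region_ts()] (or plain T x R matrix).
#' @param window Window length W in timepoints (default 24).
#' @param step Window advance in timepoints (default 1).
#' @param taper Length-W weight vector; defaults to
#'   `gaussian_taper(window)`. Pass `rep(1/window, window)` for an untapered
#'   window.
#' @return Object of class `"connectivity_series"`: list with `matrices`
#'   (R x R x N array), `window`, `step`, `taper`, `method = "windowed"`,
#'   `tr_seconds`, `region_ids`, and `flagged` (indices of windows containing
#'   a zero-variance region; their undefined entries are `NA`).
#' @export
sliding_window_connectivity <- function(ts, window = 24, step = 1,
                                        taper = gaussian_taper(window)) {
  X <- unclass(as.matrix(ts))
  T_ <- nrow(X); R_ <- ncol(X)
  stopifnot(window >= 2, step >= 1)
  if (T_ < window)
    stop("sliding_window_connectivity: series shorter than the window")
  if (length(taper) != window)
    stop("sliding_window_connectivity: taper length must equal the window")
  if (any(taper <= 0)) stop("sliding_window_connectivity: taper weights must be positive")
  taper <- taper / sum(taper)
  N <- (T_ - window) %/% step + 1L
  out <- array(NA_real_, dim = c(R_, R_, N))
  flagged <- integer(0)
  for (n in seq_len(N)) {
    idx <- ((n - 1L) * step + 1L):((n - 1L) * step + window)
    wc <- weighted_cor_matrix(X[idx, , drop = FALSE], taper)
    out[, , n] <- wc$cor
    if (wc$degenerate) flagged <- c(flagged, n)
  }
  structure(list(matrices = out, window = window, step = step, taper = taper,
                 method = "windowed",
                 tr_seconds = attr(ts, "tr_seconds"),
                 region_ids = if (is.null(colnames(X))) NULL else colnames(X),
                 flagged = flagged),
            class = "connectivity_series")
}

#' @export
print.connectivity_series <- function(x, ...) {
  cat("Connectivity series (", x$method, "): ", dim(x$matrices)[3],
      " matrices of ", dim(x$matrices)[1], " x ", dim(x$matrices)[2],
      if (x$method == "windowed")
        paste0(", W = ", x$window, ", step = ", x$step), "\n", sep = "")
  if (length(x$flagged))
    cat("  flagged windows:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Number of windows in a connectivity series
#' @param cs A `connectivity_series`.
#' @return Integer window count N.
#' @export
n_windows <- function(cs) dim(cs$matrices)[3]

#' Truncate a connectivity series to its first n windows
#'
#' Used to equalize window counts across subjects before meta-matrix
#' construction (cohorts are truncated to the minimum N, from the start of
#' the series).
#'
#' @param cs A `connectivity_series`.
#' @param n Number of windows to keep.
#' @return Truncated `connectivity_series`.
#' @export
truncate_series <- function(cs, n) {
  stopifnot(inherits(cs, "connectivity_series"), n >= 1, n <= n_windows(cs))
  cs$matrices <- cs$matrices[, , seq_len(n), drop = FALSE]
  cs$flagged <- cs$flagged[cs$flagged <= n]
  cs
}

# Analytic signal of a real vector via the one-sided spectrum (frequency-
# domain construction of the Hilbert transform pair).
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase-synchrony connectivity
#'
#' Band-passes each region's series (zero-phase second-order Butterworth,
#' applied forwards and backwards), extracts instantaneous phases from the
#' analytic signal, and computes per-timepoint pairwise synchrony
#' `1 - |sin((theta_i - theta_j)/2)|`, which lies in `[0, 1]` and equals 1
#' for identical phases. One matrix is produced per timepoint; `trim`
#' timepoints at each edge may be discarded to suppress filter transients.
#'
#' @param ts A [region_ts()]; its `tr_seconds` sets the sampling rate.
#' @param band_low,band_high Pass band in Hz (defaults 0.03 and 0.07, a
#'   narrow band satisfying the analytic-phase interpretability requirement).
#' @param trim Timepoints removed at each edge after synchrony computation
#'   (default 10).
#' @return A `connectivity_series` with `method = "phase"` and one matrix
#'   per retained timepoint.
#' @export
phase_synchrony_series <- function(ts, band_low = 0.03, band_high = 0.07,
                                   trim = 10) {
  X <- unclass(as.matrix(ts))
  tr <- attr(ts, "tr_seconds")
  if (is.null(tr)) tr <- 2
  nyq <- 1 / (2 * tr)
  if (band_low <= 0 || band_high >= nyq || band_low >= band_high)
    stop("phase_synchrony_series: band must lie within (0, Nyquist)")
  T_ <- nrow(X); R_ <- ncol(X)
  if (T_ < 30) stop("phase_synchrony_series: series too short for band-pass edge padding")
  bf <- signal::butter(2, c(band_low, band_high) / nyq, type = "pass")
  theta <- matrix(0, T_, R_)
  for (r in seq_len(R_)) {
    xf <- signal::filtfilt(bf, X[, r])
    theta[, r] <- Arg(analytic_signal(xf))
  }
  keep <- seq_len(T_)
  if (trim > 0) {
    if (2 * trim >= T_) stop("phase_synchrony_series: trim removes all timepoints")
    keep <- (trim + 1):(T_ - trim)
  }
  N <- length(keep)
  out <- array(NA_real_, dim = c(R_, R_, N))
  for (n in seq_len(N)) {
    d <- outer(theta[keep[n], ], theta[keep[n], ], "-")
    out[, , n] <- 1 - abs(sin(d / 2))
  }
  structure(list(matrices = out, window = NA_integer_, step = 1L,
                 taper = NULL, method = "phase", tr_seconds = tr,
                 region_ids = if (is.null(colnames(X))) NULL else colnames(X),
                 flagged = integer(0)),
            class = "connectivity_series")
}
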