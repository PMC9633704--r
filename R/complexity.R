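#' Shannon entropy of a binned real-valued series
#'
#' Bins the values into `bins` equal-width bins spanning the observed range
#' and returns the Shannon entropy (in bits) of the resulting histogram.
#' Empty bins contribute nothing; a constant input has zero entropy.
#'
#' @param x Numeric vector.
#' @param bins Number of equal-width bins (default 10).
#' @return Entropy in bits (base-2 logarithm), a single number.
#' @export
#' @examples
#' shannon_entropy(rnorm(200))
#' shannon_entropy(rep(1, 50))  # 0
shannon_entropy <- function(x, bins = 10) {
  stopifnot(is.numeric(x), length(x) >= 1, bins >= 1)
  if (anyNA(x)) stop("shannon_entropy: input contains missing values")
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  sym <- symbolize(x, bins = bins)
  p <- tabulate(sym + 1L, nbins = bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Discretize a real-valued series into integer symbols
#'
#' Equal-width binning over the observed range `[min, max]`, the maximum
#' mapping into the top bin. Symbols are 0-based integers; a constant input
#' yields the all-zero sequence with alphabet size 1.
#'
#' @param x Numeric vector.
#' @param bins Number of equal-width bins (default 10, the usual choice for
#'   short physiological series).
#' @return Integer vector of symbols in `0:(bins-1)` with attributes
#'   `alphabet` (number of distinct possible symbols) and `edges` (bin
#'   boundaries).
#' @export
symbolize <- function(x, bins = 10) {
  stopifnot(is.numeric(x), length(x) >= 1, bins >= 1)
  if (anyNA(x)) stop("symbolize: input contains missing values")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    sym <- integer(length(x))
    attr(sym, "alphabet") <- 1L
    attr(sym, "edges") <- rng
    return(sym)
  }
  width <- (rng[2] - rng[1]) / bins
  sym <- pmin.int(as.integer(floor((x - rng[1]) / width)), bins - 1L)
  attr(sym, "alphabet") <- as.integer(bins)
  attr(sym, "edges") <- seq(rng[1], rng[2], length.out = bins + 1)
  sym
}

#' Sample entropy of a real-valued series
#'
#' SampEn = -ln(A/B), where B counts ordered pairs of distinct length-`m`
#' templates whose Chebyshev distance is at most `r`, and A counts the same
#' for length `m+1` templates. The tolerance is `r = r_coeff * sd(x)`, so the
#' measure is invariant to affine rescaling of the input. Higher values mean
#' a less self-similar, less predictable series.
#'
#' A constant series (zero standard deviation) returns 0 with attribute
#' `degenerate = TRUE`. If no templates match at either length the ratio is
#' undefined and `NA` is returned with a warning (never silently 0 or Inf).
#'
#' @param x Numeric vector, length >= m + 2.
#' @param m Template length for the denominator count (default 1, i.e.
#'   template lengths 2 and 1 enter the ratio).
#' @param r_coeff Tolerance as a multiple of `sd(x)` (default 0.2).
#' @return Sample entropy (natural log), possibly with attributes
#'   `degenerate` or `undefined`.
#' @export
sample_entropy <- function(x, m = 1, r_coeff = 0.2) {
  stopifnot(is.numeric(x), m >= 1, r_coeff > 0)
  n <- length(x)
  if (n < m + 2) stop("sample_entropy: need at least m + 2 observations")
  if (anyNA(x)) stop("sample_entropy: input contains missing values")
  s <- stats::sd(x)
  if (s == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  r <- r_coeff * s
  # Chebyshev template matching: templates of length m and m+1 both taken
  # from starts 1..n-m so the pair sets are nested (Richman & Moorman).
  # One pairwise proximity mask serves every template offset.
  nt <- n - m
  M <- abs(outer(x, x, "-")) <= r
  base <- seq_len(nt)
  within_r <- function(len) {
    ok <- M[base, base]
    for (d in seq_len(len - 1)) ok <- ok & M[base + d, base + d]
    sum(ok) - nt  # drop self-pairs i == j
  }
  B <- within_r(m)
  A <- within_r(m + 1)
  if (A == 0 || B == 0) {
    warning("sample_entropy: no template matches at one length; result undefined")
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  -log(A / B)
}

#' One non-sequential recursive pair substitution (NSRPS) step
#'
#' Counts all adjacent symbol pairs over overlapping positions, selects the
#' most frequent pair (ties broken by the pair whose first occurrence starts
#' earliest), and replaces its non-overlapping occurrences left-to-right with
#' a fresh symbol (the current alphabet size). The output is strictly
#' shorter than the input.
#'
#' @param s Integer vector of nonnegative symbols, length >= 2.
#' @return Integer vector, the substituted sequence.
#' @export
#' @examples
#' nsrps_step(c(0L, 0L, 1L, 0L, 1L, 1L, 0L, 1L))  # 0 2 2 1 2
nsrps_step <- function(s) {
  s <- as.integer(s)
  n <- length(s)
  if (n < 2) stop("nsrps_step: need at least 2 symbols")
  if (any(s < 0)) stop("nsrps_step: symbols must be nonnegative integers")
  alphabet <- max(s) + 1L
  # encode adjacent pairs as single integers; count only codes that occur,
  # in first-occurrence order, so which.max lands on the earliest-starting
  # pair among ties
  code <- s[-n] * alphabet + s[-1]
  uc <- unique(code)
  cand <- uc[which.max(tabulate(match(code, uc), nbins = length(uc)))]
  a <- cand %/% alphabet
  b <- cand %% alphabet
  pos <- which(code == cand)
  if (a == b && length(pos) > 1L) {
    # equal-symbol pairs can overlap; keep matches greedily left-to-right
    keep <- pos[1]
    last <- pos[1]
    for (p in pos[-1]) if (p > last + 1L) { keep <- c(keep, p); last <- p }
    pos <- keep
  }
  s[pos] <- alphabet
  s[-(pos + 1L)]
}

#' Effort-to-compress (ETC) of a symbol sequence
#'
#' Applies [nsrps_step()] repeatedly until the sequence is constant or has
#' length 1, and counts the iterations. The count is the effort-to-compress;
#' it is normalized by `L - 1` (the maximum possible number of steps for a
#' length-`L` input), so the normalized value lies in `[0, 1]`. A constant
#' or single-symbol input needs 0 iterations.
#'
#' @param s Integer vector of nonnegative symbols (use [symbolize()] for
#'   real-valued series).
#' @param keep_trace If TRUE, retain every intermediate sequence.
#' @return List of class `"etc_result"` with elements `iterations`,
#'   `normalized`, and (optionally) `trace`.
#' @export
#' @examples
#' effort_to_compress(c(0L, 0L, 1L, 0L, 1L, 1L, 0L, 1L))$iterations  # 5
effort_to_compress <- function(s, keep_trace = FALSE) {
  s <- as.integer(s)
  L <- length(s)
  if (L < 1) stop("effort_to_compress: empty sequence")
  trace <- if (keep_trace) list() else NULL
  iterations <- 0L
  cur <- s
  while (length(cur) > 1L && length(unique(cur)) > 1L) {
    cur <- nsrps_step(cur)
    iterations <- iterations + 1L
    if (keep_trace) trace[[iterations]] <- cur
  }
  normalized <- if (L >= 2) iterations / (L - 1) else 0
  structure(list(iterations = iterations, normalized = normalized,
                 trace = trace),
            class = "etc_result")
}

#' @export
print.etc_result <- function(x, ...) {
  cat("Effort-to-compress:", x$iterations, "iterations (normalized",
      format(x$normalized, digits = 4), ")\n")
  invisible(x)
}

#' Effort-to-compress of a real-valued series
#'
#' Convenience wrapper: symbolizes with [symbolize()] then runs
#' [effort_to_compress()], returning the normalized value.
#'
#' @inheritParams symbolize
#' @return Normalized ETC in `[0, 1]`.
#' @export
etc_norm <- function(x, bins = 10) {
  effort_to_compress(symbolize(x, bins = bins))$normalized
}
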