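# Independent oracles used across the suite. These deliberately use naive
# direct computation (double loops, full sorts, explicit recursion) so they
# share no code path with the package implementations they check.

# Sample entropy by explicit enumeration of all ordered template pairs.
sampen_oracle <- function(x, m = 1, r_coeff = 0.2) {
  n <- length(x)
  r <- r_coeff * sd(x)
  count_matches <- function(len) {
    cnt <- 0L
    for (i in 1:(n - m)) for (j in 1:(n - m)) {
      if (i == j) next
      if (max(abs(x[i:(i + len - 1)] - x[j:(j + len - 1)])) <= r)
        cnt <- cnt + 1L
    }
    cnt
  }
  B <- count_matches(m)
  A <- count_matches(m + 1)
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# NSRPS effort-to-compress, coded independently: pair counting with string
# keys, recursion instead of iteration.
etc_oracle <- function(s) {
  compress <- function(s, iters) {
    if (length(s) <= 1 || length(unique(s)) == 1) return(iters)
    keys <- paste(s[-length(s)], s[-1], sep = ",")
    tab <- table(factor(keys, levels = unique(keys)))  # unique() keeps first-occurrence order
    best <- names(tab)[tab == max(tab)][1]             # earliest-first tie-break
    pair <- as.integer(strsplit(best, ",")[[1]])
    fresh <- max(s) + 1L
    out <- integer(0); i <- 1L
    while (i <= length(s)) {
      if (i < length(s) && s[i] == pair[1] && s[i + 1] == pair[2]) {
        out <- c(out, fresh); i <- i + 2L
      } else {
        out <- c(out, s[i]); i <- i + 1L
      }
    }
    compress(out, iters + 1L)
  }
  compress(as.integer(s), 0L)
}

# Weighted Pearson via the raw moment formula, separate summation order.
weighted_pearson_oracle <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  num <- sum(w * x * y) / sw - mx * my
  den <- sqrt((sum(w * x^2) / sw - mx^2) * (sum(w * y^2) / sw - my^2))
  num / den
}

# Random symmetric "meta-matrix-like" matrix with unit diagonal.
random_mm <- function(N, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(N * N), N)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  structure(m, metric = "pearson", orientation = "similarity",
            n_windows = N, class = c("meta_matrix", "matrix", "array"))
}

# Small synthetic subject for integration-style tests.
quick_subject <- function(seed = 1, n_regions = 15, n_timepoints = 80, ...) {
  cfg <- sim_config(n_regions = n_regions, n_timepoints = n_timepoints,
                    seed = seed, ...)
  sc <- generate_structural_connectome(n_regions, density = 0.2,
                                       seed = seed + 1)
  ts <- suppressMessages(generate_bold(cfg, sc))
  list(ts = ts, sc = sc, cfg = cfg)
}
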