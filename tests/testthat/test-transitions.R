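test_that("subdiagonal extraction matches direct indexing", {
  mm <- random_mm(5, seed = 1)
  expect_length(subdiagonal_series(mm, 1), 4)
  expect_equal(subdiagonal_series(mm, 1),
               c(mm[1, 2], mm[2, 3], mm[3, 4], mm[4, 5]))
  expect_equal(subdiagonal_series(mm, 4), mm[1, 5])
  ones <- random_mm(6, seed = 2); ones[, ] <- 1
  expect_equal(subdiagonal_series(ones, 2), rep(1, 4))
  expect_error(subdiagonal_series(mm, 0), "lag")
  expect_error(subdiagonal_series(mm, 5), "lag")
})

test_that("proximal series averages sub-diagonals aligned on start index", {
  mm <- random_mm(12, seed = 3)
  expect_equal(as.numeric(proximal_series(mm, 1)),
               subdiagonal_series(mm, 1))
  # brute-force three-lag average
  L <- 3
  want <- sapply(seq_len(12 - L), function(i)
    mean(c(mm[i, i + 1], mm[i, i + 2], mm[i, i + 3])))
  got <- proximal_series(mm, max_lag = 3)
  expect_equal(as.numeric(got), want)
  expect_equal(attr(got, "max_lag"), 3)
  # lag-stationary matrix gives a constant series
  N <- 10
  f <- function(l) exp(-l / 4)
  m <- outer(seq_len(N), seq_len(N), function(i, j) f(abs(i - j)))
  mst <- structure(m, metric = "pearson", orientation = "similarity",
                   n_windows = N, class = c("meta_matrix", "matrix", "array"))
  ps <- as.numeric(proximal_series(mst, max_lag = 4))
  expect_equal(ps, rep(mean(f(1:4)), N - 4))
})

test_that("summarize_series computes the advertised measures", {
  ms <- summarize_series(c(1, 1, 1, 1))
  expect_equal(ms$sd, 0)
  expect_equal(ms$mean_abs_derivative, 0)
  expect_equal(ms$shannon_entropy, 0)
  expect_equal(ms$sample_entropy, 0)
  expect_true(ms$degenerate)
  ms2 <- summarize_series(c(0, 1, 0, 1))
  expect_equal(ms2$mean_abs_derivative, 1)
  set.seed(4)
  x <- cumsum(rnorm(80))
  ms3 <- summarize_series(x)
  expect_equal(ms3$mean, mean(x))
  expect_equal(ms3$median, median(x))
  expect_equal(ms3$sd, sd(x))
  expect_equal(ms3$sample_entropy, as.numeric(sample_entropy(x)))
  expect_equal(ms3$effort_to_compress_norm, etc_norm(x))
  expect_equal(ms3$mean_abs_derivative, mean(abs(diff(x))))
})

test_that("sd and mean absolute derivative rank series consistently", {
  set.seed(5)
  stats <- t(replicate(100, {
    scale <- runif(1, 0.2, 5)
    x <- as.numeric(arima.sim(list(ar = 0.5), 200, sd = scale))
    c(sd = sd(x), mad_ = mean(abs(diff(x))))
  }))
  expect_gt(cor(stats[, "sd"], stats[, "mad_"], method = "spearman"), 0.5)
})

test_that("distal matrix equals the brute-force index map for all N <= 12", {
  for (N in 4:12) {
    mm <- random_mm(N, seed = N)
    for (k in 1:(N - 3)) {
      D <- unclass(build_distal_matrix(mm, k))
      M <- N - k
      expect_equal(dim(D), c(M, M))
      for (a in seq_len(M)) for (b in seq_len(M)) {
        if (a == b) expect_true(is.na(D[a, b]))
        else expect_equal(D[a, b], mm[min(a, b), max(a, b) + k])
      }
      # multiset of defined upper cells equals MM cells with lag > k
      got <- sort(D[upper.tri(D)])
      lags <- col(mm) - row(mm)
      want <- sort(mm[lags > k])
      expect_equal(got, want)
      # no defined cell has source lag <= k
      src_lags <- outer(seq_len(M), seq_len(M),
                        function(a, b) abs(pmax(a, b) + k - pmin(a, b)))
      expect_true(all(src_lags[!is.na(D)] > k))
    }
  }
  mm <- random_mm(6, seed = 99)
  expect_equal(dim(build_distal_matrix(mm, 2)), c(4, 4))
  expect_error(build_distal_matrix(mm, 4), "distal lags")
})

test_that("index-valued meta-matrix gives D[a,b] = |a-b| + k", {
  N <- 9
  m <- outer(seq_len(N), seq_len(N), function(i, j) abs(i - j))
  mm <- structure(m, metric = "pearson", orientation = "similarity",
                  n_windows = N, class = c("meta_matrix", "matrix", "array"))
  k <- 3
  D <- unclass(build_distal_matrix(mm, k))
  M <- N - k
  for (a in seq_len(M)) for (b in seq_len(M))
    if (a != b) expect_equal(D[a, b], abs(a - b) + k)
})

test_that("distal per-column measures match a direct loop", {
  mm <- random_mm(40, seed = 6)
  k <- 13
  got <- distal_measures(mm, k = k, mode = "per_column")
  D <- unclass(build_distal_matrix(mm, k))
  M <- 40 - k
  etc_cols <- sampen_cols <- max_cols <- numeric(M)
  for (b in seq_len(M)) {
    col <- D[-b, b]
    etc_cols[b] <- effort_to_compress(symbolize(col, 10))$normalized /
      1  # normalized already
    sampen_cols[b] <- as.numeric(sample_entropy(col))
    max_cols[b] <- max(col)
  }
  expect_equal(got$effort_to_compress_norm, mean(etc_cols))
  expect_equal(got$sample_entropy, mean(sampen_cols, na.rm = TRUE))
  expect_equal(got$mean_max_similarity, mean(max_cols))
})

test_that("vectorized distal mode summarizes all defined cells once", {
  mm <- random_mm(30, seed = 7)
  got <- distal_measures(mm, k = 10, mode = "vectorized")
  D <- unclass(build_distal_matrix(mm, 10))
  v <- D[upper.tri(D)]
  expect_equal(got$mean, mean(v))
  expect_equal(got$sd, sd(v))
  expect_equal(got$effort_to_compress_norm, etc_norm(v))
  # balanced average: per-column mean of means equals vectorized mean
  # when every column has the same number of defined cells
  pc <- distal_measures(mm, k = 10, mode = "per_column")
  expect_equal(pc$mean, got$mean, tolerance = 1e-12)
})

test_that("all-ones meta-matrix gives degenerate distal measures", {
  ones <- random_mm(20, seed = 8); ones[, ] <- 1
  dm <- distal_measures(ones, k = 5)
  expect_equal(dm$sd, 0)
  expect_equal(dm$sample_entropy, 0)
  expect_equal(dm$effort_to_compress_norm, 0)
  expect_equal(dm$mean_max_similarity, 1)
  expect_true(dm$degenerate)
})
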