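test_that("vectorize_upper extracts the strict upper triangle", {
  m <- matrix(c(1, 2, 3, 2, 1, 4, 3, 4, 1), 3, 3)
  expect_equal(vectorize_upper(m), c(2, 3, 4))
  expect_equal(vectorize_upper(diag(4)), rep(0, 6))
  # round trip
  set.seed(1)
  s <- matrix(rnorm(25), 5); s <- s + t(s); diag(s) <- 1
  v <- vectorize_upper(s)
  expect_length(v, 10)
  rebuilt <- mmdfc:::unvectorize_upper(v, 5)
  expect_equal(vectorize_upper(rebuilt), v)
  expect_error(vectorize_upper(matrix(1:6, 2, 3)), "square")
})

make_cs <- function(mats) {
  structure(list(matrices = simplify2array(mats), window = 24, step = 1,
                 taper = NULL, method = "windowed", tr_seconds = 2,
                 region_ids = NULL, flagged = integer(0)),
            class = "connectivity_series")
}

test_that("meta-matrix entries equal direct pairwise metrics", {
  set.seed(2)
  mk <- function() { m <- matrix(rnorm(16), 4); m <- m + t(m); diag(m) <- 1; m }
  a <- mk(); b <- mk()
  mm <- build_meta_matrix(make_cs(list(a, b)), "pearson")
  expect_equal(mm[1, 2], cor(vectorize_upper(a), vectorize_upper(b)))
  expect_equal(unclass(mm), t(unclass(mm)))
  expect_equal(diag(unclass(mm)), c(1, 1))

  man <- build_meta_matrix(make_cs(list(a, b)), "manhattan")
  expect_equal(man[1, 2], sum(abs(vectorize_upper(a) - vectorize_upper(b))))
  expect_equal(attr(man, "orientation"), "distance")

  cosd <- build_meta_matrix(make_cs(list(a, b)), "cosine")
  va <- vectorize_upper(a); vb <- vectorize_upper(b)
  expect_equal(cosd[1, 2],
               1 - sum(va * vb) / sqrt(sum(va^2) * sum(vb^2)))
})

test_that("identical windows give the degenerate meta-matrices", {
  m <- matrix(0.5, 3, 3); diag(m) <- 1
  cs <- make_cs(list(m, m, m))
  # Pearson between identical vectors is defined but constant-vector cases
  # aside, identical windows must give distance 0
  expect_true(all(unclass(build_meta_matrix(cs, "manhattan")) == 0))
  expect_true(all(abs(unclass(build_meta_matrix(cs, "cosine"))) < 1e-12))
})

test_that("TDSM profiles match the generating expressions", {
  for (n in c(2, 10, 122)) {
    slow <- build_tdsm(n, "exp_slow")
    fast <- build_tdsm(n, "exp_fast")
    lin <- build_tdsm(n, "linear")
    # endpoint values from direct evaluation
    expect_equal(attr(slow, "profile")[1], 0.0001^(1 / 3))
    expect_equal(attr(fast, "profile")[1], 0.0001^(1 / 1.5))
    expect_equal(attr(slow, "profile")[n], 1)
    expect_equal(attr(lin, "profile"), seq(0, 1, length.out = n))
    for (M in list(slow, fast, lin)) {
      expect_equal(diag(unclass(M)), rep(1, n))
      expect_equal(unclass(M), t(unclass(M)))
      expect_true(all(diff(attr(M, "profile")) > 0))
    }
    # full profile equals the printed construction evaluated independently
    expect_equal(attr(slow, "profile"),
                 exp(seq(log(0.0001), log(1), length.out = n) / 3))
  }
  # entries depend only on |i - j| and decay away from the diagonal
  M <- unclass(build_tdsm(12, "exp_slow"))
  for (lag in 0:11)
    expect_equal(length(unique(round(M[col(M) - row(M) == lag], 14))), 1)
  expect_true(all(diff(M[1, ]) < 0))
  expect_error(build_tdsm(10, "quadratic"))
})

test_that("tdsm_fit: self-fit is 1, permutation destroys it, affine invariant", {
  n <- 122
  model <- build_tdsm(n, "exp_slow")
  mm_self <- structure(unclass(model), metric = "pearson",
                       orientation = "similarity", n_windows = n,
                       class = c("meta_matrix", "matrix", "array"))
  expect_equal(tdsm_fit(mm_self, model), 1)
  expect_equal(tdsm_fit(mm_self, "exp_slow"), 1)

  set.seed(3)
  fits <- replicate(100, {
    v <- vectorize_upper(unclass(model))
    perm <- mmdfc:::unvectorize_upper(sample(v), n)
    mm_p <- structure(perm, metric = "pearson", orientation = "similarity",
                      n_windows = n, class = c("meta_matrix", "matrix", "array"))
    tdsm_fit(mm_p, model)
  })
  expect_lt(abs(mean(fits)), 0.1)

  # linear-kind fit is invariant to affine re-specification of the profile
  mm_r <- random_mm(40, seed = 9)
  lin <- build_tdsm(40, "linear")
  lin_aff <- structure(5 * unclass(lin) - 2, kind = "linear",
                       profile = 5 * attr(lin, "profile") - 2, n_windows = 40,
                       class = c("tdsm", "matrix", "array"))
  expect_equal(tdsm_fit(mm_r, lin), tdsm_fit(mm_r, lin_aff), tolerance = 1e-12)

  # distance-oriented meta-matrices are negated before fitting
  mm_d <- structure(max(unclass(model)) - unclass(model), metric = "manhattan",
                    orientation = "distance", n_windows = n,
                    class = c("meta_matrix", "matrix", "array"))
  expect_equal(tdsm_fit(mm_d, model), 1)

  expect_error(tdsm_fit(mm_self, build_tdsm(50, "exp_slow")), "sizes differ")
})

test_that("pure-decay dynamics fit the TDSM better than regime-revisiting ones", {
  # many states with few revisits (a trajectory that keeps moving on) vs a
  # fast-switching two-state system that constantly returns to past states
  fit_of <- function(sub) {
    cs <- sliding_window_connectivity(sub$ts)
    tdsm_fit(build_meta_matrix(cs), "exp_slow")
  }
  fits <- sapply(1:8, function(i) {
    onward <- quick_subject(seed = 300 + i, n_timepoints = 145, n_states = 40,
                            mean_dwell = 20, transition_width = 8,
                            ar_coefficient = 0, noise_sd = 0.05)
    revisit <- quick_subject(seed = 400 + i, n_timepoints = 145, n_states = 2,
                             mean_dwell = 20, transition_width = 0,
                             ar_coefficient = 0, noise_sd = 0.05)
    c(onward = fit_of(onward), revisit = fit_of(revisit))
  })
  # ensemble property: individual regime realizations vary, the mean
  # advantage of the never-revisiting trajectory is the planted signal
  expect_gt(mean(fits["onward", ] - fits["revisit", ]), 0)
})

test_that("TDSM kinds rank subjects consistently", {
  dwells <- rep(c(6, 12, 30, 60, 100), 2)
  subs <- lapply(1:10, function(i)
    quick_subject(seed = 100 + i, mean_dwell = dwells[i]))
  fits <- sapply(subs, function(sub) {
    mm <- build_meta_matrix(sliding_window_connectivity(sub$ts))
    c(slow = tdsm_fit(mm, "exp_slow"), fast = tdsm_fit(mm, "exp_fast"),
      lin = tdsm_fit(mm, "linear"))
  })
  expect_gt(cor(fits["slow", ], fits["fast", ], method = "spearman"), 0.8)
  expect_gt(cor(fits["slow", ], fits["lin", ], method = "spearman"), 0.8)
})

test_that("embedding is centred and preserves column geometry", {
  sub <- quick_subject(seed = 77, n_timepoints = 53)
  mm <- build_meta_matrix(sliding_window_connectivity(sub$ts))
  xy <- embed_mm(mm, dims = 2)
  expect_equal(dim(xy), c(30, 2))
  expect_true(all(abs(colMeans(xy)) < 1e-8))
  d_in <- as.vector(dist(t(unclass(mm))))
  d_out <- as.vector(dist(xy))
  expect_gt(cor(d_in, d_out), 0.8)
  expect_error(embed_mm(mm, dims = 30), "dims")
  # identical windows collapse to coincident points
  m0 <- matrix(1, 8, 8)
  mm0 <- structure(m0, metric = "pearson", orientation = "similarity",
                   n_windows = 8, class = c("meta_matrix", "matrix", "array"))
  xy0 <- embed_mm(mm0, dims = 2)
  expect_true(all(abs(xy0) < 1e-8))
})
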