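test_that("two-level outcome reduces to ordinary logistic regression", {
  set.seed(1)
  n <- 300
  x <- rnorm(n)
  p <- plogis(-0.4 + 0.8 * x)
  y <- factor(ifelse(runif(n) < p, "high", "low"), levels = c("low", "high"))
  fit <- fit_proportional_odds(y, x, standardize = FALSE)
  # oracle: the same MLE via glm on the binary indicator
  glm_fit <- glm(I(y == "high") ~ x, family = binomial)
  expect_equal(unname(fit$beta), unname(coef(glm_fit)["x"]), tolerance = 1e-4)
  expect_equal(unname(fit$zeta), -unname(coef(glm_fit)["(Intercept)"]),
               tolerance = 1e-4)
  expect_true(fit$converged)
  expect_true(fit$ci_low <= fit$odds_ratio && fit$odds_ratio <= fit$ci_high)
})

test_that("null simulations keep the odds ratio near 1", {
  set.seed(2)
  devs <- replicate(50, {
    y <- factor(rep(c("a", "b", "c"), each = 500),
                levels = c("a", "b", "c"))
    x <- rnorm(1500)
    abs(fit_proportional_odds(y, x)$odds_ratio - 1)
  })
  expect_lt(mean(devs), 0.15)
})

test_that("latent-variable simulation recovers a planted slope", {
  set.seed(3)
  betas <- replicate(10, {
    n <- 2000
    x <- rnorm(n)
    latent <- x + rlogis(n)
    y <- cut(latent, c(-Inf, -1, 1, Inf), labels = c("l", "m", "h"),
             ordered_result = TRUE)
    fit_proportional_odds(y, x, standardize = FALSE)$beta
  })
  expect_lt(abs(mean(betas) - 1), 0.1)
})

test_that("reversing condition order inverts the coefficient exactly", {
  set.seed(4)
  x <- rnorm(120)
  y <- cut(x + rlogis(120), c(-Inf, -1, 0.5, Inf), labels = c("l", "m", "h"))
  f1 <- fit_proportional_odds(factor(y, levels = c("l", "m", "h")), x)
  f2 <- fit_proportional_odds(factor(y, levels = c("h", "m", "l")), x)
  expect_equal(unname(f1$beta), -unname(f2$beta), tolerance = 1e-6)
  expect_equal(unname(f1$odds_ratio), 1 / unname(f2$odds_ratio),
               tolerance = 1e-6)
})

test_that("fitted log-likelihood dominates the intercept-only model", {
  set.seed(5)
  x <- rnorm(90)
  y <- cut(0.5 * x + rlogis(90), c(-Inf, -1, 1, Inf), labels = c("l", "m", "h"))
  fit <- fit_proportional_odds(y, x)
  expect_gte(fit$log_lik, fit$log_lik_null)
})

test_that("one-sided p-values halve the two-sided value on the matching sign", {
  set.seed(6)
  x <- rnorm(150)
  y <- cut(x + rlogis(150), c(-Inf, -1, 1, Inf), labels = c("l", "m", "h"))
  f2 <- fit_proportional_odds(y, x, sided = "two")
  f1 <- fit_proportional_odds(y, x, sided = "one", direction = sign(f2$beta))
  expect_equal(unname(f1$p_value), unname(f2$p_value) / 2)
  f1b <- fit_proportional_odds(y, x, sided = "one", direction = -sign(f2$beta))
  expect_equal(unname(f1b$p_value), 1 - unname(f2$p_value) / 2)
})

test_that("Wald and likelihood-ratio inference broadly agree", {
  set.seed(7)
  x <- rnorm(200)
  y <- cut(0.25 * x + rlogis(200), c(-Inf, -1, 1, Inf),
           labels = c("l", "m", "h"))
  fit <- fit_proportional_odds(y, x)
  lr <- 2 * (fit$log_lik - fit$log_lik_null)
  p_lr <- pchisq(lr, df = 1, lower.tail = FALSE)
  p_wald <- unname(fit$p_value)
  expect_lt(abs(log(p_wald / p_lr)), log(2))
})

test_that("proportional-odds LR check returns a valid nonnegative statistic", {
  set.seed(8)
  x <- rnorm(300)
  y <- cut(x + rlogis(300), c(-Inf, -1, 1, Inf), labels = c("l", "m", "h"))
  chk <- proportional_odds_check(y, x)
  expect_true(chk$converged)
  expect_gte(chk$statistic, 0)
  expect_equal(chk$df, 1)
  expect_gte(chk$p_value, 0)
  expect_lte(chk$p_value, 1)
  expect_error(proportional_odds_check(factor(rep(c("a", "b"), 50)), rnorm(100)),
               "3 outcome levels")
})

test_that("grossly non-parallel slopes are detected with high power", {
  set.seed(9)
  rejections <- replicate(25, {
    n <- 900
    x <- rnorm(n)
    # the top category depends on |x|: violates a common slope badly
    y <- character(n)
    p_low <- plogis(-0.5 - 2 * x)
    p_high <- plogis(-0.5 + 2 * abs(x))
    for (i in seq_len(n)) {
      u <- runif(1)
      y[i] <- if (u < p_low[i]) "l" else if (u < p_low[i] + 0.2) "m" else "h"
    }
    chk <- proportional_odds_check(factor(y, levels = c("l", "m", "h")), x)
    isTRUE(chk$p_value < 0.05)
  })
  expect_gt(mean(rejections), 0.8)
})

test_that("measure correlations behave like Spearman", {
  set.seed(10)
  tb <- data.frame(a = rnorm(40))
  tb$b <- tb$a^3                      # monotone transform
  tb$c <- rnorm(40)
  mc <- measure_correlations(tb, c("a", "b", "c"))
  expect_equal(mc$rho["a", "b"], 1)
  expect_equal(diag(mc$rho), c(a = 1, b = 1, c = 1))
  expect_equal(mc$rho, t(mc$rho))
  # null columns stay mostly uncorrelated at n = 59
  hits <- replicate(60, {
    tb2 <- data.frame(x = rnorm(59), y = rnorm(59))
    abs(measure_correlations(tb2, c("x", "y"))$rho["x", "y"]) < 0.5
  })
  expect_gt(mean(hits), 0.95)
  tb$k <- 1
  expect_warning(measure_correlations(tb, c("a", "k")), "constant")
})

test_that("rank-sum z matches exact enumeration for small groups", {
  set.seed(11)
  for (i in 1:10) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    a <- rnorm(na); b <- rnorm(nb)
    got <- rank_sum_compare(a, b)
    # exact permutation distribution of the rank sum
    n <- na + nb
    rk <- rank(c(a, b))
    Ws <- apply(combn(n, na), 2, function(idx) sum(rk[idx]))
    z_exact <- (got$W - mean(Ws)) / sqrt(mean((Ws - mean(Ws))^2))
    expect_equal(got$z, z_exact, tolerance = 1e-10)
  }
})

test_that("rank-sum handles ties, identity, and large shifts", {
  g <- rank_sum_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(g$z, 0)
  expect_equal(g$p_value, 1)
  all_tied <- rank_sum_compare(rep(5, 4), rep(5, 6))
  expect_equal(all_tied$p_value, 1)
  set.seed(12)
  shift <- rank_sum_compare(rnorm(12) + 10, rnorm(12))
  expect_lt(shift$p_value, 0.001)
  expect_gt(shift$z, 0)
  # agrees with the tie-corrected normal approximation in wilcox.test
  a <- c(1, 2, 2, 3, 5); b <- c(2, 3, 3, 4, 6, 7)
  wt <- suppressWarnings(wilcox.test(a, b, correct = FALSE, exact = FALSE))
  expect_equal(rank_sum_compare(a, b)$p_value, wt$p.value, tolerance = 1e-10)
})

test_that("single-condition input is rejected", {
  tb <- data.frame(subject_id = letters[1:6], condition = "only",
                   condition_rank = 1, subset = "whole_brain", m = rnorm(6))
  expect_error(run_cohort_analysis(tb, "m", conditions = "only"),
               ">= 2 levels")
})

test_that("permuted labels give a null odds-ratio distribution around 1", {
  set.seed(13)
  x <- rnorm(60)
  y0 <- rep(c("a", "b", "c"), each = 20)
  ors <- replicate(50, {
    y <- factor(sample(y0), levels = c("a", "b", "c"))
    fit_proportional_odds(y, x)$odds_ratio
  })
  expect_lt(abs(median(log(ors))), 0.3)
})
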