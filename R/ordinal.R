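#' Proportional-odds ordinal logistic regression
#'
#' Maximum-likelihood cumulative-logit model with parallel slopes,
#' `P(Y <= j | x) = logistic(zeta_j - x %*% beta)`, fitted via
#' [MASS::polr()]. Under this parameterization a positive `beta` means
#' higher predictor values push probability mass toward higher (more aware)
#' outcome categories; the odds ratio `exp(beta)` is reported with Wald
#' confidence intervals and z-based p-values. Predictors are z-scored by
#' default, so odds ratios are per standard deviation of the predictor.
#'
#' Reversing the order of the outcome levels exactly negates `beta`
#' (mapping OR to 1/OR), which is how directionally "decreasing" effects
#' are conventionally reported on an interpretable scale.
#'
#' @param y Ordered outcome: an ordered factor, or anything coercible with
#'   levels taken in order of first appearance unless already a factor.
#' @param X Numeric predictor vector, matrix or data frame.
#' @param standardize Z-score predictors before fitting (default TRUE).
#' @param sided "two" (default) or "one"; one-sided p-values are half the
#'   two-sided value when the estimated sign matches `direction`, and
#'   `1 - p/2` otherwise.
#' @param direction Expected sign of `beta` (+1 or -1) for one-sided tests.
#' @param conf_level Confidence level for the Wald interval (default 0.95).
#' @return Object of class `"olr_fit"`: list with `beta`, `se`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `sided`, `zeta`
#'   (intercepts), `log_lik`, `log_lik_null`, `converged`, `standardized`,
#'   `vif` (variance inflation factors, NA for a single predictor), `n`,
#'   `levels`, and the underlying `fit`.
#' @export
fit_proportional_odds <- function(y, X, standardize = TRUE,
                                  sided = c("two", "one"), direction = 1,
                                  conf_level = 0.95) {
  sided <- match.arg(sided)
  if (!is.factor(y)) y <- factor(y, levels = unique(y))
  y <- as.ordered(y)
  if (nlevels(y) < 2) stop("ordinal outcome needs >= 2 levels")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop("fit_proportional_odds: y and X sizes differ")
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) stop("fit_proportional_odds: constant predictor")
    X <- scale(X)
  }
  dat <- data.frame(.y = y, X)
  fml <- stats::as.formula(paste(".y ~", paste(colnames(X), collapse = " + ")))
  if (nlevels(y) == 2L) {
    # with two outcome levels the cumulative-logit model *is* ordinary
    # logistic regression on P(Y = upper level)
    fit <- tryCatch(
      stats::glm(stats::as.formula(
        paste("I(as.integer(.y) == 2) ~", paste(colnames(X), collapse = " + "))),
        data = dat, family = stats::binomial(),
        control = list(epsilon = 1e-12, maxit = 100)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      return(structure(list(converged = FALSE, error = conditionMessage(fit),
                            standardized = standardize, n = length(y),
                            levels = levels(y)),
                       class = "olr_fit"))
    }
    converged <- fit$converged
    cf <- stats::coef(fit)
    beta <- cf[-1]
    zeta <- c(-cf[1])
    names(zeta) <- paste(levels(y), collapse = "|")
    vc <- stats::vcov(fit)
    se <- sqrt(diag(vc))[-1]
    ll <- as.numeric(stats::logLik(fit))
    ll0 <- as.numeric(stats::logLik(stats::glm(I(as.integer(.y) == 2) ~ 1,
                                               data = dat,
                                               family = stats::binomial())))
    return(finish_olr_fit(beta, se, zeta, ll, ll0, converged, standardize,
                          sided, direction, conf_level, X, y, fit))
  }
  fit <- tryCatch(
    MASS::polr(fml, data = dat, method = "logistic", Hess = TRUE,
               control = list(reltol = 1e-12)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(converged = FALSE, error = conditionMessage(fit),
                          standardized = standardize, n = length(y),
                          levels = levels(y)),
                     class = "olr_fit"))
  }
  converged <- fit$convergence == 0
  beta <- fit$coefficients
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(vc)) {
    se <- rep(NA_real_, length(beta)); converged <- FALSE
  } else se <- sqrt(diag(vc))[seq_along(beta)]
  ll <- as.numeric(stats::logLik(fit))
  fit0 <- MASS::polr(.y ~ 1, data = dat, method = "logistic")
  finish_olr_fit(beta, se, fit$zeta, ll, as.numeric(stats::logLik(fit0)),
                 converged, standardize, sided, direction, conf_level, X, y,
                 fit)
}

# Shared inference tail for fit_proportional_odds (Wald CI, p-values, VIF).
finish_olr_fit <- function(beta, se, zeta, ll, ll0, converged, standardized,
                           sided, direction, conf_level, X, y, fit) {
  z <- beta / se
  p_two <- 2 * stats::pnorm(-abs(z))
  p <- if (sided == "two") p_two else
    ifelse(sign(beta) == sign(direction), p_two / 2, 1 - p_two / 2)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  vif <- if (ncol(X) >= 2) {
    v <- vapply(seq_len(ncol(X)), function(j) {
      r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
      1 / (1 - r2)
    }, numeric(1))
    names(v) <- colnames(X)
    if (any(v > 5))
      warning("fit_proportional_odds: variance inflation factor above 5")
    v
  } else NA_real_
  structure(list(beta = beta, se = se, odds_ratio = exp(beta),
                 ci_low = exp(beta - q * se), ci_high = exp(beta + q * se),
                 p_value = p, sided = sided, zeta = zeta,
                 log_lik = ll, log_lik_null = ll0,
                 converged = converged, standardized = standardized,
                 vif = vif, n = length(y), levels = levels(y), fit = fit),
            class = "olr_fit")
}

#' @export
print.olr_fit <- function(x, ...) {
  if (!isTRUE(x$converged) && is.null(x$beta)) {
    cat("Proportional-odds fit FAILED:", x$error, "\n")
    return(invisible(x))
  }
  cat("Proportional-odds ordinal regression (n =", x$n, ", levels:",
      paste(x$levels, collapse = " < "), ")\n")
  tab <- data.frame(OR = x$odds_ratio, ci_low = x$ci_low, ci_high = x$ci_high,
                    p = x$p_value)
  print(round(tab, 4))
  cat("predictors", if (x$standardized) "z-scored" else "on raw scale",
      "; p-values", x$sided, "sided\n")
  if (!isTRUE(x$converged)) cat("WARNING: fit flagged as non-converged\n")
  invisible(x)
}

#' @export
coef.olr_fit <- function(object, ...) object$beta

#' @export
summary.olr_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Likelihood-ratio check of the proportional-odds assumption
#'
#' Compares the parallel-slopes cumulative-logit model against the model
#' with level-specific slopes (fitted as an unconstrained multinomial
#' logit via [nnet::multinom()]). Twice the log-likelihood difference is
#' referred to a chi-square distribution with
#' `(levels - 2) * predictors` degrees of freedom; a small p-value means
#' the parallel-slopes (proportional odds) assumption is questionable.
#'
#' @inheritParams fit_proportional_odds
#' @return List with `statistic`, `df`, `p_value`, `converged`
#'   (FALSE marks the check inconclusive).
#' @export
proportional_odds_check <- function(y, X) {
  if (!is.factor(y)) y <- factor(y, levels = unique(y))
  y <- as.ordered(y)
  J <- nlevels(y)
  if (J < 3)
    stop("proportional_odds_check: needs >= 3 outcome levels")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  dat <- data.frame(.y = y, X)
  fml <- stats::as.formula(paste(".y ~", paste(colnames(X), collapse = " + ")))
  fit1 <- tryCatch(
    MASS::polr(fml, data = dat, method = "logistic",
               control = list(reltol = 1e-12)),
    error = function(e) NULL)
  fit2 <- tryCatch(
    nnet::multinom(fml, data = dat, trace = FALSE, maxit = 500,
                   reltol = 1e-12),
    error = function(e) NULL)
  if (is.null(fit1) || is.null(fit2) || fit2$convergence != 0)
    return(list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
                converged = FALSE))
  lr <- max(0, 2 * (as.numeric(stats::logLik(fit2)) -
                      as.numeric(stats::logLik(fit1))))
  df <- (J - 2L) * ncol(X)
  list(statistic = lr, df = df,
       p_value = stats::pchisq(lr, df, lower.tail = FALSE), converged = TRUE)
}

#' Spearman correlations between cohort measures
#'
#' Pairwise Spearman rank correlations (with p-values from
#' [stats::cor.test()]) over subjects, pooled across conditions.
#'
#' @param table Data frame with one row per subject.
#' @param measures Character vector of numeric column names (default: all
#'   numeric columns except `condition_rank`).
#' @return List with matrices `rho` and `p`. Constant columns give `NA`
#'   entries with a warning.
#' @export
measure_correlations <- function(table, measures = NULL) {
  if (is.null(measures)) {
    num <- vapply(table, is.numeric, logical(1))
    measures <- setdiff(names(table)[num], "condition_rank")
  }
  if (nrow(table) < 5) stop("measure_correlations: need >= 5 subjects")
  k <- length(measures)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(measures, measures))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    xi <- table[[measures[i]]]; xj <- table[[measures[j]]]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
      warning("measure_correlations: constant measure column: ",
              measures[if (stats::sd(xi) == 0) i else j])
      next
    }
    ct <- suppressWarnings(stats::cor.test(xi, xj, method = "spearman"))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(rho = rho, p = p)
}

#' Two-sample rank-sum comparison (normal approximation)
#'
#' Wilcoxon rank-sum test computed from mid-ranks with the tie-corrected
#' normal approximation: `z = (W - mu_W) / sigma_W` where `W` is the rank
#' sum of the first group. Positive `z` means group `a` tends to be larger.
#'
#' @param a,b Numeric vectors (both nonempty).
#' @return List with `z`, `p_value` (two-sided), `W`, `n_a`, `n_b`. When
#'   all values are tied, `z = 0` and `p = 1`.
#' @export
rank_sum_compare <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  na <- length(a); nb <- length(b); n <- na + nb
  rk <- rank(c(a, b))
  W <- sum(rk[seq_len(na)])
  mu <- na * (n + 1) / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties)
  if (n < 2 || tie_term == n^3 - n)  # all values identical
    return(list(z = 0, p_value = 1, W = W, n_a = na, n_b = nb))
  sig2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sig2 <= 0) return(list(z = 0, p_value = 1, W = W, n_a = na, n_b = nb))
  z <- (W - mu) / sqrt(sig2)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), W = W, n_a = na, n_b = nb)
}
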