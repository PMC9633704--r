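# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulation configuration for synthetic BOLD generation
#'
#' Bundles and validates the parameters of the piecewise-stationary
#' covariance-regime model used by [generate_bold()]. Defaults emulate a
#' 5-minute resting-state acquisition: 145 usable volumes at TR = 2 s over
#' 30 regions, with 5 latent covariance states.
#'
#' @param n_regions Number of regions R.
#' @param n_timepoints Number of timepoints T.
#' @param tr_seconds Repetition time in seconds.
#' @param n_states Number of latent covariance states.
#' @param mean_dwell Mean state dwell time in timepoints (>= 1).
#' @param transition_width Timepoints of linear covariance blending around
#'   each state switch (0 = abrupt switches).
#' @param noise_sd Standard deviation of iid observation noise.
#' @param sc_coupling Convex weight in `[0, 1]` of the structural-connectome-
#'   derived covariance in each state's covariance.
#' @param ar_coefficient AR(1) smoothing coefficient in `[0, 1)`.
#' @param seed Integer RNG seed; identical seed + config gives bit-identical
#'   output.
#' @return Object of class `"sim_config"` (a validated named list).
#' @export
sim_config <- function(n_regions = 30, n_timepoints = 145, tr_seconds = 2,
                       n_states = 5, mean_dwell = 24, transition_width = 4,
                       noise_sd = 0.1, sc_coupling = 0.3,
                       ar_coefficient = 0.3, seed = 1) {
  stopifnot(n_regions >= 2, n_timepoints >= 2, tr_seconds > 0, n_states >= 1,
            transition_width >= 0, noise_sd >= 0)
  if (mean_dwell < 1) stop("sim_config: mean_dwell must be >= 1")
  if (sc_coupling < 0 || sc_coupling > 1)
    stop("sim_config: sc_coupling must be in [0, 1]")
  if (ar_coefficient < 0 || ar_coefficient >= 1)
    stop("sim_config: ar_coefficient must be in [0, 1)")
  structure(list(n_regions = as.integer(n_regions),
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds, n_states = as.integer(n_states),
                 mean_dwell = mean_dwell,
                 transition_width = as.integer(transition_width),
                 noise_sd = noise_sd, sc_coupling = sc_coupling,
                 ar_coefficient = ar_coefficient, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a random structural connectome
#'
#' Geometric random connectome: regions receive latent 2-D positions, the
#' `round(density * R*(R-1)/2)` shortest inter-region distances become
#' edges, and edge weights decay exponentially with distance (scaled to
#' unit maximum). Distance-dependent connectivity is the dominant
#' organizing principle of tractography-derived connectomes and gives the
#' weight matrix the strong community structure real connectomes show.
#'
#' @param n_regions Number of regions R.
#' @param density Fraction of possible edges present, in `(0, 1]`.
#' @param seed Integer RNG seed.
#' @return A [structural_connectome()] with exactly the requested number
#'   of edges (symmetric, nonnegative, zero diagonal).
#' @export
generate_structural_connectome <- function(n_regions, density = 0.2, seed = 1) {
  stopifnot(n_regions >= 2)
  if (density <= 0 || density > 1)
    stop("generate_structural_connectome: density must be in (0, 1]")
  n_up <- n_regions * (n_regions - 1) / 2
  n_edges <- round(density * n_up)
  if (n_edges < 1) stop("empty connectome")
  with_seed(seed, {
    pts <- matrix(stats::runif(n_regions * 2), n_regions, 2)
    D <- as.matrix(stats::dist(pts))
    up <- which(upper.tri(D))
    keep <- up[order(D[up])[seq_len(n_edges)]]
    w <- matrix(0, n_regions, n_regions)
    w[keep] <- exp(-3 * D[keep] / max(D))
    w <- w + t(w)
    structural_connectome(w / max(w))
  })
}

# First-order Markov state labels under the current RNG stream.
markov_labels <- function(n_timepoints, n_states, mean_dwell) {
  labels <- integer(n_timepoints)
  labels[1] <- sample.int(n_states, 1)
  if (n_states == 1) return(rep(1L, n_timepoints))
  p_switch <- 1 / mean_dwell
  for (t in 2:n_timepoints) {
    if (stats::runif(1) < p_switch) {
      others <- setdiff(seq_len(n_states), labels[t - 1])
      labels[t] <- if (length(others) == 1) others else sample(others, 1)
    } else labels[t] <- labels[t - 1]
  }
  labels
}

#' Generate a first-order Markov regime sequence
#'
#' State labels with self-transition probability `1 - 1/mean_dwell` and
#' uniform switch targets among the other states, so dwell times are
#' geometric with mean `mean_dwell`.
#'
#' @param n_timepoints Sequence length.
#' @param n_states Number of states (>= 1).
#' @param mean_dwell Mean dwell time in timepoints (>= 1).
#' @param seed Integer RNG seed.
#' @return Integer vector of state labels in `1:n_states`.
#' @export
generate_regime_sequence <- function(n_timepoints, n_states, mean_dwell,
                                     seed = 1) {
  stopifnot(n_timepoints >= 1, n_states >= 1)
  if (mean_dwell < 1) stop("generate_regime_sequence: mean_dwell must be >= 1")
  with_seed(seed, markov_labels(n_timepoints, n_states, mean_dwell))
}

#' Mean realized dwell time of a label sequence
#'
#' @param labels Integer state labels (e.g. from
#'   [generate_regime_sequence()]).
#' @return Mean run length.
#' @export
realized_dwell <- function(labels) mean(rle(as.integer(labels))$lengths)

# Shift the diagonal so the smallest eigenvalue reaches floor_eig.
# The structural component SC/max + I need not be positive definite (graph
# weight matrices can have eigenvalues below -1), so composed state
# covariances are repaired here; the repair is reported by the caller.
repair_pd <- function(S, floor_eig = 1e-6) {
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < floor_eig) {
    list(S = S + diag(floor_eig - ev, nrow(S)), shift = floor_eig - ev)
  } else list(S = S, shift = 0)
}

# Cholesky with escalating diagonal jitter; errors only if repair fails.
chol_with_repair <- function(S) {
  U <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(U)) return(U)
  scale <- mean(diag(S))
  for (eps in scale * 10^seq(-8, -2)) {
    U <- tryCatch(chol(S + diag(eps, nrow(S))), error = function(e) NULL)
    if (!is.null(U)) {
      message("generate_bold: covariance repaired with jitter ", signif(eps, 2))
      return(U)
    }
  }
  stop("generate_bold: covariance not positive definite after jitter repair")
}

#' Generate synthetic BOLD-like timeseries
#'
#' Piecewise-stationary multivariate-normal model: a hidden Markov regime
#' sequence selects among `n_states` correlation states. Each state is the
#' convex blend `sc_coupling * C_sc + (1 - sc_coupling) * C_s` of a
#' structural component and a state-specific random factor component.
#' `C_sc` is the correlation matrix of the positive-semidefinite part of
#' `SC/max(SC)` (the graph's community/hub structure); `C_s` is the
#' correlation matrix of a rank-3 factor model `L L' + 0.1 I` (R x 3
#' standard-normal loadings). Both components are shrunk toward the
#' identity to a common off-diagonal amplitude (0.2), so `sc_coupling`
#' moves pattern *content* toward the structural backbone without changing
#' overall connectivity strength; regions have unit variance, making
#' `noise_sd` a fraction of signal amplitude. A composed covariance that
#' loses positive definiteness is repaired by a logged diagonal eigenvalue
#' shift. Covariances are linearly blended over `transition_width`
#' timepoints around switches, each timepoint is drawn from the active
#' blended covariance, the draws are AR(1)-smoothed, and iid Gaussian
#' noise of standard deviation `noise_sd` is added.
#'
#' @param config A [sim_config()].
#' @param structural A [structural_connectome()] with `n_regions` regions.
#' @return A [region_ts()] (T x R) with attribute `regimes`, the
#'   ground-truth state label per timepoint.
#' @export
generate_bold <- function(config, structural) {
  stopifnot(inherits(config, "sim_config"),
            inherits(structural, "structural_connectome"))
  R_ <- config$n_regions
  if (nrow(structural) != R_)
    stop("generate_bold: structural connectome does not match n_regions")
  T_ <- config$n_timepoints
  S_ <- config$n_states
  # Shrink a correlation matrix toward the identity until its off-diagonal
  # spread is `a` (shrinking preserves positive definiteness; a component
  # already weaker than `a` is left as-is).
  shrink_to_amplitude <- function(C, a) {
    s <- min(1, a / stats::sd(C[upper.tri(C)]))
    s * C + (1 - s) * diag(nrow(C))
  }
  # Common off-diagonal amplitude for both components: sc_coupling then
  # moves pattern *content* (structural backbone vs state-specific factor
  # structure) without changing overall connectivity strength.
  pattern_amplitude <- 0.2
  # correlation-like structural component: positive-semidefinite part of
  # the scaled graph (retains its community/hub structure)
  A <- unclass(structural) / max(structural)
  ea <- eigen(A, symmetric = TRUE)
  Apsd <- ea$vectors %*% (pmax(ea$values, 0) * t(ea$vectors))
  sc_corr <- shrink_to_amplitude(stats::cov2cor(Apsd + diag(1e-8, R_)),
                                 pattern_amplitude)
  with_seed(config$seed, {
    sigmas <- lapply(seq_len(S_), function(s) {
      L <- matrix(stats::rnorm(R_ * 3), R_, 3)
      f_corr <- shrink_to_amplitude(stats::cov2cor(tcrossprod(L) + diag(0.1, R_)),
                                    pattern_amplitude)
      config$sc_coupling * sc_corr + (1 - config$sc_coupling) * f_corr
    })
    repaired <- lapply(sigmas, repair_pd)
    shifts <- vapply(repaired, `[[`, numeric(1), "shift")
    if (any(shifts > 0))
      message("generate_bold: ", sum(shifts > 0), " state covariance(s) ",
              "repaired with diagonal shift up to ", signif(max(shifts), 3))
    sigmas <- lapply(repaired, `[[`, "S")
    labels <- markov_labels(T_, S_, config$mean_dwell)
    # state-weight matrix: one-hot rows, box-smoothed over the transition
    # width so covariances blend linearly around switches
    W <- matrix(0, T_, S_)
    W[cbind(seq_len(T_), labels)] <- 1
    tw <- config$transition_width
    if (tw > 0 && S_ > 1) {
      h <- ceiling(tw / 2)
      Ws <- matrix(0, T_, S_)
      for (t in seq_len(T_)) {
        win <- max(1, t - h):min(T_, t + h)
        Ws[t, ] <- colMeans(W[win, , drop = FALSE])
      }
      W <- Ws / rowSums(Ws)
    }
    X <- matrix(0, T_, R_)
    U <- NULL
    prev_w <- rep(NA_real_, S_)
    for (t in seq_len(T_)) {
      if (!identical(W[t, ], prev_w)) {
        Sig <- Reduce(`+`, Map(`*`, W[t, ], sigmas))
        U <- chol_with_repair(Sig)
        prev_w <- W[t, ]
      }
      X[t, ] <- crossprod(U, stats::rnorm(R_))
    }
    if (config$ar_coefficient > 0) {
      for (t in 2:T_)
        X[t, ] <- config$ar_coefficient * X[t - 1, ] + X[t, ]
    }
    if (config$noise_sd > 0)
      X <- X + matrix(stats::rnorm(T_ * R_, sd = config$noise_sd), T_, R_)
    ts <- region_ts(X, tr_seconds = config$tr_seconds)
    attr(ts, "regimes") <- labels
    attr(ts, "state_covariances") <- sigmas
    ts
  })
}

#' Cohort specification with a planted arousal gradient
#'
#' Defines an ordered set of conditions (least to most aware) and how the
#' generator parameters vary along that order. Less-aware conditions
#' receive longer mean dwell times (slower state turnover), wider
#' transition blending (more sluggish switches) and stronger
#' structure-function coupling — the planted direction of the contrasts the
#' analysis is designed to recover. Parameters are interpolated linearly in
#' the awareness rank between the "least aware" and "most aware" endpoint
#' values.
#'
#' Less-aware conditions additionally receive a smaller AR(1) coefficient:
#' in this generator the AR term controls how far windowed connectivity
#' patterns drift within a state, so a larger coefficient yields richer,
#' less predictable short-term pattern exploration — the aware phenotype —
#' while a smaller one yields shallow fluctuations around a fixed pattern.
#'
#' @param conditions Ordered character vector of condition labels, least to
#'   most aware (default `c("UWS", "MCS", "SED", "CON")` — unresponsive
#'   wakefulness syndrome, minimally conscious state, sedated, control
#'   awake).
#' @param n_subjects Subjects per condition; scalar or vector matching
#'   `conditions` (default `c(12, 11, 18, 18)`).
#' @param base_seed Integer seed from which all per-subject seeds are
#'   derived.
#' @param base_config A [sim_config()] supplying the parameters that do not
#'   vary with awareness.
#' @param dwell_range,transition_width_range,sc_coupling_range,ar_range
#'   Length-2 vectors giving the (least aware, most aware) endpoint values
#'   of the planted parameters.
#' @param sc_density Edge density of each subject's structural connectome.
#' @param overrides Optional named list (by condition label) of named lists
#'   of `sim_config` fields overriding the interpolated values.
#' @return Object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(conditions = c("UWS", "MCS", "SED", "CON"),
                        n_subjects = c(12, 11, 18, 18),
                        base_seed = 1,
                        base_config = sim_config(),
                        dwell_range = c(60, 6),
                        transition_width_range = c(8, 2),
                        sc_coupling_range = c(0.35, 0.15),
                        ar_range = c(0.1, 0.7),
                        sc_density = 0.2,
                        overrides = NULL) {
  K <- length(conditions)
  if (K < 2) stop("cohort_spec: need at least 2 conditions")
  if (anyDuplicated(conditions)) stop("cohort_spec: duplicate condition labels")
  n_subjects <- rep_len(as.integer(n_subjects), K)
  if (any(n_subjects < 1)) stop("cohort_spec: n_subjects must be positive")
  stopifnot(length(dwell_range) == 2, length(transition_width_range) == 2,
            length(sc_coupling_range) == 2, length(ar_range) == 2)
  structure(list(conditions = conditions, n_subjects = n_subjects,
                 base_seed = as.integer(base_seed),
                 base_config = base_config,
                 dwell_range = dwell_range,
                 transition_width_range = transition_width_range,
                 sc_coupling_range = sc_coupling_range,
                 ar_range = ar_range,
                 sc_density = sc_density,
                 overrides = overrides),
            class = "cohort_spec")
}

# Deterministic per-subject seed, kept inside 32-bit integer range.
subject_seed <- function(base_seed, cond_idx, subj_idx) {
  as.integer((abs(base_seed) * 97 + cond_idx * 7919 + subj_idx * 104729) %%
               2147483647L)
}

#' Generate a synthetic cohort
#'
#' Draws one timeseries and one structural connectome per subject under the
#' arousal-graded parameters of a [cohort_spec()]. Per-subject seeds are a
#' deterministic function of `base_seed`, the condition index and the
#' subject index, so an identical spec reproduces the identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `"cohort"`: list of subjects, each a list with
#'   `subject_id`, `condition`, `condition_rank` (1 = least aware), `ts`
#'   (a [region_ts()] with ground-truth `regimes` attribute), `sc` and
#'   `config`. The attribute `conditions` preserves the condition order.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  K <- length(spec$conditions)
  interp <- function(rng, i) rng[1] + (rng[2] - rng[1]) * (i - 1) / (K - 1)
  subjects <- list()
  for (i in seq_len(K)) {
    cond <- spec$conditions[i]
    cfg_fields <- unclass(spec$base_config)
    cfg_fields$mean_dwell <- interp(spec$dwell_range, i)
    cfg_fields$transition_width <- round(interp(spec$transition_width_range, i))
    cfg_fields$sc_coupling <- interp(spec$sc_coupling_range, i)
    cfg_fields$ar_coefficient <- interp(spec$ar_range, i)
    if (!is.null(spec$overrides[[cond]]))
      cfg_fields[names(spec$overrides[[cond]])] <- spec$overrides[[cond]]
    for (j in seq_len(spec$n_subjects[i])) {
      sd_ij <- subject_seed(spec$base_seed, i, j)
      cfg_fields$seed <- sd_ij
      cfg <- do.call(sim_config, cfg_fields)
      sc <- generate_structural_connectome(cfg$n_regions,
                                           density = spec$sc_density,
                                           seed = sd_ij + 1L)
      ts <- generate_bold(cfg, sc)
      subjects[[length(subjects) + 1L]] <- list(
        subject_id = sprintf("%s_%02d", cond, j),
        condition = cond, condition_rank = i,
        ts = ts, sc = sc, config = cfg)
    }
  }
  structure(subjects, conditions = spec$conditions, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  conds <- vapply(x, `[[`, character(1), "condition")
  cat("Synthetic cohort:", length(x), "subjects\n")
  print(table(factor(conds, levels = attr(x, "conditions"))))
  invisible(x)
}
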