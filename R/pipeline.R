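#' Per-subject intrinsic-dynamics measures
#'
#' Runs the full single-subject analysis: tapered sliding-window
#' connectivity, meta-matrix, temporal-decay-model fits, proximal
#' sub-diagonal measures, distal meta-matrix complexity, and (if a
#' structural connectome is supplied) structure-function series
#' complexity. Returns one scalar per measure, named so that the same
#' measure under different parameterizations stays distinguishable
#' (e.g. `proximal_sampen_l1`, `dmm_etc_k13`).
#'
#' @param ts A [region_ts()].
#' @param sc Optional [structural_connectome()] for the structure-function
#'   measures.
#' @param config A [pipeline_config()].
#' @param truncate_n Optional window count to truncate the connectivity
#'   series to (used to equalize subjects before meta-matrix construction).
#' @return Named list of scalar measures.
#' @export
subject_measures <- function(ts, sc = NULL, config = pipeline_config(),
                             truncate_n = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cs <- sliding_window_connectivity(
    ts, window = config$window, step = config$step,
    taper = gaussian_taper(config$window, config$taper_sigma))
  if (!is.null(truncate_n)) cs <- truncate_series(cs, truncate_n)
  mm <- build_meta_matrix(cs, metric = config$mm_metric)
  out <- list()
  for (kind in config$tdsm_kinds)
    out[[paste0("tdsm_fit_", kind)]] <- tdsm_fit(mm, kind)
  for (L in config$proximal_lags) {
    ps <- as.numeric(proximal_series(mm, max_lag = L))
    ms <- summarize_series(ps, bins = config$bins, sampen_m = config$sampen_m,
                           sampen_r = config$sampen_r)
    tag <- paste0("_l", L)
    out[[paste0("proximal_mean", tag)]] <- ms$mean
    out[[paste0("proximal_median", tag)]] <- ms$median
    out[[paste0("proximal_sd", tag)]] <- ms$sd
    out[[paste0("proximal_shannon", tag)]] <- ms$shannon_entropy
    out[[paste0("proximal_sampen", tag)]] <- ms$sample_entropy
    out[[paste0("proximal_etc", tag)]] <- ms$effort_to_compress_norm
    out[[paste0("proximal_mad", tag)]] <- ms$mean_abs_derivative
  }
  for (k in config$distal_k) {
    dm <- distal_measures(mm, k = k, mode = "per_column", bins = config$bins,
                          sampen_m = config$sampen_m,
                          sampen_r = config$sampen_r)
    tag <- paste0("_k", k)
    out[[paste0("dmm_etc", tag)]] <- dm$effort_to_compress_norm
    out[[paste0("dmm_sampen", tag)]] <- dm$sample_entropy
    out[[paste0("dmm_mean", tag)]] <- dm$mean
    out[[paste0("dmm_sd", tag)]] <- dm$sd
    out[[paste0("dmm_max", tag)]] <- dm$mean_max_similarity
  }
  if (!is.null(sc)) {
    sf <- struct_func_series(cs, sc, metric = config$sf_metric,
                             rank = config$sf_rank)
    sfs <- struct_func_summary(sf, bins = config$bins,
                               sampen_m = config$sampen_m,
                               sampen_r = config$sampen_r)
    out$sf_sampen <- sfs$sample_entropy
    out$sf_etc <- sfs$effort_to_compress_norm
    out$sf_max <- sfs$max_similarity
  }
  out
}

# Restrict a subject's data to a region subset (ids or indices).
subset_regions <- function(ts, sc, subset) {
  if (is.null(subset)) return(list(ts = ts, sc = sc))
  ids <- attr(ts, "region_ids")
  idx <- if (is.character(subset)) match(subset, ids) else as.integer(subset)
  if (anyNA(idx) || any(idx < 1) || any(idx > ncol(ts)))
    stop("subset_regions: unknown region in subset")
  ts2 <- region_ts(unclass(ts)[, idx, drop = FALSE],
                   tr_seconds = attr(ts, "tr_seconds"),
                   region_ids = ids[idx])
  sc2 <- if (is.null(sc)) NULL else
    structural_connectome(unclass(sc)[idx, idx, drop = FALSE])
  list(ts = ts2, sc = sc2)
}

#' Cohort measures table
#'
#' Computes [subject_measures()] for every subject and region subset of a
#' cohort, after truncating all connectivity series to the cohort-wide
#' minimum window count. Subjects whose analysis fails at any stage are
#' dropped with a recorded message; the pipeline continues.
#'
#' @param cohort A `"cohort"` (from [generate_cohort()] or
#'   [read_cohort_manifest()]).
#' @param config A [pipeline_config()].
#' @return Data frame: `subject_id`, `condition`, `condition_rank`,
#'   `subset`, one column per measure; attribute `failures` lists dropped
#'   subjects.
#' @export
cohort_measures <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(cohort, "cohort"))
  n_win <- vapply(cohort, function(s)
    as.integer((nrow(s$ts) - config$window) %/% config$step + 1), integer(1))
  trunc_n <- min(n_win)
  rows <- list(); failures <- character(0)
  for (s in cohort) for (sub_name in names(config$region_subsets)) {
    res <- tryCatch({
      d <- subset_regions(s$ts, s$sc, config$region_subsets[[sub_name]])
      m <- subject_measures(d$ts, d$sc, config, truncate_n = trunc_n)
      data.frame(subject_id = s$subject_id, condition = s$condition,
                 condition_rank = s$condition_rank, subset = sub_name,
                 as.data.frame(m))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures,
                    paste0(s$subject_id, "/", sub_name, ": ",
                           conditionMessage(res)))
    } else rows[[length(rows) + 1L]] <- res
  }
  if (length(failures))
    message("cohort_measures: ", length(failures), " subject/subset run(s) failed")
  out <- do.call(rbind, rows)
  attr(out, "failures") <- failures
  attr(out, "conditions") <- attr(cohort, "conditions")
  out
}

#' Ordinal regression of cohort measures against awareness level
#'
#' Fits one proportional-odds regression per measure (and region subset),
#' with the ordered condition as outcome and the measure as predictor, plus
#' optional joint (covariate) models. Subjects with missing measures are
#' dropped with a message.
#'
#' @param table Measures table from [cohort_measures()] (must contain
#'   `condition`, `condition_rank`, `subset` and measure columns).
#' @param measures Measure columns to analyse (default: all numeric columns
#'   except `condition_rank`).
#' @param conditions Condition labels ordered least to most aware; default
#'   taken from the table attribute or rank order.
#' @param covariate_sets Optional named list of character vectors; each
#'   gives a set of measures entered jointly as covariates.
#' @param ... Passed to [fit_proportional_odds()] (e.g. `sided`).
#' @return Object of class `"cohort_analysis"`: list with `results` (data
#'   frame of OR, CI, p per measure x subset), `fits` (the `olr_fit`
#'   objects), `covariate_fits` and `conditions`.
#' @export
run_cohort_analysis <- function(table, measures = NULL, conditions = NULL,
                                covariate_sets = NULL, ...) {
  if (is.null(conditions)) {
    conditions <- attr(table, "conditions")
    if (is.null(conditions))
      conditions <- unique(table$condition[order(table$condition_rank)])
  }
  if (length(unique(table$condition)) < 2)
    stop("ordinal outcome needs >= 2 levels")
  if (is.null(measures)) {
    num <- vapply(table, is.numeric, logical(1))
    measures <- setdiff(names(table)[num], "condition_rank")
  }
  if (!"subset" %in% names(table)) table$subset <- "whole_brain"
  rows <- list(); fits <- list()
  for (sub_name in unique(table$subset)) {
    tb <- table[table$subset == sub_name, , drop = FALSE]
    y <- factor(tb$condition, levels = conditions, ordered = TRUE)
    for (msr in measures) {
      x <- tb[[msr]]
      keep <- !is.na(x)
      if (sum(!keep) > 0)
        message("run_cohort_analysis: dropping ", sum(!keep),
                " subject(s) with missing ", msr)
      fit <- fit_proportional_odds(y[keep], matrix(x[keep], ncol = 1,
                                                   dimnames = list(NULL, msr)),
                                   ...)
      key <- paste0(sub_name, ".", msr)
      fits[[key]] <- fit
      rows[[key]] <- data.frame(
        subset = sub_name, measure = msr,
        odds_ratio = if (is.null(fit$odds_ratio)) NA_real_ else unname(fit$odds_ratio),
        ci_low = if (is.null(fit$ci_low)) NA_real_ else unname(fit$ci_low),
        ci_high = if (is.null(fit$ci_high)) NA_real_ else unname(fit$ci_high),
        p_value = if (is.null(fit$p_value)) NA_real_ else unname(fit$p_value),
        converged = isTRUE(fit$converged), n = fit$n)
    }
  }
  covariate_fits <- NULL
  if (!is.null(covariate_sets)) {
    covariate_fits <- lapply(covariate_sets, function(set) {
      tb <- table[table$subset == table$subset[1], , drop = FALSE]
      y <- factor(tb$condition, levels = conditions, ordered = TRUE)
      X <- as.matrix(tb[, set, drop = FALSE])
      keep <- stats::complete.cases(X)
      fit_proportional_odds(y[keep], X[keep, , drop = FALSE], ...)
    })
  }
  structure(list(results = do.call(rbind, c(rows, make.row.names = FALSE)),
                 fits = fits, covariate_fits = covariate_fits,
                 conditions = conditions),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("Cohort ordinal analysis (", paste(x$conditions, collapse = " < "),
      ")\n", sep = "")
  df <- x$results
  df$odds_ratio <- round(df$odds_ratio, 3)
  df$ci_low <- round(df$ci_low, 3); df$ci_high <- round(df$ci_high, 3)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cohort_analysis <- function(object, ...) {
  print(object)
  invisible(object$results)
}

#' End-to-end pipeline: cohort to measures table and ordinal results
#'
#' Composes [cohort_measures()] and [run_cohort_analysis()]: for each
#' subject and region subset, windowed connectivity, meta-matrix,
#' temporal-decay fits, proximal and distal complexity measures, and
#' structure-function summaries; then one proportional-odds regression per
#' measure.
#'
#' @param cohort A `"cohort"`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; if given, the measures table and
#'   results table are written there as TSV with JSON sidecars echoing the
#'   configuration.
#' @param ... Passed to [run_cohort_analysis()].
#' @return List with `measures` (data frame) and `analysis`
#'   (`cohort_analysis`).
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL,
                         ...) {
  measures <- cohort_measures(cohort, config)
  analysis <- run_cohort_analysis(measures, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    mpath <- file.path(out_dir, "measures.tsv")
    utils::write.table(measures, mpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_sidecar(mpath, list(config = unclass(config)))
    rpath <- file.path(out_dir, "olr_results.tsv")
    utils::write.table(analysis$results, rpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_sidecar(rpath, list(config = unclass(config),
                              conditions = analysis$conditions))
  }
  list(measures = measures, analysis = analysis)
}
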