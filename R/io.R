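#' Read a parcellated timeseries from delimited text
#'
#' Expects a TSV with regions as rows (region ids in the first column, a
#' header row of timepoint labels) — the layout written by
#' [write_timeseries()] — or the transpose with
#' `orientation = "time_by_regions"`.
#'
#' @param path File path.
#' @param orientation "regions_by_time" (default) or "time_by_regions".
#' @param tr_seconds Repetition time metadata to attach (default 2).
#' @return A [region_ts()].
#' @export
read_timeseries <- function(path,
                            orientation = c("regions_by_time",
                                            "time_by_regions"),
                            tr_seconds = 2) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, header = TRUE, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(raw)
  if (!is.numeric(m)) {
    bad <- which(!vapply(raw, is.numeric, logical(1)))
    stop("read_timeseries: non-numeric column(s): ",
         paste(names(raw)[bad], collapse = ", "))
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)
    stop("read_timeseries: missing value at row '", rownames(m)[idx[1, 1]],
         "', column '", colnames(m)[idx[1, 2]], "'",
         if (nrow(idx) > 1) paste0(" (and ", nrow(idx) - 1, " more)"))
  }
  if (orientation == "regions_by_time") {
    ids <- rownames(m)
    m <- t(m)
  } else ids <- colnames(m)
  rownames(m) <- NULL
  if (anyDuplicated(ids)) stop("read_timeseries: duplicate region ids")
  region_ts(m, tr_seconds = tr_seconds, region_ids = ids)
}

#' Write a parcellated timeseries as delimited text
#'
#' Regions as rows, region ids in the first column, header row of
#' timepoint indices (`t1 .. tT`).
#'
#' @param ts A [region_ts()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  m <- t(unclass(as.matrix(ts)))
  colnames(m) <- paste0("t", seq_len(ncol(m)))
  df <- data.frame(region = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a structural connectome from a delimited square matrix
#'
#' @param path File path to a TSV square matrix (no header).
#' @return A [structural_connectome()].
#' @export
read_connectome <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
  dimnames(m) <- NULL
  structural_connectome(m)
}

#' Write a structural connectome as a delimited square matrix
#'
#' @param sc A [structural_connectome()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(sc, path) {
  utils::write.table(unclass(sc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# JSON sidecar with provenance for a written artifact.
write_sidecar <- function(path, info) {
  info$package_version <- as.character(utils::packageVersion("mmdfc"))
  jsonlite::write_json(info, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a cohort to disk with a manifest
#'
#' One timeseries TSV and one connectome TSV per subject plus a manifest
#' table (`subject_id`, `condition`, `ts_path`, `sc_path`) and a JSON
#' sidecar recording the condition order.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    ts_path <- file.path(dir, paste0(s$subject_id, "_ts.tsv"))
    sc_path <- file.path(dir, paste0(s$subject_id, "_sc.tsv"))
    write_timeseries(s$ts, ts_path)
    write_connectome(s$sc, sc_path)
    data.frame(subject_id = s$subject_id, condition = s$condition,
               ts_path = basename(ts_path), sc_path = basename(sc_path))
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_sidecar(mpath, list(conditions = attr(cohort, "conditions")))
  invisible(mpath)
}

#' Read a cohort from a manifest
#'
#' @param manifest_path Path to a manifest TSV written by [write_cohort()].
#' @param conditions Condition labels in order, least to most aware;
#'   defaults to the manifest sidecar if present, else order of first
#'   appearance.
#' @param tr_seconds Repetition time of the stored timeseries.
#' @return A `"cohort"` list (without generator configs).
#' @export
read_cohort_manifest <- function(manifest_path, conditions = NULL,
                                 tr_seconds = 2) {
  man <- utils::read.delim(manifest_path)
  need <- c("subject_id", "condition", "ts_path", "sc_path")
  if (!all(need %in% names(man)))
    stop("read_cohort_manifest: manifest must have columns ",
         paste(need, collapse = ", "))
  base <- dirname(manifest_path)
  if (is.null(conditions)) {
    side <- paste0(manifest_path, ".json")
    conditions <- if (file.exists(side))
      unlist(jsonlite::read_json(side)$conditions) else unique(man$condition)
  }
  if (!all(man$condition %in% conditions))
    stop("read_cohort_manifest: manifest conditions not all in condition order")
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    list(subject_id = man$subject_id[i], condition = man$condition[i],
         condition_rank = match(man$condition[i], conditions),
         ts = read_timeseries(file.path(base, man$ts_path[i]),
                              tr_seconds = tr_seconds),
         sc = read_connectome(file.path(base, man$sc_path[i])),
         config = NULL)
  })
  structure(subjects, conditions = conditions, class = "cohort")
}

#' Pipeline configuration
#'
#' Validated bundle of every analysis parameter used by [run_pipeline()].
#'
#' @param window,step Sliding-window length and advance (defaults 24 and 1).
#' @param taper_sigma Gaussian taper width in timepoints (default
#'   `window/6`).
#' @param mm_metric Meta-matrix metric ("pearson", "manhattan", "cosine").
#' @param tdsm_kinds Character vector of decay-model kinds to fit.
#' @param proximal_lags Integer vector of maximum sub-diagonal lags for the
#'   proximal series (default 1; 6 and 13 are common additions).
#' @param distal_k Integer vector of distal exclusion lags (default 13;
#'   24 is the non-overlap sensitivity choice).
#' @param sampen_m,sampen_r Sample-entropy parameters.
#' @param bins Bins for Shannon entropy / ETC symbolization.
#' @param sf_metric,sf_rank Structure-function similarity metric and
#'   threshold ranking rule.
#' @param region_subsets Named list of region-id (or index) vectors;
#'   `NULL` entries mean all regions (default `list(whole_brain = NULL)`).
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(window = 24, step = 1, taper_sigma = window / 6,
                            mm_metric = "pearson",
                            tdsm_kinds = c("exp_slow", "exp_fast", "linear"),
                            proximal_lags = 1, distal_k = 13,
                            sampen_m = 1, sampen_r = 0.2, bins = 10,
                            sf_metric = "pearson", sf_rank = "signed",
                            region_subsets = list(whole_brain = NULL)) {
  stopifnot(window >= 2, step >= 1, taper_sigma > 0,
            all(proximal_lags >= 1), all(distal_k >= 1),
            sampen_m >= 1, sampen_r > 0, bins >= 2)
  mm_metric <- match.arg(mm_metric, c("pearson", "manhattan", "cosine"))
  tdsm_kinds <- match.arg(tdsm_kinds, c("exp_slow", "exp_fast", "linear"),
                          several.ok = TRUE)
  sf_metric <- match.arg(sf_metric, c("pearson", "cosine", "manhattan"))
  sf_rank <- match.arg(sf_rank, c("signed", "absolute"))
  if (is.null(names(region_subsets)))
    stop("pipeline_config: region_subsets must be a named list")
  structure(list(window = window, step = step, taper_sigma = taper_sigma,
                 mm_metric = mm_metric, tdsm_kinds = tdsm_kinds,
                 proximal_lags = as.integer(proximal_lags),
                 distal_k = as.integer(distal_k),
                 sampen_m = sampen_m, sampen_r = sampen_r, bins = bins,
                 sf_metric = sf_metric, sf_rank = sf_rank,
                 region_subsets = region_subsets),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_pipeline_config`, a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
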