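#' Assemble a machine-readable report across measurement modules
#'
#' Builds one figure-style panel per supplied component with group n,
#' mean +/- SEM, the relevant test, and QC exclusion counts. Output is
#' deterministic: rerunning on identical inputs yields a byte-identical JSON
#' serialisation.
#'
#' @param tether Optional `data.frame` of tether measurements (from
#'   [measure_tether_force()] rows, after [flag_double_tethers()]).
#' @param relative Optional `data.frame` from [relative_forces()].
#' @param lfq Optional list with elements `ratios` (from [call_outliers()])
#'   and `fit` (a `gaussian_fit`).
#' @param actin Optional `data.frame` with columns `group`, `f_actin_ratio`,
#'   `g_actin_mean`.
#' @param uptake Optional `data.frame` with columns `group`, `value`
#'   (normalized uptake) and optionally `reference_group`.
#' @param flow Optional `data.frame` with columns `sample_id`, `group`,
#'   `geometric_mean`.
#' @param config Optional list; `config$normalization_reference` is required
#'   when uptake rows carry more than one distinct `reference_group`.
#' @return List of class `mitocme_report` (panels keyed by name).
#' @export
assemble_report <- function(tether = NULL, relative = NULL, lfq = NULL,
                            actin = NULL, uptake = NULL, flow = NULL,
                            config = list()) {
  panels <- list()

  summarize_by <- function(values, groups) {
    out <- lapply(split(values, groups), function(v)
      group_summary(v, label = ""))
    labs <- names(out)
    res <- do.call(rbind, out)
    res$group <- labs
    rownames(res) <- NULL
    res[order(res$group), , drop = FALSE]
  }

  if (!is.null(tether)) {
    ok <- tether$qc_flags == "" | is.na(tether$qc_flags)
    excl <- table(unlist(strsplit(tether$qc_flags[!ok], ";", fixed = TRUE)))
    panel <- list(groups = summarize_by(tether$force_pN[ok],
                                        tether$phase[ok]),
                  qc_exclusions = as.list(excl),
                  n_excluded = sum(!ok))
    phases <- unique(tether$phase[ok])
    if (length(phases) == 2) {
      tt <- two_sample_t(tether$force_pN[ok & tether$phase == phases[1]],
                         tether$force_pN[ok & tether$phase == phases[2]])
      panel$test <- list(name = tt$test, statistic = tt$statistic,
                         df = tt$df, p = tt$p_two_sided)
    }
    panels$tether_force <- panel
  }

  if (!is.null(relative)) {
    panels$relative_force <- list(
      groups = summarize_by(relative$relative_force, relative$phase))
  }

  if (!is.null(lfq)) {
    r <- lfq$ratios
    panels$lfq_outliers <- list(
      fit = list(mu = lfq$fit$mu, sigma = lfq$fit$sigma,
                 n_fitted = lfq$fit$n_fitted),
      n_interphase_enriched = sum(r$outlier_call == "interphase_enriched"),
      n_mitotic_enriched = sum(r$outlier_call == "mitotic_enriched"),
      interphase_exclusive = sort(r$protein_id[r$status == "interphase_exclusive"]),
      mitotic_exclusive = sort(r$protein_id[r$status == "mitotic_exclusive"]),
      n_excluded_zero = sum(r$status == "excluded_zero"))
  }

  if (!is.null(actin)) {
    panels$actin <- list(
      f_actin_ratio = summarize_by(actin$f_actin_ratio, actin$group),
      g_actin_mean = summarize_by(actin$g_actin_mean, actin$group))
    if (length(unique(actin$group)) >= 3) {
      at <- anova_tukey(split(actin$f_actin_ratio, actin$group))
      panels$actin$test <- list(name = at$test, F = at$statistic,
                                df = at$df, p = at$p_two_sided,
                                pairwise = at$pairwise)
    }
  }

  if (!is.null(uptake)) {
    if ("reference_group" %in% names(uptake)) {
      refs <- unique(uptake$reference_group)
      if (length(refs) > 1 && is.null(config$normalization_reference))
        stop("mixed normalization references; set config$normalization_reference")
    }
    panels$tf_uptake <- list(
      groups = summarize_by(uptake$value, uptake$group))
  }

  if (!is.null(flow)) {
    panels$flow <- list(
      per_sample = flow[order(flow$sample_id), , drop = FALSE],
      groups = summarize_by(flow$geometric_mean, flow$group))
  }

  if (!length(panels)) stop("no module output supplied")
  structure(panels, class = "mitocme_report")
}

#' Write a report bundle to disk
#'
#' Writes `report.json` plus one CSV per panel group table.
#'
#' @param report A `mitocme_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path to `report.json`.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mitocme_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (nm in names(report)) {
    g <- report[[nm]]$groups
    if (!is.null(g))
      utils::write.csv(g, file.path(dir, paste0(nm, "_groups.csv")),
                       row.names = FALSE)
  }
  invisible(path)
}
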