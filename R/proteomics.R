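#' Read a MaxQuant-style proteinGroups table
#'
#' Parses a tab-separated protein-group quantitation file with a `Protein IDs`
#' column and per-sample `LFQ intensity ...` columns. Contaminant and
#' reverse-decoy rows (ids prefixed `CON__` / `REV__`) are dropped and the
#' count reported via a message.
#'
#' @param path Path to the tab-separated file.
#' @param condition_column_map Optional named list mapping condition names
#'   (`interphase`, `mitotic`) to character vectors of LFQ column names. When
#'   `NULL`, columns matching `LFQ intensity <condition>[_<experiment>]` are
#'   auto-detected.
#' @return A `protein_quant_table`: a `data.frame` with attributes
#'   `lfq_columns` (named list per condition) and `n_dropped_decoys`.
#' @export
read_protein_groups <- function(path, condition_column_map = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  protein_quant_table(tab, condition_column_map)
}

#' Validate and annotate a protein quantitation table
#'
#' @param tab `data.frame` with `Protein IDs` and LFQ intensity columns.
#' @param condition_column_map See [read_protein_groups()].
#' @return The validated table with LFQ column metadata attached.
#' @export
protein_quant_table <- function(tab, condition_column_map = NULL) {
  if (!"Protein IDs" %in% names(tab))
    stop("input lacks a 'Protein IDs' column")
  if (is.null(condition_column_map)) {
    lfq <- grep("^LFQ intensity ", names(tab), value = TRUE)
    cond <- sub("^LFQ intensity ([A-Za-z]+).*$", "\\1", lfq)
    condition_column_map <- split(lfq, cond)
  } else {
    missing <- setdiff(unlist(condition_column_map), names(tab))
    if (length(missing))
      stop("mapped columns absent from table: ", paste(missing, collapse = ", "))
  }
  if (!all(c("interphase", "mitotic") %in% names(condition_column_map)))
    stop("need LFQ intensity columns for both 'interphase' and 'mitotic'")
  lfq_cols <- unlist(condition_column_map)
  vals <- as.matrix(tab[, lfq_cols, drop = FALSE])
  if (!is.numeric(vals) || any(is.na(vals)))
    stop("LFQ intensity columns must be numeric and complete")
  if (any(vals < 0)) stop("negative LFQ intensity values found")

  decoy <- grepl("^(CON__|REV__)", tab$`Protein IDs`)
  if (any(decoy))
    message("dropped ", sum(decoy), " contaminant/decoy rows (CON__/REV__)")
  out <- tab[!decoy, , drop = FALSE]
  rownames(out) <- NULL
  if (anyDuplicated(out$`Protein IDs`)) stop("duplicate Protein IDs")
  attr(out, "lfq_columns") <- condition_column_map
  attr(out, "n_dropped_decoys") <- sum(decoy)
  class(out) <- c("protein_quant_table", "data.frame")
  out
}

#' Interphase/mitotic LFQ ratios with exclusion and exclusivity status
#'
#' For each protein the per-condition LFQ value is either the combined-run
#' column for that condition (when a single column per condition exists) or
#' the mean over experiments with nonzero intensity. The ratio is
#' interphase/mitotic. Proteins with a zero condition value are excluded from
#' ratio analysis (`excluded_zero`): the zero may reflect true absence or poor
#' detection. When the nonzero side exceeds `exclusive_threshold` the protein
#' is classified as condition-exclusive (`interphase_exclusive` /
#' `mitotic_exclusive`), a likely genuine presence/absence difference.
#'
#' @param table A `protein_quant_table`.
#' @param exclusive_threshold LFQ units above which a one-sided protein is
#'   called condition-exclusive (default 1e6).
#' @return `data.frame` of ratio results: `protein_id`, `gene_name`,
#'   `interphase_lfq`, `mitotic_lfq`, `ratio`, `log2_ratio`, `status`,
#'   `outlier_call` (initialised to `"none"`).
#' @export
compute_ratios <- function(table, exclusive_threshold = 1e6) {
  cmap <- attr(table, "lfq_columns")
  if (is.null(cmap)) stop("table lacks LFQ column metadata; use protein_quant_table()")
  cond_value <- function(cols) {
    m <- as.matrix(table[, cols, drop = FALSE])
    if (length(cols) == 1L) return(as.numeric(m))
    apply(m, 1, function(v) if (any(v > 0)) mean(v[v > 0]) else 0)
  }
  inter <- cond_value(cmap$interphase)
  mito <- cond_value(cmap$mitotic)

  status <- rep("ratio_ok", nrow(table))
  zero <- inter == 0 | mito == 0
  status[zero] <- "excluded_zero"
  status[mito == 0 & inter > exclusive_threshold] <- "interphase_exclusive"
  status[inter == 0 & mito > exclusive_threshold] <- "mitotic_exclusive"

  ratio <- ifelse(status == "ratio_ok", inter / mito, NA_real_)
  gene <- if ("Gene names" %in% names(table)) table$`Gene names`
          else table$`Protein IDs`
  data.frame(protein_id = table$`Protein IDs`, gene_name = gene,
             interphase_lfq = inter, mitotic_lfq = mito,
             ratio = ratio, log2_ratio = log2(ratio),
             status = status, outlier_call = "none",
             stringsAsFactors = FALSE)
}

#' Fit a single Gaussian to the histogram of log2 ratios
#'
#' A frequency histogram of the log2 interphase/mitotic ratios of all
#' `ratio_ok` proteins is constructed and a Gaussian
#' `A * exp(-(x - mu)^2 / (2 sigma^2))` is least-squares fitted to the bin
#' counts, initialised at the sample mean and SD. The fitted `mu` and `sigma`
#' define the null against which enrichment outliers are called. With
#' `method = "moments"` the sample mean/SD are returned directly.
#'
#' @param ratios Ratio results from [compute_ratios()].
#' @param bin_width Histogram bin width in log2 units (default 0.25), or
#'   `"FD"` for the Freedman-Diaconis rule.
#' @param method `"histogram"` (default) or `"moments"`.
#' @return List of class `gaussian_fit`: `mu`, `sigma`, `amplitude`,
#'   `bin_width`, `n_fitted`, `goodness` (residual SD over bin counts, NA for
#'   moments), `method`.
#' @export
fit_gaussian_null <- function(ratios, bin_width = 0.25,
                              method = c("histogram", "moments")) {
  method <- match.arg(method)
  x <- ratios$log2_ratio[ratios$status == "ratio_ok"]
  x <- x[is.finite(x)]
  if (length(x) < 50) stop("need at least 50 ratio_ok proteins to fit the null")
  m0 <- mean(x); s0 <- stats::sd(x)
  if (!is.finite(s0) || s0 == 0)
    stop("degenerate log2 ratios (zero spread); initial estimates mu=", m0)
  if (method == "moments") {
    return(structure(list(mu = m0, sigma = s0, amplitude = NA_real_,
                          bin_width = NA_real_, n_fitted = length(x),
                          goodness = NA_real_, method = method),
                     class = "gaussian_fit"))
  }
  if (identical(bin_width, "FD")) {
    bw <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  } else bw <- bin_width
  breaks <- seq(floor(min(x) / bw) * bw, max(x) + bw, by = bw)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  df <- data.frame(mid = h$mids, count = h$counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(count ~ A * exp(-(mid - mu)^2 / (2 * sigma^2)),
                      data = df,
                      start = list(A = max(df$count), mu = m0, sigma = s0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Gaussian fit did not converge (initial mu=",
                             signif(m0, 4), ", sd=", signif(s0, 4), "): ",
                             conditionMessage(e)))
  p <- stats::coef(fit)
  structure(list(mu = unname(p["mu"]), sigma = abs(unname(p["sigma"])),
                 amplitude = unname(p["A"]), bin_width = bw,
                 n_fitted = length(x),
                 goodness = stats::sd(stats::resid(fit)), method = method),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("Gaussian null fit (%s): mu = %.4f, sigma = %.4f (n = %d)\n",
              x$method, x$mu, x$sigma, x$n_fitted))
  invisible(x)
}

#' Call enrichment outliers at two fitted standard deviations
#'
#' Proteins whose log2 interphase/mitotic ratio lies strictly above
#' `mu + 2 sigma` are called `interphase_enriched` (depleted from mitotic
#' fractions); strictly below `mu - 2 sigma`, `mitotic_enriched`. Only
#' `ratio_ok` proteins are considered.
#'
#' @param ratios Ratio results from [compute_ratios()].
#' @param fit A `gaussian_fit`.
#' @param n_sigma Width of the null band in fitted SD units (default 2).
#' @return `ratios` with `outlier_call` set.
#' @export
call_outliers <- function(ratios, fit, n_sigma = 2) {
  stopifnot(inherits(fit, "gaussian_fit"))
  hi <- fit$mu + n_sigma * fit$sigma
  lo <- fit$mu - n_sigma * fit$sigma
  ok <- ratios$status == "ratio_ok"
  ratios$outlier_call <- "none"
  ratios$outlier_call[ok & ratios$log2_ratio > hi] <- "interphase_enriched"
  ratios$outlier_call[ok & ratios$log2_ratio < lo] <- "mitotic_enriched"
  ratios
}

#' Per-experiment outlier consistency
#'
#' Runs the ratio -> Gaussian fit -> outlier-call chain on each experiment's
#' own LFQ columns and reports each experiment's outlier set, their
#' intersection, and a per-protein consistency count (how many analysable
#' experiments called the protein an outlier). A genuine enrichment difference
#' should be re-detected when each run is analysed individually.
#'
#' @param table A `protein_quant_table` with per-experiment LFQ columns.
#' @param exclusive_threshold Passed to [compute_ratios()].
#' @param bin_width Passed to [fit_gaussian_null()].
#' @return List with `per_experiment` (named list of outlier-id character
#'   vectors), `intersection`, and `consistency` (`data.frame` with
#'   `protein_id`, `n_called`, `n_experiments`).
#' @export
per_experiment_consistency <- function(table, exclusive_threshold = 1e6,
                                       bin_width = 0.25) {
  cmap <- attr(table, "lfq_columns")
  exps <- lapply(cmap, function(cols) sub("^.*_", "", cols))
  shared <- Reduce(intersect, exps)
  if (length(shared) < 2)
    stop("need at least 2 experiments shared by both conditions")
  per_exp <- list()
  for (e in shared) {
    sub_map <- lapply(names(cmap), function(cn)
      cmap[[cn]][exps[[cn]] == e])
    names(sub_map) <- names(cmap)
    sub_tab <- protein_quant_table(
      as.data.frame(table)[, c("Protein IDs",
                               intersect("Gene names", names(table)),
                               unlist(sub_map)), drop = FALSE],
      condition_column_map = sub_map)
    r <- compute_ratios(sub_tab, exclusive_threshold)
    if (sum(r$status == "ratio_ok") < 50) {
      warning("experiment ", e, " has < 50 ratio_ok proteins; skipped")
      next
    }
    fit <- fit_gaussian_null(r, bin_width = bin_width)
    r <- call_outliers(r, fit)
    per_exp[[e]] <- r$protein_id[r$outlier_call != "none"]
  }
  if (!length(per_exp)) stop("no analysable experiment")
  inter <- Reduce(intersect, per_exp)
  all_ids <- unique(unlist(per_exp))
  consistency <- data.frame(
    protein_id = all_ids,
    n_called = vapply(all_ids, function(id)
      sum(vapply(per_exp, function(s) id %in% s, logical(1))), integer(1)),
    n_experiments = length(per_exp),
    stringsAsFactors = FALSE)
  rownames(consistency) <- NULL
  list(per_experiment = per_exp, intersection = inter,
       consistency = consistency)
}

#' Annotate ratio results against reference protein lists
#'
#' Restricts the ratio table to proteins found in one or more reference lists
#' (e.g., bona fide clathrin-coated-structure proteins, actin-cytoskeleton
#' components recruited to coated pits) and attaches the matching labels.
#' Proteins on several lists carry all matching labels. The result is ordered
#' by decreasing log2 ratio, as in the comparative-abundance bar chart.
#'
#' @param ratios Ratio results.
#' @param reference_lists Named list of character vectors of protein/gene ids;
#'   matched against both `protein_id` and `gene_name`.
#' @return The annotated subset with a `labels` column (`;`-separated).
#' @export
annotate_ratios <- function(ratios, reference_lists) {
  stopifnot(is.list(reference_lists), length(reference_lists) > 0)
  if (any(!lengths(reference_lists)))
    stop("empty reference list: ",
         paste(names(reference_lists)[!lengths(reference_lists)], collapse = ", "))
  labs <- vapply(seq_len(nrow(ratios)), function(i) {
    hit <- vapply(reference_lists, function(ids)
      ratios$protein_id[i] %in% ids || ratios$gene_name[i] %in% ids, logical(1))
    paste(names(reference_lists)[hit], collapse = ";")
  }, character(1))
  out <- ratios[labs != "", , drop = FALSE]
  out$labels <- labs[labs != ""]
  out[order(-out$log2_ratio, out$protein_id), , drop = FALSE]
}

#' Read a one-id-per-line reference list
#' @param path Text file with one protein/gene id per line; blank lines and
#'   `#` comments ignored.
#' @return Character vector of ids.
#' @export
read_reference_list <- function(path) {
  x <- trimws(readLines(path))
  x[x != "" & !startsWith(x, "#")]
}
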