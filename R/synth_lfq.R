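#' Specification for a synthetic protein-group LFQ table
#'
#' Describes a label-free quantitation experiment comparing clathrin-coated
#' structure fractions from interphase and mitotic cells over several paired
#' runs. Null proteins have log2 interphase/mitotic ratios drawn from
#' `Normal(null_mu, null_sigma^2)`; named outliers carry stated true ratios;
#' condition-exclusive proteins have intensity in one condition only; zeros
#' (MS dropout) are injected at `dropout_rate`.
#'
#' @param n_proteins Number of null (background) proteins.
#' @param n_experiments Number of paired experiments (default 4).
#' @param null_mu,null_sigma Mean and SD of the null log2 ratio distribution.
#' @param outlier_specs `data.frame` with columns `protein_id`, `true_ratio`
#'   (interphase/mitotic, > 0) and optionally `experiments` (comma-separated
#'   experiment indices carrying the outlier ratio; others draw from the
#'   null). `NULL` for none.
#' @param dropout_rate Probability that any single LFQ cell of a null protein
#'   is set to 0 (in `[0, 1)`).
#' @param exclusive_specs `data.frame` with columns `protein_id`, `condition`
#'   (`"interphase"` or `"mitotic"`) and `intensity`; the other condition is 0
#'   in every experiment. `NULL` for none.
#' @param intensity_scale Geometric centre of mitotic LFQ intensities
#'   (arbitrary LFQ units).
#' @param protein_sdlog Protein-to-protein spread (natural-log SD) of base
#'   abundance.
#' @param seed Integer seed.
#' @return An object of class `lfq_gen_spec`.
#' @export
lfq_gen_spec <- function(n_proteins = 1000,
                         n_experiments = 4,
                         null_mu = 0,
                         null_sigma = 0.8,
                         outlier_specs = NULL,
                         dropout_rate = 0,
                         exclusive_specs = NULL,
                         intensity_scale = 1e7,
                         protein_sdlog = 1,
                         seed = 1L) {
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (null_sigma <= 0) stop("null_sigma must be > 0")
  if (!is.null(outlier_specs)) {
    stopifnot(all(c("protein_id", "true_ratio") %in% names(outlier_specs)))
    if (any(outlier_specs$true_ratio <= 0)) stop("true_ratio must be > 0")
  }
  if (!is.null(exclusive_specs))
    stopifnot(all(c("protein_id", "condition", "intensity") %in%
                    names(exclusive_specs)))
  ids <- c(if (!is.null(outlier_specs)) outlier_specs$protein_id,
           if (!is.null(exclusive_specs)) exclusive_specs$protein_id)
  if (anyDuplicated(ids)) stop("duplicate protein_id across outlier/exclusive specs")
  structure(list(n_proteins = n_proteins, n_experiments = n_experiments,
                 null_mu = null_mu, null_sigma = null_sigma,
                 outlier_specs = outlier_specs, dropout_rate = dropout_rate,
                 exclusive_specs = exclusive_specs,
                 intensity_scale = intensity_scale,
                 protein_sdlog = protein_sdlog,
                 seed = as.integer(seed)),
            class = "lfq_gen_spec")
}

#' Generate a synthetic proteinGroups-style LFQ table with ground truth
#'
#' LFQ intensities are log-normal; each protein's base abundance varies from
#' run to run by a shared experiment factor applied to both conditions, and
#' the interphase channel is multiplied by the protein's true
#' interphase/mitotic ratio. The per-protein ratio of condition aggregates is
#' therefore exactly the true ratio before dropout.
#'
#' @param spec An [lfq_gen_spec()].
#' @return List with:
#'   * `table`: `data.frame` in MaxQuant proteinGroups dialect
#'     (`Protein IDs`, `Gene names`, `LFQ intensity <condition>_<e>` columns);
#'   * `truth`: `data.frame` with `protein_id`, `class`
#'     (`null`/`outlier`/`interphase_exclusive`/`mitotic_exclusive`),
#'     `true_ratio`, `true_log2_ratio`, and `outlier_experiments`.
#' @export
gen_lfq_table <- function(spec) {
  stopifnot(inherits(spec, "lfq_gen_spec"))
  withr_seed(spec$seed, {
    E <- spec$n_experiments
    n_out <- if (is.null(spec$outlier_specs)) 0L else nrow(spec$outlier_specs)
    n_exc <- if (is.null(spec$exclusive_specs)) 0L else nrow(spec$exclusive_specs)
    n <- spec$n_proteins + n_out + n_exc

    ids <- sprintf("NULLP%04d", seq_len(spec$n_proteins))
    class <- rep("null", spec$n_proteins)
    # per-protein true log2 ratio; per-experiment overrides for outliers
    l2 <- matrix(stats::rnorm(n * E, spec$null_mu, spec$null_sigma), n, E)
    l2[seq_len(spec$n_proteins), ] <- stats::rnorm(spec$n_proteins,
                                                   spec$null_mu,
                                                   spec$null_sigma)
    true_ratio <- 2^l2[, 1]
    out_exps <- rep(NA_character_, n)

    if (n_out) {
      os <- spec$outlier_specs
      idx <- spec$n_proteins + seq_len(n_out)
      ids <- c(ids, os$protein_id)
      class[idx] <- "outlier"
      for (j in seq_len(n_out)) {
        ex_str <- if ("experiments" %in% names(os) && !is.na(os$experiments[j]))
          os$experiments[j] else paste(seq_len(E), collapse = ",")
        carrying <- as.integer(strsplit(ex_str, ",")[[1]])
        l2[idx[j], carrying] <- log2(os$true_ratio[j])
        out_exps[idx[j]] <- ex_str
      }
      true_ratio[idx] <- os$true_ratio
    }
    if (n_exc) {
      es <- spec$exclusive_specs
      idx <- spec$n_proteins + n_out + seq_len(n_exc)
      ids <- c(ids, es$protein_id)
      class[idx] <- paste0(es$condition, "_exclusive")
      true_ratio[idx] <- NA_real_
    }

    # log-normal base abundance; shared run-to-run loading factor applied to
    # both conditions, so each protein's condition ratio is exact
    base <- stats::rlnorm(n, log(spec$intensity_scale), spec$protein_sdlog)
    expf <- matrix(stats::rlnorm(n * E, 0, 0.2), n, E)
    mito <- base * expf
    inter <- mito * 2^l2

    if (spec$dropout_rate > 0) {
      nulls <- class == "null"
      drop_i <- matrix(stats::runif(n * E) < spec$dropout_rate, n, E) & nulls
      drop_m <- matrix(stats::runif(n * E) < spec$dropout_rate, n, E) & nulls
      inter[drop_i] <- 0
      mito[drop_m] <- 0
    }
    if (n_exc) {
      idx <- spec$n_proteins + n_out + seq_len(n_exc)
      es <- spec$exclusive_specs
      for (j in seq_len(n_exc)) {
        if (es$condition[j] == "interphase") {
          inter[idx[j], ] <- es$intensity[j]; mito[idx[j], ] <- 0
        } else {
          mito[idx[j], ] <- es$intensity[j]; inter[idx[j], ] <- 0
        }
      }
    }

    tab <- data.frame(ids, ids, inter, mito,
                      check.names = FALSE, stringsAsFactors = FALSE)
    names(tab) <- c("Protein IDs", "Gene names",
                    paste0("LFQ intensity interphase_", seq_len(E)),
                    paste0("LFQ intensity mitotic_", seq_len(E)))
    truth <- data.frame(protein_id = ids, class = class,
                        true_ratio = true_ratio,
                        true_log2_ratio = log2(true_ratio),
                        outlier_experiments = out_exps,
                        stringsAsFactors = FALSE)
    list(table = tab, truth = truth)
  })
}
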