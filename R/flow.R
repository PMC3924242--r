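#' Specification for synthetic flow-cytometry events
#'
#' Mixtures of cell populations (Gaussian FSC, log-normal FL1) plus small
#' debris with forward scatter below the analysis gate.
#'
#' @param n_events Total number of events (> 0).
#' @param population_params `data.frame` with columns `fraction`, `fsc_mean`,
#'   `fsc_sd`, `fl1_log_mean`, `fl1_log_sd` (natural-log scale); fractions
#'   must sum to 1 and describe the non-debris events.
#' @param debris_fraction Fraction of all events that are sub-gate debris
#'   (FSC drawn uniformly in `[20, 180]`, dim FL1).
#' @param seed Integer seed.
#' @return An object of class `flow_gen_spec`.
#' @export
flow_gen_spec <- function(n_events = 10000,
                          population_params = data.frame(
                            fraction = 1, fsc_mean = 500, fsc_sd = 60,
                            fl1_log_mean = log(100), fl1_log_sd = 0.5),
                          debris_fraction = 0,
                          seed = 1L) {
  stopifnot(n_events > 0,
            all(c("fraction", "fsc_mean", "fsc_sd", "fl1_log_mean",
                  "fl1_log_sd") %in% names(population_params)))
  if (abs(sum(population_params$fraction) - 1) > 1e-8)
    stop("population fractions must sum to 1")
  if (debris_fraction < 0 || debris_fraction >= 1)
    stop("debris_fraction must be in [0, 1)")
  structure(list(n_events = as.integer(n_events),
                 population_params = population_params,
                 debris_fraction = debris_fraction,
                 seed = as.integer(seed)),
            class = "flow_gen_spec")
}

#' Generate synthetic flow-cytometry events with ground truth
#'
#' @param spec A [flow_gen_spec()].
#' @return List with:
#'   * `events`: `data.frame` with `FSC`, `SSC`, `FL1` and a `population`
#'     label column (`"debris"` or `pop<k>`);
#'   * `truth`: list with `fl1_geometric_mean` per population
#'     (`exp(fl1_log_mean)`), `n_below_gate` (count of generated events with
#'     FSC < 200) and `n_debris`.
#' @export
gen_flow_events <- function(spec) {
  stopifnot(inherits(spec, "flow_gen_spec"))
  withr_seed(spec$seed, {
    n_debris <- round(spec$n_events * spec$debris_fraction)
    n_cells <- spec$n_events - n_debris
    pp <- spec$population_params
    counts <- stats::rmultinom(1, n_cells, pp$fraction)[, 1]
    parts <- lapply(seq_len(nrow(pp)), function(k) {
      m <- counts[k]
      data.frame(FSC = stats::rnorm(m, pp$fsc_mean[k], pp$fsc_sd[k]),
                 SSC = stats::rnorm(m, pp$fsc_mean[k] * 0.6, pp$fsc_sd[k]),
                 FL1 = stats::rlnorm(m, pp$fl1_log_mean[k], pp$fl1_log_sd[k]),
                 population = paste0("pop", k), stringsAsFactors = FALSE)
    })
    if (n_debris > 0)
      parts <- c(parts, list(data.frame(
        FSC = stats::runif(n_debris, 20, 180),
        SSC = stats::runif(n_debris, 10, 120),
        FL1 = stats::rlnorm(n_debris, log(5), 0.5),
        population = "debris", stringsAsFactors = FALSE)))
    ev <- do.call(rbind, parts)
    ev <- ev[sample.int(nrow(ev)), , drop = FALSE]
    rownames(ev) <- NULL
    truth <- list(
      fl1_geometric_mean = stats::setNames(exp(pp$fl1_log_mean),
                                           paste0("pop", seq_len(nrow(pp)))),
      n_below_gate = sum(ev$FSC < 200),
      n_debris = n_debris)
    list(events = ev, truth = truth)
  })
}

#' Gate events on forward scatter
#'
#' Retains events with `FSC >= threshold`; particles smaller than cells fall
#' below the gate and are excluded from analysis. The number of gated-out
#' events is attached as attribute `n_excluded`.
#'
#' @param events `data.frame` with an `FSC` column.
#' @param threshold Gate value in detector units (default 200, inclusive).
#' @return The gated `data.frame` with attribute `n_excluded`.
#' @export
gate_fsc <- function(events, threshold = 200) {
  if (!"FSC" %in% names(events)) stop("events lack an FSC column")
  keep <- events$FSC >= threshold
  if (!any(keep)) stop("no events remain after FSC gating")
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Geometric mean of the FL1 channel
#'
#' `exp(mean(log(FL1)))` over events with positive FL1, the standard summary
#' for log-normally distributed cytometry fluorescence. Non-positive events
#' (unmeasurable on a log scale) are excluded and counted in attribute
#' `n_excluded_nonpositive`.
#'
#' @param events Gated `data.frame` with an `FL1` column, or a numeric vector
#'   of FL1 values.
#' @return Geometric mean (detector units) with attribute
#'   `n_excluded_nonpositive`.
#' @export
fl1_geometric_mean <- function(events) {
  fl1 <- if (is.data.frame(events)) events$FL1 else events
  if (is.null(fl1)) stop("events lack an FL1 column")
  pos <- fl1 > 0
  if (!any(pos)) stop("no positive FL1 values")
  structure(exp(mean(log(fl1[pos]))),
            n_excluded_nonpositive = sum(!pos))
}
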