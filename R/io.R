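#' Write a tether trace as CSV with an events sidecar
#'
#' The trace is written with header `time_s,displacement_nm`; stage events go
#' to a sidecar `<stem>_events.csv` with header `time_s,event`. Stiffness and
#' identifiers belong in the per-experiment config (see
#' [write_experiment_config()]).
#'
#' @param trace A [tether_trace()].
#' @param path Output CSV path.
#' @return Invisibly, `c(trace = path, events = events_path)`.
#' @export
write_tether_trace <- function(trace, path) {
  stopifnot(inherits(trace, "tether_trace"))
  utils::write.csv(data.frame(time_s = trace$time,
                              displacement_nm = trace$displacement),
                   path, row.names = FALSE)
  epath <- sub("\\.csv$", "", path)
  epath <- paste0(epath, "_events.csv")
  utils::write.csv(trace$events, epath, row.names = FALSE)
  invisible(c(trace = path, events = epath))
}

#' Read a tether trace from CSV (+ events sidecar)
#'
#' @param path Trace CSV (`time_s,displacement_nm`).
#' @param stiffness Calibrated trap stiffness in pN/nm.
#' @param events_path Events CSV (`time_s,event`); defaults to the
#'   `<stem>_events.csv` sidecar, and to no events if neither exists.
#' @param cell_id,experiment_id,phase Identifiers.
#' @return A [tether_trace()].
#' @export
read_tether_trace <- function(path, stiffness, events_path = NULL,
                              cell_id = "cell1", experiment_id = "exp1",
                              phase = "interphase") {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "displacement_nm") %in% names(d)))
  if (is.null(events_path))
    events_path <- paste0(sub("\\.csv$", "", path), "_events.csv")
  ev <- if (file.exists(events_path)) utils::read.csv(events_path)
        else data.frame(time_s = numeric(0), event = character(0))
  formed <- ev$time_s[ev$event == "tether_formed"][1]
  tether_trace(time = d$time_s, displacement = d$displacement_nm, events = ev,
               stiffness = stiffness, cell_id = cell_id,
               experiment_id = experiment_id, phase = phase,
               tether_formed_at = if (length(formed)) formed else NA_real_,
               has_zero_reference =
                 any(ev$event == "stage_toward_cell_contact"))
}

#' Write / read a per-experiment configuration (JSON)
#'
#' Holds per-experiment acquisition settings: trap stiffness (pN/nm),
#' temperature (K), averaging span, settling margin and tether-age cutoff.
#'
#' @param config Named list of settings.
#' @param path JSON path.
#' @return `write_experiment_config` invisibly returns `path`;
#'   `read_experiment_config` returns the config list.
#' @export
write_experiment_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a protein quantitation table in proteinGroups dialect
#'
#' Tab-separated with the original column names (`Protein IDs`, `Gene names`,
#' `LFQ intensity ...`).
#'
#' @param table `data.frame` (or `protein_quant_table`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_protein_groups <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read image channels as multi-page TIFF
#'
#' Intensities are stored as 32-bit float TIFF scaled by `scale` (TIFF float
#' samples live in `[0, 1]`); reading multiplies the scale back, so arbitrary
#' fluorescence units round-trip to single precision.
#'
#' @param channels A matrix or list of matrices (one page each).
#' @param path TIFF path.
#' @param scale Intensity corresponding to 1.0 in the file (default 65535).
#' @return `write_image_tiff` invisibly returns `path`; `read_image_tiff`
#'   returns a list of matrices.
#' @export
write_image_tiff <- function(channels, path, scale = 65535) {
  if (is.matrix(channels)) channels <- list(channels)
  if (any(vapply(channels, function(m) any(m < 0 | m > scale), logical(1))))
    stop("intensities must lie in [0, scale]")
  tiff::writeTIFF(lapply(channels, function(m) m / scale), path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) p * scale)
}

#' Write a binary mask as single-page TIFF of 0/1
#' @param mask Logical matrix.
#' @param path TIFF path.
#' @return Invisibly, `path`.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF((mask > 0) * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write / read flow-cytometry events as CSV (`FSC,SSC,FL1`)
#' @param events `data.frame` with `FSC`, `SSC`, `FL1` columns.
#' @param path CSV path.
#' @return `write_flow_events` invisibly returns `path`; `read_flow_events`
#'   returns the events `data.frame`.
#' @export
write_flow_events <- function(events, path) {
  utils::write.csv(events[, c("FSC", "SSC", "FL1")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_events
#' @export
read_flow_events <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("FSC", "SSC", "FL1") %in% names(d)))
    stop("flow CSV must have FSC,SSC,FL1 columns")
  d
}
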