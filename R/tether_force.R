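#' Tether trace container
#'
#' A timestamped bead-displacement record from an optical-trap tether-pulling
#' experiment, with stage-event annotations and the calibrated trap stiffness.
#' Displacement is the bead offset from the trap centre in nm; force at any
#' instant is `stiffness * displacement`.
#'
#' @param time Numeric vector of times in seconds, strictly increasing.
#' @param displacement Numeric vector of bead displacements in nm, same length
#'   as `time`.
#' @param events `data.frame` with columns `time_s`, `event` (may have zero
#'   rows); event times must lie within the trace span.
#' @param stiffness Trap stiffness in pN/nm (> 0).
#' @param cell_id,experiment_id Identifiers.
#' @param phase `"interphase"` or `"metaphase"`.
#' @param tether_formed_at Time (s) at which the tether was formed, or `NA`.
#' @param has_zero_reference Logical; whether the trace contains an annotated
#'   zero-force window.
#' @return An object of class `tether_trace`.
#' @export
tether_trace <- function(time, displacement, events, stiffness,
                         cell_id = "cell1", experiment_id = "exp1",
                         phase = "interphase", tether_formed_at = NA_real_,
                         has_zero_reference = NA) {
  stopifnot(length(time) == length(displacement), length(time) >= 2)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (!is.numeric(stiffness) || stiffness <= 0) stop("stiffness must be > 0")
  if (nrow(events) &&
      (min(events$time_s) < time[1] || max(events$time_s) > time[length(time)]))
    stop("event times must lie within the trace span")
  structure(list(time = time, displacement = displacement, events = events,
                 stiffness = stiffness, cell_id = cell_id,
                 experiment_id = experiment_id,
                 phase = match.arg(phase, c("interphase", "metaphase")),
                 tether_formed_at = tether_formed_at,
                 has_zero_reference = has_zero_reference),
            class = "tether_trace")
}

#' @export
print.tether_trace <- function(x, ...) {
  cat(sprintf("tether_trace: %d samples over %.2f s, stiffness %.3g pN/nm\n",
              length(x$time), x$time[length(x$time)] - x$time[1], x$stiffness))
  cat(sprintf("  cell %s, experiment %s, %s; %d stage events\n",
              x$cell_id, x$experiment_id, x$phase, nrow(x$events)))
  invisible(x)
}

# Boltzmann constant in pN nm / K
.kB_pN_nm <- 1.380649e-2

#' Calibrate trap stiffness by equipartition
#'
#' From a tether-free (no-load) displacement segment, the equipartition
#' theorem gives `k = kB * T / var(x)`: the thermal positional variance of the
#' bead in the harmonic trap potential determines the stiffness.
#'
#' @param no_load_segment Numeric vector of displacements (nm) recorded with
#'   no tether attached; at least 1000 samples.
#' @param temperature Absolute temperature in K (default 298).
#' @return Stiffness in pN/nm.
#' @examples
#' # variance 13.71 nm^2 at 298 K (kB*T = 4.114 pN nm) -> ~0.30 pN/nm
#' @export
calibrate_stiffness <- function(no_load_segment, temperature = 298) {
  if (length(no_load_segment) < 1000)
    stop("no-load segment must contain at least 1000 samples")
  v <- stats::var(no_load_segment)
  if (!is.finite(v) || v <= 0)
    stop("degenerate no-load segment: zero displacement variance")
  .kB_pN_nm * temperature / v
}

#' Convert a displacement trace to a force trace
#'
#' Pointwise `force = stiffness * displacement`; the trap acts as a Hookean
#' spring over the working range.
#'
#' @param trace A [tether_trace()].
#' @return Numeric vector of forces in pN, same length as the trace.
#' @export
force_trace <- function(trace) {
  stopifnot(inherits(trace, "tether_trace"))
  trace$stiffness * trace$displacement
}

#' Locate the zero-force reference window
#'
#' The stage is moved toward the bead to relax the tether; the displacement in
#' that window defines zero force. The window runs from the toward-cell event
#' plus a settling margin (to exclude stage-motion transients) to the next
#' away event. If the trace carries no toward/away annotation, a changepoint
#' fallback proposes the contiguous window of length `averaging_span` with the
#' lowest mean displacement, and the result is flagged `no_zero_reference`.
#'
#' @param trace A [tether_trace()].
#' @param settling_margin Seconds to skip after the toward-cell event
#'   (default 0.2 s).
#' @param averaging_span Minimum usable window length in seconds (default 1).
#' @return List with `window` (`c(start_s, end_s)`) and `qc_flags`
#'   (character vector, possibly empty).
#' @export
locate_zero_reference <- function(trace, settling_margin = 0.2,
                                  averaging_span = 1.0) {
  stopifnot(inherits(trace, "tether_trace"))
  ev <- trace$events
  toward <- ev$time_s[ev$event == "stage_toward_cell_contact"]
  away <- ev$time_s[ev$event == "stage_away"]
  if (length(toward)) {
    tw <- toward[1]
    aw <- away[away > tw][1]
    if (is.na(aw)) aw <- trace$time[length(trace$time)]
    win <- c(tw + settling_margin, aw)
    if (diff(win) < averaging_span)
      stop("zero-reference window shorter than the averaging span")
    return(list(window = win, qc_flags = character(0)))
  }
  # fallback: sliding-window minimum of the displacement mean
  dt <- mean(diff(trace$time))
  w <- max(2L, round(averaging_span / dt))
  cs <- cumsum(c(0, trace$displacement))
  means <- (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
  i <- which.min(means)
  win <- c(trace$time[i], trace$time[i + w - 1L])
  list(window = win, qc_flags = "no_zero_reference")
}

#' Measure the tether force of one trace
#'
#' The plateau window is the `averaging_span` seconds immediately preceding
#' the first stage manipulation after tether formation; the baseline is the
#' mean over the zero-reference window. The tether force is the trap stiffness
#' times the difference of the two mean displacements, so any constant
#' displacement offset cancels. A measurement whose plateau window ends more
#' than `max_tether_age` seconds after tether formation is flagged
#' `stale_tether` (actin polymerises into older tethers and corrupts the
#' reading) and is excluded from downstream summaries.
#'
#' @param trace A [tether_trace()].
#' @param averaging_span Plateau averaging window in seconds (default 1).
#' @param max_tether_age Maximum tether age in seconds at measurement
#'   (default 30).
#' @param settling_margin Settling margin passed to [locate_zero_reference()].
#' @return A one-row `data.frame` (a tether measurement) with columns
#'   `cell_id`, `experiment_id`, `phase`, `force_pN`, `baseline_pN`,
#'   `plateau_start`, `plateau_end`, `baseline_start`, `baseline_end`,
#'   `qc_flags` (`;`-separated, `""` if clean).
#' @export
measure_tether_force <- function(trace, averaging_span = 1.0,
                                 max_tether_age = 30,
                                 settling_margin = 0.2) {
  stopifnot(inherits(trace, "tether_trace"))
  ev <- trace$events
  formed <- trace$tether_formed_at
  if (is.na(formed)) {
    f <- ev$time_s[ev$event == "tether_formed"][1]
    formed <- if (is.na(f)) trace$time[1] else f
  }
  stage <- ev$time_s[ev$event %in% c("stage_toward_cell_contact", "stage_away") &
                       ev$time_s > formed]
  if (!length(stage))
    stop("no stage-manipulation event after tether formation to anchor the plateau window")
  anchor <- min(stage)
  plateau_win <- c(anchor - averaging_span, anchor)
  if (plateau_win[1] < trace$time[1])
    stop("plateau window extends before the start of the trace")

  zr <- locate_zero_reference(trace, settling_margin = settling_margin,
                              averaging_span = averaging_span)
  flags <- zr$qc_flags

  # half-open windows: the sample at a stage-event instant belongs downstream
  in_win <- function(w) trace$time >= w[1] & trace$time < w[2]
  f <- force_trace(trace)
  plateau_mean <- mean(f[in_win(plateau_win)])
  baseline_mean <- mean(f[in_win(zr$window)])

  if (plateau_win[2] - formed > max_tether_age)
    flags <- c(flags, "stale_tether")

  data.frame(cell_id = trace$cell_id, experiment_id = trace$experiment_id,
             phase = trace$phase,
             force_pN = plateau_mean - baseline_mean,
             baseline_pN = baseline_mean,
             plateau_start = plateau_win[1], plateau_end = plateau_win[2],
             baseline_start = zr$window[1], baseline_end = zr$window[2],
             qc_flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

has_flag <- function(qc_flags, flag) {
  vapply(strsplit(ifelse(is.na(qc_flags), "", qc_flags), ";", fixed = TRUE),
         function(fl) flag %in% fl, logical(1))
}

add_flag <- function(qc_flags, flag, where) {
  ifelse(where & !has_flag(qc_flags, flag),
         ifelse(qc_flags == "" | is.na(qc_flags), flag,
                paste(qc_flags, flag, sep = ";")),
         qc_flags)
}

#' Flag double-tether measurements within each cell
#'
#' A bead occasionally pulls two tethers at once, doubling the measured force
#' for the same cell; such readings are excluded. A measurement is flagged
#' `double_tether` when its force lies within `tolerance` (relative) of twice
#' the median of the cell's unflagged forces; flagging is iterated to a fixed
#' point so the median is computed over single-tether readings only. An
#' `annotated_double` column, when present and `TRUE`, flags the measurement
#' unconditionally (e.g., a double tether seen directly by DIC).
#'
#' @param measurements `data.frame` of tether measurements (one or more cells).
#' @param tolerance Relative tolerance around the twofold force (default 0.15).
#' @return The measurements with `qc_flags` updated.
#' @export
flag_double_tethers <- function(measurements, tolerance = 0.15) {
  stopifnot(is.data.frame(measurements),
            all(c("cell_id", "force_pN", "qc_flags") %in% names(measurements)))
  m <- measurements
  if ("annotated_double" %in% names(m))
    m$qc_flags <- add_flag(m$qc_flags, "double_tether",
                           m$annotated_double %in% TRUE)
  for (cell in unique(m$cell_id)) {
    idx <- which(m$cell_id == cell)
    if (length(idx) < 2) next
    repeat {
      dbl <- has_flag(m$qc_flags[idx], "double_tether")
      if (all(dbl)) break
      med <- stats::median(m$force_pN[idx][!dbl])
      hit <- !dbl & abs(m$force_pN[idx] - 2 * med) <= tolerance * 2 * med
      if (!any(hit)) break
      m$qc_flags[idx] <- add_flag(m$qc_flags[idx], "double_tether", hit)
    }
  }
  m
}

#' Tether forces relative to the same-experiment interphase mean
#'
#' Each measurement's force is divided by the mean unflagged interphase force
#' of its own experiment, removing day-to-day trap and cell-batch variation.
#' By construction the interphase values of each experiment average exactly 1.
#'
#' @param measurements `data.frame` of tether measurements with `qc_flags`.
#' @return `data.frame` with columns `cell_id`, `experiment_id`, `phase`,
#'   `relative_force` for unflagged measurements only.
#' @export
relative_forces <- function(measurements) {
  ok <- measurements$qc_flags == "" | is.na(measurements$qc_flags)
  m <- measurements[ok, , drop = FALSE]
  out <- lapply(split(m, m$experiment_id), function(g) {
    inter <- g$force_pN[g$phase == "interphase"]
    if (!length(inter))
      stop("experiment ", g$experiment_id[1],
           " has no unflagged interphase measurement")
    data.frame(cell_id = g$cell_id, experiment_id = g$experiment_id,
               phase = g$phase,
               relative_force = g$force_pN / mean(inter),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
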