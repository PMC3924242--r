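#' Specification for a synthetic tether-pulling trace
#'
#' Describes one optical-trap tether experiment to be simulated by
#' [gen_tether_trace()]: a bead held in a trap of known stiffness is attached
#' to the cell, a membrane tether is pulled, and the stage is later moved
#' toward the cell to relax the tether and record a zero-force reference
#' before moving away again.
#'
#' @param sampling_rate Acquisition rate in Hz. Quadrant-detector recordings
#'   of this kind are typically acquired at 5--20 kHz.
#' @param trap_stiffness Trap stiffness in pN/nm (typically ~0.3 pN/nm).
#' @param true_force True tether force per tether, in pN.
#' @param noise_sd Standard deviation of i.i.d. Gaussian displacement noise,
#'   in nm.
#' @param event_schedule `data.frame` with columns `time_s` and `event`;
#'   allowed events are `"tether_formed"`, `"stage_toward_cell_contact"` and
#'   `"stage_away"`. Times must be strictly increasing and within
#'   `[0, duration]`.
#' @param tether_count Number of tethers pulled by the bead (>= 1). Double
#'   tethers double the plateau force.
#' @param drift_offset Constant displacement offset in nm (detector offset /
#'   slow drift).
#' @param duration Trace duration in seconds.
#' @param cell_id,experiment_id,phase Identifiers carried into the trace.
#' @param seed Integer seed; the same spec and seed regenerate a bit-identical
#'   trace.
#'
#' @return An object of class `trace_gen_spec`.
#' @seealso [gen_tether_trace()]
#' @export
trace_gen_spec <- function(sampling_rate = 5000,
                           trap_stiffness = 0.3,
                           true_force = 20,
                           noise_sd = 10,
                           event_schedule = default_event_schedule(),
                           tether_count = 1L,
                           drift_offset = 0,
                           duration = 20,
                           cell_id = "cell1",
                           experiment_id = "exp1",
                           phase = "interphase",
                           seed = 1L) {
  stopifnot(is.data.frame(event_schedule),
            all(c("time_s", "event") %in% names(event_schedule)))
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (trap_stiffness <= 0) stop("trap_stiffness must be positive")
  if (true_force < 0) stop("true_force must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (tether_count < 1) stop("tether_count must be >= 1")
  if (duration <= 0) stop("duration must be positive")
  ts <- event_schedule$time_s
  if (length(ts) && (any(diff(ts) <= 0) || any(ts < 0) || any(ts > duration)))
    stop("event_schedule times must be strictly increasing within [0, duration]")
  bad <- setdiff(event_schedule$event,
                 c("tether_formed", "stage_toward_cell_contact", "stage_away"))
  if (length(bad)) stop("unknown events: ", paste(bad, collapse = ", "))
  structure(list(sampling_rate = sampling_rate,
                 trap_stiffness = trap_stiffness,
                 true_force = true_force,
                 noise_sd = noise_sd,
                 event_schedule = event_schedule,
                 tether_count = as.integer(tether_count),
                 drift_offset = drift_offset,
                 duration = duration,
                 cell_id = cell_id,
                 experiment_id = experiment_id,
                 phase = match.arg(phase, c("interphase", "metaphase")),
                 seed = as.integer(seed)),
            class = "trace_gen_spec")
}

#' Default stage-event schedule for a synthetic tether trace
#'
#' Tether formed at 1 s, stage moved toward the cell at 12 s (zero-force
#' reference), stage moved away at 14 s.
#' @return `data.frame` with columns `time_s`, `event`.
#' @export
default_event_schedule <- function() {
  data.frame(time_s = c(1, 12, 14),
             event = c("tether_formed", "stage_toward_cell_contact",
                       "stage_away"),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic bead-displacement tether trace
#'
#' Simulates the displacement of a trapped bead during a tether-pulling
#' experiment. While the tether is under tension the mean displacement is
#' `drift_offset + true_force * tether_count / trap_stiffness`; during the
#' zero-reference window (between the toward-cell and away stage events) the
#' tether is relaxed and the mean displacement returns to `drift_offset`.
#' I.i.d. Gaussian noise of SD `noise_sd` is added throughout.
#'
#' @param spec A [trace_gen_spec()].
#' @return A list with components:
#'   * `trace`: a [tether_trace()] object;
#'   * `truth`: list with `force_per_tether_pN`, `apparent_force_pN`
#'     (`true_force * tether_count`), `plateau_nm`, `drift_offset_nm` and
#'     `has_zero_reference`.
#' @export
gen_tether_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_gen_spec"))
  n <- floor(spec$duration * spec$sampling_rate) + 1L
  time <- seq(0, by = 1 / spec$sampling_rate, length.out = n)
  ev <- spec$event_schedule

  formed_at <- ev$time_s[ev$event == "tether_formed"][1]
  toward <- ev$time_s[ev$event == "stage_toward_cell_contact"]
  away <- ev$time_s[ev$event == "stage_away"]

  plateau <- spec$true_force * spec$tether_count / spec$trap_stiffness
  mean_disp <- rep(spec$drift_offset, n)
  if (!is.na(formed_at)) {
    tensioned <- time >= formed_at
    # tension relaxed between each toward-cell event and the following away
    for (tw in toward) {
      aw <- away[away > tw][1]
      if (is.na(aw)) aw <- spec$duration
      tensioned[time >= tw & time < aw] <- FALSE
    }
    mean_disp[tensioned] <- mean_disp[tensioned] + plateau
  }

  disp <- mean_disp
  if (spec$noise_sd > 0) {
    disp <- withr_seed(spec$seed, mean_disp + stats::rnorm(n, 0, spec$noise_sd))
  }

  has_zero <- length(toward) > 0 && any(away > toward[1])
  tr <- tether_trace(time = time, displacement = disp, events = ev,
                     stiffness = spec$trap_stiffness,
                     cell_id = spec$cell_id,
                     experiment_id = spec$experiment_id,
                     phase = spec$phase,
                     tether_formed_at = formed_at,
                     has_zero_reference = has_zero)
  list(trace = tr,
       truth = list(force_per_tether_pN = spec$true_force,
                    apparent_force_pN = spec$true_force * spec$tether_count,
                    plateau_nm = plateau,
                    drift_offset_nm = spec$drift_offset,
                    has_zero_reference = has_zero))
}

# Evaluate expr under a local RNG seed without disturbing the caller's RNG.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
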