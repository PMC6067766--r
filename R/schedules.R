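# Piecewise-stochastic coupling schedules K(t).
#
# A schedule is a contiguous list of segments; within a segment, K is redrawn
# every `redraw_interval` time units from the segment's distribution and held
# constant in between. Used to mimic physiological fluctuation of the coupling
# and the onset/remission of a seizure-like hypersynchronisation episode.

#' Piecewise-constant stochastic coupling schedule
#'
#' @param segments List of segments; each a list with `t_start`, `t_end`,
#'   `type` (`"constant"`, `"uniform"` or `"ramp"`) and parameters: `value`
#'   for constant, `lo`/`hi` for uniform, `mean_start`/`mean_end`/`halfwidth`
#'   for a ramp (uniform draws of fixed half-width whose mean moves linearly
#'   across the segment). Segments must be contiguous, non-overlapping and
#'   start at 0.
#' @param redraw_interval Time between redraws of K inside a segment.
#' @param seed Optional integer seed fixing the whole draw sequence.
#' @return An object of class `coupling_schedule`.
#' @seealso [seizure_schedule_km()], [constant_schedule()],
#'   [realize_schedule()]
#' @export
coupling_schedule <- function(segments, redraw_interval, seed = NULL) {
  check_scalar(redraw_interval, "redraw_interval")
  if (redraw_interval <= 0) abort("redraw_interval must be positive",
                                  "invalid_parameter")
  if (length(segments) == 0) abort("need at least one segment", "invalid_parameter")
  t_prev <- 0
  for (sg in segments) {
    if (!isTRUE(all.equal(sg$t_start, t_prev)))
      abort("segments must be contiguous and start at 0", "invalid_parameter")
    if (sg$t_end <= sg$t_start) abort("empty segment", "invalid_parameter")
    type <- sg$type %||% "constant"
    if (!type %in% c("constant", "uniform", "ramp"))
      abort(paste("unknown segment type:", type), "invalid_parameter")
    lo <- switch(type, constant = sg$value, uniform = sg$lo,
                 ramp = min(sg$mean_start, sg$mean_end) - sg$halfwidth)
    if (is.null(lo) || lo < 0)
      abort("schedule would draw a negative coupling", "invalid_parameter")
    t_prev <- sg$t_end
  }
  structure(list(segments = segments, redraw_interval = redraw_interval,
                 t_end = t_prev, seed = seed),
            class = "coupling_schedule")
}

#' Constant-coupling schedule
#'
#' @param K Coupling strength (nonnegative).
#' @param t_end Duration in time units.
#' @return A [coupling_schedule()] with a single constant segment.
#' @export
constant_schedule <- function(K, t_end) {
  check_scalar(K, "K", lower = 0)
  check_scalar(t_end, "t_end")
  coupling_schedule(list(list(t_start = 0, t_end = t_end, type = "constant",
                              value = K)),
                    redraw_interval = t_end)
}

#' Seizure-like coupling protocol for the Kuramoto experiments
#'
#' Five segments: a sub-critical baseline (K redrawn every `100/scale` time
#' units from Uniform(0.05, 0.15), mean 0.1), a linear ramp of the mean from
#' 0.1 to 0.5, a supercritical plateau with K drawn from
#' Uniform(`plateau[1]`, `plateau[2]`), then a mirrored ramp-down and a
#' return to baseline. At `scale = 1` the first three boundaries are t = 0,
#' 5000, 7500 and the plateau runs to 125000; `scale` compresses every
#' duration and the redraw interval proportionally (the regimes are
#' quasi-stationary, so the claims are insensitive to segment length past
#' equilibration).
#'
#' @param scale Time-compression factor, `>= 1`.
#' @param seed Optional integer seed for the K draws.
#' @param plateau Plateau support; default `c(0.55, 0.65)` (mean 0.6). The
#'   preset `"caption"` uses `c(0.45, 0.55)` (mean 0.5).
#' @return A [coupling_schedule()].
#' @examples
#' sch <- seizure_schedule_km(scale = 50, seed = 1)
#' sch$t_end  # 2650 time units
#' @export
seizure_schedule_km <- function(scale = 1, seed = NULL,
                                plateau = c(0.55, 0.65)) {
  check_scalar(scale, "scale", lower = 1)
  if (identical(plateau, "caption")) plateau <- c(0.45, 0.55)
  plateau_mean <- mean(plateau)
  segs <- list(
    list(t_start = 0,           t_end = 5000 / scale,   type = "uniform",
         lo = 0.05, hi = 0.15),
    list(t_start = 5000 / scale, t_end = 7500 / scale,  type = "ramp",
         mean_start = 0.1, mean_end = 0.5, halfwidth = 0.05),
    list(t_start = 7500 / scale, t_end = 125000 / scale, type = "uniform",
         lo = plateau[1], hi = plateau[2]),
    list(t_start = 125000 / scale, t_end = 127500 / scale, type = "ramp",
         mean_start = plateau_mean, mean_end = 0.1, halfwidth = 0.05),
    list(t_start = 127500 / scale, t_end = 132500 / scale, type = "uniform",
         lo = 0.05, hi = 0.15))
  coupling_schedule(segs, redraw_interval = 100 / scale, seed = seed)
}

#' Seizure-like coupling protocol for the Stuart-Landau experiment
#'
#' A short protocol matching the published Stuart-Landau seizure windows:
#' baseline mean 0.1 on `[0, 90]`, ramp to the plateau over `[90, 110]`,
#' plateau with mean 0.5 (support `[0.45, 0.55]`) on `[110, 170]`, mirrored
#' ramp-down and recovery baseline to `t = 260`. K is redrawn every 10 time
#' units.
#'
#' @param seed Optional integer seed.
#' @return A [coupling_schedule()].
#' @export
seizure_schedule_sl <- function(seed = NULL) {
  segs <- list(
    list(t_start = 0,   t_end = 90,  type = "uniform", lo = 0.05, hi = 0.15),
    list(t_start = 90,  t_end = 110, type = "ramp",
         mean_start = 0.1, mean_end = 0.5, halfwidth = 0.05),
    list(t_start = 110, t_end = 170, type = "uniform", lo = 0.45, hi = 0.55),
    list(t_start = 170, t_end = 190, type = "ramp",
         mean_start = 0.5, mean_end = 0.1, halfwidth = 0.05),
    list(t_start = 190, t_end = 260, type = "uniform", lo = 0.05, hi = 0.15))
  coupling_schedule(segs, redraw_interval = 10, seed = seed)
}

#' Realise a schedule as a per-step coupling vector
#'
#' Draws the stochastic K sequence (seeded by the schedule's seed) and expands
#' it to one value per integrator step; K is held constant within each redraw
#' window and within each step.
#'
#' @param schedule A [coupling_schedule()].
#' @param dt Integrator step.
#' @return Numeric vector of length `round(t_end / dt)`.
#' @export
realize_schedule <- function(schedule, dt) {
  stopifnot(inherits(schedule, "coupling_schedule"))
  check_scalar(dt, "dt")
  if (dt <= 0) abort("dt must be positive", "invalid_parameter")
  draws <- with_seed(schedule$seed, {
    out <- list()
    for (sg in schedule$segments) {
      starts <- seq(sg$t_start, sg$t_end - 1e-9, by = schedule$redraw_interval)
      type <- sg$type %||% "constant"
      k <- switch(type,
        constant = rep(sg$value, length(starts)),
        uniform  = stats::runif(length(starts), sg$lo, sg$hi),
        ramp     = {
          frac <- (starts - sg$t_start) / (sg$t_end - sg$t_start)
          mid <- sg$mean_start + frac * (sg$mean_end - sg$mean_start)
          stats::runif(length(starts), mid - sg$halfwidth, mid + sg$halfwidth)
        })
      out[[length(out) + 1L]] <- list(starts = starts, k = k)
    }
    out
  })
  window_start <- unlist(lapply(draws, `[[`, "starts"))
  window_k <- unlist(lapply(draws, `[[`, "k"))
  n_steps <- round(schedule$t_end / dt)
  t_step <- (seq_len(n_steps) - 1L) * dt
  window_k[findInterval(t_step, window_start)]
}

#' Segment boundaries of a schedule
#'
#' @param schedule A [coupling_schedule()].
#' @return Numeric vector of boundary times (including 0 and `t_end`).
#' @export
schedule_boundaries <- function(schedule) {
  c(0, vapply(schedule$segments, `[[`, numeric(1), "t_end"))
}
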