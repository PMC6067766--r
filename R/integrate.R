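# Time integration front-ends over the compiled RK4 cores, and trace
# summaries. Integration is fixed-step classical RK4 (default dt = 0.01): the
# control terms are instantaneous functions of the state and the coupling
# protocols are piecewise constant, so adaptive stepping would complicate
# schedule alignment for no accuracy gain.

#' Random initial phases
#'
#' Uniform draws on `[0, 2*pi)`, the initial condition used throughout the
#' suppression and seizure experiments.
#'
#' @param n Number of oscillators.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
random_phases <- function(n, seed = NULL) {
  n <- check_count(n, "n")
  with_seed(seed, stats::runif(n, 0, 2 * pi))
}

# shared preparation of the control arguments passed to the C++ cores
prepare_control <- function(layout, omega, n) {
  if (is.null(layout))
    return(list(control = 0L, electrodes = integer(0),
                E = matrix(0, 0, 0), ig = matrix(0, 0, 0)))
  stopifnot(inherits(layout, "electrode_layout"))
  if (nrow(layout$distances) != n)
    abort("electrode layout does not match network size", "dimension_mismatch")
  el <- layout$electrode_nodes
  gap <- outer(omega[el], omega[el], "-")
  diag(gap) <- Inf
  if (any(abs(gap) < EPS_RES)) {
    kk <- which(abs(gap) < EPS_RES, arr.ind = TRUE)[1, ]
    abort(sprintf("near-resonant electrode pair (%d, %d)", el[kk[1]], el[kk[2]]),
          "near_resonance")
  }
  ig <- 1 / gap
  diag(ig) <- 0
  list(control = 1L, electrodes = el - 1L,
       E = layout$c_s * exp(-2 * layout$distances), ig = ig)
}

new_sim_trace <- function(raw, dt, model, meta) {
  tr <- list(times = as.vector(raw$times), R_series = as.vector(raw$R),
             K_series = as.vector(raw$K), dt = dt, model = model, meta = meta)
  tr$t_end <- tr$times[length(tr$times)]
  if (model == "km") {
    tr$Psi_series <- as.vector(raw$Psi)
    tr$final_phases <- as.vector(raw$final_phases)
    if (!is.null(raw$phases)) tr$phases <- raw$phases
  } else {
    tr$total_signal <- as.vector(raw$total_signal)
    tr$final_z <- as.vector(raw$final_z)
    if (!is.null(raw$z)) {
      tr$z <- raw$z
      tr$phases <- Arg(raw$z) %% (2 * pi)
    }
  }
  structure(tr, class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("<sim_trace> %s model, t in [0, %g], dt = %g, %d records\n",
              x$model, x$t_end, x$dt, length(x$times)))
  cat(sprintf("  final R = %.3f, mean R (2nd half) = %.3f\n",
              x$R_series[length(x$R_series)], mean_R(x)))
  invisible(x)
}

#' Integrate the (optionally controlled) Kuramoto model
#'
#' Fixed-step RK4 integration of the networked or mean-field Kuramoto model,
#' optionally with the operational Hamiltonian control (an
#' [electrode_layout()]) or the Proportional-Differential Feedback baseline
#' (a [pdf_config()]). The coupling is either a constant `K` or a
#' [coupling_schedule()] held piecewise constant across steps. Phases are
#' wrapped to `[0, 2*pi)` after every step; the order parameter is recorded
#' every `record_every` steps.
#'
#' @param state0 Initial phase vector.
#' @param omega Natural frequencies.
#' @param net An [oscillator_network()], or `NULL` with `meanfield = TRUE`.
#' @param K Constant coupling strength (give `K` and `t_end`, or `schedule`).
#' @param schedule A [coupling_schedule()].
#' @param t_end Run length in time units (required with constant `K`).
#' @param dt Integrator step, default 0.01.
#' @param record_every Record stride in steps, default 10.
#' @param control Optional [electrode_layout()] switching on the operational
#'   Hamiltonian control.
#' @param control_mode `"global-R"` (as printed) or `"sampled-R"` (order
#'   parameter estimated from electrode phases only).
#' @param pdf Optional [pdf_config()] switching on the PDF baseline control
#'   (mutually exclusive with `control`).
#' @param meanfield Use the mean-field coupling term instead of the networked
#'   sum; defaults to `TRUE` when no network is given.
#' @param record_phases Keep the full phase trajectory (records x N matrix).
#' @return A `sim_trace` with `times`, `R_series`, `Psi_series`, `K_series`,
#'   `final_phases`, and optionally `phases`.
#' @examples
#' om <- sample_frequencies(10, seed = 1)
#' tr <- integrate_km(random_phases(10, seed = 2), om, K = 0.5, t_end = 20,
#'                    meanfield = TRUE)
#' mean_R(tr)
#' @export
integrate_km <- function(state0, omega, net = NULL, K = NULL, schedule = NULL,
                         t_end = NULL, dt = 0.01, record_every = 10L,
                         control = NULL,
                         control_mode = c("global-R", "sampled-R"),
                         pdf = NULL, meanfield = is.null(net),
                         record_phases = FALSE) {
  control_mode <- match.arg(control_mode)
  n <- length(state0)
  check_frequencies(omega, n)
  if (!meanfield && is.null(net))
    abort("give a network or set meanfield = TRUE", "invalid_parameter")
  if (!is.null(net) && net$n_nodes != n)
    abort("network size does not match state", "dimension_mismatch")
  if (!is.null(control) && !is.null(pdf))
    abort("control and pdf are mutually exclusive", "invalid_parameter")
  if (is.null(schedule)) {
    if (is.null(K) || is.null(t_end))
      abort("give either a schedule or both K and t_end", "invalid_parameter")
    schedule <- constant_schedule(K, t_end)
  }
  K_steps <- realize_schedule(schedule, dt)
  ctl <- prepare_control(control, omega, n)
  measured <- integer(0); stimulated <- integer(0); P <- 0; D <- 0
  if (!is.null(pdf)) {
    stopifnot(inherits(pdf, "pdf_config"))
    if (pdf$n_total != n)
      abort("pdf config does not match network size", "dimension_mismatch")
    ctl$control <- 2L
    measured <- pdf$measured - 1L
    stimulated <- pdf$stimulated - 1L
    P <- pdf$P; D <- pdf$D
  }
  raw <- km_integrate_cpp(state0, as.numeric(omega),
                          if (is.null(net)) matrix(0, 0, 0) else net$adjacency,
                          meanfield, K_steps, dt,
                          as.integer(record_every), ctl$control,
                          ctl$electrodes, ctl$E, ctl$ig,
                          if (is.null(control)) 0 else control$gamma,
                          control_mode == "sampled-R",
                          measured, stimulated, P, D, record_phases)
  new_sim_trace(raw, dt, "km",
                meta = list(n = n, meanfield = meanfield,
                            control = if (!is.null(control)) "hamiltonian"
                                      else if (!is.null(pdf)) "pdf" else "none",
                            control_mode = control_mode,
                            schedule_seed = schedule$seed))
}

#' Time-averaged order parameter of a trace
#'
#' Average of the recorded `R` after discarding an initial transient. The
#' default transient is the first half of the run.
#'
#' @param trace A `sim_trace`.
#' @param t_transient Discard records with `time < t_transient`; default
#'   `t_end / 2`.
#' @return Scalar in `[0, 1]`.
#' @export
mean_R <- function(trace, t_transient = NULL) {
  stopifnot(inherits(trace, "sim_trace"))
  t_transient <- t_transient %||% (trace$t_end / 2)
  if (t_transient >= trace$t_end)
    abort("transient discards the whole run", "invalid_parameter")
  keep <- trace$times >= t_transient
  if (!any(keep)) abort("empty averaging window", "invalid_parameter")
  mean(trace$R_series[keep])
}

#' Estimate the critical coupling of the synchronisation onset
#'
#' Sweeps a K grid; for each K the time-averaged order parameter is averaged
#' over `reps` random initial conditions (frequencies held fixed). The onset
#' is the threshold crossing of the ensemble mean, located by linear
#' interpolation between the bracketing grid points.
#'
#' @param net An [oscillator_network()].
#' @param omega Natural frequencies.
#' @param K_grid Increasing coupling grid spanning the transition.
#' @param reps Initial-condition repetitions per grid point.
#' @param threshold Order-parameter level defining the onset, default 0.5.
#' @param seed Integer seed for the initial conditions.
#' @param t_end,dt,record_every Integration controls per run.
#' @param t_transient Transient discarded before averaging R (default half).
#' @return Scalar estimate of the critical coupling, with the per-grid-point
#'   ensemble means in attribute `"profile"`.
#' @export
critical_coupling <- function(net, omega, K_grid, reps = 10, threshold = 0.5,
                              seed = NULL, t_end = 200, dt = 0.01,
                              record_every = 20L, t_transient = NULL) {
  if (is.unsorted(K_grid, strictly = TRUE))
    abort("K_grid must be strictly increasing", "invalid_parameter")
  reps <- check_count(reps, "reps")
  prof <- vapply(seq_along(K_grid), function(i) {
    mean(vapply(seq_len(reps), function(r) {
      ic <- random_phases(net$n_nodes,
                          seed = if (is.null(seed)) NULL else seed + 1000L * r)
      mean_R(integrate_km(ic, omega, net = net, K = K_grid[i], t_end = t_end,
                          dt = dt, record_every = record_every),
             t_transient)
    }, numeric(1)))
  }, numeric(1))
  above <- which(prof > threshold)
  if (length(above) == 0 || above[1] == 1L)
    abort("threshold crossing not bracketed by K_grid", "not_bracketed")
  i <- above[1]
  kc <- K_grid[i - 1] + (threshold - prof[i - 1]) *
    (K_grid[i] - K_grid[i - 1]) / (prof[i] - prof[i - 1])
  structure(kc, profile = stats::setNames(prof, K_grid))
}
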