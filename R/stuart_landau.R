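# Stuart-Landau (supercritical Hopf normal form) network model. Each unit
# carries a complex amplitude z_k = rho_k exp(i phi_k); uncoupled units relax
# onto the unit-radius limit cycle and rotate at their natural frequency. In
# the weak-coupling, near-equal-amplitude regime the phase dynamics reduce to
# the Kuramoto model, which is what makes the phase-model control transfer.

#' Stuart-Landau network right-hand side
#'
#' `dz_k/dt = (1 + i omega_k - |z_k|^2) z_k + Z_k` with diffusive-free linear
#' coupling `Z_k = (K/N) sum_j A_kj z_j` (or the plain average over all units
#' when `meanfield = TRUE`, the all-to-all form used by the controlled model).
#'
#' @param z Complex state vector.
#' @param omega Natural frequencies.
#' @param K Coupling strength.
#' @param net An [oscillator_network()] (ignored when `meanfield = TRUE`).
#' @param meanfield Couple through `(K/N) sum_j z_j` for every node.
#' @return Complex velocity vector.
#' @export
sl_rhs <- function(z, omega, K, net = NULL, meanfield = is.null(net)) {
  n <- length(z)
  if (length(omega) != n) abort("dimension mismatch", "dimension_mismatch")
  coup <- if (meanfield) rep((K / n) * sum(z), n)
          else {
            if (net$n_nodes != n) abort("dimension mismatch", "dimension_mismatch")
            (K / n) * as.vector(net$adjacency %*% z)
          }
  as.vector((1 + 1i * omega - Mod(z)^2) * z + coup)
}

#' Theoretical Stuart-Landau control term
#'
#' The all-node control drive `Zctrl_k = -i (K/4) Rt_k Z`, where `Rt_k` is the
#' frequency-weighted local order parameter of the phases `Arg(z)` and
#' `Z = (K/N) sum_j z_j` the mean-field signal. Adding it to the mean-field
#' Stuart-Landau dynamics yields, in the near-equal-amplitude regime, the
#' controlled Kuramoto phase dynamics.
#'
#' @inheritParams sl_rhs
#' @param k Node index, or `NULL` for the full vector.
#' @return Complex control term (scalar or length-N vector).
#' @export
sl_control_term <- function(z, omega, K, k = NULL) {
  n <- length(z)
  check_frequencies(omega, n)
  phases <- Arg(z)
  rt <- Mod(modified_order_all(phases, omega))
  Z <- (K / n) * sum(z)
  ctrl <- as.vector(-1i * (K / 4) * rt * Z)
  if (is.null(k)) ctrl else ctrl[[check_count(k, "k")]]
}

#' Operationally controlled Stuart-Landau right-hand side
#'
#' The networked Stuart-Landau velocities plus a phase-torque injection of the
#' M-electrode stimulation field: the scalar control of
#' [operational_control()] (computed on the phases `Arg(z)`) is spread through
#' the `exp(-2 r)` field and enters each node multiplicatively as
#' `-i S_k z_k`, so that in the equal-amplitude limit the induced phase
#' velocity gains exactly `S_k`, matching the controlled Kuramoto model.
#'
#' @inheritParams sl_rhs
#' @inheritParams operational_control
#' @return Complex velocity vector.
#' @export
sl_operational_controlled_rhs <- function(z, omega, K, net = NULL, layout,
                                          mode = c("global-R", "sampled-R"),
                                          meanfield = is.null(net)) {
  mode <- match.arg(mode)
  phases <- Arg(z)
  hh <- operational_control(phases, omega, K, layout, mode)
  s <- stimulation_field(hh, layout)
  sl_rhs(z, omega, K, net, meanfield) - 1i * s * z
}

#' Total real signal of a Stuart-Landau state
#'
#' `sum_k Re(z_k) = sum_k rho_k cos(phi_k)` — the quantity whose envelope
#' grows when the oscillators synchronise and their signals add coherently.
#'
#' @param z Complex state vector, or a Stuart-Landau `sim_trace` (in which
#'   case the recorded time series is returned).
#' @return Scalar, or the recorded numeric series for a trace.
#' @export
total_signal <- function(z) {
  if (inherits(z, "sim_trace")) {
    if (z$model != "sl") abort("trace is not a Stuart-Landau run", "invalid_parameter")
    return(z$total_signal)
  }
  sum(Re(z))
}

#' Random initial Stuart-Landau state on the unit circle
#'
#' @param n Number of oscillators.
#' @param seed Optional integer seed.
#' @return Complex vector `exp(i phi)` with uniform random phases.
#' @export
random_unit_state <- function(n, seed = NULL) {
  exp(1i * random_phases(n, seed))
}

#' Integrate the (optionally controlled) Stuart-Landau network
#'
#' Fixed-step RK4 on the complex state (real/imaginary parts advance
#' together). Control options: `"operational"` composes the M-electrode
#' control and the stimulation field exactly as in the Kuramoto case and
#' injects it as a phase torque `-i S_k z_k`; `"theoretical"` adds the
#' all-node drive of [sl_control_term()] scaled by `gamma/4` in place of the
#' plain `K/4` factor when a layout gain is supplied.
#'
#' @param state0 Complex initial state.
#' @param omega Natural frequencies.
#' @param net An [oscillator_network()], or `NULL` with `meanfield = TRUE`.
#' @param K,schedule,t_end,dt,record_every As in [integrate_km()].
#' @param control Optional [electrode_layout()].
#' @param control_form `"operational"` (default) or `"theoretical"`.
#' @param control_mode `"global-R"` or `"sampled-R"` (operational form only).
#' @param meanfield Couple through the plain average rather than `net`.
#' @param record_states Keep the full complex trajectory.
#' @return A `sim_trace` with `times`, `R_series`, `total_signal`,
#'   `K_series`, `final_z` and optionally `z` and `phases`.
#' @export
integrate_sl <- function(state0, omega, net = NULL, K = NULL, schedule = NULL,
                         t_end = NULL, dt = 0.01, record_every = 10L,
                         control = NULL,
                         control_form = c("operational", "theoretical"),
                         control_mode = c("global-R", "sampled-R"),
                         meanfield = is.null(net), record_states = FALSE) {
  control_form <- match.arg(control_form)
  control_mode <- match.arg(control_mode)
  n <- length(state0)
  check_frequencies(omega, n)
  if (!meanfield && is.null(net))
    abort("give a network or set meanfield = TRUE", "invalid_parameter")
  if (is.null(schedule)) {
    if (is.null(K) || is.null(t_end))
      abort("give either a schedule or both K and t_end", "invalid_parameter")
    schedule <- constant_schedule(K, t_end)
  }
  K_steps <- realize_schedule(schedule, dt)
  ig_full <- matrix(0, 0, 0)
  if (is.null(control)) {
    ctl <- list(control = 0L, electrodes = integer(0),
                E = matrix(0, 0, 0), ig = matrix(0, 0, 0))
    gamma <- 0
  } else if (control_form == "operational") {
    ctl <- prepare_control(control, omega, n)
    gamma <- control$gamma
  } else {
    check_pair_resonances(omega)
    gap <- outer(omega, omega, "-")
    diag(gap) <- Inf
    ig_full <- 1 / gap
    diag(ig_full) <- 0
    ctl <- list(control = 2L, electrodes = integer(0),
                E = matrix(0, 0, 0), ig = matrix(0, 0, 0))
    gamma <- control$gamma
  }
  raw <- sl_integrate_cpp(state0, as.numeric(omega),
                          if (is.null(net)) matrix(0, 0, 0) else net$adjacency,
                          meanfield, K_steps, dt, as.integer(record_every),
                          ctl$control, ctl$electrodes, ctl$E, ctl$ig, ig_full,
                          gamma, control_mode == "sampled-R", record_states)
  new_sim_trace(raw, dt, "sl",
                meta = list(n = n, meanfield = meanfield,
                            control = if (is.null(control)) "none" else control_form,
                            control_mode = control_mode,
                            schedule_seed = schedule$seed))
}

#' Phase discrepancy between Stuart-Landau and Kuramoto runs
#'
#' Quantifies the quality of the Kuramoto reduction: the maximum over time of
#' the node-mean circular distance between the recorded Stuart-Landau phases
#' and the Kuramoto phases of a matched run (same frequencies, coupling,
#' network and initial phases; Stuart-Landau initialised on the unit circle).
#' Shrinks as the coupling weakens.
#'
#' @param trace_sl Stuart-Landau `sim_trace` recorded with
#'   `record_states = TRUE`.
#' @param trace_km Kuramoto `sim_trace` recorded with `record_phases = TRUE`.
#' @return Scalar discrepancy in radians.
#' @export
km_reduction_error <- function(trace_sl, trace_km) {
  stopifnot(inherits(trace_sl, "sim_trace"), inherits(trace_km, "sim_trace"))
  if (trace_sl$model != "sl" || trace_km$model != "km")
    abort("need one Stuart-Landau and one Kuramoto trace", "invalid_parameter")
  if (is.null(trace_sl$phases) || is.null(trace_km$phases))
    abort("both traces must carry recorded phases", "invalid_parameter")
  if (!isTRUE(all.equal(trace_sl$times, trace_km$times)) ||
      !identical(dim(trace_sl$phases), dim(trace_km$phases)))
    abort("traces are not matched (times/dimensions differ)", "config_mismatch")
  per_time <- rowMeans(circ_dist(trace_sl$phases, trace_km$phases))
  max(per_time)
}
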