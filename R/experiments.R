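# Experiment drivers: suppression phase diagrams over (M, gamma/4) and
# (n2, P), iso-desynchronisation curves, and the seizure-protocol runs.
# Everything is seeded and reproducible; controlled-vs-uncontrolled
# comparisons reuse identical schedule draws and initial conditions
# (common random numbers).

new_sweep_result <- function(counts, strengths, mean_R, sd_R, reps, meta) {
  structure(list(counts = counts, strengths = strengths, mean_R = mean_R,
                 sd_R = sd_R, reps = reps, meta = meta),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s: %d counts x %d strengths, %d reps/cell\n",
              x$meta$method, length(x$counts), length(x$strengths), x$reps))
  m <- round(x$mean_R, 2)
  dimnames(m) <- list(count = x$counts, strength = x$strengths)
  print(m)
  invisible(x)
}

#' Suppression phase diagram of the operational Hamiltonian control
#'
#' For every pair (`M` electrodes, strength `gamma/4`) runs the controlled
#' all-to-all Kuramoto model from `reps` fresh random initial conditions
#' (frequencies drawn once per sweep) and records the ensemble mean and sd of
#' the post-transient time-averaged order parameter. Electrode positions are
#' re-drawn uniformly at random each repetition. The all-to-all benchmark is
#' spatially abstract — electrode layout is immaterial there — so the sweep
#' defaults to `distance_mode = "isolated"` (each electrode drives only its
#' own node); pass `"ring"` to add the spatially spreading field of the
#' embedded experiments.
#'
#' @param M_grid Electrode counts (0 allowed: uncontrolled column).
#' @param gamma_over_4_grid Control strengths `gamma/4`.
#' @param n Number of oscillators, default 100.
#' @param K Coupling strength, default 0.5.
#' @param freq_sd Frequency-distribution sd (mean 1), default 0.1.
#' @param reps Repetitions per cell, default 50.
#' @param seed Master seed.
#' @param t_end,dt,record_every Integration controls per run.
#' @param resample_frequencies Draw fresh frequencies every repetition instead
#'   of once per sweep (default `FALSE`, matching the published averaging over
#'   initial conditions only).
#' @param distance_mode Electrode field geometry, see [place_electrodes()];
#'   default `"isolated"`.
#' @return A `sweep_result` with `counts = M_grid` and
#'   `strengths = gamma_over_4_grid`.
#' @export
sweep_hamiltonian <- function(M_grid, gamma_over_4_grid, n = 100, K = 0.5,
                              freq_sd = 0.1, reps = 50, seed = NULL,
                              t_end = 200, dt = 0.01, record_every = 20L,
                              resample_frequencies = FALSE,
                              distance_mode = "isolated") {
  if (length(M_grid) == 0 || length(gamma_over_4_grid) == 0)
    abort("empty sweep grid", "invalid_parameter")
  omega <- sample_frequencies(n, 1, freq_sd,
                              seed = derive_seeds(seed, "frequencies"))
  mean_R <- sd_R <- matrix(NA_real_, length(M_grid), length(gamma_over_4_grid))
  for (mi in seq_along(M_grid)) {
    for (gi in seq_along(gamma_over_4_grid)) {
      vals <- vapply(seq_len(reps), function(r) {
        # seeds indexed by count and repetition only: strengths share common
        # random numbers, and the M = 0 column equals the uncontrolled system
        rs <- derive_seeds(seed, sprintf("cell_%d_rep_%d", mi, r))
        om <- if (resample_frequencies)
          sample_frequencies(n, 1, freq_sd, seed = rs + 3L) else omega
        ic <- random_phases(n, seed = rs)
        lay <- if (M_grid[mi] > 0)
          place_electrodes(all_to_all(n), M_grid[mi], seed = rs + 1L,
                           distance_mode = distance_mode,
                           gamma_over_4 = gamma_over_4_grid[gi])
        else NULL
        mean_R(integrate_km(ic, om, K = K, t_end = t_end, dt = dt,
                            record_every = record_every, control = lay,
                            meanfield = TRUE))
      }, numeric(1))
      mean_R[mi, gi] <- mean(vals)
      sd_R[mi, gi] <- stats::sd(vals)
    }
  }
  new_sweep_result(M_grid, gamma_over_4_grid, mean_R, sd_R, reps,
                   meta = list(method = "hamiltonian", n = n, K = K,
                               freq_sd = freq_sd, t_end = t_end, dt = dt,
                               seed = seed))
}

#' Suppression phase diagram of the PDF baseline
#'
#' As [sweep_hamiltonian()] but with Proportional-Differential Feedback:
#' `n2` stimulated oscillators and proportional gain `P` are swept at fixed
#' derivative gain `D`; the strength axis of the result is `P + D`. The
#' published benchmark uses a narrower frequency distribution
#' (`freq_sd = 0.01`) than the Hamiltonian sweep.
#'
#' @param n2_grid Stimulated-oscillator counts.
#' @param P_grid Proportional gains.
#' @param D Derivative gain, default 10.
#' @inheritParams sweep_hamiltonian
#' @return A `sweep_result` with `counts = n2_grid` and
#'   `strengths = P_grid + D`.
#' @export
sweep_pdf <- function(n2_grid, P_grid, D = 10, n = 100, K = 0.5,
                      freq_sd = 0.01, reps = 25, seed = NULL,
                      t_end = 200, dt = 0.01, record_every = 20L,
                      resample_frequencies = FALSE) {
  if (length(n2_grid) == 0 || length(P_grid) == 0)
    abort("empty sweep grid", "invalid_parameter")
  omega <- sample_frequencies(n, 1, freq_sd,
                              seed = derive_seeds(seed, "frequencies"))
  mean_R <- sd_R <- matrix(NA_real_, length(n2_grid), length(P_grid))
  for (mi in seq_along(n2_grid)) {
    for (gi in seq_along(P_grid)) {
      vals <- vapply(seq_len(reps), function(r) {
        rs <- derive_seeds(seed, sprintf("pdf_%d_rep_%d", mi, r))
        om <- if (resample_frequencies)
          sample_frequencies(n, 1, freq_sd, seed = rs + 3L) else omega
        ic <- random_phases(n, seed = rs)
        cfg <- pdf_config(n, n2_grid[mi], P = P_grid[gi], D = D,
                          seed = rs + 2L)
        mean_R(integrate_km(ic, om, K = K, t_end = t_end, dt = dt,
                            record_every = record_every, pdf = cfg,
                            meanfield = TRUE))
      }, numeric(1))
      mean_R[mi, gi] <- mean(vals)
      sd_R[mi, gi] <- stats::sd(vals)
    }
  }
  new_sweep_result(n2_grid, P_grid + D, mean_R, sd_R, reps,
                   meta = list(method = "pdf", n = n, K = K, D = D,
                               freq_sd = freq_sd, t_end = t_end, dt = dt,
                               seed = seed))
}

#' Iso-desynchronisation curve of a sweep
#'
#' For each controller count, the smallest swept strength whose ensemble-mean
#' order parameter is at or below the level `r`; `NA` where no swept strength
#' achieves it.
#'
#' @param sweep A `sweep_result`.
#' @param r Desynchronisation level in `(0, 1]`.
#' @return `data.frame` with columns `count` and `strength`.
#' @export
iso_desync_curve <- function(sweep, r) {
  stopifnot(inherits(sweep, "sweep_result"))
  check_scalar(r, "r", 0, 1)
  strength <- apply(sweep$mean_R, 1, function(row) {
    ok <- which(row <= r)
    if (length(ok) == 0) NA_real_ else min(sweep$strengths[ok])
  })
  data.frame(count = sweep$counts, strength = strength)
}

#' Seizure-protocol experiment
#'
#' Runs the seizure coupling schedule on `N` oscillators coupled by a
#' Newman-Watts network, uncontrolled and controlled (`M` electrodes, gain
#' `gamma/4`), with common random numbers: each repetition reuses the same
#' schedule realisation and initial condition for both runs. For the Kuramoto
#' model the tracked observable is the order parameter `R(t)`; for the
#' Stuart-Landau model it is `R(t)` together with the total real signal.
#'
#' @param model `"km"` or `"sl"`.
#' @param n Number of oscillators, default 100.
#' @param p Newman-Watts shortcut probability, default 0.85.
#' @param k_half Ring-backbone half coordination number, default 2.
#' @param M Number of electrodes, default 20.
#' @param gamma_over_4 Control strength, default 4.25.
#' @param reps Number of independent realisations to average, default 20.
#' @param scale Time compression of the Kuramoto schedule, default 50
#'   (ignored for `"sl"`, whose protocol is short already).
#' @param seed Master seed.
#' @param dt,record_every Integration controls.
#' @param control_mode Passed to the controlled runs.
#' @param plateau Plateau support passed to [seizure_schedule_km()].
#' @return A list of class `seizure_experiment`: `times`, rep-averaged series
#'   `R_unc`/`R_ctl` (and `total_unc`/`total_ctl` envelopes for `"sl"`), the
#'   schedule `boundaries`, and a per-segment `summary` data frame whose
#'   `unc`/`ctl` columns average the observable over the final two-thirds of
#'   each segment.
#' @export
run_seizure_experiment <- function(model = c("km", "sl"), n = 100, p = 0.85,
                                   k_half = 2, M = 20, gamma_over_4 = 4.25,
                                   reps = 20, scale = 50, seed = NULL,
                                   dt = 0.01, record_every = 50L,
                                   control_mode = "global-R",
                                   plateau = c(0.55, 0.65)) {
  model <- match.arg(model)
  net <- newman_watts(n, p, k_half, seed = derive_seeds(seed, "network"))
  omega <- sample_frequencies(n, 1, 0.1, seed = derive_seeds(seed, "frequencies"))
  proto <- if (model == "km") seizure_schedule_km(scale, plateau = plateau)
           else seizure_schedule_sl()
  runs_unc <- list(); runs_ctl <- list()
  for (r in seq_len(reps)) {
    rs <- derive_seeds(seed, paste0("rep_", r))
    sch <- proto
    sch$seed <- rs + 1L
    lay <- place_electrodes(net, M, seed = rs + 2L,
                            gamma_over_4 = gamma_over_4)
    if (model == "km") {
      ic <- random_phases(n, seed = rs)
      runs_unc[[r]] <- integrate_km(ic, omega, net = net, schedule = sch,
                                    dt = dt, record_every = record_every)
      runs_ctl[[r]] <- integrate_km(ic, omega, net = net, schedule = sch,
                                    dt = dt, record_every = record_every,
                                    control = lay, control_mode = control_mode)
    } else {
      ic <- random_unit_state(n, seed = rs)
      runs_unc[[r]] <- integrate_sl(ic, omega, net = net, schedule = sch,
                                    dt = dt, record_every = record_every)
      runs_ctl[[r]] <- integrate_sl(ic, omega, net = net, schedule = sch,
                                    dt = dt, record_every = record_every,
                                    control = lay, control_mode = control_mode)
    }
  }
  times <- runs_unc[[1]]$times
  avg <- function(runs, field, abs_val = FALSE) {
    m <- vapply(runs, function(tr) {
      x <- tr[[field]]
      if (abs_val) abs(x) else x
    }, numeric(length(times)))
    rowMeans(m)
  }
  out <- list(model = model, times = times,
              R_unc = avg(runs_unc, "R_series"),
              R_ctl = avg(runs_ctl, "R_series"),
              boundaries = schedule_boundaries(proto),
              reps = reps, seed = seed,
              config = list(n = n, p = p, k_half = k_half, M = M,
                            gamma_over_4 = gamma_over_4, scale = scale,
                            dt = dt))
  if (model == "sl") {
    out$total_unc <- avg(runs_unc, "total_signal", abs_val = TRUE)
    out$total_ctl <- avg(runs_ctl, "total_signal", abs_val = TRUE)
  }
  b <- out$boundaries
  seg_names <- c("baseline", "ramp_up", "plateau", "ramp_down", "recovery")
  summarise <- function(series) {
    vapply(seq_len(length(b) - 1L), function(i) {
      t0 <- b[i] + (b[i + 1] - b[i]) / 3    # settle: keep final two-thirds
      mean(series[times >= t0 & times <= b[i + 1]])
    }, numeric(1))
  }
  measure <- if (model == "km") "R" else "abs_total_signal"
  unc_series <- if (model == "km") out$R_unc else out$total_unc
  ctl_series <- if (model == "km") out$R_ctl else out$total_ctl
  out$summary <- data.frame(segment = seg_names[seq_len(length(b) - 1L)],
                            t_start = b[-length(b)], t_end = b[-1],
                            measure = measure,
                            unc = summarise(unc_series),
                            ctl = summarise(ctl_series))
  class(out) <- "seizure_experiment"
  out
}

#' @export
print.seizure_experiment <- function(x, ...) {
  cat(sprintf("<seizure_experiment> %s model, %d reps, t_end = %g\n",
              x$model, x$reps, max(x$times)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Plot a seizure experiment
#'
#' Base-graphics time course of the tracked observable for the uncontrolled
#' and controlled ensembles, with segment boundaries marked.
#'
#' @param x A `seizure_experiment`.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.seizure_experiment <- function(x, ...) {
  if (x$model == "km") {
    plot(x$times, x$R_unc, type = "l", col = "steelblue", ylim = c(0, 1),
         xlab = "time", ylab = "R", ...)
    graphics::lines(x$times, x$R_ctl, col = "firebrick")
  } else {
    ylim <- range(0, x$total_unc, x$total_ctl)
    plot(x$times, x$total_unc, type = "l", col = "steelblue", ylim = ylim,
         xlab = "time", ylab = "|total signal|", ...)
    graphics::lines(x$times, x$total_ctl, col = "firebrick")
  }
  graphics::abline(v = x$boundaries, lty = 3, col = "grey50")
  graphics::legend("topleft", c("uncontrolled", "controlled"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
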