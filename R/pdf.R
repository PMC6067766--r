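# Proportional-Differential Feedback (PDF) baseline: the gold-standard
# closed-loop desynchronisation scheme the Hamiltonian control is benchmarked
# against. One subpopulation of n1 oscillators is measured, the remaining n2
# are stimulated with a signal proportional to the measured mean field X(t)
# (gain P) and to its derivative (gain D). The injected force F = -(P*X +
# D*dX/dt) enters the phase model through the standard phase-sensitivity
# function Z(phi) = -sin(phi) of a near-harmonic oscillator driven in its
# x-variable, giving the additive term +(P*X + D*dX/dt) * sin(phi_k) on each
# stimulated node (the opposite overall sign amplifies the collective mode
# instead of quenching it). The derivative is computed analytically from the
# uncontrolled velocities so the right-hand side remains a well-defined ODE.

#' PDF control configuration
#'
#' Splits `n` oscillators into `n1 = n - n2` measured and `n2` stimulated
#' units. Membership is assigned by index after a seeded shuffle, so the two
#' groups are disjoint and reproducible.
#'
#' @param n Total number of oscillators.
#' @param n2 Number of stimulated oscillators (`0 <= n2 <= n - 1`).
#' @param P Proportional gain, `>= 0`.
#' @param D Derivative gain, `>= 0`.
#' @param seed Optional integer seed for the group shuffle; `NULL` keeps the
#'   natural order (first `n1` measured, last `n2` stimulated).
#' @return An object of class `pdf_config` with fields `measured`,
#'   `stimulated`, `P`, `D`, `n_total`.
#' @export
pdf_config <- function(n, n2, P, D = 0, seed = NULL) {
  n <- check_count(n, "n", lower = 2L)
  n2 <- check_count(n2, "n2", lower = 0L)
  if (n2 > n - 1L)
    abort("need at least one measured oscillator (n2 <= n - 1)",
          "invalid_parameter")
  check_scalar(P, "P", lower = 0)
  check_scalar(D, "D", lower = 0)
  ord <- if (is.null(seed)) seq_len(n) else with_seed(seed, sample.int(n))
  n1 <- n - n2
  structure(list(n_total = n, n1 = n1, n2 = n2, P = P, D = D,
                 measured = sort(ord[seq_len(n1)]),
                 stimulated = sort(ord[n1 + seq_len(n2)])),
            class = "pdf_config")
}

#' @export
print.pdf_config <- function(x, ...) {
  cat(sprintf("<pdf_config> n1 = %d measured, n2 = %d stimulated, P = %g, D = %g\n",
              x$n1, x$n2, x$P, x$D))
  invisible(x)
}

#' PDF-controlled Kuramoto right-hand side
#'
#' Uncontrolled phase velocities plus the feedback term: with measured mean
#' field `X = (1/n1) sum cos(phi_j)` and analytic derivative
#' `dX/dt = -(1/n1) sum sin(phi_j) * dphi_j/dt` (uncontrolled velocities),
#' every stimulated node `k` receives the injected force `-(P*X + D*dX/dt)`
#' through the phase sensitivity `-sin(phi_k)`, i.e. the additive term
#' `+(P*X + D*dX/dt) * sin(phi_k)`.
#' Reduces to the uncontrolled dynamics when `P = D = 0` or `n2 = 0`.
#'
#' @inheritParams km_rhs_network
#' @param cfg A [pdf_config()].
#' @param meanfield Use the mean-field coupling term.
#' @return Phase-velocity vector.
#' @export
pdf_controlled_rhs <- function(phases, omega, K, net = NULL, cfg,
                               meanfield = is.null(net)) {
  stopifnot(inherits(cfg, "pdf_config"))
  if (cfg$n_total != length(phases))
    abort("pdf config does not match state size", "dimension_mismatch")
  v <- if (meanfield) km_rhs_meanfield(phases, omega, K)
       else km_rhs_network(phases, omega, K, net)
  if (cfg$n2 == 0L || (cfg$P == 0 && cfg$D == 0)) return(v)
  mea <- cfg$measured
  x <- mean(cos(phases[mea]))
  xdot <- mean(-sin(phases[mea]) * v[mea])
  f <- cfg$P * x + cfg$D * xdot
  v[cfg$stimulated] <- v[cfg$stimulated] + f * sin(phases[cfg$stimulated])
  v
}

#' Required-strength ratio between two control methods
#'
#' For every controller count shared by two suppression sweeps, finds the
#' minimal control strength at which each method reaches the target
#' time-averaged order parameter `r`, and returns the median ratio
#' (second / first) across counts where both methods succeed. With the
#' Hamiltonian sweep in the first slot and the PDF sweep in the second, the
#' conventional strengths are `gamma/4` and `P + D`.
#'
#' @param sweep_h A `sweep_result` (see [sweep_hamiltonian()]).
#' @param sweep_pdf A `sweep_result` on the same controller-count axis.
#' @param r Target desynchronisation level for `mean R`.
#' @return Median ratio (PDF strength / Hamiltonian strength), with the
#'   per-count minimal strengths in attribute `"detail"`.
#' @export
strength_ratio <- function(sweep_h, sweep_pdf, r) {
  stopifnot(inherits(sweep_h, "sweep_result"),
            inherits(sweep_pdf, "sweep_result"))
  check_scalar(r, "r", 0, 1)
  counts <- intersect(sweep_h$counts, sweep_pdf$counts)
  if (length(counts) == 0)
    abort("sweeps share no controller counts", "undefined_ratio")
  min_strength <- function(sw, count) {
    row <- sw$mean_R[match(count, sw$counts), ]
    ok <- which(row <= r)
    if (length(ok) == 0) NA_real_ else min(sw$strengths[ok])
  }
  h <- vapply(counts, function(m) min_strength(sweep_h, m), numeric(1))
  p <- vapply(counts, function(m) min_strength(sweep_pdf, m), numeric(1))
  both <- is.finite(h) & is.finite(p)
  if (!any(both))
    abort("no controller count at which both methods reach the target",
          "undefined_ratio")
  structure(stats::median(p[both] / h[both]),
            detail = data.frame(count = counts, hamiltonian = h, pdf = p))
}
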