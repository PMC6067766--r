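# Kuramoto model: natural frequencies, order parameters, right-hand sides.
#
# State convention: phases are length-N numeric vectors in radians, wrapped to
# [0, 2*pi) after every integrator step; natural frequencies are plain numeric
# vectors in radians per time unit.

# minimal allowed frequency gap; control denominators contain omega_j - omega_k
EPS_RES <- 1e-9

#' Sample natural frequencies
#'
#' Draws `n` angular frequencies from Normal(`mean`, `sd`). Pairwise
#' distinctness (minimum gap `min_gap`, default `1e-9`) is enforced by
#' resampling near-coincident draws, because the control divides by frequency
#' differences; the control theory additionally assumes non-resonant
#' frequencies, and a larger `min_gap` (for example `sd / n`, the order of the
#' typical nearest-neighbour spacing) can be requested to bound the control
#' amplitude a priori. A degenerate `sd = 0` request is rejected outright.
#'
#' @param n Number of oscillators.
#' @param mean Distribution mean (default 1, the value used throughout the
#'   suppression experiments).
#' @param sd Distribution standard deviation, strictly positive (default 0.1).
#' @param seed Optional integer seed.
#' @param min_gap Minimum pairwise frequency separation; default `1e-9`.
#' @return Numeric vector of length `n` with attributes `mean`, `sd`, `seed`.
#' @examples
#' omega <- sample_frequencies(10, seed = 1)
#' min(diff(sort(omega))) > 1e-9
#' @export
sample_frequencies <- function(n, mean = 1, sd = 0.1, seed = NULL,
                               min_gap = NULL) {
  n <- check_count(n, "n")
  check_scalar(mean, "mean")
  check_scalar(sd, "sd")
  if (sd <= 0)
    abort("sd must be strictly positive: distinct frequencies are required",
          "invalid_parameter")
  min_gap <- max(min_gap %||% EPS_RES, EPS_RES)
  omega <- with_seed(seed, {
    w <- stats::rnorm(n, mean, sd)
    for (iter in 1:200) {
      o <- order(w)
      gaps <- diff(w[o])
      if (n == 1L || min(gaps) >= min_gap) break
      dup <- o[which(gaps < min_gap) + 1L]
      w[dup] <- stats::rnorm(length(dup), mean, sd)
    }
    w
  })
  structure(omega, mean = mean, sd = sd, seed = seed)
}

check_frequencies <- function(omega, n = NULL) {
  if (!is.numeric(omega) || any(!is.finite(omega)))
    abort("frequencies must be finite numeric", "invalid_parameter")
  if (!is.null(n) && length(omega) != n)
    abort("frequency vector length does not match state", "dimension_mismatch")
  if (length(omega) > 1 && min(diff(sort(omega))) <= EPS_RES) {
    o <- order(omega)
    i <- which(diff(omega[o]) <= EPS_RES)[1]
    abort(sprintf("near-resonant frequency pair (nodes %d, %d): gap %.3g",
                  o[i], o[i + 1L], omega[o[i + 1L]] - omega[o[i]]),
          "near_resonance")
  }
  invisible(omega)
}

#' Kuramoto order parameter
#'
#' The mean unit phasor `R exp(i Psi) = (1/N) sum_j exp(i phi_j)`. `R` close
#' to 1 signals phase-locking, `R` close to 0 incoherence. When `R` is
#' numerically zero the phase `Psi` is reported as 0 by convention (every use
#' of `Psi` in the package multiplies by `R`, so the convention is inert).
#'
#' @param phases Numeric vector of phases in radians.
#' @return List with elements `R` (in `[0, 1]`) and `Psi` (in `[0, 2*pi)`).
#' @examples
#' order_parameter(c(0, pi / 2))  # R = cos(pi/4), Psi = pi/4
#' @export
order_parameter <- function(phases) {
  z <- mean(exp(1i * phases))
  r <- Mod(z)
  psi <- if (r < 1e-12) 0 else wrap_phase(Arg(z))
  list(R = min(r, 1), Psi = psi)
}

#' Frequency-weighted local order parameter
#'
#' The modified local order parameter entering the control amplitude:
#' `Rt_k exp(i Psi_k) = (1/N) sum_{j != k} exp(i phi_j) / (omega_j - omega_k)`.
#' The `j = k` term has a singular denominator and is excluded. Unlike the
#' plain order parameter, `Rt_k` is not bounded by 1: it scales with the
#' inverse width of the frequency distribution.
#'
#' @param phases Phase vector.
#' @param omega Natural frequencies (pairwise distinct).
#' @param k Node index (1-based).
#' @return List with `R` (nonnegative) and `Psi` (in `[0, 2*pi)`).
#' @export
local_modified_order <- function(phases, omega, k) {
  n <- length(phases)
  k <- check_count(k, "k")
  if (k > n) abort("node index out of range", "invalid_parameter")
  check_frequencies(omega, n)
  gaps <- omega[-k] - omega[k]
  if (any(abs(gaps) < EPS_RES)) {
    j <- setdiff(seq_len(n), k)[which(abs(gaps) < EPS_RES)[1]]
    abort(sprintf("near-resonant pair (%d, %d)", j, k), "near_resonance")
  }
  z <- sum(exp(1i * phases[-k]) / gaps) / n
  r <- Mod(z)
  list(R = r, Psi = if (r < 1e-12) 0 else wrap_phase(Arg(z)))
}

#' Electrode-sampled modified order parameter
#'
#' The operational counterpart of [local_modified_order()]: the sum runs over
#' the `M` electrode-bearing nodes only, with `1/M` normalisation —
#' `Rh_k exp(i Psih_k) = (1/M) sum_{j in electrodes, j != k}
#' exp(i phi_j) / (omega_j - omega_k)`.
#'
#' @param phases Full phase vector (only electrode entries are read).
#' @param omega Natural frequencies.
#' @param layout An [electrode_layout()].
#' @param k Node index of an electrode-bearing node.
#' @return List with `R` and `Psi` as in [local_modified_order()].
#' @export
sampled_modified_order <- function(phases, omega, layout, k) {
  stopifnot(inherits(layout, "electrode_layout"))
  check_frequencies(omega, length(phases))
  el <- layout$electrode_nodes
  if (!(k %in% el)) abort("k is not an electrode-bearing node", "invalid_parameter")
  m <- length(el)
  j <- setdiff(el, k)
  gaps <- omega[j] - omega[k]
  if (any(abs(gaps) < EPS_RES)) {
    jj <- j[which(abs(gaps) < EPS_RES)[1]]
    abort(sprintf("near-resonant pair (%d, %d)", jj, k), "near_resonance")
  }
  z <- if (length(j)) sum(exp(1i * phases[j]) / gaps) / m else 0 + 0i
  r <- Mod(z)
  list(R = r, Psi = if (r < 1e-12) 0 else wrap_phase(Arg(z)))
}

#' Networked Kuramoto right-hand side
#'
#' `dphi_k/dt = omega_k + (K/N) sum_j A_kj sin(phi_j - phi_k)`; weighted
#' adjacency matrices use the same formula.
#'
#' @param phases Phase vector.
#' @param omega Natural frequencies.
#' @param K Coupling strength.
#' @param net An [oscillator_network()].
#' @return Phase-velocity vector.
#' @export
km_rhs_network <- function(phases, omega, K, net) {
  n <- length(phases)
  if (net$n_nodes != n || length(omega) != n)
    abort("state, frequency and network dimensions disagree", "dimension_mismatch")
  s <- sin(phases); c <- cos(phases)
  # sin(phi_j - phi_k) = sin(phi_j) cos(phi_k) - cos(phi_j) sin(phi_k)
  as.vector(omega + (K / n) * (c * as.vector(net$adjacency %*% s) -
                                 s * as.vector(net$adjacency %*% c)))
}

#' Mean-field Kuramoto right-hand side
#'
#' `dphi_k/dt = omega_k + K R sin(Psi - phi_k)`. On an all-to-all topology this
#' is algebraically identical to [km_rhs_network()] because the `j = k` term of
#' the full sum vanishes (`sin 0 = 0`).
#'
#' @inheritParams km_rhs_network
#' @return Phase-velocity vector.
#' @export
km_rhs_meanfield <- function(phases, omega, K) {
  if (length(omega) != length(phases))
    abort("state and frequency dimensions disagree", "dimension_mismatch")
  op <- order_parameter(phases)
  as.vector(omega + K * op$R * sin(op$Psi - phases))
}
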