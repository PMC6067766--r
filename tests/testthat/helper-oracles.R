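# Independent brute-force oracles: plain-loop transcriptions of the control
# formulas and a reference RK4 stepper, deliberately written without reusing
# the package's vectorised implementations.

# full control term, term-by-term loops
oracle_control_full <- function(phases, omega, K, A, k) {
  n <- length(phases)
  t1a <- 0
  for (j in 1:n) t1a <- t1a + A[k, j] * cos(phases[j] - phases[k])
  t1b <- 0
  for (l in 1:n) if (l != k)
    t1b <- t1b + A[k, l] / (omega[l] - omega[k]) * cos(phases[l] - phases[k])
  t2a <- 0
  for (j in 1:n) if (j != k)
    t2a <- t2a + A[k, j] / (omega[j] - omega[k]) * sin(phases[j] - phases[k])
  t2b <- 0
  for (l in 1:n) t2b <- t2b + A[k, l] * sin(phases[l] - phases[k])
  t3 <- 0
  for (l in 1:n) {
    in1 <- 0
    for (j in 1:n) if (j != l)
      in1 <- in1 + A[j, l] / (omega[j] - omega[l]) * cos(phases[j] - phases[l])
    in2 <- 0
    for (j in 1:n) in2 <- in2 + A[j, l] * sin(phases[j] - phases[l])
    part <- A[k, l] * cos(phases[k] - phases[l]) * in1
    if (l != k)
      part <- part + A[k, l] / (omega[k] - omega[l]) * sin(phases[k] - phases[l]) * in2
    t3 <- t3 + part
  }
  -(K^2 / (4 * n^2)) * (t1a * t1b + t2a * t2b - t3)
}

# modified local order parameter by loops
oracle_modified_order <- function(phases, omega, k) {
  n <- length(phases)
  z <- 0 + 0i
  for (j in 1:n) if (j != k)
    z <- z + exp(1i * phases[j]) / (omega[j] - omega[k])
  z / n
}

# correction term B_k by loops (1/N on both sums, l = k excluded where the
# frequency denominator is singular)
oracle_b_term <- function(phases, omega, k) {
  n <- length(phases)
  rt <- numeric(n); psil <- numeric(n)
  for (l in 1:n) {
    z <- oracle_modified_order(phases, omega, l)
    rt[l] <- Mod(z); psil[l] <- Arg(z)
  }
  zg <- mean(exp(1i * phases))
  R <- Mod(zg); Psi <- Arg(zg)
  s1 <- 0
  for (l in 1:n)
    s1 <- s1 + cos(phases[k] - phases[l]) * cos(psil[l] - phases[l]) * rt[l]
  s2 <- 0
  for (l in 1:n) if (l != k)
    s2 <- s2 + sin(phases[k] - phases[l]) / (omega[k] - omega[l]) *
      sin(Psi - phases[l]) * R
  (s1 + s2) / n
}

# Stuart-Landau rhs by loops
oracle_sl_rhs <- function(z, omega, K, A) {
  n <- length(z)
  out <- complex(n)
  for (k in 1:n) {
    coup <- 0 + 0i
    for (j in 1:n) coup <- coup + A[k, j] * z[j]
    out[k] <- (1 + 1i * omega[k] - Mod(z[k])^2) * z[k] + (K / n) * coup
  }
  out
}

# classical RK4 reference stepper with phase wrapping, for cross-checking the
# compiled integrator against the R-level right-hand sides
oracle_rk4_phases <- function(f, phi, dt, n_steps) {
  for (s in seq_len(n_steps)) {
    k1 <- f(phi)
    k2 <- f(phi + dt / 2 * k1)
    k3 <- f(phi + dt / 2 * k2)
    k4 <- f(phi + dt * k3)
    phi <- (phi + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)) %% (2 * pi)
  }
  phi
}

# small reproducible test fixtures
fixture_omega <- function(n, sd = 0.3, seed = 42) {
  sample_frequencies(n, 1, sd, seed = seed)
}

# circular distance on the torus, in [0, pi]
circ_dist <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# simple path graph used for graph-distance checks
load_network_fixture_path <- function(n = 6) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) { a[i, i + 1] <- 1; a[i + 1, i] <- 1 }
  oscillator_network(a)
}
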