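test_that("sampled frequencies are centred and pairwise distinct", {
  om <- sample_frequencies(100, 1, 0.1, seed = 7)
  expect_lt(abs(mean(om) - 1), 4 * 0.1 / sqrt(100))
  expect_gt(min(diff(sort(om))), 1e-9)
  om2 <- sample_frequencies(2, 1, 0.1, seed = 3)
  expect_gt(abs(om2[1] - om2[2]), 1e-9)
  expect_error(sample_frequencies(10, 1, 0), class = "invalid_parameter")
})

test_that("order parameter matches the complex mean of unit phasors", {
  op <- order_parameter(rep(1.3, 5))
  expect_equal(op$R, 1)
  expect_equal(op$Psi, 1.3)
  expect_lt(order_parameter(c(0, pi / 2, pi, 3 * pi / 2))$R, 1e-15)
  op2 <- order_parameter(c(0, pi / 2))
  expect_equal(op2$R, cos(pi / 4))
  expect_equal(op2$Psi, pi / 4)
  set.seed(11)
  ph <- runif(31, 0, 2 * pi)
  z <- mean(exp(1i * ph))
  op3 <- order_parameter(ph)
  expect_equal(op3$R * exp(1i * op3$Psi), z, tolerance = 1e-12)
})

test_that("modified local order parameter: hand value, oracle, gap antisymmetry", {
  r0 <- local_modified_order(c(0, 0), c(1.0, 1.2), k = 1)
  expect_equal(r0$R, 2.5)
  expect_equal(r0$Psi, 0)
  set.seed(4)
  for (i in 1:10) {
    ph <- runif(3, 0, 2 * pi); om <- sort(rnorm(3, 1, 0.4))
    for (k in 1:3) {
      got <- local_modified_order(ph, om, k)
      want <- oracle_modified_order(ph, om, k)
      expect_equal(got$R, Mod(want), tolerance = 1e-12)
      expect_equal(got$R * exp(1i * got$Psi), want, tolerance = 1e-12)
    }
  }
  # negating every frequency gap flips the phasor: Psi shifts by pi, R unchanged
  ph <- runif(5, 0, 2 * pi); om <- fixture_omega(5)
  a <- local_modified_order(ph, om, 2)
  b <- local_modified_order(ph, 2 * om[2] - om, 2)
  expect_equal(b$R, a$R, tolerance = 1e-12)
  expect_equal(circ_diff <- min(abs(b$Psi - a$Psi - pi), abs(b$Psi - a$Psi + pi)),
               0, tolerance = 1e-12)
  om_res <- c(1, 1 + 1e-12, 2)
  expect_error(local_modified_order(c(0, 1, 2), om_res, 1),
               class = "near_resonance")
})

test_that("electrode-sampled modified order parameter reduces and permutes correctly", {
  n <- 6
  ph <- random_phases(n, seed = 2)
  om <- fixture_omega(n)
  lay_all <- electrode_layout(1:n, {
    r <- matrix(1, n, n); diag(r) <- 0; r
  }, gamma = 1)
  for (k in 1:n) {
    expect_equal(sampled_modified_order(ph, om, lay_all, k)$R,
                 local_modified_order(ph, om, k)$R, tolerance = 1e-12)
  }
  # M = 2 single-term hand computation
  lay2 <- electrode_layout(c(1, 2), rbind(c(0, 1), c(1, 0), c(2, 2),
                                          c(3, 3), c(4, 4), c(5, 5)),
                           gamma = 1)
  got <- sampled_modified_order(c(0, 0, ph[-(1:2)]), c(1.0, 1.2, om[-(1:2)]),
                                lay2, 1)
  expect_equal(got$R, 2.5)
  # permuting electrode labels leaves the estimate invariant
  lay_a <- electrode_layout(c(2, 4, 5), {
    r <- matrix(1, n, 3); r[2, 1] <- 0; r[4, 2] <- 0; r[5, 3] <- 0; r
  }, gamma = 1)
  lay_b <- electrode_layout(c(5, 2, 4), {
    r <- matrix(1, n, 3); r[5, 1] <- 0; r[2, 2] <- 0; r[4, 3] <- 0; r
  }, gamma = 1)
  expect_equal(sampled_modified_order(ph, om, lay_a, 4)$R,
               sampled_modified_order(ph, om, lay_b, 4)$R)
})

test_that("networked Kuramoto rhs matches closed forms", {
  om <- fixture_omega(4)
  expect_equal(km_rhs_network(rep(0.7, 4), om, 0.8, all_to_all(4)),
               as.numeric(om))
  # N = 2: velocity difference (omega_2 - omega_1) - K sin(phi_2 - phi_1)
  om2 <- c(1.0, 1.3); ph2 <- c(0.2, 1.1)
  v <- km_rhs_network(ph2, om2, 0.6, all_to_all(2))
  expect_equal(v[2] - v[1], (om2[2] - om2[1]) - 0.6 * sin(ph2[2] - ph2[1]))
  # coupling part sums to zero on symmetric adjacency
  net <- newman_watts(20, 0.4, seed = 1)
  ph <- random_phases(20, seed = 5)
  om20 <- fixture_omega(20)
  expect_equal(sum(km_rhs_network(ph, om20, 0.7, net) - om20), 0,
               tolerance = 1e-12)
  # weighted adjacency uses the same formula
  w <- net$adjacency * 0.5
  netw <- oscillator_network(w)
  manual <- sapply(1:20, function(k)
    om20[k] + (0.7 / 20) * sum(w[k, ] * sin(ph - ph[k])))
  expect_equal(km_rhs_network(ph, om20, 0.7, netw), manual, tolerance = 1e-12)
})

test_that("mean-field rhs is an exact identity with the all-to-all network rhs", {
  set.seed(9)
  net <- all_to_all(50)
  om <- fixture_omega(50)
  for (i in 1:100) {
    ph <- runif(50, 0, 2 * pi)
    expect_lt(max(abs(km_rhs_meanfield(ph, om, 0.5) -
                        km_rhs_network(ph, om, 0.5, net))), 1e-12)
  }
  # incoherent configuration: velocity reduces to omega
  ph0 <- c(0, pi / 2, pi, 3 * pi / 2)
  expect_equal(km_rhs_meanfield(ph0, c(0.9, 1, 1.1, 1.2), 2),
               c(0.9, 1, 1.1, 1.2), tolerance = 1e-12)
  expect_equal(km_rhs_meanfield(0.3, 1.7, 5), 1.7)
})
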