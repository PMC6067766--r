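# The compiled RK4 core is cross-checked against a reference R stepper built
# on the package's R-level right-hand sides, then against closed-form
# Kuramoto behaviour (free rotation, the N = 2 locking fixed point, the
# integrator's fourth-order convergence).

test_that("compiled integrator agrees with the R reference stepper", {
  n <- 12
  net <- newman_watts(n, 0.4, seed = 2)
  om <- fixture_omega(n, sd = 0.2)
  ph0 <- random_phases(n, seed = 3)
  dt <- 0.01; n_steps <- 25

  cases <- list(
    list(f = function(p) km_rhs_network(p, om, 0.7, net),
         args = list(net = net, K = 0.7)),
    list(f = function(p) km_rhs_meanfield(p, om, 0.7),
         args = list(K = 0.7, meanfield = TRUE)))
  lay <- place_electrodes(net, 5, seed = 4, gamma_over_4 = 4.25)
  cases[[3]] <- list(f = function(p) controlled_km_rhs(p, om, 0.7, net, lay),
                     args = list(net = net, K = 0.7, control = lay))
  cases[[4]] <- list(
    f = function(p) controlled_km_rhs(p, om, 0.7, net, lay, "sampled-R"),
    args = list(net = net, K = 0.7, control = lay,
                control_mode = "sampled-R"))
  cfgp <- pdf_config(n, 4, P = 8, D = 3, seed = 9)
  cases[[5]] <- list(f = function(p) pdf_controlled_rhs(p, om, 0.7, net, cfgp),
                     args = list(net = net, K = 0.7, pdf = cfgp))

  for (cs in cases) {
    want <- oracle_rk4_phases(cs$f, ph0, dt, n_steps)
    got <- do.call(integrate_km, c(list(state0 = ph0, omega = om,
                                        t_end = n_steps * dt, dt = dt,
                                        record_every = n_steps), cs$args))
    expect_lt(max(circ_dist(got$final_phases, want)), 1e-10)
  }
})

test_that("uncoupled oscillators rotate freely", {
  om <- fixture_omega(5)
  ph0 <- random_phases(5, seed = 1)
  tr <- integrate_km(ph0, om, K = 0, t_end = 10, meanfield = TRUE)
  expect_equal(tr$final_phases, as.vector((ph0 + om * 10) %% (2 * pi)),
               tolerance = 1e-9)
})

test_that("two oscillators lock at the arcsine fixed point when |dw| < K", {
  om <- c(1.0, 1.2); net <- all_to_all(2)
  tr <- integrate_km(c(0, 0), om, net = net, K = 0.5, t_end = 100,
                     record_phases = TRUE)
  d_end <- tr$final_phases[2] - tr$final_phases[1]
  d_end <- atan2(sin(d_end), cos(d_end))
  expect_equal(d_end, asin(0.2 / 0.5), tolerance = 1e-4)
  expect_gt(mean_R(tr), 0.95)
})

test_that("two oscillators drift when |dw| > K", {
  om <- c(1.0, 1.2); net <- all_to_all(2)
  tr <- integrate_km(c(0, 0), om, net = net, K = 0.1, t_end = 200,
                     record_phases = TRUE)
  expect_lt(mean_R(tr), 0.95)
  # phase difference keeps winding: it visits both half-circles
  d <- tr$phases[, 2] - tr$phases[, 1]
  expect_gt(sd(cos(d)), 0.3)
})

test_that("halving dt shrinks the end-state error by about 2^4", {
  n <- 6
  net <- all_to_all(n)
  om <- fixture_omega(n)
  ph0 <- random_phases(n, seed = 17)
  run <- function(dt) integrate_km(ph0, om, net = net, K = 0.4, t_end = 2,
                                   dt = dt, record_every = 1e6)$final_phases
  ref <- run(0.00625)
  e1 <- max(circ_dist(run(0.05), ref))
  e2 <- max(circ_dist(run(0.025), ref))
  expect_gt(e1 / e2, 8)
  expect_lt(e1 / e2, 40)
})

test_that("traces keep their invariants and record the applied coupling", {
  sch <- seizure_schedule_km(scale = 500, seed = 5)
  om <- sample_frequencies(20, 1, 0.1, seed = 2)
  net <- newman_watts(20, 0.85, 2, seed = 3)
  tr <- integrate_km(random_phases(20, seed = 1), om, net = net,
                     schedule = sch, record_every = 20, record_phases = TRUE)
  expect_true(all(tr$R_series >= 0 & tr$R_series <= 1))
  expect_true(all(diff(tr$times) > 0))
  expect_true(all(tr$phases >= 0 & tr$phases < 2 * pi))
  expect_true(all(is.finite(tr$phases)))
  b <- schedule_boundaries(sch)
  in_seg <- function(t) t >= b[1] & t < b[2]
  expect_true(all(tr$K_series[in_seg(tr$times)] >= 0.05 &
                    tr$K_series[in_seg(tr$times)] <= 0.15))
})

test_that("mean_R averages the post-transient window linearly", {
  om <- fixture_omega(4)
  tr <- integrate_km(random_phases(4, seed = 2), om, K = 0.2, t_end = 10,
                     meanfield = TRUE)
  full <- mean_R(tr, 0)
  expect_equal(full, mean(tr$R_series))
  keep1 <- tr$times < 5; keep2 <- tr$times >= 5
  recomb <- (sum(tr$R_series[keep1]) + sum(tr$R_series[keep2])) /
    length(tr$R_series)
  expect_equal(full, recomb)
  expect_error(mean_R(tr, 10), class = "invalid_parameter")
})

test_that("critical coupling locates the synchronisation onset on a small system", {
  net <- all_to_all(30)
  om <- sample_frequencies(30, 1, 0.1, seed = 8)
  kc <- critical_coupling(net, om, seq(0.05, 0.6, 0.05), reps = 3, seed = 4,
                          t_end = 80)
  expect_gt(as.numeric(kc), 0.05)
  expect_lt(as.numeric(kc), 0.45)
  prof <- attr(kc, "profile")
  expect_gt(prof[length(prof)], prof[1])
  expect_error(critical_coupling(net, om, c(0.9, 1.0, 1.1), reps = 2,
                                 seed = 1, t_end = 30),
               class = "not_bracketed")
})
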