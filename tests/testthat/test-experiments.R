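test_that("seizure schedule reproduces the protocol boundaries and supports", {
  s1 <- seizure_schedule_km(scale = 1)
  expect_equal(schedule_boundaries(s1)[1:4], c(0, 5000, 7500, 125000))
  s50 <- seizure_schedule_km(scale = 50)
  expect_equal(schedule_boundaries(s50), c(0, 100, 150, 2500, 2550, 2650))
  expect_equal(s50$redraw_interval, 2)
  k <- realize_schedule(seizure_schedule_km(scale = 50, seed = 9), dt = 0.01)
  expect_length(k, 265000)
  tstep <- (seq_along(k) - 1) * 0.01
  base <- k[tstep < 100]
  expect_true(all(base >= 0.05 & base <= 0.15))
  plateau <- k[tstep >= 150 & tstep < 2500]
  expect_true(all(plateau >= 0.55 & plateau <= 0.65))
  ramp <- k[tstep >= 100 & tstep < 150]
  frac <- (tstep[tstep >= 100 & tstep < 150] - 100) / 50
  mid <- 0.1 + frac * 0.4
  expect_true(all(abs(ramp - mid) <= 0.05 + 0.4 * (2 / 50) + 1e-9))
  # K held constant within each redraw window
  expect_lte(length(unique(base)), 50)
  expect_identical(realize_schedule(seizure_schedule_km(50, seed = 9), 0.01), k)
})

test_that("schedule validation rejects gaps and negative couplings", {
  expect_error(coupling_schedule(list(
    list(t_start = 0, t_end = 10, type = "uniform", lo = 0.1, hi = 0.2),
    list(t_start = 11, t_end = 20, type = "constant", value = 0.1)), 1),
    class = "invalid_parameter")
  expect_error(coupling_schedule(list(
    list(t_start = 0, t_end = 10, type = "uniform", lo = -0.1, hi = 0.2)), 1),
    class = "invalid_parameter")
  expect_error(constant_schedule(-1, 10), class = "invalid_parameter")
})

test_that("the M = 0 sweep column reproduces the uncontrolled system exactly", {
  sw <- sweep_hamiltonian(c(0, 5), c(2, 10), n = 20, reps = 2, seed = 3,
                          t_end = 20)
  expect_equal(sw$mean_R[1, 1], sw$mean_R[1, 2])
  om <- sample_frequencies(20, 1, 0.1, seed = derive_seeds(3, "frequencies"))
  manual <- mean(sapply(1:2, function(r) {
    rs <- derive_seeds(3, sprintf("cell_%d_rep_%d", 1, r))
    mean_R(integrate_km(random_phases(20, seed = rs), om, K = 0.5,
                        t_end = 20, record_every = 20, meanfield = TRUE))
  }))
  expect_equal(sw$mean_R[1, 1], manual)
  expect_true(all(sw$mean_R >= 0 & sw$mean_R <= 1))
})

test_that("iso-desynchronisation curves read the sweep surface", {
  sw <- structure(list(counts = c(10, 20, 30), strengths = c(2, 6, 10),
                       mean_R = rbind(c(0.9, 0.8, 0.7), c(0.8, 0.3, 0.2),
                                      c(0.05, 0.04, 0.03)),
                       sd_R = matrix(0, 3, 3), reps = 1,
                       meta = list(method = "hamiltonian")),
                  class = "sweep_result")
  expect_equal(iso_desync_curve(sw, 1)$strength, rep(2, 3))
  cur <- iso_desync_curve(sw, 0.4)
  expect_equal(cur$strength, c(NA, 6, 2))
  expect_true(all(diff(cur$strength[!is.na(cur$strength)]) <= 0))
})

test_that("seizure driver pairs controlled and uncontrolled runs with common draws", {
  sch <- seizure_schedule_km(scale = 500, seed = 11)
  om <- sample_frequencies(15, 1, 0.1, seed = 1)
  net <- newman_watts(15, 0.85, 2, seed = 2)
  ic <- random_phases(15, seed = 3)
  lay <- place_electrodes(net, 4, seed = 4, gamma_over_4 = 4.25)
  a <- integrate_km(ic, om, net = net, schedule = sch)
  b <- integrate_km(ic, om, net = net, schedule = sch, control = lay)
  expect_identical(a$K_series, b$K_series)

  ex <- run_seizure_experiment("km", n = 15, M = 4, reps = 2, scale = 500,
                               seed = 5, record_every = 20)
  expect_equal(nrow(ex$summary), 5)
  expect_equal(ex$summary$segment[3], "plateau")
  expect_equal(max(ex$times), 265)
  expect_true(all(ex$R_unc >= 0 & ex$R_unc <= 1))
  ex2 <- run_seizure_experiment("km", n = 15, M = 4, reps = 2, scale = 500,
                                seed = 5, record_every = 20)
  expect_identical(ex$R_ctl, ex2$R_ctl)   # byte-reproducible from the seed
})

test_that("configs run end-to-end deterministically", {
  cfg <- run_config(model = "km", n = 12,
                    network = list(type = "newman_watts", p = 0.6),
                    coupling = list(K = 0.4),
                    control = list(method = "hamiltonian", M = 3,
                                   gamma_over_4 = 2),
                    integrator = list(t_end = 10), seed = 21)
  t1 <- run_from_config(cfg)
  t2 <- run_from_config(cfg)
  expect_identical(t1$R_series, t2$R_series)
  expect_identical(t1$final_phases, t2$final_phases)
  cfg_sl <- run_config(model = "sl", n = 10, coupling = list(K = 0.2),
                       integrator = list(t_end = 5), seed = 3)
  tr <- run_from_config(cfg_sl)
  expect_equal(tr$model, "sl")
  expect_true(all(is.finite(tr$total_signal)))
})
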