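test_that("full control term matches an independent loop transcription", {
  set.seed(21)
  for (i in 1:8) {
    n <- sample(3:8, 1)
    net <- if (i %% 2 == 0) all_to_all(n)
           else erdos_renyi_connected(n, 0.7, seed = i)
    a <- net$adjacency
    if (i == 5) { a <- a * matrix(runif(n * n, 0.5, 2), n); a <- (a + t(a)) / 2
                  diag(a) <- 0; net <- oscillator_network(a); a <- net$adjacency }
    ph <- runif(n, 0, 2 * pi)
    om <- sort(rnorm(n, 1, 0.4))
    K <- runif(1, 0.1, 1)
    for (k in 1:n)
      expect_equal(control_full(ph, om, K, net, k),
                   oracle_control_full(ph, om, K, a, k), tolerance = 1e-12)
  }
})

test_that("control term vanishes at K = 0 and scales as K^2", {
  n <- 6
  net <- all_to_all(n)
  ph <- random_phases(n, seed = 3)
  om <- fixture_omega(n)
  expect_equal(control_full(ph, om, 0, net), rep(0, n))
  expect_equal(control_full(ph, om, 0.8, net), 4 * control_full(ph, om, 0.4, net),
               tolerance = 1e-13)
})

test_that("B_k matches its loop oracle and is invariant under global phase shifts", {
  set.seed(31)
  for (i in 1:6) {
    n <- sample(3:7, 1)
    ph <- runif(n, 0, 2 * pi)
    om <- sort(rnorm(n, 1, 0.3))
    for (k in 1:n)
      expect_equal(b_term(ph, om, k), oracle_b_term(ph, om, k),
                   tolerance = 1e-12)
    shift <- runif(1, 0, 2 * pi)
    expect_equal(b_term((ph + shift) %% (2 * pi), om), b_term(ph, om),
                 tolerance = 1e-10)
  }
})

test_that("all-to-all closed form reproduces the full control on complete graphs", {
  set.seed(41)
  for (n in c(3, 5, 10)) {
    net <- all_to_all(n)
    for (i in 1:30) {
      ph <- runif(n, 0, 2 * pi)
      om <- sort(rnorm(n, 1, 0.25))
      expect_lt(max(abs(control_full(ph, om, 0.5, net) -
                          control_alltoall(ph, om, 0.5))), 1e-12)
    }
  }
})

test_that("operational control equals its closed composition and hand value", {
  # hand-chained value through the sampled order parameter
  lay <- electrode_layout(c(1, 2), rbind(c(0, 1), c(1, 0)), gamma = 17)
  h <- operational_control(c(0, 0), c(1.0, 1.2), K = 0.5, lay, k = 1)
  expect_equal(h, -(17 / 4) * 0.25 * 1 * 2.5 * 1)
  expect_equal(h, -2.65625)
  # gamma = 0 kills the control
  lay0 <- electrode_layout(c(1, 2), rbind(c(0, 1), c(1, 0)), gamma = 0)
  expect_equal(operational_control(c(0.3, 1.2), c(1.0, 1.2), 0.5, lay0),
               c(0, 0))
  # composition: -(gamma/4) K^2 R Rhat_k cos(Psi - phi_k), electrode by electrode
  n <- 8
  ph <- random_phases(n, seed = 6)
  om <- fixture_omega(n)
  net <- all_to_all(n)
  lay8 <- place_electrodes(net, 4, seed = 2, gamma_over_4 = 3)
  op <- order_parameter(ph)
  h_all <- operational_control(ph, om, 0.5, lay8)
  for (i in seq_along(lay8$electrode_nodes)) {
    k <- lay8$electrode_nodes[i]
    rhat <- sampled_modified_order(ph, om, lay8, k)$R
    expect_equal(h_all[i],
                 -(lay8$gamma / 4) * 0.25 * op$R * rhat * cos(op$Psi - ph[k]),
                 tolerance = 1e-12)
    # quarter-period form: cosine is the coupling signal advanced by T/4
    expect_equal(h_all[i],
                 -(lay8$gamma / 4) * 0.5 * rhat *
                   (0.5 * op$R * sin(op$Psi - ph[k] + pi / 2)),
                 tolerance = 1e-12)
  }
  expect_error(operational_control(ph, om, 0.5, lay8,
                                   k = setdiff(1:n, lay8$electrode_nodes)[1]),
               class = "invalid_parameter")
})

test_that("stimulation field attenuates exponentially with distance", {
  lay1 <- electrode_layout(1, matrix(c(0, log(2) / 2), 2, 1), gamma = 1)
  s <- stimulation_field(-1.5, lay1)
  expect_equal(s[1], -1.5)       # r = 0: e^0 = 1
  expect_equal(s[2], -0.75)      # r = ln(2)/2: e^{-2r} = 1/2
  lay_c0 <- electrode_layout(1, matrix(c(0, 1), 2, 1), c_s = 0, gamma = 1)
  expect_equal(stimulation_field(3, lay_c0), c(0, 0))
  expect_error(stimulation_field(c(1, 2), lay1), class = "dimension_mismatch")
})

test_that("controlled rhs reduces to its parts in the limits", {
  n <- 10
  ph <- random_phases(n, seed = 8)
  om <- fixture_omega(n)
  net <- all_to_all(n)
  lay0 <- place_electrodes(net, 4, seed = 1, gamma_over_4 = 0)
  expect_equal(controlled_km_rhs(ph, om, 0.5, net, lay0),
               km_rhs_network(ph, om, 0.5, net))
  # isolated electrodes: each electroded node receives exactly its own control
  layI <- place_electrodes(net, n, seed = 3, distance_mode = "isolated",
                           gamma_over_4 = 2)
  v <- controlled_km_rhs(ph, om, 0.5, net, layI)
  hh <- operational_control(ph, om, 0.5, layI)
  expect_equal(v - km_rhs_network(ph, om, 0.5, net),
               hh[match(1:n, layI$electrode_nodes)], tolerance = 1e-12)
})

test_that("control magnitude is minimally invasive and scales as K^2", {
  n <- 50
  ph <- random_phases(n, seed = 12)
  om <- sample_frequencies(n, 1, 0.1, seed = 13)
  net <- all_to_all(n)
  lay <- place_electrodes(net, 10, seed = 4, gamma = gamma_default(net))
  ratio <- sapply(c(0.05, 0.1, 0.2), function(K) {
    s <- stimulation_field(operational_control(ph, om, K, lay), lay)
    coup <- km_rhs_network(ph, om, K, net) - om
    max(abs(s)) / max(abs(coup))
  })
  expect_lt(ratio[1], 0.3)                       # control << coupling below K_c
  expect_equal(ratio[2] / ratio[1], 2, tolerance = 1e-10)
  expect_equal(ratio[3] / ratio[2], 2, tolerance = 1e-10)
})

test_that("control signals are covariant under a global phase shift", {
  n <- 12
  ph <- random_phases(n, seed = 14)
  om <- fixture_omega(n)
  lay <- place_electrodes(all_to_all(n), 5, seed = 5, gamma_over_4 = 4.25)
  for (shift in c(0.7, 2.9)) {
    h1 <- operational_control(ph, om, 0.5, lay)
    h2 <- operational_control((ph + shift) %% (2 * pi), om, 0.5, lay)
    expect_equal(abs(h2), abs(h1), tolerance = 1e-10)
    expect_equal(abs(stimulation_field(h2, lay)),
                 abs(stimulation_field(h1, lay)), tolerance = 1e-10)
  }
})

test_that("electrode placement: geometry, determinism, validation", {
  net <- all_to_all(100)
  lay <- place_electrodes(net, 100, seed = 1, gamma = 1)
  expect_equal(sort(lay$electrode_nodes), 1:100)
  expect_equal(lay$distances[cbind(lay$electrode_nodes, 1:100)], rep(0, 100))
  # arc distance between nodes two apart on the unit-circle ring
  l3 <- which(lay$electrode_nodes == 3)
  expect_equal(lay$distances[1, l3], 2 * (2 * pi / 100))
  expect_identical(place_electrodes(net, 7, seed = 9)$electrode_nodes,
                   place_electrodes(net, 7, seed = 9)$electrode_nodes)
  expect_error(place_electrodes(net, 101), class = "invalid_parameter")
  # graph mode scales hop counts
  path <- load_network_fixture_path()
  lg <- place_electrodes(path, 1, seed = 2, distance_mode = "graph",
                         length_per_hop = 0.5)
  hops <- igraph::distances(igraph::graph_from_adjacency_matrix(
    path$adjacency, mode = "undirected"), to = lg$electrode_nodes)
  expect_equal(lg$distances[, 1], as.numeric(hops) * 0.5)
})

test_that("gamma_default is the mean connectivity ratio", {
  expect_equal(gamma_default(all_to_all(17)), 1)
  ring <- newman_watts(100, p = 0, k_half = 2)
  expect_equal(gamma_default(ring), 4 / 99)
  expect_gt(gamma_default(newman_watts(100, 0.85, 2, seed = 1)),
            gamma_default(ring))
})
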