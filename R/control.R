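# Desynchronising control terms.
#
# The control derives from a Hamiltonian embedding of the Kuramoto model: a
# perturbation of order K^2 added to the phase dynamics stabilises the
# incoherent torus and counteracts phase-locking. Three tiers are implemented:
#   * control_full      — the full theoretical term (any symmetric network),
#   * control_alltoall  — its closed form under all-to-all coupling, written
#                         with order parameters and the correction B_k,
#   * operational_control — the electrode-implementable simplification using
#                         only M measured nodes and a gain gamma.

#' Microelectrode layout
#'
#' Describes where the `M` stimulation/recording microelectrodes sit, how far
#' every node is from every electrode (the stimulation field decays as
#' `exp(-2 r)`), the field strength `c_s`, and the control gain `gamma`.
#' Experiments in the source literature report the gain as `gamma/4`, so the
#' constructor accepts either parametrisation.
#'
#' @param electrode_nodes Integer vector of `M` distinct node indices (1-based).
#' @param distances Numeric `N x M` matrix; `distances[k, l]` is the distance
#'   of node `k` from electrode `l`. Must be zero exactly where `k` is the node
#'   electrode `l` sits on.
#' @param c_s Field strength scalar, default 1.
#' @param gamma Control gain; give either `gamma` or `gamma_over_4`.
#' @param gamma_over_4 Convenience parametrisation: `gamma = 4 * gamma_over_4`.
#' @return An object of class `electrode_layout`.
#' @seealso [place_electrodes()] which builds layouts from a network.
#' @export
electrode_layout <- function(electrode_nodes, distances, c_s = 1,
                             gamma = NULL, gamma_over_4 = NULL) {
  electrode_nodes <- as.integer(electrode_nodes)
  m <- length(electrode_nodes)
  if (m < 1L) abort("need at least one electrode", "invalid_parameter")
  if (anyDuplicated(electrode_nodes))
    abort("electrode nodes must be distinct", "invalid_parameter")
  if (!is.matrix(distances) || ncol(distances) != m)
    abort("distances must be an N x M matrix", "dimension_mismatch")
  n <- nrow(distances)
  if (m > n) abort("more electrodes than nodes", "invalid_parameter")
  if (any(electrode_nodes < 1L | electrode_nodes > n))
    abort("electrode node index out of range", "invalid_parameter")
  if (any(distances < 0)) abort("negative electrode distance", "invalid_parameter")
  for (l in seq_len(m)) {
    if (distances[electrode_nodes[l], l] != 0)
      abort(sprintf("distance of electrode %d to its own node must be 0", l),
            "invalid_parameter")
    if (any(distances[-electrode_nodes[l], l] == 0))
      abort(sprintf("distance to electrode %d is 0 for a non-electrode node", l),
            "invalid_parameter")
  }
  if (!is.null(gamma) && !is.null(gamma_over_4))
    abort("give gamma or gamma_over_4, not both", "invalid_parameter")
  if (is.null(gamma)) gamma <- if (is.null(gamma_over_4)) 0 else 4 * gamma_over_4
  check_scalar(gamma, "gamma", lower = 0)
  check_scalar(c_s, "c_s", lower = 0)
  structure(list(electrode_nodes = electrode_nodes, distances = distances,
                 c_s = c_s, gamma = gamma),
            class = "electrode_layout")
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf("<electrode_layout> M = %d electrodes on %d nodes, c_s = %g, gamma/4 = %g\n",
              length(x$electrode_nodes), nrow(x$distances), x$c_s, x$gamma / 4))
  invisible(x)
}

#' Place microelectrodes uniformly at random
#'
#' Samples `m` distinct nodes without replacement and computes the node-to-
#' electrode distance matrix. Three geometries are available. `"ring"`
#' (default): nodes sit uniformly on the unit circle in index order — the
#' natural embedding of the small-world ring backbone — and `r_kl` is arc
#' length, so adjacent nodes are `spacing = 2*pi/n` apart and the `exp(-2 r)`
#' stimulation fields of neighbouring electrodes overlap strongly; `spacing`
#' can be raised to shrink the field footprint. `"graph"`: shortest-path hop
#' counts scaled by `length_per_hop`. `"isolated"`: infinite off-node
#' distances, i.e. no cross-talk — each electrode stimulates only the patch
#' it is implanted in (the spatially abstract all-to-all setting, where
#' electrode layout is immaterial; used by the suppression sweeps).
#'
#' @param net An [oscillator_network()].
#' @param m Number of electrodes, `1 <= m <= n`.
#' @param seed Optional integer seed (fixed seed gives a reproducible layout).
#' @param distance_mode `"ring"`, `"graph"` or `"isolated"`.
#' @param spacing Arc length between adjacent nodes in `"ring"` mode,
#'   default `2*pi/n` (unit circle).
#' @param length_per_hop Physical length of one graph hop in `"graph"` mode;
#'   default `spacing`.
#' @inheritParams electrode_layout
#' @return An [electrode_layout()].
#' @examples
#' lay <- place_electrodes(all_to_all(10), 3, seed = 1, gamma_over_4 = 4.25)
#' lay$electrode_nodes
#' @export
place_electrodes <- function(net, m, seed = NULL,
                             distance_mode = c("ring", "graph", "isolated"),
                             spacing = NULL, length_per_hop = NULL, c_s = 1,
                             gamma = NULL, gamma_over_4 = NULL) {
  distance_mode <- match.arg(distance_mode)
  n <- net$n_nodes
  spacing <- spacing %||% (2 * pi / n)
  check_scalar(spacing, "spacing")
  if (spacing <= 0) abort("spacing must be positive", "invalid_parameter")
  m <- check_count(m, "m")
  if (m > n) abort("m exceeds the number of nodes", "invalid_parameter")
  nodes <- with_seed(seed, sample.int(n, m))
  if (distance_mode == "ring") {
    gap <- abs(outer(seq_len(n), nodes, "-"))
    r <- pmin(gap, n - gap) * spacing
  } else if (distance_mode == "graph") {
    hop <- igraph::distances(as_igraph(net), v = seq_len(n), to = nodes,
                             weights = NA)
    r <- hop * (length_per_hop %||% spacing)
  } else {
    r <- matrix(Inf, n, m)
    r[cbind(nodes, seq_len(m))] <- 0
  }
  electrode_layout(nodes, r, c_s = c_s, gamma = gamma,
                   gamma_over_4 = gamma_over_4)
}

#' Network-average connectivity ratio
#'
#' The mean (weighted) degree divided by `n - 1`, i.e. the realised fraction
#' of the maximum possible number of links: 1 for all-to-all coupling, small
#' for sparse graphs. Suggested in the source control scheme as an a-priori
#' macroscopic guess for the gain `gamma`; the suppression experiments
#' themselves use far larger gains, so treat this as a helper, not a default.
#'
#' @param net An [oscillator_network()].
#' @return Scalar in `[0, Inf)` (`<= 1` for unweighted graphs).
#' @export
gamma_default <- function(net) {
  if (net$n_nodes < 2) abort("need at least two nodes", "invalid_size")
  mean(degrees(net)) / (net$n_nodes - 1)
}

# complex modified local order parameters for every node:
# mt[l] = (1/N) sum_{j != l} exp(i phi_j) / (omega_j - omega_l)
modified_order_all <- function(phases, omega) {
  n <- length(phases)
  gap <- outer(omega, omega, "-")        # gap[j, l] = omega_j - omega_l
  diag(gap) <- Inf                       # excludes the singular j = l term
  as.vector(t(1 / gap) %*% exp(1i * phases)) / n
}

check_pair_resonances <- function(omega, a = NULL) {
  gap <- abs(outer(omega, omega, "-"))
  diag(gap) <- Inf
  bad <- if (is.null(a)) gap < EPS_RES else gap < EPS_RES & a > 0
  if (any(bad)) {
    kk <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("near-resonant pair (%d, %d)", kk[1], kk[2]), "near_resonance")
  }
}

#' Full theoretical desynchronising control term
#'
#' The order-`K^2` control contribution to the phase velocity of node `k` on
#' an arbitrary symmetric (possibly weighted) network: a three-part bracket of
#' frequency-difference-weighted cosine/sine sums scaled by `-K^2 / (4 N^2)`.
#' Terms with a vanishing frequency denominator never arise on a zero-diagonal
#' adjacency; near-resonant connected pairs raise an error.
#'
#' @param phases Phase vector.
#' @param omega Natural frequencies (pairwise distinct).
#' @param K Coupling strength.
#' @param net An [oscillator_network()].
#' @param k Node index, or `NULL` for the full length-N vector.
#' @return Scalar control term `h_k` (or vector over all nodes).
#' @export
control_full <- function(phases, omega, K, net, k = NULL) {
  n <- length(phases)
  if (net$n_nodes != n || length(omega) != n)
    abort("dimension mismatch", "dimension_mismatch")
  a <- net$adjacency
  check_pair_resonances(omega, a)
  gap <- outer(omega, omega, "-")
  diag(gap) <- Inf
  g <- a / gap                           # g[j, l] = A_jl / (omega_j - omega_l)
  s <- sin(phases); c <- cos(phases)
  # column l of the inner sums: C_l = sum_j A_jl cos(phi_j - phi_l)/(omega_j - omega_l)
  #                             S_l = sum_j A_jl sin(phi_j - phi_l)
  C_in <- (crossprod(g, c) * c + crossprod(g, s) * s)  # cos(a-b) expansion
  C_in <- as.vector(C_in)
  S_in <- as.vector(crossprod(a, s) * c - crossprod(a, c) * s)
  ks <- if (is.null(k)) seq_len(n) else check_count(k, "k")
  if (any(ks > n)) abort("node index out of range", "invalid_parameter")
  h <- vapply(ks, function(kk) {
    dc <- cos(phases - phases[kk])       # cos(phi_j - phi_k)
    ds <- sin(phases - phases[kk])       # sin(phi_j - phi_k)
    t1 <- sum(a[kk, ] * dc) * sum(g[, kk] * dc)
    t2 <- sum(g[, kk] * ds) * sum(a[kk, ] * ds)
    # third bracket: outer sum over l; note cos(phi_k - phi_l) = dc,
    # sin(phi_k - phi_l) = -ds, and A_kl/(omega_k - omega_l) = -g[, kk]
    t3 <- sum(a[kk, ] * dc * C_in + (-g[, kk]) * (-ds) * S_in)
    -(K^2 / (4 * n^2)) * (t1 + t2 - t3)
  }, numeric(1))
  if (is.null(k)) h else h[[1]]
}

#' Correction term B_k of the all-to-all control
#'
#' The oscillatory-average correction appearing in the all-to-all closed form
#' of the control: two sums over nodes `l`, both normalised by `1/N`, built
#' from the modified local order parameters and the global order parameter.
#' The second sum excludes `l = k` (singular frequency denominator).
#'
#' @inheritParams control_full
#' @param k Node index, or `NULL` for the full vector.
#' @return Scalar `B_k` (or vector over all nodes).
#' @export
b_term <- function(phases, omega, k = NULL) {
  n <- length(phases)
  check_frequencies(omega, n)
  mt <- modified_order_all(phases, omega)
  op <- order_parameter(phases)
  # Rt_l * cos(Psi_l - phi_l) without extracting the angle explicitly
  proj <- Re(mt * exp(-1i * phases))
  zg <- op$R * exp(1i * op$Psi)
  sin_psi_phi <- Im(zg * exp(-1i * phases)) # R sin(Psi - phi_l)
  gap <- outer(omega, omega, "-")           # gap[k, l] = omega_k - omega_l
  diag(gap) <- Inf
  ks <- if (is.null(k)) seq_len(n) else check_count(k, "k")
  if (any(ks > n)) abort("node index out of range", "invalid_parameter")
  b <- vapply(ks, function(kk) {
    dc <- cos(phases[kk] - phases)
    ds <- sin(phases[kk] - phases)
    (sum(dc * proj) + sum(ds * sin_psi_phi / gap[kk, ])) / n
  }, numeric(1))
  if (is.null(k)) b else b[[1]]
}

#' All-to-all closed form of the control term
#'
#' Under all-to-all coupling the full control term reduces to
#' `h_k = -(K^2/4) * (R * Rt_k * cos(Psi - Psi_k) - B_k)`, with `(R, Psi)` the
#' global order parameter, `(Rt_k, Psi_k)` the frequency-weighted local one
#' and `B_k` from [b_term()]. Agrees with [control_full()] on complete graphs
#' to machine precision.
#'
#' @inheritParams b_term
#' @param K Coupling strength.
#' @return Scalar `h_k` (or vector over all nodes).
#' @export
control_alltoall <- function(phases, omega, K, k = NULL) {
  n <- length(phases)
  check_frequencies(omega, n)
  mt <- modified_order_all(phases, omega)
  zg <- mean(exp(1i * phases))            # R exp(i Psi)
  main <- Re(zg * Conj(mt))               # R * Rt_k * cos(Psi - Psi_k)
  b <- b_term(phases, omega)
  h <- -(K^2 / 4) * (main - b)
  if (is.null(k)) h else h[[check_count(k, "k")]]
}

#' Operational M-electrode control signal
#'
#' The implementable simplification of the control: for an electrode-bearing
#' node `k`,
#' `hh_k = -(gamma/4) * K^2 * R * Rh_k * cos(Psi - phi_k)`,
#' where `Rh_k` is the electrode-sampled modified order parameter
#' ([sampled_modified_order()]) and the local mean-field angle `Psi_k` of the
#' closed form is replaced by the node's own phase `phi_k`. The cosine is the
#' Kuramoto coupling signal advanced by a quarter period
#' (`cos(x) = sin(x + pi/2)`), so the scheme realises quarter-period-delayed
#' re-injection without simulating an actual delay.
#'
#' @inheritParams control_full
#' @param layout An [electrode_layout()] carrying the gain `gamma`.
#' @param mode `"global-R"` uses the order parameter of all `N` phases (the
#'   form as printed); `"sampled-R"` estimates `(R, Psi)` from the `M`
#'   electrode phases only (strict operational realism).
#' @param k Electrode-bearing node index, or `NULL` for the vector over all
#'   electrodes (in `layout$electrode_nodes` order).
#' @return Scalar `hh_k` (or length-M vector).
#' @export
operational_control <- function(phases, omega, K, layout,
                                mode = c("global-R", "sampled-R"), k = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(layout, "electrode_layout"))
  el <- layout$electrode_nodes
  if (!is.null(k) && !(k %in% el))
    abort("k is not an electrode-bearing node", "invalid_parameter")
  op <- if (mode == "global-R") order_parameter(phases)
        else order_parameter(phases[el])
  rh <- vapply(el, function(kk)
    sampled_modified_order(phases, omega, layout, kk)$R, numeric(1))
  h <- -(layout$gamma / 4) * K^2 * op$R * rh * cos(op$Psi - phases[el])
  if (is.null(k)) h else h[[match(k, el)]]
}

#' Stimulation field produced by the microelectrodes
#'
#' Each electrode `l` injects its control signal `hh_l`; the field reaching
#' node `k` decays exponentially with distance, giving
#' `S_k = c_s * sum_l exp(-2 r_kl) * hh_l`. For an electrode-bearing node this
#' is its own (undecayed) control plus the field of the other `M - 1`
#' electrodes.
#'
#' @param controls Length-M vector of per-electrode control signals, in
#'   `layout$electrode_nodes` order.
#' @param layout An [electrode_layout()].
#' @param k Node index, or `NULL` for the full length-N field vector.
#' @return Scalar `S_k` (or length-N vector).
#' @export
stimulation_field <- function(controls, layout, k = NULL) {
  stopifnot(inherits(layout, "electrode_layout"))
  if (length(controls) != length(layout$electrode_nodes))
    abort("one control value per electrode required", "dimension_mismatch")
  s <- layout$c_s * as.vector(exp(-2 * layout$distances) %*% controls)
  if (is.null(k)) s else s[[check_count(k, "k")]]
}

#' Controlled Kuramoto right-hand side
#'
#' The uncontrolled phase velocities ([km_rhs_network()] or
#' [km_rhs_meanfield()]) plus the stimulation field of the operational
#' control at every node.
#'
#' @inheritParams km_rhs_network
#' @inheritParams operational_control
#' @param meanfield If `TRUE` use the mean-field coupling term (exact on
#'   all-to-all topologies); otherwise the networked sum over `net`.
#' @return Phase-velocity vector of length N.
#' @export
controlled_km_rhs <- function(phases, omega, K, net = NULL, layout,
                              mode = c("global-R", "sampled-R"),
                              meanfield = is.null(net)) {
  mode <- match.arg(mode)
  base <- if (meanfield) km_rhs_meanfield(phases, omega, K)
          else km_rhs_network(phases, omega, K, net)
  hh <- operational_control(phases, omega, K, layout, mode)
  base + stimulation_field(hh, layout)
}

#' Save / load an electrode layout as JSON
#'
#' Node indices are written 0-based on disk (the package's file convention)
#' and restored to 1-based on load.
#'
#' @param layout An [electrode_layout()].
#' @param path JSON file path.
#' @return `save_layout` returns `path` invisibly; `load_layout` the layout.
#' @export
save_layout <- function(layout, path) {
  jsonlite::write_json(
    list(electrode_nodes = layout$electrode_nodes - 1L,
         distances = layout$distances, c_s = layout$c_s,
         gamma = layout$gamma),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_layout
#' @export
load_layout <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  electrode_layout(x$electrode_nodes + 1L, as.matrix(x$distances),
                   c_s = x$c_s, gamma = x$gamma)
}
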