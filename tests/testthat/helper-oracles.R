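# Independent oracles and small fixtures shared across the test files.

# SSE log-likelihood by an independent route: deSolve::lsoda along each
# branch and a plain R postorder recursion, no rescaling (small trees
# only).  Shares no code with the package's C++ integrator.
sse_loglik_desolve <- function(tree, tip_states_int, lambda, mu, Q,
                               prior, condition_survival = TRUE) {
  S <- length(lambda)
  Qo <- Q
  diag(Qo) <- 0
  rowq <- rowSums(Qo)
  deriv <- function(t, y, parms) {
    E <- y[1:S]
    D <- y[(S + 1):(2 * S)]
    dE <- mu - (lambda + mu + rowq) * E + lambda * E^2 + as.numeric(Qo %*% E)
    dD <- -(lambda + mu + rowq) * D + 2 * lambda * E * D +
      as.numeric(Qo %*% D)
    list(c(dE, dD))
  }
  ntip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth) - depth
  h[1:ntip] <- 0
  po <- reorder(tree, "postorder")
  prodD <- matrix(1, ntip + tree$Nnode, S)
  Enode <- matrix(0, ntip + tree$Nnode, S)
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; chi <- po$edge[e, 2]
    if (chi <= ntip) {
      D0 <- rep(0, S); D0[tip_states_int[chi]] <- 1
      y0 <- c(rep(0, S), D0)
    } else {
      y0 <- c(Enode[chi, ], prodD[chi, ] * lambda)
    }
    out <- deSolve::lsoda(y0, c(h[chi], h[par]), deriv, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    yT <- out[nrow(out), -1]
    prodD[par, ] <- prodD[par, ] * yT[(S + 1):(2 * S)]
    Enode[par, ] <- yT[1:S]
  }
  root <- ntip + 1
  d <- prodD[root, ] * lambda
  if (condition_survival)
    d <- d / (lambda * (1 - Enode[root, ])^2)
  log(sum(prior * d))
}

# Markov (Mk) tip-state likelihood by matrix exponentials
mk_loglik_expm <- function(tree, tip_states_int, Q, prior) {
  Qg <- Q
  diag(Qg) <- 0
  diag(Qg) <- -rowSums(Qg)
  S <- nrow(Qg)
  ntip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth) - depth
  h[1:ntip] <- 0
  po <- reorder(tree, "postorder")
  prodD <- matrix(1, ntip + tree$Nnode, S)
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; chi <- po$edge[e, 2]
    D0 <- if (chi <= ntip) {
      v <- rep(0, S); v[tip_states_int[chi]] <- 1; v
    } else prodD[chi, ]
    P <- as.matrix(Matrix::expm(Qg * (h[par] - h[chi])))
    prodD[par, ] <- prodD[par, ] * as.numeric(P %*% D0)
  }
  log(sum(prior * prodD[ntip + 1, ]))
}

# hand-built simulation snapshot in the shape sim_state() returns,
# for direct unit tests of the metrics
fake_state <- function(populations, species, band_cell_counts) {
  n_bands <- length(band_cell_counts)
  rich <- vapply(seq_len(n_bands) - 1L, function(b)
    length(unique(populations$species_id[populations$band == b])), 0L)
  list(time = 0, n_events = 0,
       populations = populations, species = species,
       band_richness = rich,
       regional_richness = length(unique(populations$species_id)),
       band_cell_counts = band_cell_counts)
}

# small landscape where colonization can never succeed once saturated:
# every cell at K = 1 occupied by the same species
frozen_saturated_sim <- function(seed = 1) {
  land <- suppressWarnings(
    build_banded_landscape(24, rep(0.25, 4), band_K = rep(1L, 4),
                           band_lambda = rep(1e-7, 4)))
  cfg <- scenario_config(gamma = 1, mu = 1e-7, base_lambda = 1e-7,
                         base_K = 1, seed = seed, log_events = TRUE)
  sim <- sim_init(cfg, landscape = land)
  # fill the whole landscape deterministically
  for (i in 1:200) {
    st <- sim_state(sim)
    if (nrow(st$populations) == nrow(land$cells)) break
    p <- st$populations[sample.int(nrow(st$populations), 1), ]
    sim_force_event(sim, "colonization", p$species_id, p$cell_id)
  }
  stopifnot(nrow(sim_state(sim)$populations) == nrow(land$cells))
  sim
}

# initialize a simulation and run until it holds at least `target`
# populations, redrawing the seed if the clade dies first
grow_sim <- function(cfg, land, target = 200, max_tries = 50) {
  for (k in seq_len(max_tries)) {
    cfg$seed <- cfg$seed + (k - 1L) * 1013L
    sim <- sim_init(cfg, landscape = land)
    repeat {
      status <- sim_run(sim, 500)
      n <- nrow(sim_state(sim)$populations)
      if (n == 0L || status == "extinct") break
      if (n >= target) return(sim)
    }
  }
  stop("no replicate grew to ", target, " populations")
}
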