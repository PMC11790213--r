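# Gillespie engine: fitness weights, initialization, event semantics,
# bookkeeping invariants and determinism.

test_that("local-adaptation fitness matches the stabilizing-selection form", {
  expect_equal(local_adaptation_fitness(20, 20, V = 5), 1)
  expect_equal(local_adaptation_fitness(20, 15, V = 5), exp(-2.5),
               tolerance = 1e-12)
  expect_equal(local_adaptation_fitness(15, 20, V = 5), exp(-2.5))
  # huge V effectively disables selection even across a whole band step
  expect_equal(local_adaptation_fitness(20, 15, V = 10000), 0.9987508,
               tolerance = 1e-6)
  expect_true(all(diff(local_adaptation_fitness(20, 20 - 0:5, V = 5)) < 0))
  expect_error(local_adaptation_fitness(20, 15, V = 0), "V")
  expect_error(local_adaptation_fitness(20, 15, V = -1), "V")
})

test_that("founder starts alone, in the right band, perfectly adapted", {
  cfg <- scenario_config(origin = "lowland", seed = 5)
  sim <- sim_init(cfg)
  st <- sim_state(sim)
  expect_identical(nrow(st$populations), 1L)
  expect_identical(st$populations$band, 0L)
  expect_equal(st$populations$temperature_preference, 20)
  expect_identical(st$regional_richness, 1L)

  cfg_h <- scenario_config(origin = "highland", seed = 5)
  st_h <- sim_state(sim_init(cfg_h))
  expect_identical(st_h$populations$band, 3L)
  expect_equal(st_h$populations$temperature_preference, 5)

  # same seed, same founding cell; different seed, usually different
  again <- sim_state(sim_init(cfg))
  expect_identical(again$populations$cell_id, st$populations$cell_id)
})

test_that("total event rate sums gamma + mu + band lambda over populations", {
  land <- suppressWarnings(
    build_banded_landscape(40, rep(0.25, 4), band_K = rep(5, 4),
                           band_lambda = c(1, 2, 3, 4) / 10))
  cfg <- scenario_config(gamma = 1 / 3, mu = 1 / 3, base_lambda = 1 / 3,
                         seed = 3)
  sim <- sim_init(cfg, landscape = land)
  st <- sim_state(sim)
  lam_b <- land$band_lambda[st$populations$band + 1]
  expect_equal(sim_total_rate(sim), sum(1 / 3 + 1 / 3 + lam_b))

  # grow the clade and re-check against the recomputed sum
  sim_run(sim, 500)
  st <- sim_state(sim)
  lam_b <- land$band_lambda[st$populations$band + 1]
  expect_equal(sim_total_rate(sim),
               nrow(st$populations) * (1 / 3 + 1 / 3) + sum(lam_b))
})

test_that("waiting times are exponential at the total rate (KS, alpha 0.01)", {
  sim <- frozen_saturated_sim(seed = 42)
  rate <- sim_total_rate(sim)
  t0 <- sim_state(sim)$time
  set.seed(99)
  sim_run(sim, 1e4)
  log <- sim_event_log(sim)
  waits <- diff(c(t0, log$time[log$time > t0]))
  expect_gte(length(waits), 1e4 - 1)
  ks <- suppressWarnings(stats::ks.test(waits, "pexp", rate))
  expect_gt(ks$p.value, 0.01)
})

test_that("event kinds are drawn proportionally to their rates (chi-squared)", {
  # gamma : mu : lambda = 2 : 1 : 1 -> colonization attempts ~ 50% of events
  land <- suppressWarnings(
    build_banded_landscape(100, rep(0.25, 4), band_K = rep(20, 4),
                           band_lambda = rep(0.5, 4)))
  cfg <- scenario_config(gamma = 1, mu = 0.5, base_lambda = 0.5,
                         base_K = 20, seed = 17, log_events = TRUE,
                         max_events = 4e4)
  # grow the clade first so extinction cannot cut the sample short
  sim <- grow_sim(cfg, land, target = 200)
  t_grown <- sim_state(sim)$time
  sim_run(sim, 4e4)
  log <- sim_event_log(sim)
  log <- log[log$time > t_grown, ]
  counts <- c(
    colonization = sum(log$kind %in% c("colonization", "colonization_blocked",
                                       "colonization_rejected")),
    extirpation = sum(log$kind == "extirpation"),
    speciation = sum(log$kind %in% c("speciation", "anagenesis")))
  counts["colonization"] <- counts["colonization"] - 0  # attempts, not successes
  chi <- stats::chisq.test(counts, p = c(0.5, 0.25, 0.25))
  expect_gt(chi$p.value, 0.01)
  expect_equal(unname(counts["colonization"] / sum(counts)), 0.5,
               tolerance = 0.02)
  expect_gt(sum(counts), 3e4)
})

test_that("colonization creates an adjacent population with N(0,1) preference drift", {
  land <- suppressWarnings(
    build_banded_landscape(100, rep(0.25, 4), band_K = rep(1e6, 4)))
  cfg <- scenario_config(seed = 1, base_K = 1e6)
  set.seed(2024)
  drift <- numeric(400)
  for (i in seq_along(drift)) {
    sim <- sim_init(scenario_config(), landscape = land)
    st0 <- sim_state(sim)
    sim_force_event(sim, "colonization", st0$populations$species_id,
                    st0$populations$cell_id)
    st1 <- sim_state(sim)
    expect_identical(nrow(st1$populations), 2L)
    newp <- st1$populations[st1$populations$cell_id !=
                              st0$populations$cell_id, ]
    expect_true(newp$cell_id %in%
                  land$adjacency[[st0$populations$cell_id]])
    drift[i] <- newp$temperature_preference -
      st0$populations$temperature_preference
  }
  expect_lt(abs(mean(drift)), 3 / sqrt(length(drift)))   # mean ~ 0
  expect_gt(sd(drift), 0.85)                             # sd ~ 1
  expect_lt(sd(drift), 1.15)
})

test_that("colonization into a fully saturated neighborhood is a no-op", {
  sim <- frozen_saturated_sim(seed = 7)
  st0 <- sim_state(sim)
  p <- st0$populations[1, ]
  sim_force_event(sim, "colonization", p$species_id, p$cell_id)
  st1 <- sim_state(sim)
  expect_identical(nrow(st1$populations), nrow(st0$populations))
  log <- sim_event_log(sim)
  expect_identical(as.character(log$kind[nrow(log)]), "colonization_blocked")
})

test_that("local adaptation off accepts any mismatch; strong selection rejects", {
  land <- suppressWarnings(
    build_banded_landscape(100, rep(0.25, 4), band_K = rep(1e6, 4)))
  # focal population with preference far from every neighbour still spreads
  # when local adaptation is off (success probability 1)
  cfg_off <- scenario_config(local_adaptation = FALSE, seed = 30)
  set.seed(31)
  sim <- sim_init(cfg_off, landscape = land)
  p <- sim_state(sim)$populations
  for (i in 1:10) sim_force_event(sim, "colonization", 1, p$cell_id)
  expect_gt(nrow(sim_state(sim)$populations), 1L)

  # with local adaptation and a 5-degree band step the success odds are
  # exp(-2.5) ~ 0.082 per attempt
  n_succ <- 0
  set.seed(32)
  for (r in 1:200) {
    simb <- sim_init(scenario_config(local_adaptation = TRUE, V = 5,
                                     origin = "highland"),
                     landscape = suppressWarnings(
                       build_banded_landscape(20, c(0.5, 0.5),
                                              band_K = c(1, 1))))
    stb <- sim_state(simb)
    sim_force_event(simb, "colonization", stb$populations$species_id,
                    stb$populations$cell_id)
    n_succ <- n_succ + (nrow(sim_state(simb)$populations) - 1L)
  }
  # attempts mix same-band (always accepted) and cross-band targets, so the
  # overall success rate must sit strictly between exp(-2.5) and 1
  expect_gt(n_succ, 0)
  expect_lt(n_succ, 200)
})

test_that("extirpation removes one population; losing the last one kills the species", {
  land <- suppressWarnings(
    build_banded_landscape(40, rep(0.25, 4), band_K = rep(5, 4)))
  sim <- sim_init(scenario_config(seed = 8), landscape = land)
  st0 <- sim_state(sim)
  p <- st0$populations
  sim_force_event(sim, "colonization", p$species_id, p$cell_id)
  st1 <- sim_state(sim)
  expect_identical(nrow(st1$populations), 2L)

  # species with two populations survives losing one
  target <- st1$populations[1, ]
  occ_before <- st1$occupancy[target$cell_id]
  sim_force_event(sim, "extirpation", target$species_id, target$cell_id)
  st2 <- sim_state(sim)
  expect_identical(st2$regional_richness, 1L)
  expect_identical(nrow(st2$populations), 1L)
  expect_identical(st2$occupancy[target$cell_id], occ_before - 1L)

  # losing the last population is species extinction
  last <- st2$populations[1, ]
  sim_force_event(sim, "extirpation", last$species_id, last$cell_id)
  st3 <- sim_state(sim)
  expect_identical(st3$regional_richness, 0L)
  expect_identical(sim_total_rate(sim), 0)
})

test_that("speciation conserves populations and tags the origin band", {
  land <- suppressWarnings(
    build_banded_landscape(40, rep(0.25, 4), band_K = rep(5, 4)))
  sim <- sim_init(scenario_config(seed = 12, log_events = TRUE),
                  landscape = land)
  p <- sim_state(sim)$populations
  sim_force_event(sim, "colonization", p$species_id, p$cell_id)
  st1 <- sim_state(sim)

  focal <- st1$populations[2, ]
  sim_force_event(sim, "speciation", focal$species_id, focal$cell_id)
  st2 <- sim_state(sim)
  expect_identical(nrow(st2$populations), 2L)       # conserved
  expect_identical(st2$regional_richness, 2L)
  newsp <- st2$species[st2$species$species_id != p$species_id, ]
  expect_identical(newsp$n_populations, 1L)         # range of one cell
  expect_identical(newsp$origin_band, focal$band)
  expect_identical(newsp$parent_species_id, focal$species_id)
  # preference inherited unchanged at speciation
  tp_new <- st2$populations$temperature_preference[
    st2$populations$species_id == newsp$species_id]
  expect_equal(tp_new, focal$temperature_preference)

  # single-population parent: anagenetic replacement, species count flat
  focal2 <- st2$populations[st2$populations$species_id == newsp$species_id, ]
  sim_force_event(sim, "speciation", focal2$species_id, focal2$cell_id)
  st3 <- sim_state(sim)
  expect_identical(st3$regional_richness, 2L)
  expect_false(newsp$species_id %in% st3$species$species_id)
  log <- sim_event_log(sim)
  expect_identical(as.character(log$kind[nrow(log)]), "anagenesis")
})

test_that("occupancy never exceeds K and incremental counters match recounts", {
  cfg <- scenario_config(seed = 21, log_events = FALSE)
  sim <- sim_init(cfg)
  for (chunk in 1:6) {
    sim_run(sim, 2e4)
    expect_true(sim_check_consistency(sim))
    st <- sim_state(sim)
    K_cell <- sim$landscape$band_K[sim$landscape$cells$band + 1]
    expect_true(all(st$occupancy <= K_cell))
    expect_identical(sum(st$occupancy), nrow(st$populations))
  }
})

test_that("near-zero extirpation saturates richness below the slot bound", {
  land <- suppressWarnings(
    build_banded_landscape(40, rep(0.25, 4), band_K = rep(3, 4),
                           band_lambda = rep(0.1, 4)))
  cfg <- scenario_config(mu = 1e-9, base_lambda = 0.1, base_K = 3,
                         seed = 33, max_events = 3e4, log_events = FALSE)
  sim <- sim_init(cfg, landscape = land)
  sim_run(sim, 3e4)
  st <- sim_state(sim)
  expect_lte(st$regional_richness, sum(40 * 3))
  expect_identical(nrow(st$populations), sum(st$occupancy))
  # every cell is saturated by then
  expect_true(all(st$occupancy == 3))
})

test_that("a death-dominated clade goes extinct and is flagged", {
  cfg <- scenario_config(gamma = 0.05, mu = 2, base_lambda = 0.01, seed = 2)
  res <- run_simulation(cfg)
  expect_true(res$extinct)
  expect_identical(res$status, "extinct")
  expect_identical(res$state$regional_richness, 0L)
})

test_that("identical config and seed give bit-identical runs", {
  cfg <- scenario_config(seed = 77, total_cells = 100, max_events = 3e4,
                         log_events = TRUE, max_time = 25)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$event_log, r2$event_log)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$state$populations, r2$state$populations)
})

test_that("very weak selection (V = 1e6) is indistinguishable from no local adaptation", {
  land <- build_cone_landscape(100)
  rich_off <- rich_on <- matrix(NA_real_, 30, 4)
  for (r in 1:30) {
    cfg_off <- scenario_config(local_adaptation = FALSE, total_cells = 100,
                               seed = 4000 + r, max_time = 20,
                               max_events = 2e5)
    cfg_on <- scenario_config(local_adaptation = TRUE, V = 1e6,
                              total_cells = 100, seed = 8000 + r,
                              max_time = 20, max_events = 2e5)
    rich_off[r, ] <- run_simulation(cfg_off, landscape = land)$state$band_richness
    rich_on[r, ] <- run_simulation(cfg_on, landscape = land)$state$band_richness
  }
  p <- vapply(1:4, function(b)
    stats::wilcox.test(rich_off[, b], rich_on[, b], exact = FALSE)$p.value,
    0)
  expect_true(all(stats::p.adjust(p, "holm") > 0.01))
})

test_that("with equal band areas and uniform rates no band is favoured", {
  land <- build_banded_landscape(400, rep(0.25, 4))
  rich <- matrix(NA_real_, 50, 4)
  for (r in 1:50) {
    cfg <- scenario_config(seed = 12000 + r, max_time = 20,
                           max_events = 2e5)
    res <- run_simulation(cfg, landscape = land)
    if (res$extinct) next
    rich[r, ] <- res$state$band_richness
  }
  rich <- rich[stats::complete.cases(rich), ]
  long <- data.frame(richness = as.vector(rich),
                     band = factor(rep(0:3, each = nrow(rich))))
  kw <- stats::kruskal.test(richness ~ band, data = long)
  expect_gt(kw$p.value, 0.01)
})
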