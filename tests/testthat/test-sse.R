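# SSE module: band discretizer, model enumeration, likelihood against
# independent oracles, fitting and AIC weights, tree simulation.

test_that("elevations split into equal thirds with boundaries going down", {
  b <- assign_bands(c(a = 0, b = 1500, c = 3000))
  expect_identical(as.character(b$bands),
                   c("lowland", "midland", "highland"))
  expect_equal(unname(b$boundaries), c(0, 1000, 2000, 3000))

  # clade extremes sit in the outer bands
  b2 <- assign_bands(c(lo = 100, mid = 1600, hi = 2800))
  expect_identical(as.character(b2$bands[c("lo", "hi")]),
                   c("lowland", "highland"))

  # a species exactly on a cut point goes to the lower band
  b3 <- assign_bands(c(x = 600, y = 900, z = 1500))
  expect_identical(as.character(b3$bands[["y"]]), "lowland")

  expect_error(assign_bands(c(a = 100, b = 100)), "degenerate")
  expect_error(assign_bands(c(100, 200)), "named")
})

test_that("the candidate set enumerates exactly fifteen models", {
  models <- enumerate_models()
  expect_length(models, 15L)
  expect_identical(anyDuplicated(names(models)), 0L)

  k_trans <- c(a = 1L, b = 2L, c = 1L, d = 2L, e = 6L)
  for (m in models) {
    k_div <- c(CR = 2L, ETD = 6L, CTD = 6L)[[m$div_structure]]
    expect_identical(m$k, k_div + k_trans[[m$transition_structure]])
    expect_identical(m$n_states,
                     if (m$div_structure == "CTD") 9L else 3L)
  }
})

test_that("transition templates encode adjacency and symmetry", {
  ra <- sse_build_rates(sse_model_spec("a", "CR"),
                        c(lambda = 1, mu = 0.1, q = 0.3))
  expect_equal(ra$Q[1, 3], 0)           # no lowland <-> highland jumps
  expect_equal(ra$Q[3, 1], 0)
  expect_equal(ra$Q[1, 2], 0.3)
  expect_equal(ra$Q[2, 1], 0.3)         # symmetric

  rb <- sse_build_rates(sse_model_spec("b", "CR"),
                        c(lambda = 1, mu = 0.1, q_up = 0.3, q_down = 0.1))
  expect_equal(rb$Q[1, 2], 0.3)
  expect_equal(rb$Q[2, 1], 0.1)
  expect_equal(rb$Q[1, 3], 0)

  rd <- sse_build_rates(sse_model_spec("d", "CR"),
                        c(lambda = 1, mu = 0.1, q_up = 0.3, q_down = 0.1))
  expect_equal(rd$Q[1, 3], 0.3)         # direct lowland -> highland allowed

  # CTD: 9 states, concealed transitions mirror the structure, no dual moves
  rc <- sse_build_rates(sse_model_spec("a", "CTD"),
                        c(lambda_A = 1, lambda_B = 2, lambda_C = 3,
                          mu_A = .1, mu_B = .2, mu_C = .3, q = 0.3))
  expect_identical(dim(rc$Q), c(9L, 9L))
  expect_equal(rc$lambda, rep(1:3, each = 3))
  expect_equal(rc$Q[1, 2], 0.3)         # observed move, concealed fixed
  expect_equal(rc$Q[1, 4], 0.3)         # concealed move, observed fixed
  expect_equal(rc$Q[1, 5], 0)           # dual transition forbidden
  expect_equal(rc$Q[1, 7], 0)           # concealed A -> C is non-adjacent
  expect_error(sse_build_rates(sse_model_spec("a", "CR"),
                               c(lambda = 1, mu = -0.1, q = 0.3)), ">= 0")
})

test_that("state-independent rates factorize into birth-death times Markov", {
  set.seed(7)
  spec <- sse_model_spec("a", "CR")
  sim <- simulate_sse_tree(spec, c(lambda = 0.4, mu = 0.1, q = 0.15),
                           ntip = 10)
  pars <- c(lambda = 0.4, mu = 0.1, q = 0.15)
  rates <- sse_build_rates(spec, pars)
  prior <- elevclade:::.stationary_dist(rates$Q)
  st_int <- as.integer(sim$tip_states[sim$tree$tip.label])

  ll_sse <- sse_loglik(sim$tree, sim$tip_states, spec, pars)
  ll_bd <- bd_constant_loglik(sim$tree, 0.4, 0.1)
  ll_mk <- mk_loglik_expm(sim$tree, st_int, rates$Q, prior)
  expect_equal(ll_sse, ll_bd + ll_mk, tolerance = 1e-6)

  # and both conditionings agree with the separately coded ODE oracle
  ll_or <- sse_loglik_desolve(sim$tree, st_int, rates$lambda, rates$mu,
                              rates$Q, prior, condition_survival = TRUE)
  expect_equal(ll_sse, ll_or, tolerance = 1e-6)
})

test_that("constant-rate limit matches the closed form up to 50 tips", {
  set.seed(21)
  for (n in c(20, 50)) {
    sim <- simulate_sse_tree(sse_model_spec("a", "CR"),
                             c(lambda = 0.5, mu = 0.15, q = 0.1), ntip = n)
    pars <- c(lambda = 0.45, mu = 0.12, q = 0.2)
    rates <- sse_build_rates(sse_model_spec("a", "CR"), pars)
    prior <- elevclade:::.stationary_dist(rates$Q)
    st_int <- as.integer(sim$tip_states[sim$tree$tip.label])
    ll_sse <- sse_loglik(sim$tree, sim$tip_states,
                         sse_model_spec("a", "CR"), pars)
    ll_split <- bd_constant_loglik(sim$tree, 0.45, 0.12) +
      mk_loglik_expm(sim$tree, st_int, rates$Q, prior)
    expect_equal(ll_sse, ll_split, tolerance = 1e-6)
  }
})

test_that("state-dependent likelihood agrees with the deSolve oracle", {
  set.seed(31)
  spec <- sse_model_spec("b", "ETD")
  pars <- c(lambda_lowland = 0.3, lambda_midland = 0.45,
            lambda_highland = 0.6, mu_lowland = 0.05, mu_midland = 0.1,
            mu_highland = 0.2, q_up = 0.15, q_down = 0.08)
  sim <- simulate_sse_tree(spec, pars, ntip = 12)
  rates <- sse_build_rates(spec, pars)
  prior <- elevclade:::.stationary_dist(rates$Q)
  st_int <- as.integer(sim$tip_states[sim$tree$tip.label])
  for (cond in c(TRUE, FALSE)) {
    ll <- sse_loglik(sim$tree, sim$tip_states, spec, pars,
                     condition_survival = cond)
    ll_or <- sse_loglik_desolve(sim$tree, st_int, rates$lambda, rates$mu,
                                rates$Q, prior, condition_survival = cond)
    expect_equal(ll, ll_or, tolerance = 1e-6)
  }
})

test_that("relabelling states with permuted parameters leaves the likelihood unchanged", {
  set.seed(41)
  spec <- sse_model_spec("e", "ETD")
  pars <- c(lambda_lowland = 0.3, lambda_midland = 0.5,
            lambda_highland = 0.4, mu_lowland = 0.1, mu_midland = 0.05,
            mu_highland = 0.15, q12 = 0.1, q13 = 0.03, q21 = 0.07,
            q23 = 0.12, q31 = 0.02, q32 = 0.09)
  sim <- simulate_sse_tree(spec, pars, ntip = 10)
  ll1 <- sse_loglik(sim$tree, sim$tip_states, spec, pars,
                    root_prior = "flat")

  # swap lowland <-> highland everywhere
  flip <- c(lowland = "highland", midland = "midland", highland = "lowland")
  st_flip <- factor(flip[as.character(sim$tip_states)],
                    levels = levels(sim$tip_states))
  names(st_flip) <- names(sim$tip_states)
  pars_flip <- c(lambda_lowland = 0.4, lambda_midland = 0.5,
                 lambda_highland = 0.3, mu_lowland = 0.15, mu_midland = 0.05,
                 mu_highland = 0.1, q12 = 0.09, q13 = 0.02, q21 = 0.12,
                 q23 = 0.07, q31 = 0.03, q32 = 0.1)
  ll2 <- sse_loglik(sim$tree, st_flip, spec, pars_flip, root_prior = "flat")
  expect_equal(ll1, ll2, tolerance = 1e-9)
})

test_that("vanishing transition rates make multi-state data impossible", {
  set.seed(51)
  sim <- simulate_sse_tree(sse_model_spec("a", "CR"),
                           c(lambda = 0.5, mu = 0.1, q = 0.3), ntip = 15)
  expect_gte(length(unique(sim$tip_states)), 2)  # histories need >= 1 shift
  ll0 <- sse_loglik(sim$tree, sim$tip_states, sse_model_spec("a", "CR"),
                    c(lambda = 0.5, mu = 0.1, q = 0), root_prior = "flat")
  expect_identical(ll0, -Inf)
})

test_that("a freer nested structure never fits worse", {
  set.seed(61)
  sim <- simulate_sse_tree(sse_model_spec("a", "CR"),
                           c(lambda = 0.5, mu = 0.1, q = 0.15), ntip = 40)
  fa <- fit_sse_model(sim$tree, sim$tip_states, sse_model_spec("a", "CR"),
                      n_starts = 2)
  fb <- fit_sse_model(sim$tree, sim$tip_states, sse_model_spec("b", "CR"),
                      n_starts = 2)
  expect_gte(fb$logL, fa$logL - 1e-4)   # a is b with q_up = q_down
})

test_that("the fitted optimum is a local maximum in the generating parameters", {
  set.seed(71)
  spec <- sse_model_spec("a", "CR")
  sim <- simulate_sse_tree(spec, c(lambda = 0.5, mu = 0.1, q = 0.1),
                           ntip = 50)
  fit <- fit_sse_model(sim$tree, sim$tip_states, spec, n_starts = 2)
  ll_hat <- sse_loglik(sim$tree, sim$tip_states, spec, fit$params)
  for (p in names(fit$params)) {
    for (f in c(0.7, 1.4)) {
      pert <- fit$params
      pert[p] <- pert[p] * f
      expect_lt(sse_loglik(sim$tree, sim$tip_states, spec, pert),
                ll_hat + 1e-6)
    }
  }
})

test_that("AIC weights normalize and degenerate sets behave", {
  set.seed(81)
  sim <- simulate_sse_tree(sse_model_spec("a", "CR"),
                           c(lambda = 0.5, mu = 0.1, q = 0.1), ntip = 10)
  one <- fit_model_set(sim$tree, sim$tip_states,
                       models = enumerate_models()["a_CR"], n_starts = 1)
  expect_equal(one$table$weight, 1)

  # identical models must share the weight equally
  same <- fit_model_set(sim$tree, sim$tip_states,
                        models = setNames(rep(enumerate_models()["a_CR"], 5),
                                          paste0("m", 1:5)), n_starts = 1)
  expect_equal(same$table$weight, rep(1 / 5, 5), tolerance = 1e-10)
  expect_equal(sum(same$table$weight), 1, tolerance = 1e-12)
})

test_that("simulated trees are ultrametric, correctly sized and reproducible", {
  spec <- sse_model_spec("b", "ETD")
  pars <- c(lambda_lowland = 0.3, lambda_midland = 0.4,
            lambda_highland = 0.6, mu_lowland = 0.05, mu_midland = 0.1,
            mu_highland = 0.1, q_up = 0.1, q_down = 0.05)
  set.seed(91)
  s1 <- simulate_sse_tree(spec, pars, ntip = 30)
  expect_identical(ape::Ntip(s1$tree), 30L)
  expect_true(ape::is.ultrametric(s1$tree, tol = 1e-6))
  expect_true(ape::is.binary(s1$tree))
  expect_setequal(names(s1$tip_states), s1$tree$tip.label)
  expect_true(all(s1$tip_states %in% c("lowland", "midland", "highland")))

  set.seed(91)
  s2 <- simulate_sse_tree(spec, pars, ntip = 30)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_identical(s1$tip_states, s2$tip_states)
})

test_that("trees violating the preconditions are rejected", {
  tr <- ape::read.tree(text = "((a:1,b:2):1,c:1.5);")  # not ultrametric
  expect_error(sse_loglik(tr, c(a = 1, b = 1, c = 2),
                          sse_model_spec("a", "CR"),
                          c(lambda = 1, mu = 0.1, q = 0.1)), "ultrametric")
  tr2 <- ape::read.tree(text = "((a:1,b:1,c:1):1,d:2);")  # polytomy
  expect_error(sse_loglik(tr2, c(a = 1, b = 1, c = 2, d = 1),
                          sse_model_spec("a", "CR"),
                          c(lambda = 1, mu = 0.1, q = 0.1)), "bifurcating")
})

test_that("model comparison tables export with parameters and family weights", {
  set.seed(101)
  sim <- simulate_sse_tree(sse_model_spec("a", "CR"),
                           c(lambda = 0.5, mu = 0.1, q = 0.1), ntip = 20)
  fs <- fit_model_set(sim$tree, sim$tip_states,
                      models = enumerate_models()[c("a_CR", "c_CR", "b_CR")],
                      n_starts = 1)
  expect_equal(sum(fs$table$weight), 1, tolerance = 1e-12)
  fam <- setNames(fs$family_weights$weight, fs$family_weights$family)
  expect_equal(unname(fam["symmetric_dispersal"] +
                        fam["asymmetric_dispersal"]), 1, tolerance = 1e-12)

  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_fit_set(fs, csv, js)
  tab <- read.csv(csv)
  expect_identical(nrow(tab), 3L)
  expect_true(all(c("model_id", "logL", "AIC", "weight", "lambda") %in%
                    names(tab)))
  fw <- jsonlite::fromJSON(js)
  expect_equal(fw$symmetric_dispersal + fw$asymmetric_dispersal, 1,
               tolerance = 1e-12)
})
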