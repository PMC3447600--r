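# CA engine: neighborhood shares, stochastic factor, constraints, synthesis
# probability and the iterative allocation step.

test_that("neighborhood share counts Moore neighbors with edge-aware denominators", {
  v <- matrix(2L, 5, 5)
  v[2:4, 2:4] <- 3L
  v[3, 3] <- 1L
  # interior cell (3,3): all 8 neighbors construction
  expect_equal(neighborhood_share(v, "construction", cell = c(3, 3)), 1)
  # hand count: 3 of 8 neighbors
  w <- matrix(1L, 5, 5)
  w[2, 2] <- w[2, 3] <- w[3, 2] <- 2L
  expect_equal(neighborhood_share(w, "ecological", cell = c(3, 3)),
               3 / 8)
  # corner cell has 3 in-bounds neighbors
  u <- matrix(1L, 4, 4)
  u[1, 2] <- u[2, 1] <- u[2, 2] <- 2L
  expect_equal(neighborhood_share(u, "ecological", cell = c(1, 1)), 1)
  expect_error(neighborhood_share(u, "ecological", window = 4), "odd")
})

test_that("stochastic factor follows R = 1 + (-ln gamma)^alpha", {
  for (a in 1:10) expect_equal(stochastic_factor(exp(-1), a), 2)
  expect_equal(stochastic_factor(exp(-2), 3), 9)
  expect_lt(stochastic_factor(1 - 1e-12, 2), 1 + 1e-6)
  expect_gte(min(stochastic_factor(runif(1000), 5)), 1)
  expect_error(stochastic_factor(0, 1), "gamma")
  expect_error(stochastic_factor(0.5, 11), "alpha")
  expect_error(stochastic_factor(0.5, 2.5), "alpha")
})

test_that("constraint recipes follow the three scenario definitions", {
  b <- small_bundle()
  cm_nd <- build_constraints("natural_development", b$masks)
  expect_identical(cm_nd$block_out, b$masks$basic_farmland > 0)
  # a water cell is unconstrained under natural development
  wcell <- which(b$masks$water == 1 & b$masks$basic_farmland == 0)[1]
  expect_false(cm_nd$block_out[wcell])
  cm_oo <- build_constraints("object_orientation", b$masks)
  expect_identical(cm_oo$block_out,
                   b$masks$basic_farmland > 0 | b$masks$water > 0)
  expect_equal(sum(cm_oo$block_out),
               sum(b$masks$basic_farmland > 0 | b$masks$water > 0))
  cm_ep <- build_constraints("ecosystem_priority", b$masks)
  expect_true(cm_ep$protect_ecological)
  expect_identical(cm_ep$block_to_construction, b$masks$steep_slope > 0)
  expect_error(build_constraints("ecosystem_priority",
                                 b$masks[c("basic_farmland", "water")]),
               "requires mask")
  expect_error(build_constraints("urban_sprawl", b$masks), "unknown scenario")
})

test_that("synthesis probability multiplies its four factors and absorbs zeros", {
  expect_equal(synthesis_probability(0.5, 0.5, 1, 2), 0.5)
  expect_equal(synthesis_probability(0.9, 0.7, 0, 5), 0)
  expect_equal(synthesis_probability(0.9, 0, 1, 5), 0)
  p <- synthesis_probability(matrix(0.4, 2, 2), matrix(0.25, 2, 2), 1, 1.5)
  expect_equal(p, matrix(0.15, 2, 2))
})

test_that("an engine at its targets performs no conversions", {
  b <- small_bundle()
  at <- area_table(b$map_t0)
  targets <- macro_targets(stats::setNames(at$area_km2, at$class),
                           tolerance_floor = 0.01)
  cfg <- scenario_config("natural_development", seed = 3)
  sim <- run_scenario(b$map_t0, b$drivers, b$masks, small_models()$models,
                      cfg, targets)
  expect_identical(sim$final$values, b$map_t0$values)
  expect_equal(sim$iterations, 0L)
  expect_true(all(sim$converged))
})

test_that("cell counts are conserved at every iteration", {
  b <- small_bundle()
  tg <- scenario_targets(area_table(b$map_t1), small_models()$transition,
                         steps = 3)
  sim <- run_scenario(b$map_t1, b$drivers, b$masks, small_models()$models,
                      scenario_config("natural_development", seed = 11),
                      tg$natural_development)
  totals <- rowSums(sim$trajectory)
  expect_true(all(totals == totals[1]))
})

test_that("constrained cells never convert across many seeded iterations", {
  b <- small_bundle()
  models <- small_models()$models
  tg <- scenario_targets(area_table(b$map_t1), small_models()$transition,
                         steps = 3)
  surfaces <- theil_normalize(lapply(models, predict_surface,
                                     drivers = b$drivers))
  for (sc in c("object_orientation", "ecosystem_priority")) {
    cfg <- scenario_config(sc, seed = 17)
    cm <- build_constraints(cfg, b$masks)
    protected <- which(cm$block_out)
    ca <- ecolandca:::cell_area_km2(b$map_t1)
    tcells <- tg[[sc]]$targets / ca
    tolc <- pmax(tg[[sc]]$tolerance / ca, 1)
    state <- b$map_t1$values
    set.seed(17)
    for (i in 1:500) {
      step <- iterate_step(state, surfaces, cm, tcells, tolc, cfg)
      expect_identical(step$state[protected], b$map_t1$values[protected])
      state <- step$state
    }
    # ecosystem priority additionally never loses ecological cells
    if (sc == "ecosystem_priority") {
      eco0 <- b$map_t1$values == 2L
      expect_true(all(state[eco0] == 2L))
    }
  }
})

test_that("runs are bit-reproducible under a fixed seed", {
  b <- small_bundle()
  tg <- scenario_targets(area_table(b$map_t1), small_models()$transition,
                         steps = 3)
  cfg <- scenario_config("object_orientation", seed = 23)
  s1 <- run_scenario(b$map_t1, b$drivers, b$masks, small_models()$models,
                     cfg, tg$object_orientation)
  s2 <- run_scenario(b$map_t1, b$drivers, b$masks, small_models()$models,
                     cfg, tg$object_orientation)
  expect_identical(s1$final$values, s2$final$values)
  expect_identical(s1$trajectory, s2$trajectory)
  s3 <- run_scenario(b$map_t1, b$drivers, b$masks, small_models()$models,
                     scenario_config("object_orientation", seed = 24),
                     tg$object_orientation)
  expect_false(identical(s1$final$values, s3$final$values))
})

test_that("iterate_step with and without the cache agree exactly", {
  b <- small_bundle()
  models <- small_models()$models
  surfaces <- theil_normalize(lapply(models, predict_surface,
                                     drivers = b$drivers))
  cfg <- scenario_config("natural_development", seed = 31)
  cm <- build_constraints(cfg, b$masks)
  at <- area_table(b$map_t1)
  tcells <- stats::setNames(at$cells, at$class)
  tcells["construction"] <- tcells["construction"] + 200
  tcells["ecological"] <- tcells["ecological"] - 200
  tolc <- pmax(0.01 * tcells, 1)
  state <- b$map_t1$values
  cache <- ecolandca:::step_cache(state)
  set.seed(5)
  s_cached <- iterate_step(state, surfaces, cm, tcells, tolc, cfg,
                           cache = cache)
  set.seed(5)
  s_fresh <- iterate_step(state, surfaces, cm, tcells, tolc, cfg)
  expect_identical(s_cached$state, s_fresh$state)
  expect_identical(s_cached$counts, s_fresh$counts)
  # and the incrementally maintained cache matches a fresh recount
  fresh2 <- ecolandca:::step_cache(s_cached$state)
  expect_equal(cache$like, fresh2$like)
  expect_equal(cache$counts, fresh2$counts)
})

test_that("the simulated construction demand is met within the band", {
  b <- small_bundle()
  at <- area_table(b$map_t1)
  base <- stats::setNames(at$area_km2, at$class)
  tgt <- base
  tgt["construction"] <- base[["construction"]] * 1.10
  tgt["ecological"] <- base[["ecological"]] -
    (tgt[["construction"]] - base[["construction"]])
  targets <- macro_targets(tgt, tolerance_floor = 0.001 * sum(base))
  sim <- run_scenario(b$map_t1, b$drivers, b$masks, small_models()$models,
                      scenario_config("natural_development", seed = 41),
                      targets)
  final_c <- sum(sim$final$values == 3L) * ecolandca:::cell_area_km2(sim$final)
  expect_lte(abs(final_c - tgt[["construction"]]),
             targets$tolerance[["construction"]])
})
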