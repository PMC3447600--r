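# Suitability logits: sampling, fitting, prediction, Theil normalization
# and the per-cell argmax rule.

test_that("fraction-1 sampling takes every eligible cell exactly once", {
  b <- small_bundle()
  d <- sample_cells(b$map_t0, b$map_t1, b$drivers, fraction = 1, seed = 1)
  expect_equal(nrow(d), length(b$map_t0$values))
  expect_false(anyDuplicated(d$cell) > 0)
})

test_that("sampling is deterministic under a fixed seed and respects the fraction", {
  b <- default_bundle()
  d1 <- sample_cells(b$map_t0, b$map_t1, b$drivers, fraction = 0.2, seed = 5)
  d2 <- sample_cells(b$map_t0, b$map_t1, b$drivers, fraction = 0.2, seed = 5)
  expect_identical(d1, d2)
  # 20% of the 90,000-cell frame
  expect_equal(nrow(d1), 18000)
  d3 <- sample_cells(b$map_t0, b$map_t1, b$drivers, fraction = 0.2, seed = 6)
  expect_false(identical(d1$cell, d3$cell))
  expect_error(sample_cells(b$map_t0, b$map_t1, b$drivers,
                            fraction = 1e-4, seed = 1), "100 cells")
})

test_that("outcome columns encode conversion to each class", {
  b <- small_bundle()
  d <- sample_cells(b$map_t0, b$map_t1, b$drivers, fraction = 1, seed = 1)
  v0 <- as.vector(b$map_t0$values); v1 <- as.vector(b$map_t1$values)
  expect_equal(d$y_construction,
               as.integer(v1[d$cell] == 3L & v0[d$cell] != 3L))
  expect_equal(d$y_ecological,
               as.integer(v1[d$cell] == 2L & v0[d$cell] != 2L))
})

test_that("a null generating model fits near-zero coefficients", {
  set.seed(71)
  n <- 200000
  X <- matrix(runif(7 * n), n, 7,
              dimnames = list(NULL, c("dist_town", "dist_highway",
                                      "dist_river", "dem", "slope",
                                      "gdp_pc", "pop_density")))
  d <- data.frame(cell = seq_len(n), class_t0 = 1L,
                  y_construction = rbinom(n, 1, 0.5))
  d <- cbind(d, as.data.frame(X))
  fit <- fit_logit(d, "construction")
  expect_true(all(abs(stats::coef(fit)[-1]) <= 0.05))
})

test_that("a known single-driver effect is recovered from large samples", {
  set.seed(72)
  n <- 100000
  x <- runif(n)
  y <- rbinom(n, 1, stats::plogis(x))
  d <- data.frame(cell = seq_len(n), class_t0 = 2L, y_construction = y,
                  dist_town = x)
  fit <- fit_logit(d, "construction")
  expect_gte(stats::coef(fit)[["dist_town"]], 0.9)
  expect_lte(stats::coef(fit)[["dist_town"]], 1.1)
})

test_that("fitting requires both outcome levels and flags separation", {
  d <- data.frame(cell = 1:200, class_t0 = 2L, y_construction = 0L,
                  dist_town = runif(200))
  expect_error(fit_logit(d, "construction"), "both outcome levels")
  set.seed(4)
  x <- runif(300)
  d2 <- data.frame(cell = 1:300, class_t0 = 2L,
                   y_construction = as.integer(x > 0.5), dist_town = x)
  fit <- suppressWarnings(fit_logit(d2, "construction"))
  expect_true(fit$separation)
})

test_that("predicted surfaces match per-cell scalar computation", {
  b <- small_bundle()
  fit <- small_models()$models$construction
  surf <- predict_surface(fit, b$drivers)
  set.seed(12)
  cells <- sample(length(surf), 20)
  beta <- stats::coef(fit)
  for (i in cells) {
    eta <- beta[["(Intercept)"]] +
      sum(vapply(fit$drivers,
                 function(nm) beta[[nm]] * b$drivers$layers[[nm]][i],
                 numeric(1)))
    expect_equal(surf[i], stats::plogis(eta), tolerance = 1e-12)
  }
  expect_true(all(surf > 0 & surf < 1))
})

test_that("an all-zero-coefficient model predicts a constant 0.5 surface", {
  fit <- structure(list(class_m = "construction",
                        coefficients = c("(Intercept)" = 0, dist_town = 0),
                        drivers = "dist_town"),
                   class = "logit_model")
  d <- driver_stack(list(dist_town = matrix(runif(25), 5, 5)),
                    normalize = TRUE)
  expect_true(all(predict_surface(fit, d) == 0.5))
  expect_error(predict_surface(fit, driver_stack(list(dem = matrix(runif(25), 5, 5)))),
               "missing")
})

test_that("Theil normalization yields coherent per-cell probability sets", {
  s <- list(a = matrix(0.2, 2, 2), b = matrix(0.2, 2, 2),
            c = matrix(0.2, 2, 2))
  ns <- theil_normalize(s)
  expect_equal(ns$surfaces$a, matrix(1 / 3, 2, 2))
  s2 <- list(a = matrix(0.8, 1, 1), b = matrix(0.1, 1, 1),
             c = matrix(0.1, 1, 1))
  ns2 <- theil_normalize(s2)
  expect_equal(ns2$surfaces$a[1, 1], 0.8)
  expect_error(theil_normalize(s["a"]), "at least two")
})

test_that("normalization sums to one per cell and preserves the argmax", {
  set.seed(9)
  s <- list(cultivated = matrix(runif(400, 0.01, 1), 20, 20),
            ecological = matrix(runif(400, 0.01, 1), 20, 20),
            construction = matrix(runif(400, 0.01, 1), 20, 20))
  ns <- theil_normalize(s)
  tot <- Reduce(`+`, ns$surfaces)
  expect_true(all(abs(tot - 1) < 1e-9))
  expect_identical(argmax_class(ns), argmax_class(s))
})

test_that("all-zero cells are flagged and assigned the uniform distribution", {
  s <- list(a = matrix(c(0, 0.3), 1, 2), b = matrix(c(0, 0.1), 1, 2))
  ns <- theil_normalize(s)
  expect_equal(ns$degenerate, 1)
  expect_equal(ns$surfaces$a[1, 1], 0.5)
})

test_that("argmax_class breaks exact ties toward the lowest class code", {
  s <- list(cultivated = matrix(0.5, 1, 1), ecological = matrix(0.5, 1, 1),
            construction = matrix(0, 1, 1))
  expect_equal(argmax_class(s)[1, 1], 1L)
  s2 <- list(ecological = matrix(0.2, 1, 1), construction = matrix(0.7, 1, 1),
             cultivated = matrix(0.1, 1, 1))
  expect_equal(argmax_class(s2)[1, 1], 3L)
  # agreement with a per-cell max scan on random surfaces
  set.seed(13)
  s3 <- list(cultivated = matrix(runif(100), 10, 10),
             ecological = matrix(runif(100), 10, 10),
             construction = matrix(runif(100), 10, 10))
  am <- argmax_class(s3)
  codes <- c(cultivated = 1L, ecological = 2L, construction = 3L)
  for (i in seq_len(100)) {
    vals <- vapply(s3, `[`, numeric(1), i)
    expect_equal(am[i], unname(codes[which.max(vals)]))
  }
})

test_that("mean fitted probability matches the observed conversion rate", {
  # maximum-likelihood balance: the calibration is honest on average
  b <- default_bundle()
  cal <- default_calibration()
  d <- sample_cells(b$map_t0, b$map_t1, b$drivers, fraction = 1, seed = 1,
                    exclude = b$masks$core_area)
  for (m in c("cultivated", "ecological", "construction")) {
    code <- c(cultivated = 1L, ecological = 2L, construction = 3L)[[m]]
    dd <- d[d$class_t0 != code, ]
    beta <- stats::coef(cal$models[[m]])
    eta <- beta[["(Intercept)"]] +
      as.matrix(dd[, cal$models[[m]]$drivers]) %*% beta[cal$models[[m]]$drivers]
    expect_equal(mean(stats::plogis(eta)), mean(dd[[paste0("y_", m)]]),
                 tolerance = 0.1)
  }
})

test_that("models round-trip through JSON", {
  cal <- small_models()
  path <- withr::local_tempfile(fileext = ".json")
  write_models_json(cal$models, path)
  back <- read_models_json(path)
  expect_equal(stats::coef(back$construction),
               stats::coef(cal$models$construction), tolerance = 1e-12)
})
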