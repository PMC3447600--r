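# Landscape pattern metrics: patch labeling, LPI, COHESION, SPLIT, AI,
# change accounting, overlay accuracy and key-land loss.

test_that("a 2x2 block is one patch with area 4 and perimeter 8", {
  v <- matrix(1L, 4, 4)
  v[2:3, 2:3] <- 2L
  ps <- label_patches(v, "ecological")
  expect_length(ps$area, 1)
  expect_equal(ps$area, 4)
  expect_equal(ps$perimeter, 8)
  expect_equal(ps$A, 16)
})

test_that("diagonal cells join under 8-connectivity but not under 4", {
  v <- matrix(1L, 4, 4)
  v[2, 2] <- v[3, 3] <- 2L
  expect_length(label_patches(v, "ecological", connectivity = 8)$area, 1)
  expect_length(label_patches(v, "ecological", connectivity = 4)$area, 2)
  expect_error(label_patches(v, "ecological", connectivity = 6), "4 or 8")
})

test_that("patch labeling matches the brute-force flood fill on random grids", {
  set.seed(33)
  for (i in 1:8) {
    v <- random_class_grid(15, 15)
    for (conn in c(4, 8)) {
      ps <- label_patches(v, 2L, connectivity = conn)
      bs <- brute_patchset(v, 2L, connectivity = conn)
      expect_equal(sort(ps$area), sort(bs$area))
      # same partition: label matrices agree up to relabeling
      la <- ps$labels; lb <- brute_label(v, 2L, conn)
      expect_equal(length(unique(la[la > 0])), length(unique(lb[lb > 0])))
      for (id in unique(lb[lb > 0]))
        expect_equal(length(unique(la[lb == id])), 1)
    }
  }
})

test_that("LPI is the largest patch's share of the landscape", {
  v <- matrix(2L, 10, 10)
  expect_equal(lpi(label_patches(v, "ecological")), 100)
  v2 <- matrix(1L, 10, 10)
  v2[1:6, 1:8] <- 2L
  expect_equal(lpi(label_patches(v2, "ecological")), 48)
  empty <- lpi(label_patches(v2, "other"))
  expect_equal(as.numeric(empty), 0)
  expect_true(attr(empty, "empty"))
})

test_that("COHESION collapses to 0 for a single-cell patch and nears 100 for compact ones", {
  v <- matrix(1L, 10, 10)
  v[5, 5] <- 2L
  expect_equal(cohesion(label_patches(v, "ecological")), 0)
  big <- matrix(1L, 100, 100)
  big[26:75, 26:75] <- 2L
  co <- cohesion(label_patches(big, "ecological"))
  # closed form: a = 2500, p = 200, A = 10^4 ->
  # (1 - 1/sqrt(2500)) / (1 - 1/100) * 100
  expect_equal(co, 0.98 / 0.99 * 100, tolerance = 1e-12)
  expect_lt(co, 100)
})

test_that("SPLIT is 1 for a full single patch and 4 for a half-landscape patch", {
  v <- matrix(2L, 10, 10)
  expect_equal(split_index(label_patches(v, "ecological")), 1)
  v2 <- matrix(1L, 10, 10)
  v2[1:5, ] <- 2L
  expect_equal(split_index(label_patches(v2, "ecological")), 4)
})

test_that("splitting a patch into equal halves strictly increases SPLIT", {
  v <- matrix(1L, 12, 12)
  v[1:4, ] <- 2L
  s1 <- split_index(label_patches(v, "ecological"))
  v2 <- matrix(1L, 12, 12)
  v2[1:2, ] <- 2L; v2[7:8, ] <- 2L
  s2 <- split_index(label_patches(v2, "ecological"))
  expect_gt(s2, s1)
})

test_that("AI attains 100 on square blocks, 75 on a 4-line, 0 on a checkerboard", {
  v <- matrix(1L, 10, 10)
  v[3:6, 3:6] <- 2L
  expect_equal(aggregation_index(v, "ecological"), 100)
  v2 <- matrix(1L, 6, 6)
  v2[2, 2:5] <- 2L
  expect_equal(aggregation_index(v2, "ecological"), 75)
  cb <- matrix(rep(c(1L, 2L), length.out = 49), 7, 7)
  expect_equal(aggregation_index(cb, "ecological"), 0)
  v3 <- matrix(1L, 5, 5); v3[3, 3] <- 2L
  ai1 <- aggregation_index(v3, "ecological")
  expect_equal(as.numeric(ai1), 100)
  expect_true(attr(ai1, "degenerate"))
  expect_error(aggregation_index(v3, "other"), "empty class")
})

test_that("all four indices match brute-force oracles on random grids", {
  set.seed(44)
  for (i in 1:10) {
    v <- random_class_grid(20, 20)
    for (code in 1:3) {
      if (!any(v == code)) next
      ps <- label_patches(v, code)
      bs <- brute_patchset(v, code)
      expect_equal(lpi(ps), brute_lpi(bs), tolerance = 1e-9,
                   ignore_attr = TRUE)
      expect_equal(cohesion(ps), brute_cohesion(bs), tolerance = 1e-9)
      expect_equal(split_index(ps), brute_split(bs), tolerance = 1e-9)
      expect_equal(aggregation_index(v, code), brute_ai(v, code),
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
})

test_that("area change summary computes absolute and percent deltas", {
  base <- c(cultivated = 100, ecological = 200, construction = 50, other = 10)
  res <- c(cultivated = 90, ecological = 210, construction = 55, other = 5)
  cs <- area_change_summary(base, res)
  expect_equal(cs$change_km2, c(-10, 10, 5, -5))
  expect_equal(cs$change_pct, c(-10, 5, 10, -50))
  same <- area_change_summary(base, base)
  expect_true(all(same$change_km2 == 0) && all(same$change_pct == 0))
  expect_error(area_change_summary(c(a = 0, b = 1), c(a = 1, b = 1)), "zero base")
})

test_that("overlay accuracy is the share of matching cells", {
  a <- land_grid(matrix(1:4, 10, 10))
  expect_equal(overlay_accuracy(a, a), 1)
  b <- land_grid(matrix(c(2L, 1L, 4L, 3L)[matrix(1:4, 10, 10)], 10, 10))
  expect_equal(overlay_accuracy(a, b), 0)
  v <- a$values; v[1:10] <- ifelse(v[1:10] == 1L, 2L, 1L)
  expect_equal(overlay_accuracy(a, land_grid(v)), 0.9)
  expect_error(overlay_accuracy(a, land_grid(matrix(1L, 5, 5))), "aligned")
})

test_that("key ecological land loss is tallied per security level", {
  v0 <- matrix(2L, 10, 10)
  v1 <- v0
  mask <- matrix(0L, 10, 10)
  mask[1:4, 1:5] <- 1L            # 20 flagged cells
  g0 <- land_grid(v0); g1 <- land_grid(v1)
  expect_equal(unname(key_ecoland_loss(g0, g1, list(low = mask))), 0)
  v1[1:1, 1:5] <- 3L              # 5 of the 20 convert
  loss <- key_ecoland_loss(g0, land_grid(v1), list(low = mask))
  expect_equal(unname(loss), 0.05)
  expect_lte(loss, sum(mask) * 0.01)
  # non-ecological masked cells are excluded with a warning
  v0b <- v0; v0b[1, 1] <- 1L
  expect_warning(key_ecoland_loss(land_grid(v0b), land_grid(v1),
                                  list(low = mask)), "excluded")
})

test_that("pattern_metrics returns the four class-level indices", {
  b <- small_bundle()
  pm <- pattern_metrics(b$map_t0, "ecological")
  expect_named(pm, c("lpi", "cohesion", "split", "ai"))
  expect_true(pm[["lpi"]] > 0 && pm[["lpi"]] <= 100)
  expect_true(pm[["cohesion"]] >= 0 && pm[["cohesion"]] < 100)
  expect_gte(pm[["split"]], 1)
  expect_true(pm[["ai"]] >= 0 && pm[["ai"]] <= 100)
})
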