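test_that("linear trends report exact OLS and the F = t^2 identity", {
  d <- tibble::tibble(x = 1:20, y = 2 * (1:20))
  res <- suppressWarnings(linear_trend(d, "y", "x"))
  expect_equal(res$slope, 2, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-12)
  d2 <- tibble::tibble(x = 1:30,
                       y = withr::with_seed(1, 1:30 + rnorm(30, 0, 5)))
  res2 <- linear_trend(d2, "y", "x")
  fit <- lm(y ~ x, d2)
  tval <- summary(fit)$coefficients["x", "t value"]
  expect_equal(res2$f_statistic, tval^2, tolerance = 1e-9)
  expect_error(linear_trend(tibble::tibble(x = rep(1, 5), y = 1:5), "y", "x"),
               "constant")
})

test_that("geographic distances follow the haversine closed form", {
  sites <- tibble::tibble(site = c("a", "b", "c"),
                          site_lat = c(47, 48, 47), site_lon = c(8.4, 8.4, 8.4))
  D <- geographic_distance(sites)
  expect_equal(D["a", "c"], 0)
  expect_equal(D["a", "b"], 111.2, tolerance = 0.01) # 1 degree of latitude
  expect_equal(D, t(D))
})

test_that("Mantel r and p agree with the exact and external references", {
  pts <- withr::with_seed(2, matrix(rnorm(10), 5))
  D1 <- as.matrix(dist(pts))
  expect_equal(mantel(D1, D1, permutations = 99)$r, 1)
  D2 <- as.matrix(dist(withr::with_seed(3, matrix(rnorm(10), 5))))
  res <- mantel(D1, D2, permutations = 1999, seed = 1)
  # exact p by enumerating all 5! simultaneous row/column permutations
  perms <- do.call(rbind, combinat_perms(1:5))
  v2 <- D2[lower.tri(D2)]
  r_obs <- cor(D1[lower.tri(D1)], v2)
  r_all <- apply(perms, 1, function(ix) cor(D1[ix, ix][lower.tri(D1)], v2))
  p_exact <- mean(r_all >= r_obs - 1e-12)
  expect_lt(abs(res$p_value - p_exact), 0.08)
  # r statistic matches vegan on a larger matrix
  skip_if_not_installed("vegan")
  Da <- as.matrix(dist(withr::with_seed(4, matrix(rnorm(40), 20))))
  Db <- as.matrix(dist(withr::with_seed(5, matrix(rnorm(40), 20))))
  vg <- vegan::mantel(as.dist(Da), as.dist(Db), permutations = 99)
  expect_equal(mantel(Da, Db, permutations = 99)$r, unname(vg$statistic),
               tolerance = 1e-10)
})

test_that("Mantel permutation null is uniform", {
  ps <- vapply(1:200, function(s) {
    Da <- as.matrix(dist(withr::with_seed(s * 2, rnorm(15))))
    Db <- as.matrix(dist(withr::with_seed(s * 2 + 1, rnorm(15))))
    mantel(Da, Db, permutations = 99, seed = s)$p_value
  }, numeric(1))
  expect_gt(mean(ps <= 0.05), 0.01)
  expect_lt(mean(ps <= 0.05), 0.10)
})

test_that("partial Mantel removes exactly the controlled signal", {
  # full control: correlating a matrix with its own control gives r ~ 0
  Da <- as.matrix(dist(withr::with_seed(6, rnorm(25))))
  C <- as.matrix(dist(withr::with_seed(7, rnorm(25))))
  res_full <- partial_mantel(Da, C, C, permutations = 99, seed = 1)
  expect_lt(abs(res_full$r), 1e-10)
  expect_true(abs(res_full$r) <= 1)
  # uncorrelated control leaves the simple correlation nearly untouched
  z <- withr::with_seed(8, rnorm(25))
  Db <- as.matrix(dist(z + withr::with_seed(9, rnorm(25, 0, 0.5))))
  Dz <- as.matrix(dist(z))
  r_simple <- mantel(Dz, Db, permutations = 99)$r
  r_partial <- partial_mantel(Dz, Db, C, permutations = 99)$r
  expect_lt(abs(r_simple - r_partial), 0.1)
})

test_that("group membership matrices are symmetric block indicators", {
  m <- group_membership_matrix(c("a", "a", "b", "b"))
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_equal(m[1, 2], 0)
  expect_equal(m[1, 3], 1)
  expect_true(all(group_membership_matrix(rep("x", 5)) == 0))
})

test_that("DAPC self-assignment tracks simulated divergence", {
  spec <- setNames(rep(8L, 10), paste0("L", 1:10))
  specs2 <- lucerne_specs()[1:2, ]
  self_at <- function(f, seed) {
    pool <- sim_species_pool(2, spec, f, seed = seed)
    ind <- sim_individuals(pool, specs2, c(60, 60), seed = seed)
    d <- dapc_assign(ind$genotypes, cv_folds = 4, seed = 1)
    expect_equal(rowSums(as.matrix(d$membership[, c("sp_1", "sp_2")])),
                 rep(1, 120), tolerance = 1e-9)
    mean(self_assignment(d))
  }
  s_high <- self_at(0.1, seed = 3)
  expect_gt(s_high, 0.9)
  s_null <- self_at(0, seed = 4)
  expect_lt(s_null, 0.85)      # no signal: near the 1/K prior
  expect_gt(s_null, 0.25)
  s_mid <- self_at(0.05, seed = 5)
  expect_gte(s_mid, s_null - 0.05)
  expect_gte(s_high, s_mid - 0.05)
})

test_that("two-group tests agree in direction and calibrate at the extremes", {
  x <- withr::with_seed(10, rnorm(40, 30, 3))
  same <- two_group_tests(c(x, x), rep(c("g1", "g2"), each = 40))
  expect_gt(same$p_t, 0.95)
  # gill-raker sized effect: means 37.8 vs 27.7, sd ~2.7
  v <- withr::with_seed(11, c(rnorm(50, 37.8, 2.7), rnorm(36, 27.7, 2.7)))
  res <- two_group_tests(v, rep(c("hi", "lo"), c(50, 36)))
  expect_lt(res$p_t, 0.001)
  expect_lt(res$p_u, 0.001)
  flipped <- two_group_tests(v, rep(c("zlo", "ahi"), c(50, 36)))
  expect_equal(flipped$t, -res$t, tolerance = 1e-9)
})
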