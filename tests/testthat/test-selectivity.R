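make_model <- function(params, sl_range = c(120, 420)) {
  # build a selectivity_model directly from known parameters (no fitting)
  grid <- seq(sl_range[1] - 20, sl_range[2] + 20, by = 1)
  curves <- vapply(seq_len(nrow(params)), function(j) {
    cv <- dskewnorm(grid, params$xi[j], params$omega[j], params$alpha[j])
    cv / max(cv)
  }, numeric(length(grid)))
  out <- params
  out$mode <- vapply(seq_len(nrow(params)), function(j) {
    grid[which.max(curves[, j])]
  }, numeric(1))
  out$n <- 100L; out$reliable <- TRUE
  colnames(curves) <- as.character(params$mesh)
  attr(out, "grid") <- grid
  attr(out, "curves") <- curves
  attr(out, "total_curve") <- rowSums(curves)
  class(out) <- c("selectivity_model", class(out))
  out
}

test_that("skew-normal fit on symmetric data stays near-symmetric", {
  # alpha is weakly identified near 0 (flat likelihood ridge: sample
  # skewness of order sqrt(6/n) maps to alpha of order 1), so the
  # identifiable checks are the implied distribution skewness and the mode.
  implied_skewness <- function(alpha) {
    d <- alpha / sqrt(1 + alpha^2)
    m <- d * sqrt(2 / pi)
    (4 - pi) / 2 * m^3 / (1 - m^2)^1.5
  }
  for (s in 1:3) {
    x <- withr::with_seed(s, rnorm(500, 275, 15))
    ph <- tibble::tibble(sl = x, mesh = 35)
    m <- fit_mesh_selectivity(ph)
    expect_gte(m$alpha, 0)
    expect_lte(implied_skewness(m$alpha), 0.3)
    # mode close to the sample's densest point
    dd <- density(x)
    expect_lt(abs(m$mode - dd$x[which.max(dd$y)]), 5)
  }
})

test_that("the fit is deterministic for fixed data", {
  x <- withr::with_seed(1, 200 + 30 * abs(rnorm(200)))
  ph <- tibble::tibble(sl = x, mesh = 25)
  m1 <- fit_mesh_selectivity(ph)
  m2 <- fit_mesh_selectivity(ph)
  expect_identical(m1$xi, m2$xi)
  expect_identical(m1$omega, m2$omega)
  expect_identical(m1$alpha, m2$alpha)
})

test_that("per-mesh modes increase with mesh size on a gradient survey", {
  sim <- simulate_lucerne3(seed = 21)
  m <- fit_mesh_selectivity(sim$phenotypes)
  expect_true(all(diff(m$mode[order(m$mesh)]) > 0))
})

test_that("undersized meshes are flagged unreliable but still fitted", {
  ph <- tibble::tibble(
    sl = c(withr::with_seed(2, rnorm(40, 250, 20)), c(180, 190, 200, 185)),
    mesh = c(rep(35, 40), rep(25, 4)))
  expect_warning(m <- fit_mesh_selectivity(ph), "unreliable")
  expect_equal(nrow(m), 2L)
  expect_false(m$reliable[m$mesh == 25])
})

test_that("two shifted identical symmetric curves cross midway between their modes", {
  params <- tibble::tibble(mesh = c(25, 35), xi = c(200, 280),
                           omega = c(30, 30), alpha = c(0, 0))
  model <- make_model(params)
  b <- attr(class_boundaries(model), "boundaries")
  expect_equal(length(b), 1L)
  expect_lt(abs(b - mean(model$mode)), 1.5) # midpoint by symmetry
})

test_that("three meshes give two increasing boundaries matching a grid scan", {
  model <- make_model(tibble::tibble(mesh = c(25, 35, 45),
                                     xi = c(185, 255, 325),
                                     omega = c(40, 45, 50),
                                     alpha = c(3, 3, 3)))
  part <- class_boundaries(model)
  b <- attr(part, "boundaries")
  expect_equal(length(b), 2L)
  expect_true(b[1] < b[2])
  # brute-force oracle: dense grid scan for the crossing between modes
  grid <- seq(120, 420, by = 0.01)
  for (j in 1:2) {
    c1 <- dskewnorm(grid, model$xi[j], model$omega[j], model$alpha[j])
    c1 <- c1 / max(dskewnorm(attr(model, "grid"), model$xi[j], model$omega[j],
                             model$alpha[j]))
    c2 <- dskewnorm(grid, model$xi[j + 1], model$omega[j + 1], model$alpha[j + 1])
    c2 <- c2 / max(dskewnorm(attr(model, "grid"), model$xi[j + 1],
                             model$omega[j + 1], model$alpha[j + 1]))
    seg <- grid > model$mode[j] & grid < model$mode[j + 1]
    oracle <- grid[seg][which.min(abs(c1[seg] - c2[seg]))]
    expect_lt(abs(b[j] - oracle), 0.5)
  }
})

test_that("degenerate overlap (no crossing between modes) is an error", {
  params <- tibble::tibble(mesh = c(25, 35), xi = c(200, 200),
                           omega = c(30, 30), alpha = c(2, 2))
  model <- make_model(params)
  expect_error(class_boundaries(model), "crossing")
})

test_that("class assignment partitions fish with the boundary tie rule", {
  model <- make_model(tibble::tibble(mesh = c(25, 35, 45),
                                     xi = c(185, 255, 325),
                                     omega = c(40, 45, 50), alpha = c(3, 3, 3)))
  part <- class_boundaries(model)
  b <- attr(part, "boundaries")
  ph <- tibble::tibble(sl = c(b[1], b[2], 150, 250, 400))
  out <- assign_selectivity_classes(ph, part)
  # exactly on a boundary -> lower class
  expect_equal(out$sl_class[1:2], c("C1", "C2"))
  expect_equal(out$sl_class[3:5], c("C1", "C2", "C3"))
  # every fish gets exactly one label; order invariance
  perm <- c(4, 2, 5, 1, 3)
  out2 <- assign_selectivity_classes(ph[perm, , drop = FALSE], part)
  expect_equal(out2$sl_class, out$sl_class[perm])
  # all fish below the first boundary -> single class used
  low <- assign_selectivity_classes(tibble::tibble(sl = c(150, 160, 170)), part)
  expect_equal(unique(low$sl_class), "C1")
})

test_that("total selectivity sums the scaled curves and shows the between-mode dip", {
  one <- make_model(tibble::tibble(mesh = 35, xi = 255, omega = 45, alpha = 3))
  expect_equal(total_selectivity(one), attr(one, "curves")[, 1])
  model <- make_model(tibble::tibble(mesh = c(25, 45), xi = c(150, 330),
                                     omega = c(30, 30), alpha = c(0, 0)))
  tot <- total_selectivity(model)
  expect_true(all(tot >= attr(model, "curves")[, 1] - 1e-12))
  expect_true(all(tot >= attr(model, "curves")[, 2] - 1e-12))
  # modes separated by >= 4 omega: the total dips between the modes
  grid <- attr(model, "grid")
  between <- grid > model$mode[1] & grid < model$mode[2]
  expect_lt(min(tot[between]), 1)
  expect_equal(max(tot), max(tot[!between]))
})
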