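#' Skew-normal density
#'
#' `2/omega * phi(z) * Phi(alpha * z)` with `z = (x - xi)/omega`: the
#' right-skewed normal used for gill-net retention curves (shape
#' `alpha >= 0` gives right skew; `alpha = 0` is the normal density).
#'
#' @param x evaluation points (mm).
#' @param xi location (mm).
#' @param omega scale (mm, > 0).
#' @param alpha shape (dimensionless).
#' @return density values.
#' @export
dskewnorm <- function(x, xi, omega, alpha) {
  z <- (x - xi) / omega
  2 / omega * dnorm(z) * pnorm(alpha * z)
}

# Mode of the skew-normal by golden-section search (no closed form).
skewnorm_mode <- function(xi, omega, alpha) {
  opt <- stats::optimize(function(x) -dskewnorm(x, xi, omega, alpha),
                         interval = c(xi - 2 * omega, xi + 4 * omega), tol = 1e-6)
  opt$minimum
}

# Maximum-likelihood skew-normal fit with alpha constrained >= 0.
# Moment-matched location/scale starts at several shape values (the
# likelihood is flat along a ridge near alpha = 0, so a single start can
# stall); the best optimum by log-likelihood wins. Deterministic.
fit_skewnorm <- function(x, alpha_starts = c(0.5, 1, 3)) {
  x <- x[!is.na(x)]
  m <- mean(x); s <- sd(x)
  nll <- function(par) {
    xi <- par[1]; omega <- exp(par[2]); alpha <- par[3]
    d <- dskewnorm(x, xi, omega, alpha)
    if (any(!is.finite(d)) || any(d <= 0)) return(1e10)
    -sum(log(d))
  }
  best <- NULL
  for (a0 in alpha_starts) {
    delta <- a0 / sqrt(1 + a0^2)
    start <- c(m - s * delta * sqrt(2 / pi), log(s), a0)
    fit <- tryCatch(
      optim(start, nll, method = "L-BFGS-B",
            lower = c(-Inf, log(1e-3), 0), upper = c(Inf, Inf, 50)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  c(xi = best$par[1], omega = exp(best$par[2]), alpha = best$par[3],
    loglik = -best$value)
}

#' Fit per-mesh skew-normal selectivity curves
#'
#' Fits a right-skewed normal to the catch-at-length sample of each mesh size
#' by maximum likelihood (shape constrained to be non-negative), assuming
#' equal fishing intensity across meshes (panels set in series). Each curve
#' is rescaled to unit maximum on a 1-mm grid spanning
#' `[min(SL) - 20, max(SL) + 20]`; the total selectivity is their sum.
#' A mesh with fewer than `min_n` measured fish is flagged unreliable but
#' still fitted.
#'
#' @param pheno phenotype tibble with `sl` and `mesh` columns.
#' @param mesh_sizes meshes to fit (default: those present).
#' @param min_n minimum fish per mesh for a reliable fit.
#' @return a `selectivity_model`: tibble (mesh, xi, omega, alpha, mode, n,
#'   reliable) with the evaluation grid and unit-scaled curves as attributes.
#' @export
fit_mesh_selectivity <- function(pheno, mesh_sizes = NULL, min_n = 10) {
  stopifnot(all(c("sl", "mesh") %in% names(pheno)))
  mesh_sizes <- sort(mesh_sizes %||% unique(pheno$mesh[!is.na(pheno$mesh)]))
  sl_all <- pheno$sl[!is.na(pheno$sl)]
  grid <- seq(floor(min(sl_all)) - 20, ceiling(max(sl_all)) + 20, by = 1)
  rows <- list(); curves <- matrix(NA_real_, length(grid), length(mesh_sizes))
  for (j in seq_along(mesh_sizes)) {
    x <- pheno$sl[!is.na(pheno$sl) & pheno$mesh == mesh_sizes[j]]
    if (length(x) < 3) abort(paste0("mesh ", mesh_sizes[j], ": need at least 3 fish"))
    if (length(x) < min_n) {
      warn(sprintf("mesh %s: only %d fish with SL; fit flagged unreliable",
                   mesh_sizes[j], length(x)))
    }
    f <- fit_skewnorm(x)
    cv <- dskewnorm(grid, f["xi"], f["omega"], f["alpha"])
    curves[, j] <- cv / max(cv)
    rows[[j]] <- tibble::tibble(
      mesh = mesh_sizes[j], xi = unname(f["xi"]), omega = unname(f["omega"]),
      alpha = unname(f["alpha"]),
      mode = skewnorm_mode(f["xi"], f["omega"], f["alpha"]),
      n = length(x), reliable = length(x) >= min_n)
  }
  out <- dplyr::bind_rows(rows)
  colnames(curves) <- as.character(mesh_sizes)
  attr(out, "grid") <- grid
  attr(out, "curves") <- curves
  attr(out, "total_curve") <- rowSums(curves)
  class(out) <- c("selectivity_model", class(out))
  out
}

#' Total selectivity across meshes
#'
#' Pointwise sum of the unit-scaled per-mesh curves.
#'
#' @param model a [fit_mesh_selectivity()] result.
#' @param sl_grid optional evaluation points (mm); default the model grid.
#' @return numeric vector of summed selectivity.
#' @export
total_selectivity <- function(model, sl_grid = NULL) {
  if (is.null(sl_grid)) return(attr(model, "total_curve"))
  tot <- rep(0, length(sl_grid))
  for (j in seq_len(nrow(model))) {
    cv <- dskewnorm(sl_grid, model$xi[j], model$omega[j], model$alpha[j])
    mx <- max(dskewnorm(attr(model, "grid"), model$xi[j], model$omega[j],
                        model$alpha[j]))
    tot <- tot + cv / mx
  }
  tot
}

#' Selectivity SL class boundaries from curve crossings
#'
#' For each pair of adjacent meshes, places a class boundary at the standard
#' length where their unit-scaled selectivity curves cross, located between
#' the two modes by bisection. k meshes give k - 1 boundaries and k classes
#' tiling the observed SL range.
#'
#' @param model a [fit_mesh_selectivity()] result with >= 2 meshes.
#' @return an `sl_partition`: tibble (class, lo, hi) with `boundaries`
#'   attribute.
#' @export
class_boundaries <- function(model) {
  if (nrow(model) < 2) abort("need at least 2 fitted meshes")
  model <- model[order(model$mesh), ]
  grid <- attr(model, "grid")
  curves <- attr(model, "curves")
  bnd <- numeric(nrow(model) - 1)
  for (j in seq_len(nrow(model) - 1)) {
    m1 <- model$mode[j]; m2 <- model$mode[j + 1]
    f <- function(x) {
      c1 <- dskewnorm(x, model$xi[j], model$omega[j], model$alpha[j]) /
        max(dskewnorm(grid, model$xi[j], model$omega[j], model$alpha[j]))
      c2 <- dskewnorm(x, model$xi[j + 1], model$omega[j + 1], model$alpha[j + 1]) /
        max(dskewnorm(grid, model$xi[j + 1], model$omega[j + 1], model$alpha[j + 1]))
      c1 - c2
    }
    if (m1 >= m2 || f(m1) <= 0 || f(m2) >= 0) {
      abort(sprintf("no crossing between the modes of meshes %s and %s",
                    model$mesh[j], model$mesh[j + 1]))
    }
    bnd[j] <- uniroot(f, c(m1, m2), tol = 1e-4)$root
  }
  lo <- c(min(grid), bnd); hi <- c(bnd, max(grid))
  out <- tibble::tibble(class = paste0("C", seq_len(nrow(model))), lo = lo, hi = hi)
  attr(out, "boundaries") <- bnd
  class(out) <- c("sl_partition", class(out))
  out
}

#' Assign fish to selectivity SL classes
#'
#' Labels every fish by the SL interval of the partition, irrespective of the
#' mesh it was caught in. Intervals are half-open and closed above, so a fish
#' exactly on a boundary goes to the lower class. SL outside the partition range is
#' mapped to the nearest extreme class with a warning.
#'
#' @param pheno phenotype tibble with `sl`.
#' @param partition a [class_boundaries()] result.
#' @return `pheno` with an `sl_class` column added.
#' @export
assign_selectivity_classes <- function(pheno, partition) {
  stopifnot("sl" %in% names(pheno))
  bnd <- attr(partition, "boundaries")
  idx <- findInterval(pheno$sl, bnd, left.open = TRUE) + 1L
  oob <- !is.na(pheno$sl) &
    (pheno$sl < min(partition$lo) | pheno$sl >= max(partition$hi))
  if (any(oob)) {
    warn(sprintf("%d fish outside the partitioned SL range; assigned to nearest extreme class",
                 sum(oob)))
  }
  pheno$sl_class <- partition$class[idx]
  pheno
}
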