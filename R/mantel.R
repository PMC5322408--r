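#' Mantel test between two distance matrices
#'
#' r is the Pearson correlation of the lower-triangle (off-diagonal)
#' elements; the null distribution comes from simultaneous row/column
#' permutation of the first matrix, `p = (#{r* >= r} + 1) /
#' (permutations + 1)` (one-sided, positive association, the standard
#' convention for isolation-by-distance style tests).
#'
#' @param d1,d2 square symmetric matrices of the same order.
#' @param permutations number of permutations (default 1000).
#' @param seed integer seed.
#' @return a `mantel_result` tibble row: `r`, `p_value`, `permutations`,
#'   `controlled` (`NA` for the simple test), `seed`.
#' @export
mantel <- function(d1, d2, permutations = 1000, seed = 1L) {
  check_square_symmetric(d1, "d1"); check_square_symmetric(d2, "d2")
  if (nrow(d1) != nrow(d2)) abort("matrices must have the same order")
  v2 <- lower_vec(d2)
  r_obs <- cor(lower_vec(d1), v2)
  n <- nrow(d1)
  pv <- with_seed(split_seed(seed, "mantel"), {
    hits <- 0L
    for (b in seq_len(permutations)) {
      ix <- sample.int(n)
      if (cor(lower_vec(d1[ix, ix]), v2) >= r_obs - 1e-12) hits <- hits + 1L
    }
    (hits + 1) / (permutations + 1)
  })
  structure(tibble::tibble(r = r_obs, p_value = pv,
                           permutations = permutations,
                           controlled = NA_character_, seed = seed),
            class = c("mantel_result", class(tibble::tibble())))
}

#' Partial Mantel test (residual permutation)
#'
#' Correlates the residuals of `d1` and `d2` after regressing each
#' (element-wise, lower triangle) on the control matrix `c0`; the null
#' permutes the residualized first matrix rows/columns simultaneously.
#'
#' @param d1,d2 square symmetric matrices.
#' @param c0 control matrix, same order.
#' @param permutations number of permutations (default 1000).
#' @param seed integer seed.
#' @param control_name label stored in the result.
#' @return a `mantel_result` tibble row.
#' @export
partial_mantel <- function(d1, d2, c0, permutations = 1000, seed = 1L,
                           control_name = "control") {
  check_square_symmetric(d1, "d1"); check_square_symmetric(d2, "d2")
  check_square_symmetric(c0, "c0")
  if (!all(dim(d1) == dim(d2)) || !all(dim(d1) == dim(c0))) {
    abort("all three matrices must have the same order")
  }
  n <- nrow(d1)
  vc <- lower_vec(c0)
  resid_of <- function(v) stats::residuals(stats::lm(v ~ vc))
  # residualize d1 as a full matrix so its rows/columns can be permuted
  R1 <- matrix(0, n, n)
  R1[lower.tri(R1)] <- resid_of(lower_vec(d1))
  R1 <- R1 + t(R1)
  e2 <- resid_of(lower_vec(d2))
  # degenerate control (d2 collinear with c0): nothing left to correlate
  if (sd(e2) < 1e-10 * max(sd(lower_vec(d2)), 1e-300)) {
    return(structure(tibble::tibble(r = 0, p_value = 1,
                                    permutations = permutations,
                                    controlled = control_name, seed = seed),
                     class = c("mantel_result", class(tibble::tibble()))))
  }
  r_obs <- cor(lower_vec(R1), e2)
  pv <- with_seed(split_seed(seed, "partial_mantel"), {
    hits <- 0L
    for (b in seq_len(permutations)) {
      ix <- sample.int(n)
      if (cor(lower_vec(R1[ix, ix]), e2) >= r_obs - 1e-12) hits <- hits + 1L
    }
    (hits + 1) / (permutations + 1)
  })
  structure(tibble::tibble(r = r_obs, p_value = pv,
                           permutations = permutations,
                           controlled = control_name, seed = seed),
            class = c("mantel_result", class(tibble::tibble())))
}

#' Binary same/different-group distance matrix
#'
#' 0 when two individuals share a group label, 1 otherwise; used as the
#' control matrix when partialling out population structure.
#'
#' @param labels vector of group labels.
#' @return symmetric 0/1 matrix with zero diagonal.
#' @export
group_membership_matrix <- function(labels) {
  m <- outer(labels, labels, FUN = "!=") * 1
  diag(m) <- 0
  dimnames(m) <- list(names(labels), names(labels))
  m
}

#' Absolute-difference distance matrix of a numeric trait
#' @param values numeric vector (raw trait values; absolute differences).
#' @return symmetric matrix `|v_i - v_j|`.
#' @export
trait_distance <- function(values) {
  m <- abs(outer(values, values, "-"))
  dimnames(m) <- list(names(values), names(values))
  m
}
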