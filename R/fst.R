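#' Multilocus Weir-Cockerham theta between two or more groups
#'
#' Ratio-of-sums estimator over loci and alleles. Negative estimates are
#' reported as computed, never truncated.
#'
#' @param genotypes a [genotype_tbl()].
#' @param grouping see [allele_counts()].
#' @return theta (numeric scalar).
#' @export
wc_theta <- function(genotypes, grouping = NULL) {
  ga <- geno_arrays(genotypes)
  grp <- resolve_grouping(genotypes, grouping)
  unname(wc_theta_arrays(ga, grp)["theta"])
}

#' Pairwise F_ST matrix with permutation tests
#'
#' Weir-Cockerham theta for every group pair; significance from permuting
#' individuals between the two groups of each pair, with the add-one
#' convention `p = (#{theta* >= theta} + 1) / (permutations + 1)`.
#' Benjamini-Hochberg significance flags at rate `q` are included. Negative
#' estimates are reported as computed (never truncated) and flagged in the
#' `negative` column.
#'
#' @param genotypes a [genotype_tbl()].
#' @param grouping see [allele_counts()].
#' @param permutations permutations per pair (default 10000).
#' @param q false-discovery rate for the significance flags.
#' @param seed integer seed (logged in the result).
#' @return an `fst_matrix`: tibble (group1, group2, theta, p_value, p_adj,
#'   significant) with attributes `matrix` (symmetric, zero diagonal),
#'   `permutations`, `seed`.
#' @export
pairwise_fst <- function(genotypes, grouping = NULL, permutations = 10000,
                         q = 0.05, seed = 1L) {
  ga <- geno_arrays(genotypes)
  grp <- resolve_grouping(genotypes, grouping)
  groups <- sort(unique(grp))
  if (length(groups) < 2) abort("need at least 2 groups")
  sizes <- table(grp)
  if (any(sizes < 2)) abort("every group needs at least 2 individuals")
  pairs <- combn(groups, 2)
  rows <- list()
  M <- matrix(0, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (j in seq_len(ncol(pairs))) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    sel <- grp %in% c(g1, g2)
    sub <- list(a1 = ga$a1[sel, , drop = FALSE], a2 = ga$a2[sel, , drop = FALSE],
                loci = ga$loci)
    lab <- grp[sel]
    obs <- wc_theta_arrays(sub, lab)["theta"]
    pv <- with_seed(split_seed(seed, paste0("fst_", g1, "_", g2)), {
      hits <- 0L
      for (b in seq_len(permutations)) {
        perm <- sample(lab)
        th <- wc_theta_arrays(sub, perm)["theta"]
        if (!is.na(th) && th >= obs - 1e-12) hits <- hits + 1L
      }
      (hits + 1) / (permutations + 1)
    })
    M[g1, g2] <- M[g2, g1] <- obs
    rows[[j]] <- tibble::tibble(group1 = g1, group2 = g2,
                                theta = unname(obs), p_value = pv,
                                negative = !is.na(obs) && obs < 0)
  }
  out <- dplyr::bind_rows(rows)
  adj <- fdr_correct(out$p_value, q = q)
  out$p_adj <- adj$p_adj
  out$significant <- adj$significant
  attr(out, "matrix") <- M
  attr(out, "permutations") <- permutations
  attr(out, "seed") <- seed
  class(out) <- c("fst_matrix", class(out))
  out
}

#' Analysis of molecular variance (one grouping level)
#'
#' Partitions multilocus genetic variance into among-group and within-group
#' components using the Weir-Cockerham sums (`sigma2_a = sum a`,
#' `sigma2_w = sum b + c`, ratio of sums over loci and alleles), so
#' `Phi_ST = sigma2_a / (sigma2_a + sigma2_w)` coincides with the global
#' theta. Significance from permuting individuals among groups. Negative
#' among-group components are retained, not zeroed.
#'
#' @param genotypes a [genotype_tbl()].
#' @param grouping see [allele_counts()]; at least 2 groups.
#' @param permutations number of permutations (default 10000).
#' @param seed integer seed.
#' @return an `amova_result` list: `grouping_name`, `sigma2_among`,
#'   `sigma2_within`, `phi_st`, `p_value`, `permutations`, `seed`.
#' @export
amova <- function(genotypes, grouping = NULL, permutations = 10000, seed = 1L) {
  ga <- geno_arrays(genotypes)
  grp <- resolve_grouping(genotypes, grouping)
  if (length(unique(grp)) < 2) abort("AMOVA needs at least 2 groups")
  comp <- wc_theta_arrays(ga, grp)
  obs <- comp["theta"]
  pv <- with_seed(split_seed(seed, "amova"), {
    hits <- 0L
    for (b in seq_len(permutations)) {
      th <- wc_theta_arrays(ga, sample(grp))["theta"]
      if (!is.na(th) && th >= obs - 1e-12) hits <- hits + 1L
    }
    (hits + 1) / (permutations + 1)
  })
  structure(list(
    grouping_name = if (is.character(grouping) && length(grouping) == 1)
      grouping else "grouping",
    sigma2_among = unname(comp["a"]),
    sigma2_within = unname(comp["b"] + comp["c"]),
    phi_st = unname(obs), p_value = pv,
    permutations = permutations, seed = seed), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", x$grouping_name, "): Phi_ST = ", format(x$phi_st, digits = 4),
      ", p = ", format(x$p_value, digits = 4),
      " [", x$permutations, " permutations]\n", sep = "")
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjusted p-values (monotone) and significance flags at rate `q`.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param q target FDR (default 0.05).
#' @return tibble: `p_value`, `p_adj`, `significant`.
#' @export
fdr_correct <- function(pvalues, q = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) abort("p-values must be in [0, 1]")
  adj <- p.adjust(pvalues, method = "BH")
  tibble::tibble(p_value = pvalues, p_adj = adj, significant = adj <= q)
}
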