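# Log conditional probability of a diploid genotype table given its allele
# counts (Levene): log P = h log2 + log n! + sum log a_u! - log (2n)! -
# sum log n_uv!. `het` = number of heterozygous individuals.
log_table_prob <- function(n, allele_counts, genotype_counts, het) {
  het * log(2) + lfactorial(n) + sum(lfactorial(allele_counts)) -
    lfactorial(2 * n) - sum(lfactorial(genotype_counts))
}

# Exact Hardy-Weinberg test for a biallelic locus by complete enumeration of
# the heterozygote count (Levene distribution). Returns the Fisher-style
# exact p: total probability of tables no more probable than the observed.
hwe_exact_biallelic <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  hs <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  lp <- vapply(hs, function(h) {
    aa <- (na - h) / 2; bb <- n - aa - h
    log_table_prob(n, c(na, 2 * n - na), c(aa, h, bb), h)
  }, numeric(1))
  lp <- lp - max(lp)
  p <- exp(lp) / sum(exp(lp))
  sum(p[lp <= lp[hs == n_ab] + 1e-9])
}

# Monte-Carlo exact test for an arbitrary allele count: random re-pairings
# of the observed gene copies (conditional on allele counts), scoring the
# Levene probability of each sampled table.
hwe_mc <- function(x, y, n_samples = 100000, burnin = 1000, seed = 1L) {
  n <- length(x)
  alleles <- sort(unique(c(x, y)))
  genes <- match(c(x, y), alleles)
  # unordered-genotype integer code and tabulated Levene log-probability
  code <- function(a, b) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    lo + hi * (hi - 1L) %/% 2L
  }
  nbins <- code(length(alleles), length(alleles))
  acnt <- tabulate(genes, length(alleles))
  lfact_n <- lfactorial(n); lfact_a <- sum(lfactorial(acnt))
  lfact_2n <- lfactorial(2 * n)
  lp_of <- function(a, b) {
    tab <- tabulate(code(a, b), nbins)
    sum(a != b) * log(2) + lfact_n + lfact_a - lfact_2n - sum(lfactorial(tab))
  }
  lp_obs <- lp_of(genes[seq_len(n)], genes[n + seq_len(n)])
  with_seed(seed, {
    # burn-in draws are discarded; kept for interface parity with
    # chain-based implementations
    for (b in seq_len(min(burnin, 100))) sample(genes)
    hits <- 0L
    for (s in seq_len(n_samples)) {
      gg <- sample(genes)
      if (lp_of(gg[seq_len(n)], gg[n + seq_len(n)]) <= lp_obs + 1e-9) {
        hits <- hits + 1L
      }
    }
    (hits + 1) / (n_samples + 1)
  })
}

#' Exact tests of Hardy-Weinberg equilibrium
#'
#' Per locus and group. Biallelic loci are tested by complete enumeration of
#' the Levene distribution (exact p); loci with more alleles use a
#' Monte-Carlo exact test that re-pairs the observed gene copies
#' conditional on allele counts. Monomorphic loci return p = 1. Defaults are
#' desk-scale; raise `n_samples` for publication-scale runs.
#'
#' @param genotypes a [genotype_tbl()].
#' @param grouping see [allele_counts()].
#' @param n_samples Monte-Carlo samples for multiallelic loci.
#' @param burnin discarded initial draws (interface parity with chain-based
#'   implementations).
#' @param min_n minimum typed individuals to test (default 5).
#' @param seed integer seed.
#' @return tibble: `group`, `locus`, `n`, `n_alleles`, `p_value`, `method`.
#' @export
hwe_test <- function(genotypes, grouping = NULL, n_samples = 100000,
                     burnin = 1000, min_n = 5, seed = 1L) {
  ga <- geno_arrays(genotypes)
  grp <- resolve_grouping(genotypes, grouping)
  rows <- list()
  for (gname in unique(grp)) {
    sel <- grp == gname
    for (l in seq_along(ga$loci)) {
      x <- ga$a1[sel, l]; y <- ga$a2[sel, l]
      typed <- !is.na(x) & !is.na(y)
      x <- x[typed]; y <- y[typed]
      n <- length(x)
      alleles <- sort(unique(c(x, y)))
      if (n < min_n) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          group = gname, locus = ga$loci[l], n = n,
          n_alleles = length(alleles), p_value = NA_real_, method = "untested")
        next
      }
      if (length(alleles) < 2) {
        p <- 1; meth <- "monomorphic"
      } else if (length(alleles) == 2) {
        aa <- sum(x == alleles[1] & y == alleles[1])
        ab <- sum(x != y)
        bb <- n - aa - ab
        p <- hwe_exact_biallelic(aa, ab, bb); meth <- "exact"
      } else {
        p <- hwe_mc(x, y, n_samples, burnin,
                    seed = split_seed(seed, paste0("hwe_", gname, "_", l)))
        meth <- "monte-carlo"
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = gname, locus = ga$loci[l], n = n,
        n_alleles = length(alleles), p_value = p, method = meth)
    }
  }
  dplyr::bind_rows(rows)
}

#' Pairwise linkage-equilibrium tests
#'
#' For every locus pair within every group: G statistic on the two-locus
#' genotype contingency table, with a permutation null obtained by shuffling
#' one locus' genotypes within the group. Pairs where either locus shows
#' fewer than 2 genotype categories are skipped and counted untested.
#'
#' @param genotypes a [genotype_tbl()].
#' @param grouping see [allele_counts()].
#' @param permutations permutation count (default 499).
#' @param alpha significance level for the summary counts.
#' @param seed integer seed.
#' @return tibble (`group`, `locus1`, `locus2`, `g_stat`, `p_value`,
#'   `tested`) with a `summary` attribute: `n_tests`, `n_significant`,
#'   `pct_significant`.
#' @export
ld_pairwise_tests <- function(genotypes, grouping = NULL, permutations = 499,
                              alpha = 0.05, seed = 1L) {
  ga <- geno_arrays(genotypes)
  grp <- resolve_grouping(genotypes, grouping)
  L <- length(ga$loci)
  if (L < 2) abort("need at least 2 loci")
  g_of <- function(x, y) {
    # unordered genotype category per individual
    paste(pmin(x, y), pmax(x, y))
  }
  g_stat <- function(f1, f2) {
    tab <- table(f1, f2)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    idx <- tab > 0
    2 * sum(tab[idx] * log(tab[idx] / e[idx]))
  }
  rows <- list()
  for (gname in unique(grp)) {
    sel <- grp == gname
    for (j in seq_len(L - 1)) for (k in seq((j + 1), L)) {
      x1 <- ga$a1[sel, j]; y1 <- ga$a2[sel, j]
      x2 <- ga$a1[sel, k]; y2 <- ga$a2[sel, k]
      ok <- !is.na(x1) & !is.na(x2)
      c1 <- g_of(x1[ok], y1[ok]); c2 <- g_of(x2[ok], y2[ok])
      if (length(unique(c1)) < 2 || length(unique(c2)) < 2) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          group = gname, locus1 = ga$loci[j], locus2 = ga$loci[k],
          g_stat = NA_real_, p_value = NA_real_, tested = FALSE)
        next
      }
      obs <- g_stat(c1, c2)
      pv <- with_seed(split_seed(seed, paste0("ld_", gname, "_", j, "_", k)), {
        hits <- 0L
        for (b in seq_len(permutations)) {
          if (g_stat(c1, sample(c2)) >= obs - 1e-12) hits <- hits + 1L
        }
        (hits + 1) / (permutations + 1)
      })
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = gname, locus1 = ga$loci[j], locus2 = ga$loci[k],
        g_stat = obs, p_value = pv, tested = TRUE)
    }
  }
  out <- dplyr::bind_rows(rows)
  tested <- out[out$tested, ]
  attr(out, "summary") <- tibble::tibble(
    n_tests = nrow(tested),
    n_significant = sum(tested$p_value <= alpha, na.rm = TRUE),
    pct_significant = 100 * sum(tested$p_value <= alpha, na.rm = TRUE) /
      max(nrow(tested), 1))
  out
}
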