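# Shared fixture builders and independent oracles used across test files.

# Small deterministic genotype table: n individuals, L loci, `na` alleles
# per locus, optional group labels.
toy_genotypes <- function(n = 20, L = 10, na = 4, pop = NULL, seed = 1) {
  withr::with_seed(seed, {
    a1 <- matrix(sample.int(na, n * L, replace = TRUE), n, L)
    a2 <- matrix(sample.int(na, n * L, replace = TRUE), n, L)
  })
  genotype_tbl(sprintf("i%03d", seq_len(n)), paste0("L", seq_len(L)),
               a1, a2, pop = pop)
}

# Lucerne-like phenotype specs used by several simulation tests.
lucerne_specs <- function() {
  dplyr::bind_rows(
    species_phenotype_spec(200, 15, 37.8, 2.63, 32, 13),
    species_phenotype_spec(275, 15, 33.3, 3.79, 18, 13),
    species_phenotype_spec(350, 15, 27.7, 2.83, 6, 13))
}

lucerne_truth_selectivity <- function() {
  tibble::tibble(mesh = c(25, 35, 45), location = c(185, 255, 325),
                 scale = c(40, 45, 50), shape = c(3, 3, 3))
}

# --- independent oracles ---------------------------------------------------

# Exhaustive-subsample oracle for rarefied allele counts at one locus:
# average number of distinct alleles over all C(N, g) gene subsets.
oracle_expected_alleles <- function(counts, g) {
  genes <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(genes), g)
  mean(apply(subs, 2, function(ix) length(unique(genes[ix]))))
}

# Exhaustive oracle for the probability that each allele appears in a g-gene
# subsample (one locus, one group).
oracle_presence_prob <- function(counts, g) {
  genes <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(genes), g)
  vapply(seq_along(counts), function(a) {
    mean(apply(subs, 2, function(ix) a %in% genes[ix]))
  }, numeric(1))
}

# Hand-coded Weir-Cockerham variance components for ONE biallelic locus and
# two groups, written directly from the published definitions (independent
# of the package's vectorised implementation).
oracle_wc_biallelic <- function(p1, p2, h1, h2, n1, n2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  comp_for <- function(p1u, p2u, h1u, h2u) {
    pbar <- (n1 * p1u + n2 * p2u) / (r * nbar)
    s2 <- (n1 * (p1u - pbar)^2 + n2 * (p2u - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1u + n2 * h2u) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    c(a, b, hbar / 2)
  }
  # sum over the two alleles of a biallelic locus
  comp_for(p1, p2, h1, h2) + comp_for(1 - p1, 1 - p2, h1, h2)
}

# Exact two-sided Mann-Whitney p by complete enumeration (midranks), written
# independently in terms of rank sums.
oracle_mwu_exact_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  dev <- abs(u_obs - n1 * n2 / 2)
  subs <- utils::combn(n1 + n2, n1)
  us <- apply(subs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mean(abs(us - n1 * n2 / 2) >= dev - 1e-9)
}

# All permutations of a small vector (used for exact Mantel enumeration).
combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}
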