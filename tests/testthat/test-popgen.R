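test_that("allele counts exclude missing calls and add over groups", {
  g <- genotype_tbl(c("i1", "i2", "i3"), "L1",
                    a1 = matrix(c(1L, 1L, NA)), a2 = matrix(c(2L, 2L, NA)),
                    pop = c("A", "A", "B"))
  ac <- allele_counts(g)
  a_rows <- ac[ac$group == "A" & !is.na(ac$allele), ]
  expect_equal(a_rows$count[order(a_rows$allele)], c(2L, 2L))
  expect_equal(unique(a_rows$n_genes), 4L)
  b_rows <- ac[ac$group == "B", ]
  expect_equal(b_rows$n_genes, 0L)
  # pooled counts equal the sum of group counts
  g2 <- toy_genotypes(30, 3, na = 5, pop = rep(c("A", "B", "C"), each = 10))
  ac_g <- allele_counts(g2)
  ac_pool <- allele_counts(g2, rep("all", 30))
  for (l in locus_names(g2)) {
    by_group <- ac_g[ac_g$locus == l, ]
    pooled <- ac_pool[ac_pool$locus == l, ]
    agg <- tapply(by_group$count, by_group$allele, sum)
    expect_equal(as.integer(agg[as.character(pooled$allele)]), pooled$count)
    expect_equal(sum(pooled$count), pooled$n_genes[1])
  }
})

test_that("heterozygosity and F_IS behave at the archetypal extremes", {
  # all-homozygous group with two alleles at 50/50
  g <- genotype_tbl(sprintf("i%d", 1:10), "L1",
                    a1 = matrix(rep(c(1L, 2L), each = 5)),
                    a2 = matrix(rep(c(1L, 2L), each = 5)))
  d <- diversity_summary(g, rep("A", 10))
  expect_equal(d$h_obs, 0)
  expect_gt(d$h_exp, 0)
  expect_equal(d$f_is, 1)
  # the small-sample correction makes H_E unbiased for 2pq
  he <- vapply(1:40, function(s) {
    a <- withr::with_seed(s, matrix(rbinom(40, 1, 0.4) + 1L, 20))
    gg <- genotype_tbl(sprintf("i%d", 1:20), "L1",
                       a1 = a[, 1, drop = FALSE], a2 = a[, 2, drop = FALSE])
    diversity_summary(gg, rep("A", 20))$h_exp
  }, numeric(1))
  expect_equal(mean(he), 2 * 0.4 * 0.6, tolerance = 0.02)
})

test_that("multilocus F_IS equals the ratio-of-sums over loci", {
  g <- toy_genotypes(40, 6, na = 4, pop = rep("A", 40), seed = 5)
  d <- diversity_summary(g)
  ga <- depthcline:::geno_arrays(g)
  bc <- vapply(seq_along(ga$loci), function(l) {
    depthcline:::wc_f_locus(ga$a1[, l], ga$a2[, l])
  }, numeric(2))
  oracle <- 1 - sum(bc[2, ]) / sum(bc)
  expect_equal(diversity_by_group(d)$f_is, oracle, tolerance = 1e-12)
})

test_that("HWE exact test matches complete enumeration on the 4-individual table", {
  # AA = 1, AB = 2, BB = 1: enumerate all tables with allele counts 4/4
  g <- genotype_tbl(sprintf("i%d", 1:4), "L1",
                    a1 = matrix(c(1L, 1L, 1L, 2L)), a2 = matrix(c(1L, 2L, 2L, 2L)))
  res <- hwe_test(g, rep("A", 4), min_n = 4)
  # oracle: Levene probabilities for heterozygote counts 0, 2, 4
  hs <- c(0, 2, 4)
  lp <- vapply(hs, function(h) {
    aa <- (4 - h) / 2
    h * log(2) + lfactorial(4) + 2 * lfactorial(4) - lfactorial(8) -
      (2 * lfactorial(aa) + lfactorial(h))
  }, numeric(1))
  pr <- exp(lp) / sum(exp(lp))
  oracle <- sum(pr[lp <= lp[hs == 2] + 1e-9])
  expect_equal(res$p_value, oracle)
  expect_equal(res$p_value, 1)
})

test_that("HWE p-values are well calibrated and monomorphic loci return 1", {
  ps <- vapply(1:20, function(s) {
    a <- withr::with_seed(s, {
      freqs <- c(0.5, 0.3, 0.2)
      matrix(sample.int(3, 80, replace = TRUE, prob = freqs), 40)
    })
    gg <- genotype_tbl(sprintf("i%d", 1:40), "L1",
                       a1 = a[, 1, drop = FALSE], a2 = a[, 2, drop = FALSE])
    hwe_test(gg, rep("A", 40), n_samples = 2000, seed = s)$p_value
  }, numeric(1))
  expect_lte(mean(ps <= 0.05), 0.07 + 0.1) # small-sample slack on 20 draws
  mono <- genotype_tbl(sprintf("i%d", 1:6), "L1",
                       a1 = matrix(rep(1L, 6)), a2 = matrix(rep(1L, 6)))
  expect_equal(hwe_test(mono, rep("A", 6))$p_value, 1)
})

test_that("LD bookkeeping counts pairs per group and flags skipped pairs", {
  g <- toy_genotypes(48, 10, na = 3, pop = rep(paste0("P", 1:6), each = 8),
                     seed = 3)
  ld <- ld_pairwise_tests(g, permutations = 99, seed = 1)
  expect_equal(nrow(ld), choose(10, 2) * 6)
  s <- attr(ld, "summary")
  expect_equal(s$n_tests, sum(ld$tested))
  expect_equal(s$pct_significant,
               100 * s$n_significant / s$n_tests)
})

test_that("independently simulated loci show ~5% significant LD", {
  sig <- unlist(lapply(1:6, function(s) {
    g <- toy_genotypes(40, 10, na = 4, pop = rep("A", 40), seed = s + 100)
    ld <- ld_pairwise_tests(g, permutations = 199, seed = s)
    ld$p_value[ld$tested] <= 0.05
  }))
  expect_gt(length(sig), 200)
  expect_lt(mean(sig), 0.10)
  expect_gt(mean(sig), 0.01)
})

test_that("theta matches the hand-computed variance components on a toy locus", {
  # 4 individuals, 1 biallelic locus, 2 groups
  g <- genotype_tbl(c("i1", "i2", "i3", "i4"), "L1",
                    a1 = matrix(c(1L, 1L, 1L, 2L)),
                    a2 = matrix(c(1L, 2L, 2L, 2L)),
                    pop = c("A", "A", "B", "B"))
  th <- wc_theta(g)
  # oracle from the published component definitions (helper-fixtures.R)
  comp <- oracle_wc_biallelic(p1 = 3 / 4, p2 = 1 / 4, h1 = 1 / 2, h2 = 1 / 2,
                              n1 = 2, n2 = 2)
  expect_equal(th, comp[1] / sum(comp), tolerance = 1e-12)
})

test_that("theta hits its boundary cases", {
  # two groups fixed for different alleles at every locus
  g <- genotype_tbl(sprintf("i%d", 1:10), c("L1", "L2"),
                    a1 = cbind(rep(c(1L, 2L), each = 5), rep(c(3L, 4L), each = 5)),
                    a2 = cbind(rep(c(1L, 2L), each = 5), rep(c(3L, 4L), each = 5)),
                    pop = rep(c("A", "B"), each = 5))
  expect_equal(wc_theta(g), 1)
  # negative estimates are reported, not truncated: identical frequencies
  # but an excess of heterozygotes concentrated in one group
  gg <- genotype_tbl(c("i1", "i2", "i3", "i4"), "L1",
                     a1 = matrix(c(1L, 2L, 1L, 1L)), a2 = matrix(c(1L, 2L, 2L, 2L)),
                     pop = c("A", "A", "B", "B"))
  expect_lt(wc_theta(gg), 0)
})

test_that("AMOVA Phi_ST equals pairwise theta on balanced two-group data", {
  pool <- sim_species_pool(2, setNames(rep(6L, 5), paste0("L", 1:5)), 0.08,
                           seed = 2)
  ind <- sim_individuals(pool, lucerne_specs()[1:2, ], c(30, 30), seed = 2)
  a <- suppressWarnings(amova(ind$genotypes, permutations = 99, seed = 1))
  expect_equal(a$phi_st, wc_theta(ind$genotypes), tolerance = 1e-6)
  expect_lt(a$p_value, 0.05)
  expect_gt(a$sigma2_within, 0)
  expect_error(amova(ind$genotypes, rep("one", 60)), "2 groups")
  # random labels: Phi ~ 0 and nonsignificant most of the time
  ps <- vapply(1:10, function(s) {
    lab <- withr::with_seed(s, sample(rep(c("X", "Y"), 30)))
    suppressWarnings(amova(ind$genotypes, lab, permutations = 99, seed = s))$p_value
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.8)
})

test_that("rarefaction equals exhaustive subsample enumeration", {
  # single-locus toy: alleles A,A,B rarefied to 2 genes -> 5/3
  expect_equal(depthcline:::expected_allele_count(c(2, 1), 2), 5 / 3,
               tolerance = 1e-12)
  expect_equal(depthcline:::expected_allele_count(c(2, 1), 2),
               oracle_expected_alleles(c(2, 1), 2), tolerance = 1e-12)
  # <= 12 genes: exact match against enumeration for several configurations
  for (counts in list(c(5, 4, 3), c(7, 2, 1, 2), c(6, 6))) {
    for (g in c(2, 4, 6)) {
      expect_equal(depthcline:::expected_allele_count(counts, g),
                   oracle_expected_alleles(counts, g), tolerance = 1e-12)
      expect_equal(depthcline:::presence_prob(counts, sum(counts), g),
                   oracle_presence_prob(counts, g), tolerance = 1e-12)
    }
  }
})

test_that("rarefied richness is monotone, saturates, and flags private alleles", {
  g <- toy_genotypes(24, 4, na = 6, pop = rep(c("A", "B"), each = 12), seed = 9)
  r1 <- rarefied_richness(g, g = 6)
  r2 <- rarefied_richness(g, g = 12)
  expect_true(all(r2$per_locus$expected_alleles >=
                    r1$per_locus$expected_alleles - 1e-9))
  # at g = total genes of a single group, expected = observed count
  one <- g[g$pop == "A", , drop = FALSE]
  robs <- rarefied_richness(one, grouping = rep("A", 12), g = 24)
  ac <- allele_counts(one, rep("A", 12))
  obs <- tapply(!is.na(ac$allele), ac$locus, sum)
  expect_equal(robs$per_locus$expected_alleles,
               as.numeric(obs[robs$per_locus$locus]), ignore_attr = TRUE)
  # disjoint allele sets: private richness equals total richness
  gd <- genotype_tbl(sprintf("i%d", 1:8), "L1",
                     a1 = matrix(c(1L, 1L, 2L, 2L, 5L, 5L, 6L, 6L)),
                     a2 = matrix(c(1L, 2L, 1L, 2L, 5L, 6L, 5L, 6L)),
                     pop = rep(c("A", "B"), each = 4))
  rd <- rarefied_richness(gd, g = 8)
  expect_equal(rd$per_locus$private_alleles, rd$per_locus$expected_alleles,
               ignore_attr = TRUE)
  # generalized subsets cover every non-empty combination
  rc <- rarefied_richness(gd, g = 8, combinations = TRUE)
  expect_equal(nrow(rc$combinations), 3L)
})

test_that("individual genetic distances follow the squared count geometry", {
  g <- genotype_tbl(c("i1", "i2", "i3", "i4"), "L1",
                    a1 = matrix(c(1L, 2L, 1L, 3L)), a2 = matrix(c(1L, 2L, 2L, 4L)))
  D <- smouse_peakall_distance(g)
  expect_equal(D["i1", "i2"], 4) # AA vs BB
  expect_equal(D["i1", "i3"], 1) # AA vs AB
  expect_equal(D["i3", "i4"], 2) # AB vs CD
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  # pair sharing no typed locus -> NA
  gm <- genotype_tbl(c("i1", "i2"), c("L1", "L2"),
                     a1 = matrix(c(1L, NA, NA, 2L), 2), a2 = matrix(c(1L, NA, NA, 2L), 2))
  expect_true(is.na(smouse_peakall_distance(gm)["i1", "i2"]))
})

test_that("chord distances respect their closed forms and the triangle inequality", {
  f_id <- list(P1 = list(L1 = c(`1` = 0.3, `2` = 0.7)),
               P2 = list(L1 = c(`1` = 0.3, `2` = 0.7)))
  expect_equal(chord_distance(f_id)["P1", "P2"], 0)
  f_op <- list(P1 = list(L1 = c(`1` = 1, `2` = 0)),
               P2 = list(L1 = c(`1` = 0, `2` = 1)))
  expect_equal(chord_distance(f_op)["P1", "P2"], sqrt(2))
  for (s in 1:20) {
    p <- withr::with_seed(s, {
      m <- matrix(rgamma(9, 1), 3)
      m / rowSums(m)
    })
    fl <- list(P1 = list(L1 = setNames(p[1, ], 1:3)),
               P2 = list(L1 = setNames(p[2, ], 1:3)),
               P3 = list(L1 = setNames(p[3, ], 1:3)))
    D <- chord_distance(fl)
    expect_lte(D[1, 3], D[1, 2] + D[2, 3] + 1e-12)
  }
})

test_that("neighbour joining recovers additive trees exactly", {
  # ((A:2,B:3):1,(C:4,D:5)) as an additive distance matrix
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  D["A", "B"] <- D["B", "A"] <- 5
  D["A", "C"] <- D["C", "A"] <- 7
  D["A", "D"] <- D["D", "A"] <- 8
  D["B", "C"] <- D["C", "B"] <- 8
  D["B", "D"] <- D["D", "B"] <- 9
  D["C", "D"] <- D["D", "C"] <- 9
  nt <- nj_tree(D, bootstrap_replicates = 0)
  # the reconstructed tree reproduces the input distances exactly
  expect_equal(as.matrix(ape::cophenetic.phylo(nt$tree))[rownames(D), rownames(D)],
               D, tolerance = 1e-9)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
  # 3 taxa: branch lengths solve the three-point formulas
  D3 <- D[1:3, 1:3]
  t3 <- nj_tree(D3, bootstrap_replicates = 0)$tree
  el <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(el["A"]), (D3["A", "B"] + D3["A", "C"] - D3["B", "C"]) / 2)
  # identical loci -> 100% bootstrap support everywhere
  g <- toy_genotypes(40, 1, na = 5, pop = rep(paste0("P", 1:4), each = 10),
                     seed = 12)
  for (l in paste0("Lcopy", 1:5)) g[[l]] <- g$L1
  D4 <- chord_distance(g)
  nb <- nj_tree(D4, genotypes = g, bootstrap_replicates = 50, seed = 1)
  expect_true(all(nb$support == 100))
})

test_that("BH correction applies the step-up rule", {
  expect_true(all(fdr_correct(rep(0.001, 15))$significant))
  res <- fdr_correct(c(0.01, 0.02, 0.03, 0.04, 0.05))
  expect_true(all(res$significant)) # max k with p_(k) <= k q / m is 5
  expect_false(fdr_correct(0.06)$significant)
  expect_true(all(diff(sort(res$p_adj)) >= 0))
  expect_error(fdr_correct(c(0.5, 1.2)), "0, 1")
})

test_that("pairwise F_ST permutation test is calibrated under the null and powered", {
  g <- toy_genotypes(40, 8, na = 5, pop = rep(c("A", "B"), each = 20), seed = 31)
  f0 <- suppressWarnings(pairwise_fst(g, permutations = 199, seed = 1))
  expect_gt(f0$p_value, 0.05)             # random labels: no signal
  expect_lt(abs(f0$theta), 0.05)
  pool <- sim_species_pool(2, setNames(rep(8L, 10), paste0("L", 1:10)), 0.1,
                           seed = 7)
  ind <- sim_individuals(pool, lucerne_specs()[1:2, ], c(50, 50), seed = 7)
  f1 <- pairwise_fst(ind$genotypes, permutations = 199, seed = 1)
  expect_lt(f1$p_value, 0.05)
  M <- attr(f1, "matrix")
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
})
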