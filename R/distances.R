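#' Individual pairwise genetic distances (Smouse-Peakall)
#'
#' Per locus, each individual is an allele-count vector (entries 0/1/2
#' summing to 2); the locus distance between two individuals is half the
#' squared Euclidean norm of the difference (0 for identical genotypes,
#' 1 for AA vs AB, 2 for AB vs CD, 4 for AA vs BB). Locus distances are
#' summed over the loci typed in both individuals (pairwise deletion);
#' pairs sharing no typed locus get `NA`.
#'
#' @param genotypes a [genotype_tbl()].
#' @return symmetric numeric matrix (ids as dimnames), zero diagonal.
#' @export
smouse_peakall_distance <- function(genotypes) {
  ga <- geno_arrays(genotypes)
  n <- nrow(ga$a1)
  D <- matrix(0, n, n, dimnames = list(ga$ids, ga$ids))
  shared <- matrix(0L, n, n)
  for (l in seq_along(ga$loci)) {
    x <- ga$a1[, l]; y <- ga$a2[, l]
    typed <- which(!is.na(x) & !is.na(y))
    if (length(typed) < 2) next
    alleles <- sort(unique(c(x[typed], y[typed])))
    Y <- matrix(0, length(typed), length(alleles))
    Y[cbind(seq_along(typed), match(x[typed], alleles))] <-
      Y[cbind(seq_along(typed), match(x[typed], alleles))] + 1
    Y[cbind(seq_along(typed), match(y[typed], alleles))] <-
      Y[cbind(seq_along(typed), match(y[typed], alleles))] + 1
    dl <- 0.5 * as.matrix(stats::dist(Y))^2
    D[typed, typed] <- D[typed, typed] + dl
    shared[typed, typed] <- shared[typed, typed] + 1L
  }
  D[shared == 0] <- NA_real_
  diag(D) <- 0
  D
}

#' Cavalli-Sforza chord distances between populations
#'
#' Per locus, `cos theta = sum_i sqrt(p_i q_i)` over shared alleles; the
#' locus chord distance is `sqrt(2 * (1 - cos theta))` and locus distances
#' are averaged over the loci typed in both populations (a locus untyped in
#' either member of a pair is dropped for that pair). Zero iff the frequency
#' vectors are identical at every shared locus; symmetric; satisfies the
#' triangle inequality per locus.
#'
#' @param genotypes a [genotype_tbl()], or a pre-computed frequency list as
#'   returned by the internal frequency builder (population -> locus ->
#'   named frequency vector).
#' @param grouping see [allele_counts()] (ignored when `genotypes` is a
#'   frequency list).
#' @return symmetric population distance matrix.
#' @export
chord_distance <- function(genotypes, grouping = NULL) {
  freqs <- if (inherits(genotypes, "genotype_tbl")) {
    allele_freq_list(genotypes, grouping)
  } else genotypes
  pops <- names(freqs)
  if (length(pops) < 2) abort("need at least 2 populations")
  D <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1)) {
    f1 <- freqs[[i]]; f2 <- freqs[[j]]
    loci <- intersect(names(f1)[lengths(f1) > 0], names(f2)[lengths(f2) > 0])
    if (!length(loci)) { D[i, j] <- D[j, i] <- NA_real_; next }
    d <- vapply(loci, function(l) {
      al <- union(names(f1[[l]]), names(f2[[l]]))
      p <- f1[[l]][al]; p[is.na(p)] <- 0
      q <- f2[[l]][al]; q[is.na(q)] <- 0
      ct <- min(sum(sqrt(p * q)), 1)
      sqrt(2 * (1 - ct))
    }, numeric(1))
    D[i, j] <- D[j, i] <- mean(d)
  }
  D
}

#' Neighbour-joining tree with locus-bootstrap support
#'
#' Saitou-Nei NJ (via ape) on a population distance matrix. When genotypes
#' are supplied, bootstrap replicates resample loci with replacement,
#' recompute chord distances and NJ trees, and report majority-rule support
#' percentages on the internal edges of the point-estimate tree.
#'
#' @param distmatrix symmetric population distance matrix (>= 3 populations).
#' @param genotypes optional [genotype_tbl()] for bootstrapping.
#' @param grouping see [allele_counts()].
#' @param bootstrap_replicates number of locus resamples (default 1000).
#' @param seed integer seed.
#' @return list: `tree` (ape `phylo`), `support` (percent per internal
#'   node, `NA` without genotypes), `newick` (string with support labels).
#' @export
nj_tree <- function(distmatrix, genotypes = NULL, grouping = NULL,
                    bootstrap_replicates = 1000, seed = 1L) {
  check_square_symmetric(distmatrix, "distmatrix")
  if (nrow(distmatrix) < 3) abort("NJ needs at least 3 populations")
  tree <- ape::nj(stats::as.dist(distmatrix))
  support <- NULL
  if (!is.null(genotypes)) {
    freqs <- allele_freq_list(genotypes, grouping)
    loci <- names(freqs[[1]])
    boots <- with_seed(split_seed(seed, "nj_bootstrap"), {
      lapply(seq_len(bootstrap_replicates), function(b) {
        pick <- sample(loci, length(loci), replace = TRUE)
        fb <- lapply(freqs, function(fl) {
          out <- fl[pick]
          names(out) <- paste0("bs_", seq_along(pick))
          out
        })
        ape::nj(stats::as.dist(chord_distance(fb)))
      })
    })
    counts <- ape::prop.clades(tree, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0
    support <- 100 * counts / bootstrap_replicates
    tree$node.label <- formatC(support, format = "f", digits = 1)
  }
  list(tree = tree, support = support, newick = ape::write.tree(tree))
}
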