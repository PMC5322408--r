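# P(allele with count ni among N genes appears in a subsample of g genes):
# 1 - choose(N - ni, g) / choose(N, g), computed on the log scale.
presence_prob <- function(ni, N, g) {
  ifelse(N - ni < g, 1, 1 - exp(lchoose(N - ni, g) - lchoose(N, g)))
}

# Expected number of distinct alleles in a subsample of g genes from one
# locus with allele counts `counts`.
expected_allele_count <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g > N) g <- N
  sum(presence_prob(counts, N, g))
}

#' Rarefied allelic richness and private allelic richness
#'
#' Hypergeometric rarefaction to a standardized sample of `g` genes per
#' group. Expected distinct alleles per locus follows
#' `E[A] = sum_i (1 - C(N - N_i, g) / C(N, g))`. Private allelic richness of
#' group j sums, over alleles, the probability the allele appears in a
#' g-gene subsample of group j and in none of the other groups' subsamples.
#' With `combinations = TRUE`, the generalized variant is returned for every
#' non-empty group subset: alleles expected to occur in each subset member's
#' subsample and in no other group's.
#'
#' @param genotypes a [genotype_tbl()].
#' @param grouping see [allele_counts()].
#' @param g standardized gene count; `NULL` = smallest group gene count
#'   (values above any group's count are clipped with a warning).
#' @param combinations also compute generalized private richness over all
#'   group subsets.
#' @return a `rarefaction_result` list: `per_locus` (group x locus expected
#'   and private allele numbers), `by_group` (means per locus), and
#'   `combinations` (subset tibble) when requested; `g` used.
#' @export
rarefied_richness <- function(genotypes, grouping = NULL, g = NULL,
                              combinations = FALSE) {
  ac <- allele_counts(genotypes, grouping)
  ac <- ac[!is.na(ac$allele), ]
  groups <- unique(ac$group)
  loci <- unique(ac$locus)
  min_genes <- min(ac$n_genes)
  if (is.null(g)) {
    g <- min_genes
  } else if (g > min_genes) {
    warn(sprintf("g = %d exceeds the smallest group gene count; clipped to %d",
                 g, min_genes))
    g <- min_genes
  }
  if (g < 2) abort("rarefaction size must be at least 2 genes")

  # presence probabilities Q[group, allele] per locus
  per_locus <- list()
  subsets <- if (combinations) {
    unlist(lapply(seq_along(groups), function(k) {
      lapply(seq_len(ncol(combn(length(groups), k))), function(j) {
        groups[combn(length(groups), k)[, j]]
      })
    }), recursive = FALSE)
  } else NULL
  comb_acc <- if (combinations) {
    setNames(numeric(length(subsets)), vapply(subsets, paste, "", collapse = "+"))
  } else NULL
  for (l in loci) {
    sub <- ac[ac$locus == l, ]
    alleles <- sort(unique(sub$allele))
    Q <- matrix(0, length(groups), length(alleles),
                dimnames = list(groups, as.character(alleles)))
    for (gr in groups) {
      d <- sub[sub$group == gr, ]
      Ng <- d$n_genes[1]
      Q[gr, as.character(d$allele)] <- presence_prob(d$count, Ng, min(g, Ng))
    }
    expA <- rowSums(Q)
    priv <- vapply(seq_along(groups), function(j) {
      other <- Q[-j, , drop = FALSE]
      sum(Q[j, ] * apply(1 - other, 2, prod))
    }, numeric(1))
    per_locus[[l]] <- tibble::tibble(group = groups, locus = l,
                                     expected_alleles = expA,
                                     private_alleles = priv)
    if (combinations) {
      for (si in seq_along(subsets)) {
        inset <- groups %in% subsets[[si]]
        term <- apply(Q[inset, , drop = FALSE], 2, prod) *
          (if (any(!inset)) apply(1 - Q[!inset, , drop = FALSE], 2, prod) else 1)
        comb_acc[si] <- comb_acc[si] + sum(term)
      }
    }
  }
  pl <- dplyr::bind_rows(per_locus)
  by_group <- dplyr::summarise(dplyr::group_by(pl, .data$group),
                               allelic_richness = mean(.data$expected_alleles),
                               private_richness = mean(.data$private_alleles),
                               .groups = "drop")
  out <- list(per_locus = pl, by_group = by_group, g = g)
  if (combinations) {
    out$combinations <- tibble::tibble(
      subset = names(comb_acc),
      n_groups = vapply(subsets, length, integer(1)),
      mean_private_per_locus = unname(comb_acc) / length(loci))
  }
  structure(out, class = "rarefaction_result")
}
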