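#' Per-group per-locus allele counts
#'
#' Missing calls are excluded; gene counts are `2 x` typed individuals,
#' locus-specific. A group with no typed individual at a locus is flagged
#' with a zero-row entry (`n_genes = 0`).
#'
#' @param genotypes a [genotype_tbl()].
#' @param grouping group labels: a vector, a column name, or `NULL` for the
#'   `pop` column.
#' @return tibble: `group`, `locus`, `allele`, `count`, `n_genes`.
#' @export
allele_counts <- function(genotypes, grouping = NULL) {
  ga <- geno_arrays(genotypes)
  grp <- resolve_grouping(genotypes, grouping)
  rows <- list()
  for (gname in unique(grp)) {
    sel <- grp == gname
    for (l in seq_along(ga$loci)) {
      x <- ga$a1[sel, l]; y <- ga$a2[sel, l]
      typed <- !is.na(x) & !is.na(y)
      genes <- c(x[typed], y[typed])
      if (!length(genes)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          group = gname, locus = ga$loci[l], allele = NA_integer_,
          count = 0L, n_genes = 0L)
        next
      }
      tab <- table(genes)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = gname, locus = ga$loci[l],
        allele = as.integer(names(tab)), count = as.integer(tab),
        n_genes = length(genes))
    }
  }
  dplyr::bind_rows(rows)
}

# Allele-frequency list by group: freqs[[group]][[locus]] named numeric.
allele_freq_list <- function(genotypes, grouping = NULL) {
  ac <- allele_counts(genotypes, grouping)
  ac <- ac[!is.na(ac$allele), ]
  out <- list()
  for (gname in unique(ac$group)) {
    sub <- ac[ac$group == gname, ]
    out[[gname]] <- lapply(split(sub, sub$locus), function(d) {
      setNames(d$count / d$n_genes, d$allele)
    })
  }
  out
}

#' Genetic diversity summary per group
#'
#' Per group and locus: gene count, observed heterozygosity H_O, unbiased
#' expected heterozygosity `H_E = 2n/(2n-1) * (1 - sum p^2)`, the
#' Weir-Cockerham within-population inbreeding coefficient f (F_IS), and the
#' observed allele number A_N. Per group across loci: unweighted means of
#' H_O/H_E, multilocus F_IS as the ratio of summed variance components, and
#' allelic richness A_R rarefied to `g_std` genes. Monomorphic loci have
#' `h_exp = 0` and undefined (NA) F_IS.
#'
#' @param genotypes a [genotype_tbl()].
#' @param grouping see [allele_counts()].
#' @param g_std standardized gene count for A_R; `NULL` = smallest per-group
#'   minimum locus gene count; values above that are clipped with a warning.
#' @return a `diversity_table` tibble (per group x locus) with a `by_group`
#'   attribute holding the across-locus summary.
#' @export
diversity_summary <- function(genotypes, grouping = NULL, g_std = NULL) {
  ga <- geno_arrays(genotypes)
  grp <- resolve_grouping(genotypes, grouping)
  groups <- unique(grp)
  min_genes <- min(vapply(groups, function(gname) {
    sel <- grp == gname
    min(vapply(seq_along(ga$loci), function(l) {
      2L * sum(!is.na(ga$a1[sel, l]) & !is.na(ga$a2[sel, l]))
    }, integer(1)))
  }, integer(1)))
  if (is.null(g_std)) {
    g_std <- min_genes
  } else if (g_std > min_genes) {
    warn(sprintf("g_std = %d exceeds the smallest group gene count; clipped to %d",
                 g_std, min_genes))
    g_std <- min_genes
  }
  per_locus <- list(); per_group <- list()
  for (gname in groups) {
    sel <- grp == gname
    bc <- matrix(0, length(ga$loci), 2)
    ho_v <- he_v <- fis_v <- an_v <- ar_v <- ng_v <- rep(NA_real_, length(ga$loci))
    for (l in seq_along(ga$loci)) {
      x <- ga$a1[sel, l]; y <- ga$a2[sel, l]
      typed <- !is.na(x) & !is.na(y)
      x <- x[typed]; y <- y[typed]
      n <- length(x)
      ng_v[l] <- 2 * n
      if (n == 0) next
      ho <- mean(x != y)
      genes <- c(x, y)
      p <- as.numeric(table(genes)) / (2 * n)
      he <- if (n > 0 && 2 * n > 1) (2 * n) / (2 * n - 1) * (1 - sum(p^2)) else NA_real_
      an <- length(p)
      comp <- wc_f_locus(ga$a1[sel, l], ga$a2[sel, l])
      bc[l, ] <- comp
      fis <- if (an > 1 && sum(comp) > 0) 1 - comp[2] / sum(comp) else NA_real_
      cntl <- as.numeric(table(genes))
      ar_v[l] <- expected_allele_count(cntl, min(g_std, 2 * n))
      ho_v[l] <- ho; he_v[l] <- if (an > 1) he else 0
      fis_v[l] <- fis; an_v[l] <- an
    }
    per_locus[[gname]] <- tibble::tibble(
      group = gname, locus = ga$loci, n_genes = ng_v,
      h_obs = ho_v, h_exp = he_v, f_is = fis_v, a_n = an_v)
    fis_multi <- if (sum(bc) > 0) 1 - sum(bc[, 2]) / sum(bc) else NA_real_
    per_group[[gname]] <- tibble::tibble(
      group = gname, n = sum(sel), g_std = g_std,
      h_obs = mean(ho_v, na.rm = TRUE), h_exp = mean(he_v, na.rm = TRUE),
      f_is = fis_multi, a_r = mean(ar_v, na.rm = TRUE),
      a_n = mean(an_v, na.rm = TRUE))
  }
  out <- dplyr::bind_rows(per_locus)
  attr(out, "by_group") <- dplyr::bind_rows(per_group)
  class(out) <- c("diversity_table", class(out))
  out
}

#' Across-locus group summary of a diversity table
#' @param div a [diversity_summary()] result.
#' @return the per-group summary tibble.
#' @export
diversity_by_group <- function(div) attr(div, "by_group")

#' Append overall rows to a per-group statistics table
#'
#' Adds an unweighted overall row (plain column means, sample sizes summed)
#' and, when a size column is given, a weighted one. This reproduces the
#' usual "overall" row of published diversity tables, which for this kind of
#' survey is the unweighted mean of the per-species values.
#'
#' @param tbl tibble of per-group statistics (numeric columns averaged).
#' @param n_col name of the sample-size column (summed, and used as weights
#'   for the weighted row); `NULL` for unweighted only.
#' @param label_col name of the group-label column.
#' @return `tbl` with `overall_unweighted` (and `overall_weighted`) rows.
#' @export
add_overall_rows <- function(tbl, n_col = "n", label_col = "group") {
  num <- setdiff(names(tbl)[vapply(tbl, is.numeric, logical(1))], n_col)
  mk <- function(label, fun) {
    row <- tbl[1, ]
    row[label_col] <- label
    for (cc in names(row)) if (!cc %in% c(label_col, n_col, num)) row[[cc]] <- NA
    for (cc in num) row[[cc]] <- fun(tbl[[cc]])
    if (!is.null(n_col) && n_col %in% names(tbl)) row[[n_col]] <- sum(tbl[[n_col]])
    row
  }
  out <- dplyr::bind_rows(tbl, mk("overall_unweighted", function(v) mean(v, na.rm = TRUE)))
  if (!is.null(n_col) && n_col %in% names(tbl)) {
    w <- tbl[[n_col]]
    out <- dplyr::bind_rows(out, mk("overall_weighted", function(v) {
      ok <- !is.na(v); sum(v[ok] * w[ok]) / sum(w[ok])
    }))
  }
  out
}
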