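# Individuals x alleles count matrix (0/1/2 per allele per locus), with
# per-individual missing loci mean-imputed so the PCA is defined.
allele_count_matrix <- function(genotypes) {
  ga <- geno_arrays(genotypes)
  blocks <- lapply(seq_along(ga$loci), function(l) {
    x <- ga$a1[, l]; y <- ga$a2[, l]
    alleles <- sort(unique(c(x[!is.na(x)], y[!is.na(y)])))
    Y <- matrix(0, length(x), length(alleles))
    ok <- which(!is.na(x))
    Y[cbind(ok, match(x[ok], alleles))] <- Y[cbind(ok, match(x[ok], alleles))] + 1
    Y[cbind(ok, match(y[ok], alleles))] <- Y[cbind(ok, match(y[ok], alleles))] + 1
    miss <- which(is.na(x))
    if (length(miss) && length(ok)) {
      Y[miss, ] <- matrix(colMeans(Y[ok, , drop = FALSE]),
                          length(miss), length(alleles), byrow = TRUE)
    }
    colnames(Y) <- paste0(ga$loci[l], ".", alleles)
    Y
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- ga$ids
  out
}

#' Discriminant analysis of principal components (DAPC-style assignment)
#'
#' Column-centres the individual allele-count matrix, reduces it by PCA,
#' picks the number of retained principal components by minimising the
#' cross-validated assignment RMSE (root-mean-square of `1 - P(correct
#' group)` over held-out fish, stratified folds), then fits a linear
#' discriminant on the retained PCs and reports per-individual posterior
#' membership probabilities to each prior group.
#'
#' @param genotypes a [genotype_tbl()].
#' @param prior_groups see [allele_counts()]; >= 2 groups.
#' @param cv_folds folds for cross-validation (shrunk with a warning when a
#'   group is smaller).
#' @param max_pc upper bound of the PC grid (default 50).
#' @param seed integer seed (fold assignment).
#' @return a `dapc_result` list: `membership` (tibble id, group, one column
#'   per group, `assigned`), `rmse` (tibble n_pc, rmse), `n_pc` retained.
#' @export
dapc_assign <- function(genotypes, prior_groups = NULL, cv_folds = 5,
                        max_pc = 50, seed = 1L) {
  grp <- factor(resolve_grouping(genotypes, prior_groups))
  if (nlevels(grp) < 2) abort("need at least 2 prior groups")
  X <- allele_count_matrix(genotypes)
  X <- scale(X, center = TRUE, scale = FALSE)
  n <- nrow(X)
  min_grp <- min(table(grp))
  if (min_grp < cv_folds) {
    warn(sprintf("smallest group (%d) below cv_folds; folds shrunk", min_grp))
    cv_folds <- max(2, min_grp)
  }
  pc <- prcomp(X, center = FALSE)
  keep <- which(pc$sdev > 1e-8)
  scores <- pc$x[, keep, drop = FALSE]
  grid <- seq_len(min(max_pc, ncol(scores), n - cv_folds))
  folds <- with_seed(split_seed(seed, "dapc_folds"), {
    f <- integer(n)
    for (lv in levels(grp)) {
      idx <- which(grp == lv)
      f[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
    f
  })
  rmse <- vapply(grid, function(npc) {
    err2 <- numeric(0)
    for (k in seq_len(cv_folds)) {
      tr <- folds != k; te <- !tr
      if (length(unique(grp[tr])) < 2) return(NA_real_)
      fit <- MASS::lda(scores[tr, seq_len(npc), drop = FALSE], grouping = grp[tr])
      post <- predict(fit, scores[te, seq_len(npc), drop = FALSE])$posterior
      pc_correct <- post[cbind(seq_len(sum(te)),
                               match(grp[te], colnames(post)))]
      err2 <- c(err2, (1 - pc_correct)^2)
    }
    sqrt(mean(err2))
  }, numeric(1))
  n_pc <- grid[which.min(rmse)]
  fit <- MASS::lda(scores[, seq_len(n_pc), drop = FALSE], grouping = grp)
  post <- predict(fit, scores[, seq_len(n_pc), drop = FALSE])$posterior
  membership <- tibble::tibble(id = rownames(X) %||% as.character(seq_len(n)),
                               group = as.character(grp))
  for (lv in colnames(post)) membership[[lv]] <- post[, lv]
  membership$assigned <- colnames(post)[max.col(post)]
  structure(list(membership = membership,
                 rmse = tibble::tibble(n_pc = grid, rmse = rmse),
                 n_pc = n_pc, seed = seed),
            class = "dapc_result")
}

#' Median self-assignment probability of a DAPC result
#' @param x a `dapc_result`.
#' @return named numeric: per-group median posterior to the own group.
#' @export
self_assignment <- function(x) {
  mb <- x$membership
  vapply(split(mb, mb$group), function(d) {
    median(vapply(seq_len(nrow(d)), function(i) d[[d$group[i]]][i], numeric(1)))
  }, numeric(1))
}
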