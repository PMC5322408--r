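# Weir-Cockerham (1984) variance components for one locus.
#
# x, y: integer allele vectors (one per individual, NA = missing);
# g: integer group index per individual (1..r). Returns the per-allele
# components summed over alleles: c(a, b, c). Individuals untyped at the
# locus are dropped (per-locus pairwise deletion); groups with no typed
# individuals are dropped for that locus.
wc_locus_components <- function(x, y, g) {
  typed <- !is.na(x) & !is.na(y)
  x <- x[typed]; y <- y[typed]; g <- g[typed]
  keep <- sort(unique(g))
  g <- match(g, keep)
  r <- length(keep)
  if (r < 2 || length(x) < 2) return(c(a = 0, b = 0, c = 0))
  ni <- tabulate(g, r)
  if (any(ni < 2)) {
    keep2 <- which(ni >= 2)
    if (length(keep2) < 2) return(c(a = 0, b = 0, c = 0))
    sel <- g %in% keep2
    x <- x[sel]; y <- y[sel]; g <- match(g[sel], keep2)
    r <- length(keep2); ni <- tabulate(g, r)
  }
  alleles <- sort(unique(c(x, y)))
  if (length(alleles) < 2) return(c(a = 0, b = 0, c = 0))
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  A <- length(alleles)
  # per-group allele counts and heterozygote-containing counts (vectorised)
  ax <- match(x, alleles); ay <- match(y, alleles)
  cnt <- matrix(tabulate(c(g + (ax - 1L) * r, g + (ay - 1L) * r), r * A), r, A)
  hi <- ax != ay
  hets <- matrix(tabulate(c(g[hi] + (ax[hi] - 1L) * r, g[hi] + (ay[hi] - 1L) * r),
                          r * A), r, A)
  if (nbar <= 1) return(c(a = 0, b = 0, c = 0))
  p <- cnt / (2 * ni)
  hfreq <- hets / ni
  pbar <- colSums(ni * p) / (r * nbar)
  s2 <- colSums(ni * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(ni * hfreq) / (r * nbar)
  a_u <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b_u <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_u <- hbar / 2
  c(a = sum(a_u), b = sum(b_u), c = sum(c_u))
}

# Multilocus Weir-Cockerham theta (ratio of sums over loci and alleles) from
# decoded arrays. Returns c(theta, a, b, c).
wc_theta_arrays <- function(ga, g) {
  g <- as.integer(factor(g))
  comp <- vapply(seq_along(ga$loci),
                 function(l) wc_locus_components(ga$a1[, l], ga$a2[, l], g),
                 numeric(3))
  a <- sum(comp[1, ]); b <- sum(comp[2, ]); cc <- sum(comp[3, ])
  denom <- a + b + cc
  c(theta = if (denom > 0) a / denom else NA_real_, a = a, b = b, c = cc)
}

# Within-population Weir-Cockerham f components for one locus in ONE group.
# Returns c(b, c); f = 1 - sum(c) / sum(b + c).
wc_f_locus <- function(x, y) {
  typed <- !is.na(x) & !is.na(y)
  x <- x[typed]; y <- y[typed]
  n <- length(x)
  if (n < 2) return(c(b = 0, c = 0))
  alleles <- sort(unique(c(x, y)))
  if (length(alleles) < 2) return(c(b = 0, c = 0))
  b_tot <- c_tot <- 0
  for (u in alleles) {
    p <- (sum(x == u) + sum(y == u)) / (2 * n)
    h <- sum((x == u) != (y == u)) / n  # individuals heterozygous for u
    b_u <- (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
    c_u <- h / 2
    b_tot <- b_tot + b_u; c_tot <- c_tot + c_u
  }
  c(b = b_tot, c = c_tot)
}
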