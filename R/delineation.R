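#' Shapiro-Wilk normality test
#'
#' Thin wrapper returning a tidy one-row tibble; the screening step that
#' decides whether mixture modelling of a size distribution is warranted.
#'
#' @param values numeric vector (3 <= n <= 5000).
#' @return tibble with `statistic` (W), `p_value`, `n`.
#' @export
normality_test <- function(values) {
  values <- values[!is.na(values)]
  if (length(unique(values)) < 2) abort("normality test undefined for constant input")
  ht <- shapiro.test(values)
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n = length(values))
}

# Log-likelihood of a univariate Gaussian mixture (sds floored at 1 mm so a
# degenerate component cannot blow up the likelihood).
mixture_loglik <- function(x, means, sds, weights, sd_floor = 1) {
  sds <- pmax(sds, sd_floor)
  dens <- vapply(seq_along(means),
                 function(k) weights[k] * dnorm(x, means[k], sds[k]),
                 numeric(length(x)))
  sum(log(pmax(rowSums(as.matrix(dens)), 1e-300)))
}

# Univariate Gaussian-mixture EM with unequal variances, multiple restarts
# (first start deterministic at the k quantile midpoints, the rest
# k-means++-style seeded draws), and a 1-mm sd floor against degenerate
# components. The variance M-step carries a light inverse-gamma
# regularization (scale var(x)/k^2, dof nu = 3 pseudo-observations, matching
# mclust's defaultPrior for univariate models) so the unbounded-likelihood
# spikes of unequal-variance mixtures cannot masquerade as components; the
# reported log-likelihood is the ordinary unpenalized one. Returns the best
# fit by log-likelihood.
em_mixture <- function(x, k, restarts = 10, sd_floor = 1, tol = 1e-8,
                       maxit = 500, seed = 1L) {
  n <- length(x)
  nu <- 3
  s0 <- var(x) / k^2
  best <- NULL
  starts <- with_seed(seed, {
    lapply(seq_len(restarts), function(r) {
      if (r == 1) {
        stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
      } else {
        # k-means++-style: spread initial means out
        mu <- sample(x, 1)
        while (length(mu) < k) {
          d2 <- vapply(x, function(v) min((v - mu)^2), numeric(1))
          mu <- c(mu, if (sum(d2) > 0) sample(x, 1, prob = d2) else sample(x, 1))
        }
        sort(mu)
      }
    })
  })
  for (mu0 in starts) {
    means <- mu0; sds <- rep(max(sd(x), sd_floor), k); weights <- rep(1 / k, k)
    ll_old <- -Inf
    for (it in seq_len(maxit)) {
      dens <- vapply(seq_len(k),
                     function(j) weights[j] * dnorm(x, means[j], sds[j]),
                     numeric(n))
      dens <- matrix(dens, n, k)
      tot <- pmax(rowSums(dens), 1e-300)
      resp <- dens / tot
      nk <- colSums(resp)
      if (any(nk < 1e-8)) break
      weights <- nk / n
      means <- colSums(resp * x) / nk
      ss <- colSums(resp * (x - rep(means, each = n))^2)
      sds <- pmax(sqrt((ss + nu * s0) / (nk + nu)), sd_floor)
      ll <- sum(log(tot))
      if (is.finite(ll) && ll - ll_old < tol * (abs(ll_old) + 1)) { ll_old <- ll; break }
      ll_old <- ll
    }
    ll_final <- mixture_loglik(x, means, sds, weights, sd_floor)
    if (is.null(best) || ll_final > best$loglik) {
      ord <- order(means)
      best <- list(means = means[ord], sds = sds[ord], weights = weights[ord],
                   loglik = ll_final)
    }
  }
  best
}

#' Fit 1..k_max component Gaussian mixtures and select by AICc
#'
#' Fits univariate normal mixtures with unequal variances by EM (10
#' restarts: one deterministic quantile start plus k-means++-style seeded
#' starts; component sds floored at 1 mm) and compares them with the
#' small-sample corrected AIC: `AICc = -2 lnL + 2p + 2p(p+1)/(n - p - 1)`
#' with `p = 3k - 1` free parameters. Models within `delta_aicc < 2` of the
#' best are reported as equally likely.
#'
#' @param values numeric vector (n > 3 * k_max).
#' @param k_max maximum component count (default 3).
#' @param restarts EM restarts per k.
#' @param seed integer seed for the restart draws (results are otherwise
#'   deterministic in the data).
#' @return a `mixture_fits` tibble: one row per k with `loglik`, `n_par`,
#'   `aicc`, `delta_aicc`, `equally_likely` and list-columns `means`, `sds`,
#'   `weights`; attribute `selected_k` = argmin AICc.
#' @export
fit_gaussian_mixtures <- function(values, k_max = 3, restarts = 10, seed = 1L) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n <= 3 * k_max) abort("need n > 3 * k_max observations")
  rows <- list()
  for (k in seq_len(k_max)) {
    if (k == 1) {
      means <- mean(x)
      sds <- max(sqrt(var(x) * (n - 1) / n), 1)
      weights <- 1
    } else {
      fit <- em_mixture(x, k, restarts = restarts,
                        seed = split_seed(seed, paste0("em_", k)))
      means <- fit$means; sds <- fit$sds; weights <- fit$weights
    }
    ll <- mixture_loglik(x, means, sds, weights)
    p <- 3 * k - 1
    aicc <- if (n > p + 1) -2 * ll + 2 * p + 2 * p * (p + 1) / (n - p - 1) else Inf
    rows[[length(rows) + 1L]] <- tibble::tibble(
      k = k, loglik = ll, n_par = p, aicc = aicc,
      means = list(means), sds = list(sds), weights = list(weights))
  }
  out <- dplyr::bind_rows(rows)
  out$delta_aicc <- out$aicc - min(out$aicc)
  out$equally_likely <- out$delta_aicc < 2
  attr(out, "selected_k") <- out$k[which.min(out$aicc)]
  class(out) <- c("mixture_fits", class(out))
  out
}

#' Selected component count of a mixture fit
#' @param fits a `mixture_fits` object.
#' @return integer k minimising AICc.
#' @export
selected_k <- function(fits) attr(fits, "selected_k")

# Density-dip ratio between two candidate 1D clusters: kernel density of the
# merged sample evaluated at the midpoint between the clusters, relative to
# the smaller flanking peak. ~1 for a unimodal sample, << 1 across a true
# cluster boundary.
dip_ratio <- function(a, b) {
  xx <- c(a, b)
  if (diff(range(xx)) < 1e-9) return(1)
  d <- density(xx, n = 256)
  bdry <- (max(a) + min(b)) / 2
  fb <- approx(d$x, d$y, xout = bdry, rule = 2)$y
  peak_lo <- max(d$y[d$x <= bdry], 0)
  peak_hi <- max(d$y[d$x >= bdry], 0)
  fb / max(min(peak_lo, peak_hi), 1e-12)
}

#' Dynamic hybrid tree cut of a univariate size distribution
#'
#' Two-stage cluster detection without a prespecified k. Stage 1 walks the
#' average-linkage dendrogram of absolute SL differences top-down and splits
#' a branch only when (a) both sub-branches hold at least
#' `ceiling(min_frac * n)` fish and (b) the kernel-density dip between them
#' falls below `dip_max` times the smaller flanking peak; branches too small
#' to stand alone are left unassigned. Stage 2 attaches every unassigned
#' fish to the cluster with the nearest medoid. Clusters are numbered in
#' increasing medoid order, so labels do not depend on input order.
#'
#' @param values numeric vector (n >= 10).
#' @param min_frac minimal cluster size as a fraction of n (default 0.10).
#' @param dip_max density-dip threshold for declaring two branches distinct
#'   (0.85 by default, calibrated midway between the dip ratios observed at
#'   true cluster boundaries, below ~0.8, and within single modes, ~1).
#' @return a `cluster_solution`: tibble (`value`, `stage1`, `cluster`) with
#'   attributes `medoids`, `k`, `min_cluster_size`.
#' @export
hybrid_tree_cut <- function(values, min_frac = 0.10, dip_max = 0.85) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 10) abort("need at least 10 values")
  minsize <- max(2L, ceiling(min_frac * n))
  if (n * min_frac < 2) abort("min_frac * n must be at least 2")
  hc <- stats::hclust(dist(x), method = "average")
  m <- hc$merge; h <- hc$height
  members <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    l <- m[i, 1]; r <- m[i, 2]
    members[[i]] <- c(if (l < 0) -l else members[[l]],
                      if (r < 0) -r else members[[r]])
  }
  memb <- function(idx) if (idx < 0) -idx else members[[idx]]
  labels <- integer(n); k <- 0L
  assign_cluster <- function(idxs) { k <<- k + 1L; labels[idxs] <<- k }
  recurse <- function(node) {
    repeat {
      if (node < 0) { assign_cluster(-node); return(invisible()) }
      l <- m[node, 1]; r <- m[node, 2]
      sl <- length(memb(l)); sr <- length(memb(r))
      if (sl < minsize && sr < minsize) { assign_cluster(memb(node)); return(invisible()) }
      if (sl < minsize || sr < minsize) {
        # small side stays unassigned for stage 2; continue into the big side
        node <- if (sl >= minsize) l else r
        next
      }
      a <- x[memb(l)]; b <- x[memb(r)]
      if (mean(a) > mean(b)) { tmp <- a; a <- b; b <- tmp }
      if (dip_ratio(sort(a), sort(b)) <= dip_max) {
        recurse(l); recurse(r); return(invisible())
      }
      assign_cluster(memb(node)); return(invisible())
    }
  }
  if (n == 1) labels <- 1L else recurse(n - 1)
  stage1 <- labels
  if (any(labels == 0) && k > 0) {
    med <- vapply(seq_len(k), function(cl) median(x[labels == cl]), numeric(1))
    for (i in which(labels == 0)) labels[i] <- which.min(abs(med - x[i]))
  }
  med <- vapply(seq_len(k), function(cl) median(x[labels == cl]), numeric(1))
  ord <- order(med)
  relab <- match(seq_len(k), ord)
  labels <- relab[labels]
  stage1[stage1 > 0] <- relab[stage1[stage1 > 0]]
  out <- tibble::tibble(value = x, stage1 = stage1, cluster = labels)
  attr(out, "medoids") <- sort(med)
  attr(out, "k") <- k
  attr(out, "min_cluster_size") <- minsize
  class(out) <- c("cluster_solution", class(out))
  out
}

#' Assign new individuals to existing SL clusters
#'
#' Nearest-medoid assignment; an exact midpoint tie goes to the lower-SL
#' cluster.
#'
#' @param new_values numeric vector.
#' @param solution a [hybrid_tree_cut()] result.
#' @return integer cluster labels.
#' @export
assign_to_clusters <- function(new_values, solution) {
  med <- attr(solution, "medoids")
  if (!length(med)) abort("empty cluster solution")
  vapply(new_values, function(v) {
    d <- abs(med - v)
    which(d <= min(d) + 1e-12)[1] # ties -> lower medoid
  }, integer(1))
}

#' Pairwise Mann-Whitney age comparison between SL classes
#'
#' Compares the age distributions of every pair of SL classes with two-sided
#' Mann-Whitney U tests: if within-mesh multimodality were caused by age
#' structure of a single species, classes should differ systematically in
#' age.
#'
#' The p-value is exact (complete enumeration of group assignments, midranks
#' for ties) when the pair is small enough, otherwise the normal
#' approximation with continuity correction is used.
#'
#' @param pheno phenotype tibble with `age` and a class column.
#' @param class_col name of the class column (default `sl_class`).
#' @return tibble: class pair, sample sizes, U statistic, two-sided p.
#' @export
age_class_comparison <- function(pheno, class_col = "sl_class") {
  stopifnot("age" %in% names(pheno), class_col %in% names(pheno))
  dat <- pheno[!is.na(pheno$age) & !is.na(pheno[[class_col]]), ]
  cls <- sort(unique(dat[[class_col]]))
  ok <- cls[vapply(cls, function(cc) sum(dat[[class_col]] == cc) >= 3, logical(1))]
  if (length(ok) < 2) abort("need at least 2 classes with >= 3 aged fish")
  pairs <- combn(ok, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- dat$age[dat[[class_col]] == pairs[1, j]]
    b <- dat$age[dat[[class_col]] == pairs[2, j]]
    res <- mann_whitney_u(a, b)
    tibble::tibble(class1 = pairs[1, j], class2 = pairs[2, j],
                   n1 = length(a), n2 = length(b),
                   statistic = res$u, p_value = res$p)
  })
}

# Mann-Whitney U with exact enumeration for small pairs, normal
# approximation otherwise. Two-sided; symmetric in U and U' = n1*n2 - U.
mann_whitney_u <- function(a, b, exact_limit = 20000) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (choose(n1 + n2, n1) <= exact_limit) {
    idx <- combn(n1 + n2, n1)
    dev_obs <- abs(u - n1 * n2 / 2)
    us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(us - n1 * n2 / 2) >= dev_obs - 1e-9)
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    p <- wt$p.value
  }
  list(u = u, p = p)
}
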