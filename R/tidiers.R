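#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a mixture fit: one row per component
#' @param x a `mixture_fits` object.
#' @param ... unused.
#' @return tibble: k, component, mean, sd, weight.
#' @export
tidy.mixture_fits <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    tibble::tibble(k = x$k[i], component = seq_len(x$k[i]),
                   mean = x$means[[i]], sd = x$sds[[i]],
                   weight = x$weights[[i]])
  })
}

#' One-row mixture-selection summary
#' @param x a `mixture_fits` object.
#' @param ... unused.
#' @return tibble: selected_k, best aicc, n equally likely models.
#' @export
glance.mixture_fits <- function(x, ...) {
  tibble::tibble(selected_k = selected_k(x), aicc = min(x$aicc),
                 n_equally_likely = sum(x$equally_likely))
}

#' Tidy a cluster solution: per-cluster sizes and medoids
#' @param x a `cluster_solution`.
#' @param ... unused.
#' @export
tidy.cluster_solution <- function(x, ...) {
  med <- attr(x, "medoids")
  tibble::tibble(cluster = seq_along(med), medoid = med,
                 n = as.integer(table(x$cluster)))
}

#' @export
glance.cluster_solution <- function(x, ...) {
  tibble::tibble(k = attr(x, "k"),
                 min_cluster_size = attr(x, "min_cluster_size"),
                 n = nrow(x))
}

#' Tidy an F_ST result: the pair table itself
#' @param x an `fst_matrix`.
#' @param ... unused.
#' @export
tidy.fst_matrix <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.fst_matrix <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x), mean_theta = mean(x$theta),
                 min_theta = min(x$theta), max_theta = max(x$theta),
                 n_significant = sum(x$significant),
                 permutations = attr(x, "permutations"))
}

#' @export
tidy.amova_result <- function(x, ...) {
  tibble::tibble(term = c("among_groups", "within_groups"),
                 sigma2 = c(x$sigma2_among, x$sigma2_within))
}

#' @export
glance.amova_result <- function(x, ...) {
  tibble::tibble(grouping = x$grouping_name, phi_st = x$phi_st,
                 p_value = x$p_value, permutations = x$permutations)
}

#' @export
tidy.mantel_result <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
tidy.dapc_result <- function(x, ...) x$membership

#' @export
glance.dapc_result <- function(x, ...) {
  tibble::tibble(n_pc = x$n_pc, rmse = min(x$rmse$rmse, na.rm = TRUE))
}
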