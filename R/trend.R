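#' Linear trend of a response along a gradient covariate
#'
#' Ordinary least squares with the F test on the slope (equivalently the
#' squared t test of the slope), reported in the standard
#' `F(df1, df2) = value, p` form used for gradient regressions.
#'
#' @param data a data frame.
#' @param y,x column names (strings) of response and covariate.
#' @return tibble: `slope`, `f_statistic`, `df1`, `df2`, `p_value`, `n`.
#' @export
linear_trend <- function(data, y, x) {
  d <- data[stats::complete.cases(data[[y]], data[[x]]), c(y, x)]
  if (nrow(d) < 3) abort("need at least 3 complete observations")
  if (length(unique(d[[x]])) < 2) abort("covariate is constant")
  fit <- lm(stats::reformulate(x, y), data = d)
  an <- anova(fit)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 f_statistic = an$`F value`[1],
                 df1 = an$Df[1], df2 = an$Df[2],
                 p_value = an$`Pr(>F)`[1], n = nrow(d))
}

#' Great-circle distances between sites
#'
#' Haversine distances in km between decimal-degree coordinates.
#'
#' @param sites tibble with `site_lat` and `site_lon` (or `lat`/`lon`)
#'   columns; row names or a `site` column label the matrix.
#' @return symmetric distance matrix (km), zero diagonal.
#' @export
geographic_distance <- function(sites) {
  lat <- sites[["site_lat"]] %||% sites[["lat"]]
  lon <- sites[["site_lon"]] %||% sites[["lon"]]
  if (is.null(lat) || is.null(lon)) abort("need site_lat/site_lon columns")
  m <- geosphere::distm(cbind(lon, lat), fun = geosphere::distHaversine) / 1000
  labs <- sites[["site"]] %||% rownames(sites)
  dimnames(m) <- list(labs, labs)
  m
}

#' Two-sample location tests for a trait between two groups
#'
#' Welch t test and Mann-Whitney U (exact for small pairs) side by side, the
#' standard pairing for gill-raker and size comparisons between species.
#'
#' @param values numeric trait vector.
#' @param labels two-level group labels.
#' @return tibble: group means, `t`, `df`, `p_t`, `u`, `p_u`.
#' @export
two_group_tests <- function(values, labels) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  lv <- sort(unique(labels))
  if (length(lv) != 2) abort("exactly two groups required")
  a <- values[labels == lv[1]]; b <- values[labels == lv[2]]
  if (length(a) < 2 || length(b) < 2) abort("each group needs n >= 2")
  tt <- t.test(a, b)
  mw <- mann_whitney_u(a, b)
  tibble::tibble(group1 = lv[1], group2 = lv[2],
                 mean1 = mean(a), mean2 = mean(b),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_t = tt$p.value, u = mw$u, p_u = mw$p)
}
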