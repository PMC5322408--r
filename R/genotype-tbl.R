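#' Build a genotype table
#'
#' The package's canonical container for individual diploid multilocus
#' genotypes: a tibble with one row per individual, an `id` column, an
#' optional `pop` grouping label, and one character column per locus holding
#' the two allele codes as `"a1/a2"` (`NA` = missing). Allele codes are
#' positive integers; raw microsatellite fragment sizes are accepted verbatim.
#'
#' @param ids character vector of unique individual identifiers.
#' @param loci character vector of locus names.
#' @param a1,a2 integer matrices (individuals x loci) of allele codes; `NA`
#'   in either marks the call missing.
#' @param pop optional character vector of population labels.
#' @return a `genotype_tbl` (tibble subclass).
#' @export
genotype_tbl <- function(ids, loci, a1, a2, pop = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  stopifnot(length(ids) == nrow(a1), all(dim(a1) == dim(a2)),
            length(loci) == ncol(a1))
  if (anyDuplicated(ids)) abort("individual ids must be unique")
  bad <- stats::na.omit(c(a1, a2))
  if (length(bad) && any(bad <= 0)) abort("allele codes must be positive integers")
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  if (nrow(a1) == 0) {
    calls <- matrix(NA_character_, 0, length(loci))
  } else {
    calls <- matrix(paste0(a1, "/", a2), nrow = nrow(a1))
    calls[miss] <- NA_character_
  }
  colnames(calls) <- loci
  out <- tibble::tibble(id = as.character(ids))
  if (!is.null(pop)) out$pop <- as.character(pop)
  out <- dplyr::bind_cols(out, tibble::as_tibble(calls))
  class(out) <- c("genotype_tbl", class(out))
  out
}

#' Locus names of a genotype table
#' @param g a `genotype_tbl`.
#' @return character vector of locus column names.
#' @export
locus_names <- function(g) {
  setdiff(names(g), c("id", "pop"))
}

# Decode a genotype_tbl into integer allele matrices for computation.
geno_arrays <- function(g) {
  loci <- locus_names(g)
  n <- nrow(g)
  a1 <- a2 <- matrix(NA_integer_, n, length(loci),
                     dimnames = list(g$id, loci))
  for (j in seq_along(loci)) {
    sp <- strsplit(g[[loci[j]]], "/", fixed = TRUE)
    ok <- !is.na(g[[loci[j]]])
    if (any(ok)) {
      m <- do.call(rbind, sp[ok])
      a1[ok, j] <- as.integer(m[, 1])
      a2[ok, j] <- as.integer(m[, 2])
    }
  }
  list(a1 = a1, a2 = a2, ids = g$id, loci = loci,
       pop = if ("pop" %in% names(g)) g$pop else NULL)
}

# Resolve a grouping argument: either a vector of length nrow(g), the name of
# a column in `g`, or NULL meaning the `pop` column.
resolve_grouping <- function(g, grouping = NULL) {
  if (is.null(grouping)) {
    if (!"pop" %in% names(g)) abort("no grouping given and no `pop` column present")
    return(as.character(g$pop))
  }
  if (length(grouping) == 1 && is.character(grouping) && grouping %in% names(g)) {
    return(as.character(g[[grouping]]))
  }
  if (length(grouping) != nrow(g)) {
    abort("grouping must name a column or have one label per individual")
  }
  as.character(grouping)
}

#' Subset a genotype table keeping its class
#' @param x a `genotype_tbl`.
#' @param ... passed to the tibble method.
#' @return a `genotype_tbl`.
#' @export
`[.genotype_tbl` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("id") %in% names(out))) {
    class(out) <- unique(c("genotype_tbl", class(out)))
  }
  out
}
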