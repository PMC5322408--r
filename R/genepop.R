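#' Read a Genepop-dialect genotype file
#'
#' Parses the classic Genepop text layout: a title line, one locus name per
#' line (or a single comma-separated line), `Pop` separator lines, then one
#' line per individual of the form `id , 003005 010012 ...`. Both 2-digit and
#' 3-digit allele encodings are accepted (detected from call width);
#' `0000`/`000000` decodes to missing. Population blocks are preserved as a
#' `pop` column labelled by the id of the last individual in each block (the
#' Genepop convention), or `pop_1`, `pop_2`, ... when ids are absent.
#'
#' @param path path to the file.
#' @return a [genotype_tbl()] with a `pop` column.
#' @export
read_genepop <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readLines(path, warn = FALSE)
  lines <- trimws(raw)
  if (length(lines) < 2) abort("genepop file too short")
  body <- lines[-1]
  body_no <- seq_along(raw)[-1]
  is_pop <- tolower(body) %in% "pop"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) abort("genepop file has no 'Pop' line")
  locus_lines <- body[seq_len(first_pop - 1)]
  loci <- unlist(strsplit(locus_lines, ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (!length(loci)) abort("genepop file declares no loci")

  ids <- character(); popidx <- integer()
  a1 <- a2 <- NULL
  pop_no <- 0L
  rows1 <- list(); rows2 <- list()
  for (k in seq(first_pop, length(body))) {
    ln <- body[k]
    if (!nzchar(ln)) next
    if (tolower(ln) == "pop") { pop_no <- pop_no + 1L; next }
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) == 2) {
      id <- trimws(parts[1]); calls <- parts[2]
    } else {
      id <- ""; calls <- ln
    }
    calls <- strsplit(trimws(calls), "[[:space:]]+")[[1]]
    if (length(calls) != length(loci)) {
      abort(sprintf("line %d: expected %d locus calls, found %d",
                    body_no[k], length(loci), length(calls)))
    }
    w <- unique(nchar(calls))
    if (length(w) != 1 || !w %in% c(4L, 6L)) {
      abort(sprintf("line %d: allele calls must be uniformly 4 or 6 digits",
                    body_no[k]))
    }
    d <- w / 2
    x <- as.integer(substr(calls, 1, d))
    y <- as.integer(substr(calls, d + 1, w))
    x[x == 0 | y == 0] <- NA_integer_
    y[is.na(x)] <- NA_integer_
    ids <- c(ids, id); popidx <- c(popidx, pop_no)
    rows1[[length(rows1) + 1L]] <- x
    rows2[[length(rows2) + 1L]] <- y
  }
  a1 <- do.call(rbind, rows1); a2 <- do.call(rbind, rows2)
  # label populations by last individual id in block, genepop-style
  pop_lab <- vapply(seq_len(max(popidx)), function(p) {
    last <- utils::tail(ids[popidx == p], 1)
    if (nzchar(last)) last else paste0("pop_", p)
  }, character(1))
  blank <- !nzchar(ids)
  ids[blank] <- paste0("ind_", which(blank))
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  genotype_tbl(ids, loci, a1, a2, pop = pop_lab[popidx])
}

#' Write a genotype table as a Genepop file
#'
#' Inverse of [read_genepop()]; the round trip is lossless. Missing calls are
#' zero-encoded. Individuals are written in blocks by their `pop` column (one
#' `Pop` block if absent).
#'
#' @param g a [genotype_tbl()].
#' @param path output path.
#' @param digits 2 or 3; allele-code field width (3 by default).
#' @param title header line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(g, path, digits = 3, title = "depthcline genotypes") {
  stopifnot(digits %in% c(2, 3))
  ga <- geno_arrays(g)
  mx <- suppressWarnings(max(ga$a1, ga$a2, na.rm = TRUE))
  if (is.finite(mx) && mx > 10^digits - 1) {
    abort(sprintf("allele codes exceed %d; use a wider encoding", 10^digits - 1))
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(ga$loci, con)
  enc <- function(v) {
    v[is.na(v)] <- 0L
    formatC(v, width = digits, flag = "0")
  }
  pops <- ga$pop %||% rep("pop_1", nrow(g))
  if (nrow(g) == 0) return(invisible(path))
  for (p in unique(pops)) {
    writeLines("Pop", con)
    for (i in which(pops == p)) {
      calls <- paste0(enc(ga$a1[i, ]), enc(ga$a2[i, ]))
      writeLines(paste0(ga$ids[i], " , ", paste(calls, collapse = " ")), con)
    }
  }
  invisible(path)
}
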