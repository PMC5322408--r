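#' Convert degrees-minutes-seconds coordinate strings to decimal degrees
#'
#' Accepts strings like `47°01'36.37"` (any of the common prime/quote glyphs)
#' or plain numbers (returned as-is). Hemisphere letters `S`/`W` negate.
#'
#' @param x character (or numeric) vector.
#' @return numeric vector of decimal degrees.
#' @export
dms_to_decimal <- function(x) {
  if (is.numeric(x)) return(x)
  vapply(x, function(s) {
    if (is.na(s)) return(NA_real_)
    s0 <- trimws(s)
    neg <- grepl("[SWsw]\\s*$", s0) || grepl("^-", s0)
    num <- suppressWarnings(as.numeric(s0))
    if (!is.na(num)) return(num)
    parts <- regmatches(s0, gregexpr("[0-9]+(\\.[0-9]+)?", s0))[[1]]
    if (!length(parts)) return(NA_real_)
    v <- as.numeric(parts)
    dec <- v[1] + (if (length(v) > 1) v[2] / 60 else 0) +
      (if (length(v) > 2) v[3] / 3600 else 0)
    if (neg) -dec else dec
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a per-individual phenotype/capture table
#'
#' Reads a comma- or tab-delimited text file (delimiter sniffed from the
#' header line) into a typed tibble. Recognised columns (case-insensitive,
#' synonyms in parentheses): `id`, `sl` (standard_length, mm), `gr`
#' (gill_rakers), `age` (years), `depth` (m), `date` (ISO-8601), `mesh` (mm),
#' `site_lat`/`site_lon` (decimal degrees or DMS strings), `net_type`.
#' Extra columns are kept untouched. A `date_num` column of days since the
#' first survey date is added for regression use.
#'
#' @param path path to the delimited file.
#' @return a tibble with one row per individual.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  hdr <- readLines(path, n = 1)
  delim <- if (lengths(regmatches(hdr, gregexpr("\t", hdr))) > 0) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, col_types = readr::cols(.default = "c"))
  names(raw) <- tolower(names(raw))
  ren <- c(standard_length = "sl", gill_rakers = "gr", gillraker = "gr",
           latitude = "site_lat", longitude = "site_lon",
           lat = "site_lat", lon = "site_lon", individual_id = "id")
  for (nm in names(ren)) {
    if (nm %in% names(raw) && !ren[[nm]] %in% names(raw)) {
      names(raw)[names(raw) == nm] <- ren[[nm]]
    }
  }
  num_cols <- intersect(c("sl", "gr", "age", "depth", "mesh"), names(raw))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(!is.na(raw[[cc]]) & nzchar(raw[[cc]]) & is.na(v))
    if (length(bad)) {
      abort(sprintf("column '%s': non-numeric value in data row(s) %s",
                    cc, paste(head(bad, 5), collapse = ", ")))
    }
    raw[[cc]] <- v
  }
  if ("sl" %in% names(raw) && any(raw$sl <= 0, na.rm = TRUE)) {
    abort("standard length must be positive where present")
  }
  if ("gr" %in% names(raw)) raw$gr <- round(raw$gr)
  for (cc in intersect(c("site_lat", "site_lon"), names(raw))) {
    raw[[cc]] <- dms_to_decimal(raw[[cc]])
  }
  if ("date" %in% names(raw)) {
    raw$date <- as.Date(raw$date)
    raw$date_num <- as.numeric(raw$date - min(raw$date, na.rm = TRUE))
  }
  raw
}

#' Write a phenotype table as delimited text
#' @param pheno a tibble.
#' @param path output path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path, delim = ",") {
  readr::write_delim(pheno, path, delim = delim)
  invisible(path)
}
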