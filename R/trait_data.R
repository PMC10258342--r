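# Trait-observation data model: long-format replicate-level records with
# design metadata.  One record per (accession, year, replicate, trait).

#' Construct a trait dataset from long-format records
#'
#' The canonical container for replicate-level seed-trait observations.  Each
#' record is one measurement of one trait on one replicate (e.g. a scanned
#' batch of 100 seeds) of one accession in one year.  The trait, accession and
#' year orderings are fixed at construction as order of first appearance in
#' `records`, so downstream matrices are reproducible from the input file
#' alone.
#'
#' @param records a data.frame with columns `accession` (character), `year`
#'   (integer), `replicate` (integer >= 1), `trait` (character) and `value`
#'   (finite numeric).
#' @return An object of class `trait_dataset`: a list with elements `records`
#'   (the validated data.frame), `traits`, `accessions` and `years` (orderings
#'   by first appearance).
#' @seealso [read_trait_table()], [validate_design()], [simulate_dataset()]
#' @examples
#' df <- data.frame(accession = "A", year = 2014, replicate = 1:2,
#'                  trait = "SL", value = c(4.5, 4.6))
#' trait_dataset(df)
#' @export
trait_dataset <- function(records) {
  required <- c("accession", "year", "replicate", "trait", "value")
  if (!is.data.frame(records)) .stopf("`records` must be a data.frame")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    .stopf("missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0L) .stopf("dataset has no records")
  records <- records[required]
  records$accession <- as.character(records$accession)
  records$trait <- as.character(records$trait)
  records$year <- as.integer(records$year)
  records$replicate <- as.integer(records$replicate)
  records$value <- as.numeric(records$value)
  if (anyNA(records$year)) .stopf("`year` contains non-integer values")
  if (anyNA(records$replicate) || any(records$replicate < 1L)) {
    .stopf("`replicate` must be an integer >= 1")
  }
  if (any(!is.finite(records$value))) {
    bad <- which(!is.finite(records$value))[1L]
    .stopf("non-finite `value` in record %d", bad)
  }
  key <- paste(records$accession, records$year, records$replicate,
               records$trait, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[which(duplicated(key))[1L], ]
    .stopf("duplicate record key (%s, %d, %d, %s)",
           d$accession, d$year, d$replicate, d$trait)
  }
  rownames(records) <- NULL
  structure(
    list(records = records,
         traits = unique(records$trait),
         accessions = unique(records$accession),
         years = unique(records$year)),
    class = "trait_dataset")
}

#' @export
print.trait_dataset <- function(x, ...) {
  cat(sprintf("<trait_dataset> %d records | %d accessions x %d years x %d traits\n",
              nrow(x$records), length(x$accessions), length(x$years),
              length(x$traits)))
  cat("  traits: ", paste(x$traits, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.trait_dataset <- function(x, ...) x$records

#' Read a long-format trait table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row and one record per
#' (accession, year, replicate, trait).  Column names can be remapped through
#' `schema` when the file uses different headers.
#'
#' @param path path to a CSV file.
#' @param schema named character vector mapping the canonical column names
#'   (`accession`, `year`, `replicate`, `trait`, `value`) to the column names
#'   used in the file.
#' @return A [trait_dataset()].
#' @export
read_trait_table <- function(path,
                             schema = c(accession = "accession", year = "year",
                                        replicate = "replicate", trait = "trait",
                                        value = "value")) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  canonical <- c("accession", "year", "replicate", "trait", "value")
  schema <- schema[canonical]
  if (anyNA(schema)) {
    .stopf("schema must map all of: %s", paste(canonical, collapse = ", "))
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         encoding = "UTF-8")
  for (col in canonical) {
    if (!schema[[col]] %in% names(raw)) {
      .stopf("column '%s' not found in %s", schema[[col]], path)
    }
  }
  df <- data.frame(
    accession = raw[[schema[["accession"]]]],
    year = raw[[schema[["year"]]]],
    replicate = raw[[schema[["replicate"]]]],
    trait = raw[[schema[["trait"]]]],
    value = NA_real_,
    stringsAsFactors = FALSE)
  val <- suppressWarnings(as.numeric(raw[[schema[["value"]]]]))
  bad <- which(is.na(val))
  if (length(bad)) {
    .stopf("non-numeric value '%s' in row %d",
           raw[[schema[["value"]]]][bad[1L]], bad[1L])
  }
  df$value <- val
  yr <- suppressWarnings(as.integer(df$year))
  if (anyNA(yr)) .stopf("non-integer year in row %d", which(is.na(yr))[1L])
  rp <- suppressWarnings(as.integer(df$replicate))
  if (anyNA(rp)) .stopf("non-integer replicate in row %d", which(is.na(rp))[1L])
  df$year <- yr
  df$replicate <- rp
  trait_dataset(df)
}

# minimal CSV field quoting: only when the content requires it
.csv_quote <- function(x) {
  needs <- grepl('[",\n\r]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

# full-precision numeric formatting that round-trips exactly through
# as.numeric(); 17 significant digits suffice for IEEE doubles
.fmt_double <- function(x) sprintf("%.17g", x)

#' Write a trait dataset to CSV
#'
#' Values are written with 17 significant digits so that
#' `read_trait_table(write_trait_table(ds))` reproduces `ds` exactly.
#' Output is UTF-8 with Unix line endings, byte-stable across platforms.
#'
#' @param ds a [trait_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(ds, path) {
  stopifnot(inherits(ds, "trait_dataset"))
  r <- ds$records
  if (nrow(r) == 0L) .stopf("refusing to write an empty dataset")
  lines <- c("accession,year,replicate,trait,value",
             paste(.csv_quote(r$accession), r$year, r$replicate,
                   .csv_quote(r$trait), .fmt_double(r$value), sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' Summarize and validate the experimental design
#'
#' Reports the accession count, number of years (`nl`), modal replicate count
#' per (accession, year, trait) cell (`nr`), and whether the design is
#' balanced.  A design is balanced when every cell of the full
#' accession x year x trait grid holds exactly `nr` records.  Cells with fewer
#' than `nr` records are listed in `missing_cells`.
#'
#' @param ds a [trait_dataset()].
#' @return A list of class `design_summary` with fields `n_accessions`, `nl`,
#'   `nr`, `balanced` and `missing_cells` (data.frame with columns accession,
#'   year, trait, n_records).
#' @export
validate_design <- function(ds) {
  stopifnot(inherits(ds, "trait_dataset"))
  r <- ds$records
  grid <- expand.grid(accession = sort(ds$accessions),
                      year = sort(ds$years),
                      trait = sort(ds$traits),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  counts <- table(paste(r$accession, r$year, r$trait, sep = "\r"))
  key <- paste(grid$accession, grid$year, grid$trait, sep = "\r")
  grid$n_records <- as.integer(counts[key])
  grid$n_records[is.na(grid$n_records)] <- 0L
  # modal cell count (largest count on ties) defines nr
  tab <- table(grid$n_records)
  nr <- max(as.integer(names(tab)[tab == max(tab)]))
  missing <- grid[grid$n_records < nr, , drop = FALSE]
  rownames(missing) <- NULL
  balanced <- nrow(missing) == 0L && all(grid$n_records == nr)
  structure(
    list(n_accessions = length(ds$accessions),
         nl = length(ds$years),
         nr = nr,
         balanced = balanced,
         missing_cells = missing),
    class = "design_summary")
}

#' @export
print.design_summary <- function(x, ...) {
  cat(sprintf("<design_summary> %d accessions | nl = %d | nr = %d | %s\n",
              x$n_accessions, x$nl, x$nr,
              if (x$balanced) "balanced" else
                sprintf("UNBALANCED (%d incomplete cells)", nrow(x$missing_cells))))
  invisible(x)
}

#' Read per-accession site metadata
#'
#' A site table carries one row per accession with its altitude (m a.s.l.) and
#' any number of numeric environmental covariates (e.g. growing-season monthly
#' mean/max/min temperatures, degrees C), used by [env_correlation()].
#'
#' @param path CSV file with header `accession,altitude,<covariate>...`.
#' @return A data.frame of class `site_metadata`.
#' @export
read_site_metadata <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        encoding = "UTF-8")
  if (!"accession" %in% names(df)) .stopf("column 'accession' not found")
  if (ncol(df) < 2L) .stopf("site metadata needs at least one covariate column")
  df$accession <- as.character(df$accession)
  if (anyDuplicated(df$accession)) {
    .stopf("duplicate accession '%s' in site metadata",
           df$accession[duplicated(df$accession)][1L])
  }
  for (col in setdiff(names(df), "accession")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) .stopf("non-numeric value in covariate '%s'", col)
    df[[col]] <- v
  }
  class(df) <- c("site_metadata", "data.frame")
  df
}

# extract the records for one trait (optionally one year); internal
.slice_trait <- function(ds, trait, year = NULL) {
  stopifnot(inherits(ds, "trait_dataset"))
  if (!trait %in% ds$traits) .stopf("trait '%s' not present in dataset", trait)
  r <- ds$records[ds$records$trait == trait, , drop = FALSE]
  if (!is.null(year)) {
    if (!year %in% ds$years) .stopf("year %s not present in dataset", year)
    r <- r[r$year == year, , drop = FALSE]
  }
  rownames(r) <- NULL
  r
}
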