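#' Read and validate an individual-level morphometric trait table
#'
#' Reads a delimited text file with one row per animal: metadata columns
#' (`Individual`, `Taxon`, `Sex`, `Age`, `Site`), the unilateral traits
#' (WEIGHT, BODY, TAIL, IC, FO, ZYG, JAW), and left/right columns
#' (`<TRAIT>_L`, `<TRAIT>_R`) for the six bilateral limb traits. Cells that
#' are empty, `NA`, or unparseable are recorded as missing (the row is kept)
#' and counted in the validation report attached to the result.
#'
#' @param path Path to a CSV (or other single-character-delimited) file with
#'   a header row.
#' @param dialect Optional list: `sep` (default ","), and `aliases`, a named
#'   character vector mapping file column names to canonical ones, e.g.
#'   `c(ID = "Individual")`.
#' @return A `trait_table`: a list with `records` (data.frame in raw layout),
#'   `trait_names`, and `provenance` (source path, row count, per-column
#'   missing-cell counts, warnings).
#' @export
read_trait_table <- function(path, dialect = list()) {
  if (!file.exists(path)) {
    stop("input error: file does not exist: ", path)
  }
  sep <- if (is.null(dialect$sep)) "," else dialect$sep
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"), quote = "\"",
                           fileEncoding = "UTF-8", strip.white = TRUE)
  if (nrow(raw) == 0L) stop("input error: empty file: ", path)
  if (!is.null(dialect$aliases)) {
    hit <- names(raw) %in% names(dialect$aliases)
    names(raw)[hit] <- unname(dialect$aliases[names(raw)[hit]])
  }
  required <- c(.meta_columns(), .raw_trait_columns())
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing mandatory columns: ",
         paste(missing_cols, collapse = ", "))
  }
  dup <- raw$Individual[duplicated(raw$Individual)]
  if (length(dup) > 0L) {
    stop("validation error: duplicate individual ids: ",
         paste(unique(dup), collapse = ", "))
  }
  warnings <- character(0)
  bad_taxon <- setdiff(unique(raw$Taxon), taxon_codes())
  if (length(bad_taxon) > 0L) {
    stop("validation error: unknown taxon codes: ",
         paste(bad_taxon, collapse = ", "))
  }
  num_cols <- .raw_trait_columns()
  rec <- raw[, required]
  missing_counts <- integer(length(num_cols))
  names(missing_counts) <- num_cols
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(rec[[col]]))
    newly_bad <- sum(is.na(v) & !is.na(rec[[col]]))
    if (newly_bad > 0L) {
      warnings <- c(warnings, sprintf(
        "column %s: %d unparseable numeric cell(s) set to missing",
        col, newly_bad))
    }
    nonpos <- which(!is.na(v) & v <= 0)
    if (length(nonpos) > 0L) {
      warnings <- c(warnings, sprintf(
        "column %s: %d nonpositive measurement(s) set to missing",
        col, length(nonpos)))
      v[nonpos] <- NA_real_
    }
    rec[[col]] <- v
    missing_counts[col] <- sum(is.na(v))
  }
  rec$Age <- ifelse(is.na(rec$Age), "unknown", rec$Age)
  rec$Sex <- ifelse(is.na(rec$Sex), "unknown", rec$Sex)
  structure(list(
    records = rec,
    trait_names = trait_names(),
    provenance = list(source = path, n_rows = nrow(rec),
                      missing_cells = missing_counts,
                      warnings = warnings)
  ), class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("trait_table: %d records, %d traits (source: %s)\n",
              nrow(x$records), length(x$trait_names),
              x$provenance$source))
  cat(sprintf("  taxa: %s\n",
              paste(sort(unique(x$records$Taxon)), collapse = " ")))
  nw <- length(x$provenance$warnings)
  if (nw > 0L) cat(sprintf("  %d validation warning(s)\n", nw))
  invisible(x)
}

#' Average the left and right sides of the bilateral traits
#'
#' For each bilateral trait the per-individual value is the mean of the
#' available sides; a single available side is used as-is (maximizing
#' usable n); both sides missing gives a missing value. Symmetric in
#' (left, right) by construction.
#'
#' @param table A `trait_table` (raw layout with `_L`/`_R` columns).
#' @return A data.frame in flat layout: metadata columns plus one column per
#'   canonical trait, bilateral traits already averaged.
#' @export
flatten_traits <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  rec <- table$records
  out <- rec[, .meta_columns()]
  for (tr in trait_names()) {
    if (tr %in% bilateral_traits()) {
      out[[tr]] <- bilateral_average(rec[[paste0(tr, "_L")]],
                                     rec[[paste0(tr, "_R")]])
    } else {
      out[[tr]] <- rec[[tr]]
    }
  }
  out
}

#' @rdname flatten_traits
#' @param left,right Numeric vectors of same-side measurements (NA = missing).
#' @export
bilateral_average <- function(left, right) {
  m <- rowMeans(cbind(left, right), na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  m
}

#' Restrict a trait table to adults
#'
#' Only rows whose age class is `adult` are retained; the number of excluded
#' rows is recorded in provenance. Idempotent.
#'
#' @param table A `trait_table`.
#' @return A `trait_table` containing only adult records.
#' @export
filter_adults <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  keep <- table$records$Age == "adult"
  dropped <- sum(!keep)
  table$records <- table$records[keep, , drop = FALSE]
  rownames(table$records) <- NULL
  table$provenance$n_rows <- nrow(table$records)
  table$provenance$excluded_non_adult <-
    sum(dropped, table$provenance$excluded_non_adult)
  table
}

#' Write a trait table back to CSV
#'
#' Writes the raw layout (with `_L`/`_R` columns) so that
#' `read_trait_table(write_trait_table(x))` round-trips all cells.
#'
#' @param table A `trait_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  stopifnot(inherits(table, "trait_table"))
  utils::write.csv(table$records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write the flat 13-trait matrix and a JSON validation report
#'
#' @param table A `trait_table`.
#' @param out Path for the normalized flat CSV (bilateral traits averaged).
#' @param report Optional path for a JSON validation report.
#' @return The flat data.frame, invisibly.
#' @export
export_flat_traits <- function(table, out, report = NULL) {
  flat <- flatten_traits(table)
  utils::write.csv(flat, out, row.names = FALSE, na = "")
  if (!is.null(report)) {
    jsonlite::write_json(list(
      source = table$provenance$source,
      n_rows = table$provenance$n_rows,
      missing_cells = as.list(table$provenance$missing_cells),
      warnings = table$provenance$warnings
    ), report, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(flat)
}
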