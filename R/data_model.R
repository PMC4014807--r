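#' @keywords internal
"_PACKAGE"

# mandatory schema columns, in CSV header form and internal form
.SCHEMA_HEADERS <- c("Plate number", "Well", "Well type", "Gene symbol",
                     "Entrez Gene ID")
.SCHEMA_COLS <- c("plate", "well", "well_type", "gene_symbol", "entrez_id")
.REAGENT_HEADER <- "Reagent ID"
.MAX_DATA_COLS <- 100L

# monotone table-id source, package-local
.id_env <- new.env(parent = emptyenv())
.id_env$counter <- 0L

.next_table_id <- function() {
  .id_env$counter <- .id_env$counter + 1L
  sprintf("T%05d", .id_env$counter)
}

#' Parse a well label into row and column indices
#'
#' Well labels are a row letter followed by a column number ("A1", "A01",
#' "P24"). Labels are validated against the plate geometry.
#'
#' @param well character vector of well labels.
#' @param geometry integer vector `c(rows, cols)`; default 384-well (16 x 24).
#' @return data.frame with columns `row`, `col`.
#' @export
parse_well <- function(well, geometry = c(16L, 24L)) {
  well <- toupper(trimws(as.character(well)))
  ok <- grepl("^[A-Z][0-9]{1,2}$", well)
  if (any(!ok)) {
    stop("malformed well label(s): ",
         paste(utils::head(well[!ok], 5L), collapse = ", "), call. = FALSE)
  }
  row <- match(substr(well, 1L, 1L), LETTERS)
  col <- as.integer(substring(well, 2L))
  bad <- row > geometry[1L] | col < 1L | col > geometry[2L]
  if (any(bad)) {
    stop("well label(s) outside ", geometry[1L], "x", geometry[2L],
         " plate geometry: ", paste(utils::head(well[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  data.frame(row = row, col = col)
}

#' Format (row, column) indices as a normalized well label
#'
#' The normalized form is letter plus zero-padded two-digit column ("A01"),
#' which sorts lexicographically in plate order.
#'
#' @param row,col integer vectors.
#' @return character vector of labels.
#' @export
format_well <- function(row, col) {
  sprintf("%s%02d", LETTERS[row], as.integer(col))
}

#' Construct a screen table
#'
#' A screen table is the unit of analysis: one well-level record per
#' (plate, well) with role annotations and 1-100 numeric data columns,
#' plus provenance metadata (raw vs derived, parent, derivation log).
#'
#' @param records data.frame with columns `plate`, `well`, `well_type`,
#'   `gene_symbol`, `entrez_id`, optionally `reagent_id`, and one or more
#'   numeric data columns.
#' @param name table name.
#' @param geometry plate geometry `c(rows, cols)`.
#' @param control_types character vector of declared control well types;
#'   every other well type is expected to be `"sample"`.
#' @param nature `"raw"` or `"derived"`.
#' @param source_filename originating file, if any.
#' @param parent parent `screen_table` for derived tables.
#' @param derivation_log character vector of operation descriptions.
#' @param screen_id,project_id optional identifiers tying the table into a
#'   project/screen hierarchy.
#' @return object of class `screen_table`.
#' @export
screen_table <- function(records, name = "screen", geometry = c(16L, 24L),
                         control_types = character(), nature = c("raw", "derived"),
                         source_filename = NA_character_, parent = NULL,
                         derivation_log = character(),
                         screen_id = NA_character_, project_id = NA_character_) {
  nature <- match.arg(nature)
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.SCHEMA_COLS, names(records))
  if (length(missing_cols) > 0L) {
    stop("records lack mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records$plate <- as.integer(records$plate)
  if (nrow(records) > 0L && any(is.na(records$plate) | records$plate < 1L)) {
    stop("plate numbers must be integers >= 1", call. = FALSE)
  }
  if (nrow(records) > 0L) {
    rc <- parse_well(records$well, geometry)
    records$well <- format_well(rc$row, rc$col)
    key <- paste(records$plate, records$well)
    if (anyDuplicated(key)) {
      stop("duplicate (plate, well) record(s): ",
           paste(utils::head(unique(key[duplicated(key)]), 5L), collapse = "; "),
           call. = FALSE)
    }
  }
  records$entrez_id <- suppressWarnings(as.integer(records$entrez_id))
  schema <- c(.SCHEMA_COLS, if ("reagent_id" %in% names(records)) "reagent_id")
  data_cols <- setdiff(names(records), schema)
  if (length(data_cols) < 1L) {
    stop("a screen table needs at least one data column", call. = FALSE)
  }
  if (length(data_cols) > .MAX_DATA_COLS) {
    stop("too many data columns (", length(data_cols), "); at most ",
         .MAX_DATA_COLS, " are supported", call. = FALSE)
  }
  for (dc in data_cols) records[[dc]] <- as.numeric(records[[dc]])
  records <- records[, c(schema, data_cols), drop = FALSE]

  if (nature == "raw" && (length(derivation_log) > 0L || !is.null(parent))) {
    stop("raw tables cannot have a parent or a derivation log", call. = FALSE)
  }
  if (nature == "derived" && is.null(parent)) {
    stop("derived tables must reference a parent table", call. = FALSE)
  }

  structure(
    list(
      table_id = .next_table_id(),
      screen_id = screen_id,
      project_id = project_id,
      name = name,
      source_filename = source_filename,
      created = Sys.time(),
      nature = nature,
      parent_table_id = if (is.null(parent)) NA_character_ else parent$table_id,
      parent = parent,
      derivation_log = derivation_log,
      geometry = as.integer(geometry),
      control_types = control_types,
      data_columns = data_cols,
      records = records
    ),
    class = "screen_table"
  )
}

#' @export
print.screen_table <- function(x, ...) {
  cat(sprintf("<screen_table %s> '%s' (%s)\n", x$table_id, x$name, x$nature))
  cat(sprintf("  %d wells on %d plate(s), geometry %dx%d\n",
              nrow(x$records), length(unique(x$records$plate)),
              x$geometry[1L], x$geometry[2L]))
  cat("  data columns: ", paste(x$data_columns, collapse = ", "), "\n", sep = "")
  if (length(x$derivation_log) > 0L) {
    cat("  derivation log:\n")
    for (entry in x$derivation_log) cat("    - ", entry, "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.screen_table <- function(x, ...) x$records

#' Number of well records in a screen table
#' @param x a `screen_table`.
#' @export
n_records <- function(x) nrow(x$records)

#' Load a screen from CSV
#'
#' The file must carry the header columns "Plate number", "Well",
#' "Well type", "Gene symbol" and "Entrez Gene ID"; "Reagent ID" is
#' optional and every additional numeric column is taken up as a data
#' column (at most 100). Well types outside `sample` and the declared
#' control names are kept but flagged in the load report attached as
#' attribute `"load_report"`.
#'
#' @param path CSV file path.
#' @param geometry plate geometry `c(rows, cols)`, default 16 x 24.
#' @param control_types declared control well-type names (e.g.
#'   `c("STX16", "CLTC", "KDELR1", "PLK1", "GFP")`).
#' @param sep field separator; `","` for CSV, `"\t"` re-reads exported
#'   tables.
#' @param name,screen_id,project_id table metadata.
#' @return a raw `screen_table`.
#' @export
load_screen_csv <- function(path, geometry = c(16L, 24L),
                            control_types = character(), sep = ",",
                            name = NULL, screen_id = NA_character_,
                            project_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", na.strings = c("NA", ""))
  for (h in .SCHEMA_HEADERS) {
    if (!h %in% names(raw)) {
      stop("mandatory column missing from header: \"", h, "\"", call. = FALSE)
    }
  }
  rec <- data.frame(
    plate = raw[["Plate number"]],
    well = raw[["Well"]],
    well_type = as.character(raw[["Well type"]]),
    gene_symbol = as.character(raw[["Gene symbol"]]),
    entrez_id = raw[["Entrez Gene ID"]],
    stringsAsFactors = FALSE
  )
  if (.REAGENT_HEADER %in% names(raw)) {
    rec$reagent_id <- as.character(raw[[.REAGENT_HEADER]])
  }
  extra <- setdiff(names(raw), c(.SCHEMA_HEADERS, .REAGENT_HEADER))
  skipped_cols <- character()
  for (col in extra) {
    v <- raw[[col]]
    if (is.numeric(v)) {
      rec[[col]] <- v
    } else {
      vn <- suppressWarnings(as.numeric(v))
      # accept columns that are numeric-as-text; drop genuinely textual ones
      if (all(is.na(vn) == is.na(v))) rec[[col]] <- vn else skipped_cols <- c(skipped_cols, col)
    }
  }
  n_data <- ncol(rec) - length(c(.SCHEMA_COLS, if ("reagent_id" %in% names(rec)) "reagent_id"))
  if (n_data > .MAX_DATA_COLS) {
    stop("file has ", n_data, " data columns; at most ", .MAX_DATA_COLS,
         " are supported", call. = FALSE)
  }
  tab <- screen_table(rec,
                      name = if (is.null(name)) basename(path) else name,
                      geometry = geometry, control_types = control_types,
                      nature = "raw", source_filename = path,
                      screen_id = screen_id, project_id = project_id)
  known <- c("sample", control_types)
  unknown <- setdiff(unique(tab$records$well_type), known)
  attr(tab, "load_report") <- list(
    n_records = nrow(tab$records),
    n_data_columns = length(tab$data_columns),
    unknown_well_types = unknown,
    skipped_text_columns = skipped_cols
  )
  tab
}

#' Derive a child table from a parent
#'
#' The child records provenance: nature `"derived"`, a pointer to the
#' parent, and the parent's derivation log extended by `log_entry`
#' (append-only).
#'
#' @param parent parent `screen_table`.
#' @param new_records data.frame of records for the child (defaults to the
#'   parent's records).
#' @param log_entry non-empty description of the deriving operation.
#' @param name child table name.
#' @return derived `screen_table`.
#' @export
derive_table <- function(parent, new_records = parent$records, log_entry,
                         name = parent$name) {
  stopifnot(inherits(parent, "screen_table"))
  if (missing(log_entry) || !is.character(log_entry) || length(log_entry) != 1L ||
      !nzchar(trimws(log_entry))) {
    stop("a non-empty log_entry is required: provenance must be recorded",
         call. = FALSE)
  }
  screen_table(new_records, name = name, geometry = parent$geometry,
               control_types = parent$control_types, nature = "derived",
               source_filename = parent$source_filename, parent = parent,
               derivation_log = c(parent$derivation_log, log_entry),
               screen_id = parent$screen_id, project_id = parent$project_id)
}

#' Undo the last derivation
#'
#' Returns the parent table, i.e. the visible state before the last
#' deriving operation.
#'
#' @param table a derived `screen_table`.
#' @export
undo_derivation <- function(table) {
  stopifnot(inherits(table, "screen_table"))
  if (table$nature != "derived" || is.null(table$parent)) {
    stop("table is raw; nothing to undo", call. = FALSE)
  }
  table$parent
}

#' Export a screen table as tab-delimited text
#'
#' One row per well record, mandatory columns first in schema order, then
#' the data columns. The output round-trips through
#' `load_screen_csv(..., sep = "\t")` up to floating point formatting.
#'
#' @param table a `screen_table`.
#' @param path output file path.
#' @param digits significant digits for numeric columns.
#' @return `path`, invisibly.
#' @export
export_table <- function(table, path, digits = 10L) {
  stopifnot(inherits(table, "screen_table"))
  rec <- table$records
  out <- rec
  headers <- .SCHEMA_HEADERS
  if ("reagent_id" %in% names(rec)) headers <- c(headers, .REAGENT_HEADER)
  names(out)[seq_along(headers)] <- headers
  for (dc in table$data_columns) {
    out[[dc]] <- ifelse(is.na(rec[[dc]]), NA,
                        formatC(rec[[dc]], digits = digits, format = "g"))
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write table to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

# internal: assert a data column exists
.check_column <- function(table, column) {
  if (!column %in% table$data_columns) {
    stop("no data column named '", column, "' (have: ",
         paste(table$data_columns, collapse = ", "), ")", call. = FALSE)
  }
}

# internal: split record row indices by plate, in plate order
.plate_index <- function(table) {
  split(seq_len(nrow(table$records)), table$records$plate)
}
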