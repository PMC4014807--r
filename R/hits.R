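# Cutoff selection, hit finalization, table algebra for screen
# comparison, and multi-reagent (siRNA deconvolution) validation.

#' Define a cutoff specification
#'
#' Three modes:
#' * `"stat"`: threshold = mean(reference wells) + k * SD (direction
#'   `"ge"`) or mean - k * SD (direction `"le"`); `reference` is
#'   `"samples"` or a control type.
#' * `"value"`: a fixed threshold value.
#' * `"rank"`: the value at a given index of the column sorted
#'   descending (rank 1 = maximum).
#'
#' @param mode one of `"stat"`, `"value"`, `"rank"`.
#' @param reference `"samples"` or a control type (stat mode).
#' @param k non-negative SD multiplier (stat mode).
#' @param value threshold (value mode).
#' @param rank 1-based rank index (rank mode).
#' @param direction `"ge"` or `"le"` — whether hits lie at or above, or
#'   at or below, the threshold.
#' @return object of class `cutoff_spec`.
#' @export
cutoff_spec <- function(mode = c("stat", "value", "rank"),
                        reference = "samples", k = 2, value = NULL,
                        rank = NULL, direction = c("ge", "le")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  if (mode == "stat") {
    stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
  } else if (mode == "value") {
    stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  } else {
    stopifnot(is.numeric(rank), length(rank) == 1L, rank >= 1)
  }
  structure(list(mode = mode, reference = reference, k = k, value = value,
                 rank = rank, direction = direction),
            class = "cutoff_spec")
}

#' Resolve a cutoff specification to a threshold value
#'
#' @param table a `screen_table`.
#' @param column data column name.
#' @param spec a [cutoff_spec()].
#' @return the threshold, a single number.
#' @export
select_cutoff <- function(table, column, spec) {
  stopifnot(inherits(spec, "cutoff_spec"))
  .check_column(table, column)
  x <- table$records[[column]]
  switch(spec$mode,
    stat = {
      ref <- if (identical(spec$reference, "samples")) {
        x[table$records$well_type == "sample"]
      } else {
        x[table$records$well_type == spec$reference]
      }
      ref <- ref[!is.na(ref)]
      if (length(ref) == 0L) {
        stop("no wells of reference type '", spec$reference, "'", call. = FALSE)
      }
      sign_k <- if (spec$direction == "ge") 1 else -1
      mean(ref) + sign_k * spec$k * stats::sd(ref)
    },
    value = spec$value,
    rank = {
      v <- sort(x[!is.na(x)], decreasing = TRUE)
      if (spec$rank > length(v)) {
        stop("rank ", spec$rank, " out of range (", length(v),
             " non-missing values)", call. = FALSE)
      }
      v[spec$rank]
    }
  )
}

#' Finalize a threshold into a 0/1 hit column
#'
#' Appends a hit column (`<column>.hit`) scoring every well: 1 if the
#' score passes the threshold in the stated direction, 0 if it does not,
#' missing if the score is missing. Also returns the passing genes with
#' their scores.
#'
#' @param table a `screen_table`.
#' @param column data column name.
#' @param threshold finite threshold value.
#' @param direction `"ge"` or `"le"`.
#' @return list: `table` (derived `screen_table`), `hits` (data.frame of
#'   gene_symbol, entrez_id, score for passing rows).
#' @export
finalize_threshold <- function(table, column, threshold,
                               direction = c("ge", "le")) {
  direction <- match.arg(direction)
  .check_column(table, column)
  stopifnot(is.finite(threshold))
  x <- table$records[[column]]
  pass <- if (direction == "ge") x >= threshold else x <= threshold
  flag <- ifelse(is.na(x), NA_real_, as.numeric(pass))
  rec <- table$records
  rec[[sprintf("%s.hit", column)]] <- flag
  out <- derive_table(table, rec, log_entry = sprintf(
    "finalize_threshold(%s %s %.6g)", column,
    if (direction == "ge") ">=" else "<=", threshold))
  sel <- which(!is.na(pass) & pass)
  hits <- data.frame(gene_symbol = rec$gene_symbol[sel],
                     entrez_id = rec$entrez_id[sel],
                     score = x[sel], stringsAsFactors = FALSE)
  list(table = out, hits = hits)
}

#' Element-wise column arithmetic
#'
#' Combines a data column with another column or a scalar using one of
#' `+ - * /`, appending the result as a new column. Division by zero
#' yields missing values, counted in the `"arith_report"` attribute.
#'
#' @param table a `screen_table`.
#' @param colA data column name (left operand).
#' @param colB_or_scalar data column name or a single number.
#' @param op one of `"+"`, `"-"`, `"*"`, `"/"`.
#' @return derived `screen_table` with the result column.
#' @export
column_arithmetic <- function(table, colA, colB_or_scalar, op = c("+", "-", "*", "/")) {
  op <- match.arg(op)
  .check_column(table, colA)
  a <- table$records[[colA]]
  if (is.character(colB_or_scalar)) {
    .check_column(table, colB_or_scalar)
    b <- table$records[[colB_or_scalar]]
    b_label <- colB_or_scalar
  } else {
    stopifnot(is.numeric(colB_or_scalar), length(colB_or_scalar) == 1L)
    b <- colB_or_scalar
    b_label <- format(colB_or_scalar)
  }
  div0 <- 0L
  res <- switch(op,
    "+" = a + b, "-" = a - b, "*" = a * b,
    "/" = {
      zero <- !is.na(b) & b == 0
      div0 <- sum(zero & !is.na(a))
      out <- a / b
      out[zero] <- NA_real_
      out
    })
  new_col <- sprintf("(%s)%s(%s)", colA, op, b_label)
  rec <- table$records
  rec[[new_col]] <- res
  out <- derive_table(table, rec,
                      log_entry = sprintf("column_arithmetic(%s %s %s)", colA, op, b_label))
  attr(out, "arith_report") <- list(n_divide_by_zero = div0)
  out
}

#' Filter rows by a predicate on columns
#'
#' The predicate may be an unevaluated expression given as a string
#' (evaluated with the table's columns in scope, e.g. `"signal >= 0.6"`;
#' punctuated column names need backticks) or a function taking the
#' records data.frame
#' and returning a logical vector. Rows where the predicate is missing
#' are dropped. The predicate text is recorded in the derivation log.
#'
#' @param table a `screen_table`.
#' @param predicate character expression or function.
#' @return derived `screen_table` with the surviving rows.
#' @export
filter_rows <- function(table, predicate) {
  rec <- table$records
  if (is.character(predicate)) {
    stopifnot(length(predicate) == 1L)
    expr <- tryCatch(parse(text = predicate)[[1L]],
                     error = function(e) stop("malformed predicate: ",
                                              conditionMessage(e), call. = FALSE))
    # columns with punctuated names need backticks in the expression
    keep <- tryCatch(eval(expr, envir = rec),
                     error = function(e) stop("predicate failed: ",
                                              conditionMessage(e), call. = FALSE))
    label <- predicate
  } else if (is.function(predicate)) {
    keep <- predicate(rec)
    label <- paste(deparse(predicate), collapse = " ")
  } else {
    stop("predicate must be a character expression or a function", call. = FALSE)
  }
  if (!is.logical(keep) || length(keep) != nrow(rec)) {
    stop("predicate must yield one logical per row", call. = FALSE)
  }
  keep[is.na(keep)] <- FALSE
  derive_table(table, rec[keep, , drop = FALSE],
               log_entry = sprintf("filter_rows(%s)", label))
}

#' Multi-reagent (deconvolution) counts
#'
#' For validation screens where each gene is targeted by several
#' individual reagents (one per row), flags each reagent as passing the
#' threshold or not, then counts passing reagents per gene. Genes are
#' ranked by the number of passing reagents, descending, ties broken by
#' gene symbol. Rows with a missing score are excluded from a gene's
#' reagent total.
#'
#' @param table a `screen_table` with a `reagent_id` column.
#' @param column data column name.
#' @param threshold threshold value.
#' @param direction `"ge"` or `"le"`.
#' @return object of class `multi_reagent_result`: `reagents`
#'   (reagent_id, gene_symbol, entrez_id, score, pass) and `genes`
#'   (gene_symbol, entrez_id, n_total, n_passing), ranked.
#' @export
multi_reagent_counts <- function(table, column, threshold,
                                 direction = c("ge", "le")) {
  direction <- match.arg(direction)
  .check_column(table, column)
  rec <- table$records
  if (!"reagent_id" %in% names(rec)) {
    stop("table has no reagent_id column", call. = FALSE)
  }
  x <- rec[[column]]
  scored <- !is.na(x)
  missing_reagent <- scored & (is.na(rec$reagent_id) | !nzchar(rec$reagent_id))
  if (any(missing_reagent)) {
    stop("scored row(s) lack a reagent_id: rows ",
         paste(utils::head(which(missing_reagent), 10L), collapse = ", "),
         call. = FALSE)
  }
  multi_gene <- tapply(rec$entrez_id[scored], rec$reagent_id[scored],
                       function(g) length(unique(g)))
  if (any(multi_gene > 1L)) {
    stop("reagent(s) mapped to more than one gene: ",
         paste(utils::head(names(multi_gene)[multi_gene > 1L], 5L), collapse = ", "),
         call. = FALSE)
  }
  pass <- if (direction == "ge") x >= threshold else x <= threshold
  reagents <- data.frame(
    reagent_id = rec$reagent_id[scored],
    gene_symbol = rec$gene_symbol[scored],
    entrez_id = rec$entrez_id[scored],
    score = x[scored],
    pass = as.integer(pass[scored]),
    stringsAsFactors = FALSE
  )
  agg <- stats::aggregate(cbind(n_total = rep(1L, nrow(reagents)),
                                n_passing = reagents$pass),
                          by = list(gene_symbol = reagents$gene_symbol,
                                    entrez_id = reagents$entrez_id),
                          FUN = sum)
  agg <- agg[order(-agg$n_passing, agg$gene_symbol), , drop = FALSE]
  rownames(agg) <- NULL
  structure(
    list(column = column, threshold = threshold, direction = direction,
         reagents = reagents, genes = agg),
    class = "multi_reagent_result"
  )
}

#' @export
print.multi_reagent_result <- function(x, ...) {
  cat(sprintf("<multi_reagent_result> column '%s', threshold %s %.4g\n",
              x$column, if (x$direction == "ge") ">=" else "<=", x$threshold))
  cat(sprintf("  %d reagents over %d genes; top genes:\n",
              nrow(x$reagents), nrow(x$genes)))
  print(utils::head(x$genes, 10L), row.names = FALSE)
  invisible(x)
}

#' Finalize a multi-reagent result into table columns
#'
#' Appends two columns: a per-row 0/1 flag marking each reagent as
#' validated, and the per-gene count of validated reagents (constant
#' within a gene's rows).
#'
#' @param table the `screen_table` the result was computed from.
#' @param result a [multi_reagent_counts()] result.
#' @return derived `screen_table` with `<column>.validated` and
#'   `<column>.n_validated` columns.
#' @export
finalize_multireagent <- function(table, result) {
  stopifnot(inherits(result, "multi_reagent_result"))
  .check_column(table, result$column)
  rec <- table$records
  if (!"reagent_id" %in% names(rec)) {
    stop("table has no reagent_id column", call. = FALSE)
  }
  ri <- match(rec$reagent_id, result$reagents$reagent_id)
  scored_now <- !is.na(rec[[result$column]])
  if (any(scored_now & is.na(ri))) {
    stop("result was not computed from this table (unknown reagent ids)",
         call. = FALSE)
  }
  flag <- ifelse(is.na(ri), NA_real_, result$reagents$pass[ri])
  gi <- match(rec$entrez_id, result$genes$entrez_id)
  count <- ifelse(is.na(gi), 0, result$genes$n_passing[gi])
  rec[[sprintf("%s.validated", result$column)]] <- flag
  rec[[sprintf("%s.n_validated", result$column)]] <- count
  derive_table(table, rec, log_entry = sprintf(
    "finalize_multireagent(%s, threshold=%.6g)", result$column, result$threshold))
}
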