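# Assay quality metrics: Z' factor over control pairs, replicate
# agreement, and per-well-type summaries.

#' Z-prime factor
#'
#' Separation statistic for a positive/negative control pair:
#' `1 - 3 * (sd(pos) + sd(neg)) / |mean(pos) - mean(neg)|`.
#' 1 is a perfect assay; values at or below 0 indicate overlapping
#' control distributions. The statistic is invariant under a common
#' affine transform of both groups.
#'
#' @param pos_values,neg_values numeric vectors (>= 2 values each).
#' @return a single number, at most 1.
#' @export
zprime <- function(pos_values, neg_values) {
  pos <- pos_values[!is.na(pos_values)]
  neg <- neg_values[!is.na(neg_values)]
  if (length(pos) < 2L || length(neg) < 2L) {
    stop("each control group needs at least 2 values", call. = FALSE)
  }
  mu_p <- mean(pos); mu_n <- mean(neg)
  if (mu_p == mu_n) {
    stop("Z' is undefined when the control means are equal", call. = FALSE)
  }
  1 - 3 * (stats::sd(pos) + stats::sd(neg)) / abs(mu_p - mu_n)
}

#' Replicate correlation with its t statistic
#'
#' Pearson correlation over pairwise-complete wells of two data columns,
#' with the associated correlation t test:
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, two-sided p from the t
#' distribution with n - 2 degrees of freedom.
#'
#' @param table a `screen_table`.
#' @param colA,colB data column names (replicates).
#' @return list with `r`, `t`, `p`, `n`.
#' @export
replicate_correlation <- function(table, colA, colB) {
  .check_column(table, colA)
  .check_column(table, colB)
  a <- table$records[[colA]]
  b <- table$records[[colB]]
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 paired non-missing wells", call. = FALSE)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
    stop("zero variance in '", if (stats::sd(a[ok]) == 0) colA else colB,
         "'; correlation undefined", call. = FALSE)
  }
  r <- stats::cor(a[ok], b[ok])
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  list(r = r, t = t_stat, p = p, n = n)
}

#' Quick analysis: well-type summaries and pairwise Z' factors
#'
#' Summarizes one data column by well type (n, mean, SD, and the
#' five-number box statistics with linear-interpolation quartiles), and
#' computes the Z' factor for every ordered pair of declared control
#' types with at least two non-missing wells each. Control well
#' positions are kept in the report for plotting.
#'
#' @param table a `screen_table`.
#' @param column data column name.
#' @param replicates optional character vector of two column names; adds
#'   a replicate-correlation block to the report.
#' @return object of class `qc_report`: `summary` (per-well-type
#'   data.frame), `zprime` (data.frame pos/neg/zprime), `control_wells`
#'   (named list of plate/well data.frames), `replicate` (optional),
#'   `absent_controls` (declared types with no wells).
#' @export
quick_analysis <- function(table, column, replicates = NULL) {
  .check_column(table, column)
  x <- table$records[[column]]
  wt <- table$records$well_type
  types <- unique(wt)
  summ <- do.call(rbind, lapply(types, function(ty) {
    v <- x[wt == ty]
    v_ok <- v[!is.na(v)]
    q <- if (length(v_ok) > 0L) stats::quantile(v_ok, c(0, .25, .5, .75, 1), type = 7, names = FALSE)
         else rep(NA_real_, 5L)
    data.frame(well_type = ty, n = length(v_ok),
               mean = if (length(v_ok)) mean(v_ok) else NA_real_,
               sd = if (length(v_ok) >= 2L) stats::sd(v_ok) else NA_real_,
               min = q[1L], q1 = q[2L], median = q[3L], q3 = q[4L], max = q[5L],
               stringsAsFactors = FALSE)
  }))
  present_controls <- intersect(table$control_types, types)
  absent_controls <- setdiff(table$control_types, types)
  zp <- data.frame(pos = character(), neg = character(), zprime = numeric(),
                   stringsAsFactors = FALSE)
  if (length(present_controls) >= 2L) {
    pairs <- expand.grid(pos = present_controls, neg = present_controls,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$pos != pairs$neg, , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      pv <- x[wt == pairs$pos[k]]
      nv <- x[wt == pairs$neg[k]]
      if (sum(!is.na(pv)) < 2L || sum(!is.na(nv)) < 2L) next
      z <- tryCatch(zprime(pv, nv), error = function(e) NA_real_)
      zp <- rbind(zp, data.frame(pos = pairs$pos[k], neg = pairs$neg[k],
                                 zprime = z, stringsAsFactors = FALSE))
    }
  }
  control_wells <- lapply(stats::setNames(present_controls, present_controls),
                          function(ty) {
    table$records[wt == ty, c("plate", "well"), drop = FALSE]
  })
  rep_block <- if (!is.null(replicates)) {
    stopifnot(length(replicates) == 2L)
    replicate_correlation(table, replicates[1L], replicates[2L])
  }
  structure(
    list(column = column, summary = summ, zprime = zp,
         control_wells = control_wells, replicate = rep_block,
         absent_controls = absent_controls),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> column '%s'\n", x$column))
  cat("  per-well-type summary:\n")
  print(x$summary, row.names = FALSE, digits = 4)
  if (nrow(x$zprime) > 0L) {
    cat("  pairwise Z' factors:\n")
    print(x$zprime, row.names = FALSE, digits = 4)
  } else {
    cat("  no control pairs with enough wells for Z'\n")
  }
  if (!is.null(x$replicate)) {
    cat(sprintf("  replicates: r = %.4f, t = %.2f, p = %.3g, n = %d\n",
                x$replicate$r, x$replicate$t, x$replicate$p, x$replicate$n))
  }
  if (length(x$absent_controls) > 0L) {
    cat("  declared controls absent from table: ",
        paste(x$absent_controls, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
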