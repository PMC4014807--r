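# Plate-local normalizations. Every method here treats each plate as an
# independent unit: permuting plates permutes outputs identically, and no
# statistic is pooled across plates.

#' Extract one plate of one data column as a matrix
#'
#' Rows and columns follow the plate geometry; wells absent from the table
#' or with missing values become `NA` cells.
#'
#' @param table a `screen_table`.
#' @param column data column name.
#' @param plate plate number.
#' @return numeric matrix of dim `geometry`, with a `"plate"` attribute.
#' @export
plate_matrix <- function(table, column, plate) {
  .check_column(table, column)
  rec <- table$records[table$records$plate == plate, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records for plate ", plate, call. = FALSE)
  m <- matrix(NA_real_, nrow = table$geometry[1L], ncol = table$geometry[2L],
              dimnames = list(LETTERS[seq_len(table$geometry[1L])],
                              sprintf("%02d", seq_len(table$geometry[2L]))))
  rc <- parse_well(rec$well, table$geometry)
  m[cbind(rc$row, rc$col)] <- rec[[column]]
  attr(m, "plate") <- plate
  m
}

#' Log-transform a data column
#'
#' Adds a column `log<base>(<column>)`. Non-positive inputs cannot be
#' logged; they become missing and are counted in the `"normalize_report"`
#' attribute of the result.
#'
#' @param table a `screen_table`.
#' @param column data column name.
#' @param base logarithm base (> 0, != 1); default 10.
#' @return derived `screen_table` with the new column.
#' @export
log_transform <- function(table, column, base = 10) {
  .check_column(table, column)
  stopifnot(base > 0, base != 1)
  x <- table$records[[column]]
  nonpos <- !is.na(x) & x <= 0
  y <- ifelse(nonpos, NA_real_, log(x, base = base))
  new_col <- sprintf("log%g(%s)", base, column)
  rec <- table$records
  rec[[new_col]] <- y
  out <- derive_table(table, rec,
                      log_entry = sprintf("log_transform(%s, base=%g)", column, base))
  attr(out, "normalize_report") <- list(n_nonpositive = sum(nonpos))
  out
}

#' Per-plate Z scores
#'
#' For each plate, `Z_i = (x_i - mean_p) / sd_p` over all wells of the
#' plate, with the sample standard deviation (n - 1 denominator). Plates
#' with zero spread (or fewer than two non-missing wells) get all-missing
#' Z values with a warning.
#'
#' @param table a `screen_table`.
#' @param column data column name.
#' @return derived `screen_table` with column `zscore(<column>)`.
#' @export
zscore <- function(table, column) {
  .check_column(table, column)
  x <- table$records[[column]]
  z <- rep(NA_real_, length(x))
  degenerate <- integer()
  for (idx in .plate_index(table)) {
    v <- x[idx]
    n_ok <- sum(!is.na(v))
    s <- if (n_ok >= 2L) stats::sd(v, na.rm = TRUE) else 0
    if (n_ok < 2L || !is.finite(s) || s == 0) {
      degenerate <- c(degenerate, table$records$plate[idx[1L]])
      next
    }
    z[idx] <- (v - mean(v, na.rm = TRUE)) / s
  }
  if (length(degenerate) > 0L) {
    warning("plate(s) with zero spread, Z set to missing: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  }
  rec <- table$records
  rec[[sprintf("zscore(%s)", column)]] <- z
  derive_table(table, rec, log_entry = sprintf("zscore(%s)", column))
}

#' Control-based normalization
#'
#' With both a positive and a negative control type, each well is scored
#' as `(x_i - mean_pos_p) / (mean_pos_p - mean_neg_p)` per plate, so the
#' positive-control mean maps to 0 on every plate. With a single control
#' type the score reduces to fold change relative to that control,
#' `(x_i - mean_ctrl_p) / mean_ctrl_p`.
#'
#' The default orientation follows the score above; `orientation =
#' "scaled"` instead anchors the negative control at 0 and the positive at
#' 1: `(x_i - mean_neg_p) / (mean_pos_p - mean_neg_p)`.
#'
#' @param table a `screen_table`.
#' @param column data column name.
#' @param pos_type positive-control well type (e.g. `"STX16"`).
#' @param neg_type negative-control well type (e.g. `"GFP"`), or `NULL`
#'   for the single-control fold-change form.
#' @param orientation `"control-score"` (default) or `"scaled"`.
#' @return derived `screen_table` with column `ctrl(<column>)` (or
#'   `fc(<column>)` in the fold-change form).
#' @export
control_normalize <- function(table, column, pos_type, neg_type = NULL,
                              orientation = c("control-score", "scaled")) {
  .check_column(table, column)
  orientation <- match.arg(orientation)
  x <- table$records[[column]]
  wt <- table$records$well_type
  out <- rep(NA_real_, length(x))
  flagged <- integer()
  fold_change <- is.null(neg_type)
  for (idx in .plate_index(table)) {
    plate <- table$records$plate[idx[1L]]
    pos <- x[idx][wt[idx] == pos_type]
    if (sum(!is.na(pos)) < 1L) {
      stop("plate ", plate, " has no '", pos_type, "' control wells",
           call. = FALSE)
    }
    mp <- mean(pos, na.rm = TRUE)
    if (fold_change) {
      out[idx] <- (x[idx] - mp) / mp
      next
    }
    neg <- x[idx][wt[idx] == neg_type]
    if (sum(!is.na(neg)) < 1L) {
      stop("plate ", plate, " has no '", neg_type, "' control wells",
           call. = FALSE)
    }
    mn <- mean(neg, na.rm = TRUE)
    if (mp == mn) {
      flagged <- c(flagged, plate)
      next
    }
    out[idx] <- if (orientation == "control-score") {
      (x[idx] - mp) / (mp - mn)
    } else {
      (x[idx] - mn) / (mp - mn)
    }
  }
  if (length(flagged) > 0L) {
    warning("plate(s) with equal control means, values set to missing: ",
            paste(flagged, collapse = ", "), call. = FALSE)
  }
  new_col <- if (fold_change) sprintf("fc(%s)", column) else sprintf("ctrl(%s)", column)
  rec <- table$records
  rec[[new_col]] <- out
  derive_table(table, rec, log_entry = sprintf(
    "control_normalize(%s, pos=%s%s, orientation=%s)", column, pos_type,
    if (fold_change) "" else paste0(", neg=", neg_type), orientation))
}

#' Two-way median polish
#'
#' Decomposes a plate matrix into overall + row + column effects plus
#' residuals by iteratively sweeping row medians and then column medians
#' out of the residuals (rows first). Iteration stops when the largest
#' absolute change in any effect falls below `tol` or after `max_iter`
#' full sweeps. Missing cells are excluded from all medians.
#'
#' @param m numeric matrix (a plate; at least 2 rows and 2 columns with
#'   data).
#' @param max_iter maximum number of full row+column sweeps.
#' @param tol convergence tolerance on effect changes.
#' @return list of class `polish_result`: `overall`, `row` (per-row
#'   effects), `col` (per-column effects), `residuals`, `iterations`,
#'   `converged`. On non-missing cells
#'   `overall + row_i + col_j + residual_ij` reconstructs the input.
#' @export
median_polish <- function(m, max_iter = 10L, tol = 1e-6) {
  stopifnot(is.matrix(m))
  if (all(is.na(m))) stop("matrix is all-missing", call. = FALSE)
  if (sum(rowSums(!is.na(m)) > 0L) < 2L || sum(colSums(!is.na(m)) > 0L) < 2L) {
    stop("median polish needs at least 2 rows and 2 columns with data",
         call. = FALSE)
  }
  nr <- nrow(m); nc <- ncol(m)
  overall <- 0
  row_eff <- numeric(nr)
  col_eff <- numeric(nc)
  resid <- m
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    max_change <- 0
    # sweep row medians out of the residuals
    rmed <- apply(resid, 1L, stats::median, na.rm = TRUE)
    rmed[is.na(rmed)] <- 0
    resid <- resid - rmed
    row_eff <- row_eff + rmed
    # recentre column effects through the overall term
    cshift <- stats::median(col_eff)
    col_eff <- col_eff - cshift
    overall <- overall + cshift
    max_change <- max(max_change, max(abs(rmed)), abs(cshift))
    # sweep column medians
    cmed <- apply(resid, 2L, stats::median, na.rm = TRUE)
    cmed[is.na(cmed)] <- 0
    resid <- sweep(resid, 2L, cmed)
    col_eff <- col_eff + cmed
    rshift <- stats::median(row_eff)
    row_eff <- row_eff - rshift
    overall <- overall + rshift
    max_change <- max(max_change, max(abs(cmed)), abs(rshift))
    if (max_change < tol) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(overall = overall, row = row_eff, col = col_eff,
         residuals = resid, iterations = iter, converged = converged),
    class = "polish_result"
  )
}

#' @export
print.polish_result <- function(x, ...) {
  cat(sprintf("<polish_result> %dx%d, %d iteration(s), %s\n",
              nrow(x$residuals), ncol(x$residuals), x$iterations,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  overall effect %.4g; residual range [%.4g, %.4g]\n",
              x$overall, min(x$residuals, na.rm = TRUE),
              max(x$residuals, na.rm = TRUE)))
  invisible(x)
}

#' Per-plate B scores
#'
#' For each plate, the data column is arranged on the plate grid, a
#' two-way median polish removes row and column offsets, and each
#' residual is divided by the plate's median absolute deviation of the
#' residuals: `B_ij = R_ij / MAD_p`, `MAD_p = median(|R_ij|)`. By default
#' no consistency constant is applied; `mad_constant = TRUE` multiplies
#' the MAD by 1.4826 (the Gaussian-consistent scaling).
#'
#' Plates whose residuals have zero MAD (e.g. perfectly additive plates)
#' get all-missing B scores with a warning.
#'
#' @param table a `screen_table`.
#' @param column data column name.
#' @param max_iter,tol passed to [median_polish()].
#' @param mad_constant apply the 1.4826 consistency constant?
#' @return derived `screen_table` with column `bscore(<column>)`.
#' @export
bscore <- function(table, column, max_iter = 10L, tol = 1e-6,
                   mad_constant = FALSE) {
  .check_column(table, column)
  b <- rep(NA_real_, nrow(table$records))
  degenerate <- integer()
  for (idx in .plate_index(table)) {
    plate <- table$records$plate[idx[1L]]
    m <- plate_matrix(table, column, plate)
    pol <- median_polish(m, max_iter = max_iter, tol = tol)
    mad_p <- stats::median(abs(pol$residuals), na.rm = TRUE)
    if (mad_constant) mad_p <- mad_p * 1.4826
    if (!is.finite(mad_p) || mad_p == 0) {
      degenerate <- c(degenerate, plate)
      next
    }
    rc <- parse_well(table$records$well[idx], table$geometry)
    b[idx] <- pol$residuals[cbind(rc$row, rc$col)] / mad_p
  }
  if (length(degenerate) > 0L) {
    warning("plate(s) with zero residual MAD, B scores set to missing: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  }
  rec <- table$records
  rec[[sprintf("bscore(%s)", column)]] <- b
  derive_table(table, rec, log_entry = sprintf("bscore(%s)", column))
}
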