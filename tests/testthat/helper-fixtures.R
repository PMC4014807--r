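# Fixtures are built in code at test time; nothing binary is stored.

# A tiny screen table on a 2x3 plate geometry, built directly.
tiny_table <- function(values, well_type = rep("sample", length(values)),
                       plate = rep(1L, length(values)),
                       geometry = c(2L, 3L), control_types = c("STX16", "GFP"),
                       column = "signal") {
  n <- length(values)
  stopifnot(length(well_type) == n, length(plate) == n)
  wells <- character(n)
  for (p in unique(plate)) {
    idx <- which(plate == p)
    grid <- expand.grid(col = seq_len(geometry[2L]), row = seq_len(geometry[1L]))
    wells[idx] <- format_well(grid$row[seq_along(idx)], grid$col[seq_along(idx)])
  }
  rec <- data.frame(plate = plate, well = wells, well_type = well_type,
                    gene_symbol = sprintf("G%03d", seq_len(n)),
                    entrez_id = 1000L + seq_len(n), stringsAsFactors = FALSE)
  rec[[column]] <- values
  screen_table(rec, geometry = geometry, control_types = control_types)
}

# Convert a single plate matrix into a one-plate screen table.
matrix_table <- function(m, plate = 1L, column = "signal") {
  grid <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  rec <- data.frame(plate = plate, well = format_well(grid$row, grid$col),
                    well_type = "sample",
                    gene_symbol = sprintf("G%04d", seq_len(nrow(grid))),
                    entrez_id = seq_len(nrow(grid)), stringsAsFactors = FALSE)
  rec[[column]] <- m[cbind(grid$row, grid$col)]
  screen_table(rec, geometry = dim(m))
}

# Minimal CSV fixture text for the loader.
mini_csv <- function(path, extra_rows = NULL) {
  lines <- c(
    "Plate number,Well,Well type,Gene symbol,Entrez Gene ID,Signal",
    "1,A1,sample,TP53,7157,0.5",
    "1,A2,STX16,STX16,8675,1.2",
    extra_rows
  )
  writeLines(lines, path)
  path
}

# Independent one-sided (enrichment) Fisher p-value: explicit
# hypergeometric mass sum over the upper tail of the 2x2 table
# [[g_c, G_c], [x - g_c, N - G_c]] with fixed margins.
hyper_tail_p <- function(g_c, x, G_c, N) {
  m <- g_c + G_c          # first-row total (category)
  total <- x + N          # grand total
  k <- x                  # first-column total (selection)
  hi <- min(k, m)
  sum(stats::dhyper(g_c:hi, m, total - m, k))
}

# GO annotation fixture: five genes, two carry a proteasome term,
# two carry Golgi CC terms.
go_fixture <- function(path) {
  lines <- c(
    "GeneID\tGO_ID\tGO_term\tCategory",
    "1001\tGO:0000001\tproteasome complex\tComponent",
    "1002\tGO:0000001\tproteasome complex\tComponent",
    "1003\tGO:0000002\tGolgi membrane\tComponent",
    "1004\tGO:0000003\tGolgi apparatus\tComponent",
    "1004\tGO:0000004\tmembrane transport\tProcess",
    "1005\tGO:0000005\tkinase activity\tFunction"
  )
  writeLines(lines, path)
  path
}
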