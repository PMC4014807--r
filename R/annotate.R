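# Local GO-annotation and PPI stores, Fisher-exact term enrichment,
# term search/exclusion, and subnetwork extraction.

.NAMESPACE_MAP <- c(
  "process" = "BP", "biological_process" = "BP", "bp" = "BP",
  "component" = "CC", "cellular_component" = "CC", "cc" = "CC",
  "function" = "MF", "molecular_function" = "MF", "mf" = "MF"
)

#' Construct an annotation store
#'
#' Holds a gene-to-GO map and an undirected PPI edge set, plus the
#' genome size used as the enrichment background (22,000 protein-coding
#' genes by default).
#'
#' @param go data.frame with columns `gene_id`, `go_id`, `term`,
#'   `namespace` (BP/CC/MF).
#' @param ppi data.frame with columns `a`, `b` (integer gene ids); edges
#'   are canonicalized (smaller id first), self-loops and duplicates
#'   dropped.
#' @param genome_size total genes in the genome background.
#' @return object of class `annotation_store`.
#' @export
annotation_store <- function(go = NULL, ppi = NULL, genome_size = 22000L) {
  if (is.null(go)) {
    go <- data.frame(gene_id = integer(), go_id = character(),
                     term = character(), namespace = character(),
                     stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene_id", "go_id", "term", "namespace") %in% names(go)))
  go <- unique(go[, c("gene_id", "go_id", "term", "namespace")])
  if (nrow(go) > 0L && !all(go$namespace %in% c("BP", "CC", "MF"))) {
    stop("GO namespaces must be BP, CC or MF", call. = FALSE)
  }
  if (is.null(ppi)) {
    ppi <- data.frame(a = integer(), b = integer())
  }
  stopifnot(all(c("a", "b") %in% names(ppi)))
  ppi <- .canonical_edges(ppi$a, ppi$b)
  structure(list(go = go, ppi = ppi, genome_size = genome_size),
            class = "annotation_store")
}

# canonical undirected edge set: a < b, unique, no self-loops
.canonical_edges <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  keep <- !is.na(a) & !is.na(b) & a != b
  e <- data.frame(a = pmin(a[keep], b[keep]), b = pmax(a[keep], b[keep]))
  e <- unique(e)
  e <- e[order(e$a, e$b), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' @export
print.annotation_store <- function(x, ...) {
  cat(sprintf("<annotation_store> %d GO annotations (%d genes, %d terms); %d PPI edges; genome size %d\n",
              nrow(x$go), length(unique(x$go$gene_id)),
              length(unique(x$go$go_id)), nrow(x$ppi), x$genome_size))
  invisible(x)
}

# locate a column by candidate names, case/punctuation-insensitive
.find_col <- function(nms, candidates) {
  norm <- gsub("[^a-z0-9]", "", tolower(nms))
  cand <- gsub("[^a-z0-9]", "", tolower(candidates))
  hit <- which(norm %in% cand)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Load gene-to-GO annotations from a tab-delimited snapshot
#'
#' Reads an NCBI-style annotation snapshot (gene2go-like layout): a
#' tab-delimited file whose header includes a gene id, GO id, GO term
#' and category column (matched case-insensitively against common
#' spellings). Category strings are mapped to the three ontologies
#' (Process -> BP, Component -> CC, Function -> MF); rows with an
#' unmappable category are skipped and counted in the `"load_report"`
#' attribute. Duplicate (gene, GO) rows collapse to one annotation.
#' Gzip-compressed files are read transparently.
#'
#' @param path file path.
#' @param store optional existing `annotation_store` to merge into.
#' @param genome_size background genome size for a newly created store.
#' @return an `annotation_store` with the GO part populated.
#' @export
load_go <- function(path, store = NULL, genome_size = 22000L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "")
  nms <- names(raw)
  i_gene <- .find_col(nms, c("GeneID", "gene_id", "gene", "entrez_id", "#GeneID"))
  i_go <- .find_col(nms, c("GO_ID", "go_id", "goid"))
  i_term <- .find_col(nms, c("GO_term", "term", "go_term_text", "goterm"))
  i_cat <- .find_col(nms, c("Category", "namespace", "ontology", "aspect"))
  if (any(is.na(c(i_gene, i_go, i_term, i_cat)))) {
    stop("annotation file must carry gene id, GO id, GO term and category columns",
         call. = FALSE)
  }
  ns <- .NAMESPACE_MAP[tolower(trimws(raw[[i_cat]]))]
  skipped <- sum(is.na(ns))
  keep <- !is.na(ns)
  go <- data.frame(
    gene_id = suppressWarnings(as.integer(raw[[i_gene]][keep])),
    go_id = as.character(raw[[i_go]][keep]),
    term = as.character(raw[[i_term]][keep]),
    namespace = unname(ns[keep]),
    stringsAsFactors = FALSE
  )
  bad_gene <- is.na(go$gene_id)
  skipped <- skipped + sum(bad_gene)
  go <- go[!bad_gene, , drop = FALSE]
  if (is.null(store)) store <- annotation_store(genome_size = genome_size)
  out <- annotation_store(go = unique(rbind(store$go, go)), ppi = store$ppi,
                          genome_size = store$genome_size)
  attr(out, "load_report") <- list(n_annotations = nrow(go),
                                   n_skipped = skipped)
  out
}

#' Load protein-protein interactions from a tab-delimited snapshot
#'
#' Reads an interactions snapshot with two interactor gene-id columns
#' (matched by common names, falling back to the first two columns).
#' Rows lacking two numeric gene ids are skipped and counted; edges are
#' canonicalized (undirected, no self-loops, no duplicates).
#'
#' @param path file path.
#' @param store optional existing `annotation_store` to merge into.
#' @param cols optional character vector of the two interactor column
#'   names.
#' @param genome_size background genome size for a newly created store.
#' @return an `annotation_store` with the PPI part populated.
#' @export
load_ppi <- function(path, store = NULL, cols = NULL, genome_size = 22000L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "")
  if (is.null(cols)) {
    i_a <- .find_col(names(raw), c("gene_id", "GeneID", "gene_a", "interactor_a"))
    i_b <- .find_col(names(raw), c("interactant_id", "interactant_gene_id",
                                   "gene_b", "interactor_b"))
    if (is.na(i_a) || is.na(i_b) || i_a == i_b) { i_a <- 1L; i_b <- 2L }
  } else {
    stopifnot(length(cols) == 2L, all(cols %in% names(raw)))
    i_a <- match(cols[1L], names(raw)); i_b <- match(cols[2L], names(raw))
  }
  a <- suppressWarnings(as.integer(raw[[i_a]]))
  b <- suppressWarnings(as.integer(raw[[i_b]]))
  skipped <- sum(is.na(a) | is.na(b))
  if (is.null(store)) store <- annotation_store(genome_size = genome_size)
  edges <- rbind(store$ppi, data.frame(a = a, b = b)[!is.na(a) & !is.na(b), ])
  out <- annotation_store(go = store$go, ppi = edges,
                          genome_size = store$genome_size)
  attr(out, "load_report") <- list(n_edges = nrow(out$ppi), n_skipped = skipped)
  out
}

#' Fisher's exact test on the screen-selection contingency table
#'
#' Builds the 2x2 table contrasting the user-selected gene set against
#' the genome for one GO category:
#' rows in/not-in category, columns selected/genome, i.e.
#' `[[g_c, G_c], [x - g_c, N - G_c]]`. This layout counts the whole
#' genome (including the selected genes) in the background column;
#' `background = "standard"` instead uses the disjoint complement
#' `[[g_c, G_c - g_c], [x - g_c, N - G_c - (x - g_c)]]`.
#'
#' @param g_c selected genes in the category.
#' @param x selected genes total.
#' @param G_c genome genes in the category.
#' @param N genome size.
#' @param background `"genome"` (table as described) or `"standard"`.
#' @param alternative `"greater"` (enrichment, default) or
#'   `"two.sided"`.
#' @return list with `p_value` and `odds_ratio` (sample cross-product
#'   odds ratio of the table used; 0/Inf reported for zero cells).
#' @export
enrichment_test <- function(g_c, x, G_c, N = 22000L,
                            background = c("genome", "standard"),
                            alternative = c("greater", "two.sided")) {
  background <- match.arg(background)
  alternative <- match.arg(alternative)
  stopifnot(g_c >= 0, g_c <= x, g_c <= G_c, G_c <= N, x <= N)
  tab <- if (background == "genome") {
    matrix(c(g_c, x - g_c, G_c, N - G_c), nrow = 2L)
  } else {
    matrix(c(g_c, x - g_c, G_c - g_c, N - G_c - (x - g_c)), nrow = 2L)
  }
  ft <- stats::fisher.test(tab, alternative = alternative)
  num <- tab[1L, 1L] * tab[2L, 2L]
  den <- tab[1L, 2L] * tab[2L, 1L]
  or <- if (den == 0) { if (num == 0) NaN else Inf } else num / den
  list(p_value = unname(ft$p.value), odds_ratio = or)
}

#' GO term enrichment over a selected gene set
#'
#' For every GO category (optionally restricted to one namespace) with
#' at least one selected gene, computes Fisher's exact p-value and odds
#' ratio on the selection-vs-genome contingency table (see
#' [enrichment_test()]); `G_c` is the number of store genes carrying the
#' category and `N` the store's genome size. Results with
#' `p <= p_threshold` are returned sorted by ascending p-value. Raw
#' p-values are reported; `adjust = TRUE` adds a Benjamini-Hochberg
#' column and filters on it instead.
#'
#' @param selected integer vector of selected gene ids.
#' @param store an `annotation_store`.
#' @param namespace optional `"BP"`, `"CC"` or `"MF"`.
#' @param p_threshold report categories with p at or below this value.
#' @param background,alternative passed to [enrichment_test()].
#' @param adjust apply Benjamini-Hochberg correction?
#' @return data.frame of class `enrichment_result`: go_id, term,
#'   namespace, g_c, x, G_c, N, odds_ratio, p_value (and p_adjusted if
#'   requested).
#' @export
go_enrichment <- function(selected, store, namespace = NULL, p_threshold = 0.01,
                          background = c("genome", "standard"),
                          alternative = c("greater", "two.sided"),
                          adjust = FALSE) {
  stopifnot(inherits(store, "annotation_store"))
  background <- match.arg(background)
  alternative <- match.arg(alternative)
  selected <- unique(as.integer(selected[!is.na(selected)]))
  x <- length(selected)
  if (x == 0L) stop("empty gene selection", call. = FALSE)
  go <- store$go
  if (!is.null(namespace)) {
    stopifnot(namespace %in% c("BP", "CC", "MF"))
    go <- go[go$namespace == namespace, , drop = FALSE]
  }
  if (nrow(go) == 0L) {
    res <- data.frame(go_id = character(), term = character(),
                      namespace = character(), g_c = integer(), x = integer(),
                      G_c = integer(), N = integer(), odds_ratio = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
    class(res) <- c("enrichment_result", "data.frame")
    return(res)
  }
  sizes <- tapply(go$gene_id, go$go_id, function(g) length(unique(g)))
  hit_rows <- go[go$gene_id %in% selected, , drop = FALSE]
  overlap <- tapply(hit_rows$gene_id, hit_rows$go_id,
                    function(g) length(unique(g)))
  ids <- names(overlap)
  meta <- go[!duplicated(go$go_id), c("go_id", "term", "namespace")]
  meta <- meta[match(ids, meta$go_id), , drop = FALSE]
  N <- store$genome_size
  stats_list <- lapply(seq_along(ids), function(k) {
    enrichment_test(g_c = overlap[[k]], x = x, G_c = sizes[[ids[k]]], N = N,
                    background = background, alternative = alternative)
  })
  res <- data.frame(
    go_id = ids, term = meta$term, namespace = meta$namespace,
    g_c = as.integer(unname(overlap)), x = x,
    G_c = as.integer(unname(sizes[ids])), N = N,
    odds_ratio = vapply(stats_list, `[[`, numeric(1L), "odds_ratio"),
    p_value = vapply(stats_list, `[[`, numeric(1L), "p_value"),
    stringsAsFactors = FALSE
  )
  if (adjust) {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
    res <- res[res$p_adjusted <= p_threshold, , drop = FALSE]
  } else {
    res <- res[res$p_value <= p_threshold, , drop = FALSE]
  }
  res <- res[order(res$p_value, res$go_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Search GO annotations by term text
#'
#' Returns the genes whose GO term text contains the query as a
#' case-insensitive substring, optionally within one namespace and
#' restricted to a gene set (or the genes of a screen table).
#'
#' @param genes integer gene ids, a `screen_table`, or `NULL` for all
#'   store genes.
#' @param term non-empty query text (e.g. `"Golgi"`,
#'   `"membrane transport"`).
#' @param store an `annotation_store`.
#' @param namespace optional `"BP"`, `"CC"` or `"MF"`.
#' @return integer vector of matching gene ids, sorted.
#' @export
search_go <- function(genes = NULL, term, store, namespace = NULL) {
  stopifnot(inherits(store, "annotation_store"))
  if (!is.character(term) || length(term) != 1L || !nzchar(trimws(term))) {
    stop("query term must be a non-empty string", call. = FALSE)
  }
  go <- store$go
  if (!is.null(namespace)) {
    stopifnot(namespace %in% c("BP", "CC", "MF"))
    go <- go[go$namespace == namespace, , drop = FALSE]
  }
  # literal substring match, case-insensitive
  hit <- grepl(tolower(term), tolower(go$term), fixed = TRUE)
  matched <- unique(go$gene_id[hit])
  if (inherits(genes, "screen_table")) {
    genes <- genes$records$entrez_id
  }
  if (!is.null(genes)) {
    matched <- intersect(matched, as.integer(genes))
  }
  sort(matched)
}

#' Remove rows whose gene carries a matching GO annotation
#'
#' Drops every row whose gene has any GO annotation (in any namespace)
#' whose term text contains `term` as a case-insensitive substring —
#' e.g. excluding "proteasome"-annotated genes whose effect on a
#' readout is assay-direct rather than pathway-specific. The exclusion
#' is recorded in the derivation log.
#'
#' @param table a `screen_table`.
#' @param term query text.
#' @param store an `annotation_store`.
#' @return derived `screen_table` without the matching genes' rows.
#' @export
exclude_by_go <- function(table, term, store) {
  stopifnot(inherits(table, "screen_table"))
  matched <- search_go(NULL, term, store)
  keep <- !(table$records$entrez_id %in% matched)
  derive_table(table, table$records[keep, , drop = FALSE],
               log_entry = sprintf("exclude_by_go(\"%s\"): removed %d rows",
                                   term, sum(!keep)))
}

#' Extract the PPI subnetwork induced by a gene set
#'
#' Returns every stored interaction whose both endpoints lie in the
#' input set (equivalent to searching all pairs of the list against the
#' database). Nodes with at least one edge are flagged as connected.
#'
#' @param genes integer gene ids.
#' @param store an `annotation_store`.
#' @return data.frame of class `ppi_edges` with columns `a`, `b`;
#'   attribute `"connected"` holds the connected gene ids.
#' @export
ppi_subnetwork <- function(genes, store) {
  stopifnot(inherits(store, "annotation_store"))
  genes <- unique(as.integer(genes[!is.na(genes)]))
  e <- store$ppi[store$ppi$a %in% genes & store$ppi$b %in% genes, , drop = FALSE]
  rownames(e) <- NULL
  attr(e, "connected") <- sort(unique(c(e$a, e$b)))
  class(e) <- c("ppi_edges", "data.frame")
  e
}

#' Export a network as an edge list or SIF
#'
#' Edge-list format is two tab-separated gene-id columns with a header;
#' SIF writes `a pp b` lines (interaction type "pp"), the simple
#' interaction format consumed by network viewers.
#'
#' @param edges data.frame with columns `a`, `b`.
#' @param path output file path.
#' @param format `"tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(edges, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  stopifnot(all(c("a", "b") %in% names(edges)))
  ok <- tryCatch({
    if (format == "tsv") {
      utils::write.table(edges[, c("a", "b")], path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    } else {
      writeLines(if (nrow(edges) > 0L)
                   sprintf("%d pp %d", edges$a, edges$b) else character(),
                 path)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write network to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}
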