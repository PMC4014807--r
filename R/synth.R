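# Seeded generators for synthetic screens, deconvolution sets,
# annotations and interaction stores with planted ground truth. All
# generators are pure functions of (spec, seed): the global RNG state is
# saved and restored around each call.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default control layout for a synthetic plate
#'
#' Mimics pre-printed library plates: the last two columns are reserved
#' for controls. Second-to-last column: positive trafficking controls
#' (STX16, CLTC, KDELR1) and the cell-death control PLK1 in row blocks;
#' last column: the GFP negative control in every row.
#'
#' @param geometry plate geometry `c(rows, cols)`.
#' @return data.frame with columns `row`, `col`, `type`.
#' @export
default_control_layout <- function(geometry = c(16L, 24L)) {
  nr <- geometry[1L]; nc <- geometry[2L]
  blocks <- rep(c("STX16", "CLTC", "KDELR1", "PLK1"),
                each = ceiling(nr / 4))[seq_len(nr)]
  rbind(
    data.frame(row = seq_len(nr), col = nc - 1L, type = blocks,
               stringsAsFactors = FALSE),
    data.frame(row = seq_len(nr), col = nc, type = "GFP",
               stringsAsFactors = FALSE)
  )
}

#' Specification for a synthetic arrayed screen
#'
#' Captures the study conditions a generated screen emulates: plate
#' count and geometry, the control layout with per-type (mean, SD) on
#' the readout scale, the sample baseline, planted hit genes with
#' effect sizes in sample-SD units, row/column artifact amplitudes,
#' plate-to-plate baseline drift, and the replicate count. Defaults
#' model a normalized luminescence readout: samples at 0 with SD 0.1,
#' the STX16 positive control at 1 and GFP negative at 0 (both SD
#' 0.05), strong planted hits shifted by 4-6 SD.
#'
#' @param n_plates number of plates.
#' @param geometry plate geometry `c(rows, cols)`.
#' @param control_layout data.frame `row`/`col`/`type` of control wells
#'   on every plate.
#' @param control_params named list, type -> `c(mean, sd)`.
#' @param sample_mean,sample_sd sample-well baseline and noise SD.
#' @param n_hits number of planted hit genes.
#' @param effect_range range (SD units) planted effects are drawn from.
#' @param row_artifact,col_artifact SDs of per-plate random row / column
#'   offsets (0 = no artifact).
#' @param plate_drift SD of the per-plate baseline shift.
#' @param replicates number of replicate data columns.
#' @param noise_scale multiplier on every noise SD (samples and
#'   controls); 0 gives the exact noiseless limit while `sample_sd`
#'   still sets the unit of the planted effects.
#' @return object of class `synthetic_screen_spec`.
#' @export
synthetic_screen_spec <- function(n_plates = 8L, geometry = c(16L, 24L),
                                  control_layout = default_control_layout(geometry),
                                  control_params = list(
                                    STX16 = c(1, 0.05), CLTC = c(0.6, 0.05),
                                    KDELR1 = c(0.8, 0.05), PLK1 = c(-0.5, 0.05),
                                    GFP = c(0, 0.05)),
                                  sample_mean = 0, sample_sd = 0.1,
                                  n_hits = 50L, effect_range = c(4, 6),
                                  row_artifact = 0, col_artifact = 0,
                                  plate_drift = 0, replicates = 2L,
                                  noise_scale = 1) {
  stopifnot(n_plates >= 1L, all(geometry >= 2L), sample_sd > 0,
            all(is.finite(effect_range)), replicates >= 1L,
            row_artifact >= 0, col_artifact >= 0, plate_drift >= 0,
            noise_scale >= 0)
  stopifnot(all(control_layout$type %in% names(control_params)))
  if (any(control_layout$row > geometry[1L] | control_layout$col > geometry[2L])) {
    stop("control wells fall outside the plate geometry", call. = FALSE)
  }
  for (p in control_params) stopifnot(length(p) == 2L, p[2L] > 0)
  structure(
    list(n_plates = as.integer(n_plates), geometry = as.integer(geometry),
         control_layout = control_layout, control_params = control_params,
         sample_mean = sample_mean, sample_sd = sample_sd,
         n_hits = as.integer(n_hits), effect_range = effect_range,
         row_artifact = row_artifact, col_artifact = col_artifact,
         plate_drift = plate_drift, replicates = as.integer(replicates),
         noise_scale = noise_scale),
    class = "synthetic_screen_spec"
  )
}

# synthetic gene ids live far above real identifier ranges
.SYN_ID_BASE <- 9000000L

#' Generate a synthetic arrayed screen with planted ground truth
#'
#' Sample wells carry `baseline + plate drift + row/column artifacts +
#' planted gene effect + Gaussian noise`; control wells are drawn from
#' their declared (mean, SD) on the same artifact surface. Replicate
#' columns (`signal_1`, `signal_2`, ...) share the gene effects and
#' artifact surfaces but have independent noise. Gene identifiers are
#' synthetic integers disjoint from real ranges.
#'
#' @param spec a [synthetic_screen_spec()].
#' @param seed integer seed; the same (spec, seed) always yields the
#'   same screen.
#' @return list: `table` (a raw `screen_table`) and `truth` (planted
#'   hits with effects, artifact surfaces, per-plate drift).
#' @export
generate_screen <- function(spec, seed) {
  stopifnot(inherits(spec, "synthetic_screen_spec"))
  .with_seed(seed, {
    nr <- spec$geometry[1L]; nc <- spec$geometry[2L]
    layout_key <- paste(spec$control_layout$row, spec$control_layout$col)
    grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
    grid$type <- spec$control_layout$type[match(paste(grid$row, grid$col), layout_key)]
    grid$type[is.na(grid$type)] <- "sample"
    n_sample_wells <- sum(grid$type == "sample") * spec$n_plates
    if (spec$n_hits > n_sample_wells) {
      stop("more planted hits (", spec$n_hits, ") than sample wells (",
           n_sample_wells, ")", call. = FALSE)
    }
    n_genes <- n_sample_wells
    gene_ids <- .SYN_ID_BASE + seq_len(n_genes)
    gene_syms <- sprintf("SYNG%05d", seq_len(n_genes))
    hit_idx <- sort(sample.int(n_genes, spec$n_hits))
    effects <- numeric(n_genes)
    effects[hit_idx] <- stats::runif(spec$n_hits, spec$effect_range[1L],
                                     spec$effect_range[2L])
    row_off <- matrix(stats::rnorm(spec$n_plates * nr, 0, spec$row_artifact),
                      spec$n_plates, nr)
    col_off <- matrix(stats::rnorm(spec$n_plates * nc, 0, spec$col_artifact),
                      spec$n_plates, nc)
    drift <- stats::rnorm(spec$n_plates, 0, spec$plate_drift)
    if (spec$row_artifact == 0) row_off[] <- 0
    if (spec$col_artifact == 0) col_off[] <- 0
    if (spec$plate_drift == 0) drift[] <- 0

    recs <- vector("list", spec$n_plates)
    g <- 0L
    for (p in seq_len(spec$n_plates)) {
      df <- data.frame(
        plate = p, well = format_well(grid$row, grid$col),
        well_type = grid$type, gene_symbol = NA_character_,
        entrez_id = NA_integer_, stringsAsFactors = FALSE
      )
      is_sample <- grid$type == "sample"
      n_s <- sum(is_sample)
      idx <- g + seq_len(n_s)
      df$gene_symbol[is_sample] <- gene_syms[idx]
      df$entrez_id[is_sample] <- gene_ids[idx]
      df$gene_symbol[!is_sample] <- grid$type[!is_sample]
      df$entrez_id[!is_sample] <- 0L
      surface <- drift[p] + row_off[p, grid$row] + col_off[p, grid$col]
      signal_mean <- numeric(nrow(grid))
      signal_sd <- numeric(nrow(grid))
      signal_mean[is_sample] <- spec$sample_mean + effects[idx] * spec$sample_sd
      signal_sd[is_sample] <- spec$sample_sd
      for (ty in unique(grid$type[!is_sample])) {
        sel <- grid$type == ty
        signal_mean[sel] <- spec$control_params[[ty]][1L]
        signal_sd[sel] <- spec$control_params[[ty]][2L]
      }
      for (r in seq_len(spec$replicates)) {
        noise <- if (spec$noise_scale > 0) {
          stats::rnorm(nrow(grid), 0, signal_sd * spec$noise_scale)
        } else 0
        df[[sprintf("signal_%d", r)]] <- signal_mean + surface + noise
      }
      recs[[p]] <- df
      g <- g + n_s
    }
    tab <- screen_table(do.call(rbind, recs), name = "synthetic screen",
                        geometry = spec$geometry,
                        control_types = names(spec$control_params),
                        nature = "raw", source_filename = "synthetic")
    truth <- list(
      hits = data.frame(entrez_id = gene_ids[hit_idx],
                        gene_symbol = gene_syms[hit_idx],
                        effect_sd_units = effects[hit_idx],
                        stringsAsFactors = FALSE),
      gene_effects = stats::setNames(effects, gene_ids),
      row_offsets = row_off, col_offsets = col_off, plate_drift = drift,
      seed = seed
    )
    list(table = tab, truth = truth)
  })
}

#' Generate a synthetic siRNA deconvolution (multi-reagent) screen
#'
#' Emulates the validation stage where each candidate gene is re-tested
#' with several individual reagents instead of a pool. Each (gene,
#' reagent) row scores `gene effect x reagent potency + noise`; true
#' hit genes carry a common effect on the (control-normalized) readout
#' scale, other genes score around 0.
#'
#' @param n_genes genes under validation.
#' @param reagents_per_gene reagents per gene (>= 2; 4 matches the usual
#'   single-siRNA deconvolution of a 4-siRNA pool).
#' @param hit_fraction fraction of genes that are true hits.
#' @param effect readout effect of a fully potent reagent against a
#'   true hit.
#' @param potencies `NULL` to draw per-reagent potencies from
#'   `Uniform(0.25, 1)` (singles are weaker than pools), or a fixed
#'   numeric vector of length `reagents_per_gene` applied to every
#'   gene.
#' @param noise_sd Gaussian noise SD (0 gives the exact noiseless
#'   construction).
#' @param geometry plate geometry used to lay wells out.
#' @param seed integer seed.
#' @return list: `table` (raw `screen_table` with `reagent_id` and a
#'   `signal` column) and `truth` (per-gene hit status and effect,
#'   per-reagent potency).
#' @export
generate_deconvolution <- function(n_genes = 200L, reagents_per_gene = 4L,
                                   hit_fraction = 0.5, effect = 1,
                                   potencies = NULL, noise_sd = 0.05,
                                   geometry = c(16L, 24L), seed = 1L) {
  stopifnot(reagents_per_gene >= 2L, n_genes >= 1L,
            hit_fraction >= 0, hit_fraction <= 1)
  if (!is.null(potencies)) stopifnot(length(potencies) == reagents_per_gene)
  .with_seed(seed, {
    gene_ids <- .SYN_ID_BASE + 500000L + seq_len(n_genes)
    gene_syms <- sprintf("SYNV%05d", seq_len(n_genes))
    n_hits <- round(n_genes * hit_fraction)
    is_hit <- logical(n_genes)
    if (n_hits > 0L) is_hit[sample.int(n_genes, n_hits)] <- TRUE
    pot <- if (is.null(potencies)) {
      matrix(stats::runif(n_genes * reagents_per_gene, 0.25, 1),
             n_genes, reagents_per_gene)
    } else {
      matrix(rep(potencies, each = n_genes), n_genes, reagents_per_gene)
    }
    n_rows <- n_genes * reagents_per_gene
    gidx <- rep(seq_len(n_genes), each = reagents_per_gene)
    ridx <- rep(seq_len(reagents_per_gene), times = n_genes)
    score <- ifelse(is_hit[gidx], effect, 0) * pot[cbind(gidx, ridx)]
    if (noise_sd > 0) score <- score + stats::rnorm(n_rows, 0, noise_sd)
    wells_per_plate <- prod(geometry)
    pos <- seq_len(n_rows) - 1L
    plate <- pos %/% wells_per_plate + 1L
    wrow <- (pos %% wells_per_plate) %/% geometry[2L] + 1L
    wcol <- (pos %% wells_per_plate) %% geometry[2L] + 1L
    rec <- data.frame(
      plate = plate, well = format_well(wrow, wcol), well_type = "sample",
      gene_symbol = gene_syms[gidx], entrez_id = gene_ids[gidx],
      reagent_id = sprintf("%s_r%d", gene_syms[gidx], ridx),
      signal = score, stringsAsFactors = FALSE
    )
    tab <- screen_table(rec, name = "synthetic deconvolution",
                        geometry = geometry, nature = "raw",
                        source_filename = "synthetic")
    truth <- list(
      genes = data.frame(entrez_id = gene_ids, gene_symbol = gene_syms,
                         true_hit = is_hit,
                         effect = ifelse(is_hit, effect, 0),
                         stringsAsFactors = FALSE),
      potency = pot, seed = seed
    )
    list(table = tab, truth = truth)
  })
}

#' Generate a synthetic annotation store with planted structure
#'
#' Background GO terms annotate every gene independently at
#' `background_rate`; one planted term annotates a target gene set at
#' `fold x background_rate` (capped at 1). Background PPI edges are
#' Bernoulli(`ppi_density`) over all gene pairs; planted cliques are
#' fully connected.
#'
#' @param genes integer gene ids forming the annotated universe.
#' @param n_terms number of background GO terms.
#' @param planted `NULL`, or a list with `term` (text), `fold`
#'   (enrichment factor >= 1), `targets` (gene ids, subset of `genes`)
#'   and optionally `namespace` (default `"CC"`).
#' @param background_rate probability a background term annotates a
#'   gene.
#' @param ppi_density probability of a background interaction between
#'   any two genes.
#' @param planted_cliques list of gene-id vectors; each becomes a
#'   complete subgraph.
#' @param genome_size enrichment background size.
#' @param seed integer seed.
#' @return an `annotation_store`; attribute `"truth"` records the
#'   planted term and cliques.
#' @export
generate_annotations <- function(genes, n_terms = 50L, planted = NULL,
                                 background_rate = 0.05, ppi_density = 0.01,
                                 planted_cliques = list(),
                                 genome_size = 22000L, seed = 1L) {
  genes <- unique(as.integer(genes))
  if (!is.null(planted)) {
    stopifnot(!is.null(planted$term), !is.null(planted$targets))
    if (is.null(planted$fold)) planted$fold <- 5
    if (planted$fold < 1) stop("fold-enrichment must be >= 1", call. = FALSE)
    if (!all(planted$targets %in% genes)) {
      stop("planted target set must be a subset of the gene universe",
           call. = FALSE)
    }
    if (is.null(planted$namespace)) planted$namespace <- "CC"
  }
  .with_seed(seed, {
    ns_cycle <- rep(c("BP", "CC", "MF"), length.out = n_terms)
    go_parts <- vector("list", n_terms + 1L)
    for (t in seq_len(n_terms)) {
      hit <- stats::runif(length(genes)) < background_rate
      if (!any(hit)) next
      go_parts[[t]] <- data.frame(
        gene_id = genes[hit],
        go_id = sprintf("GO:9%06d", t),
        term = sprintf("synthetic process %03d", t),
        namespace = ns_cycle[t], stringsAsFactors = FALSE
      )
    }
    if (!is.null(planted)) {
      p_target <- min(1, planted$fold * background_rate)
      is_target <- genes %in% planted$targets
      prob <- ifelse(is_target, p_target, background_rate)
      hit <- stats::runif(length(genes)) < prob
      go_parts[[n_terms + 1L]] <- data.frame(
        gene_id = genes[hit], go_id = "GO:9999999",
        term = planted$term, namespace = planted$namespace,
        stringsAsFactors = FALSE
      )
    }
    go <- do.call(rbind, go_parts[!vapply(go_parts, is.null, logical(1L))])
    if (is.null(go)) {
      go <- data.frame(gene_id = integer(), go_id = character(),
                       term = character(), namespace = character(),
                       stringsAsFactors = FALSE)
    }
    edges <- NULL
    if (ppi_density > 0 && length(genes) >= 2L) {
      pairs <- utils::combn(genes, 2L)
      keep <- stats::runif(ncol(pairs)) < ppi_density
      if (any(keep)) edges <- data.frame(a = pairs[1L, keep], b = pairs[2L, keep])
    }
    for (cl in planted_cliques) {
      cl <- unique(as.integer(cl))
      stopifnot(length(cl) >= 2L)
      cp <- utils::combn(cl, 2L)
      edges <- rbind(edges, data.frame(a = cp[1L, ], b = cp[2L, ]))
    }
    store <- annotation_store(go = go, ppi = edges, genome_size = genome_size)
    attr(store, "truth") <- list(planted = planted, cliques = planted_cliques,
                                 seed = seed)
    store
  })
}
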