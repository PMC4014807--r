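# screensift

Analysis toolkit for **arrayed RNAi screens**: plate-based
normalization, assay quality control, threshold-based hit calling,
siRNA deconvolution (multi-reagent) validation, and gene-centric
mining of hit lists against local Gene Ontology and protein–protein
interaction snapshots. It is aimed at screeners who have well-level
readouts in CSV form (plate, well, well type, gene, one or more data
columns) and want a scriptable, provenance-preserving version of the
usual screening workflow.

## What it computes

Every operation is **plate-local** and returns a *derived* table that
records its parent and an append-only derivation log. For well *i* on
plate *p*:

* **Z score** — `Z_i = (x_i − mean_p) / sd_p` over all wells of the
  plate (sample SD).
* **Control-based score** —
  `(x_i − mean_pos_p) / (mean_pos_p − mean_neg_p)`, anchoring the
  positive-control mean at 0 on every plate (single-control form
  reduces to fold change); cancels plate-to-plate drift exactly.
* **B score** — residual of a two-way Tukey median polish of the plate
  grid divided by the plate MAD of residuals,
  `B_ij = R_ijp / MAD_p`; robust to row/column gradients.
* **Z′ factor** — `1 − 3(σ_p + σ_n) / |μ_p − μ_n|` for every ordered
  pair of declared control types, plus per-well-type box statistics
  and replicate Pearson *r* with its *t* statistic.
* **Hit calling** — thresholds from `mean ± k·SD` of samples or any
  control, a fixed value, or a rank; finalization writes a 0/1 hit
  column. Multi-reagent analysis counts, per gene, the individual
  reagents passing a threshold and ranks genes by that count.
* **GO enrichment** — Fisher's exact test per GO category on the
  selection-vs-genome 2×2 table `[[g_c, G_c], [x − g_c, N − G_c]]`
  with N = 22,000; term search/exclusion by substring; PPI subnetwork
  extraction with SIF/TSV export.
* **Synthetic screens** — seeded generators for 384-well screens with
  control layouts, planted hits, row/column artifacts, drift,
  replicates, deconvolution sets and annotation stores with planted
  enrichment, so the entire pipeline is testable without external
  data.

## Worked example

```r
library(screensift)

# a 4-plate synthetic screen with 25 planted hit genes (effects 4-6 SD)
g <- generate_screen(synthetic_screen_spec(n_plates = 4L, n_hits = 25L),
                     seed = 42)

quick_analysis(g$table, "signal_1", replicates = c("signal_1", "signal_2"))
#>  well_type    n     mean      sd ...
#>     sample 1408  0.01153 0.12019
#>      STX16   16  1.02366 0.02887
#>        GFP   64 -0.01136 0.04773
#>  pairwise Z' factors (excerpt):
#>    pos    neg  zprime
#>  STX16    GFP  0.7780
#>  replicates: r = 0.7443, t = 43.65, p = 3.34e-271, n = 1536
```

The STX16/GFP Z′ of 0.78 says the positive and negative controls are
well separated (≥ 0.5 is conventionally an excellent assay). Hit
calling on the control-normalized scale:

```r
cn  <- control_normalize(g$table, "signal_1", "STX16", "GFP")
thr <- select_cutoff(cn, "ctrl(signal_1)",
                     cutoff_spec("stat", reference = "samples", k = 2))
res <- finalize_threshold(cn, "ctrl(signal_1)", thr, "ge")
thr                 #> -0.7442
nrow(res$hits)      #> 82
# all 25 planted hits are among the 82 called wells
length(intersect(res$hits$entrez_id, g$truth$hits$entrez_id))  #> 25
res$table$derivation_log
#> [1] "control_normalize(signal_1, pos=STX16, neg=GFP, orientation=control-score)"
#> [2] "finalize_threshold(ctrl(signal_1) >= -0.744229)"
```

On this scale the positive control sits at 0 and untreated samples
near −1, so hits are wells *above* `mean(samples) + 2·SD`; the planted
hits are fully recovered, and the remaining calls are the expected
upper tail of the null wells. Validation and mining continue with
`multi_reagent_counts()`, `go_enrichment()`, `search_go()`,
`exclude_by_go()` and `ppi_subnetwork()`; see the methods vignette
(`vignettes/screen-analysis-methods.Rmd`) for the models, defaults and
numerical caveats.

A command-line front end over the same functions is installed at
`inst/cli/screensift.R`:

```sh
Rscript inst/cli/screensift.R simulate --plates 4 --hits 25 --seed 42 -o screen.tsv
Rscript inst/cli/screensift.R qc --sep '\t' screen.tsv
Rscript inst/cli/screensift.R cutoff --sep '\t' --mode stat --ref samples --k 2 -o hits.tsv screen.tsv
```

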