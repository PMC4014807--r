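---
title: "Methods: plate-based RNAi screen analysis with screensift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plate-based RNAi screen analysis with screensift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screensift)
```

## The analysis problem

An arrayed RNAi screen silences one gene per well of a multi-well plate
(typically 384-well, 16 rows x 24 columns) and measures a phenotype per
well — for instance, luminescence from a reporter whose level reflects
the integrity of a trafficking pathway after toxin challenge. The raw
data are well-level records: plate number, well position, the well's
role (library sample or a named control), gene identity, and one or
more numeric readouts. Screens of this kind face three recurring
statistical problems that this package addresses:

1. **Systematic plate artifacts.** Plate-to-plate baseline drift and
   within-plate row/column gradients (edge evaporation, dispensing
   order, incubator position) can dwarf true gene effects.
2. **Threshold-based hit calling.** Screens call hits against a
   threshold derived from sample or control statistics; off-target
   effects then demand validation with multiple independent reagents
   per gene.
3. **Biological interpretation.** Hit lists only become findings when
   connected to functional annotation (GO) and protein-protein
   interactions.

`screensift` implements this pipeline as composable functions over a
`screen_table` object that preserves provenance: every operation
returns a *derived* table pointing at its parent with an append-only
log of the operations applied, so any result can be traced back to the
raw upload (and stepped back with `undo_derivation()`).

## Normalization models

All normalizations are **plate-local**: each plate is treated as an
independent unit, and no statistic is pooled across plates. For well
$i$ on plate $p$ with value $x_i$:

* **Z score**: $Z_i = (x_i - \bar{x}_p)/s_p$ over *all* wells of the
  plate, with the sample standard deviation ($n-1$ denominator). The
  population/sample choice is a convention; the sample SD matches the
  `[1,2,3] -> [-1,0,1]` behaviour most screeners expect. Per-plate mean
  and SD of the output are exactly 0 and 1 on non-degenerate plates.
* **Control-based score**: with positive- and negative-control means
  $\bar{x}_{p}^{+}, \bar{x}_{p}^{-}$ per plate,
  $s_i = (x_i - \bar{x}_{p}^{+}) / (\bar{x}_{p}^{+} - \bar{x}_{p}^{-})$.
  This orientation anchors the *positive* control at 0 on every plate,
  which makes positive-control stability across plates directly
  visible; `orientation = "scaled"` gives the more common 0-1 anchoring
  $(x_i - \bar{x}^{-})/(\bar{x}^{+} - \bar{x}^{-})$. With a single
  control type the score reduces to fold change
  $(x_i - \bar{x}_p^{c})/\bar{x}_p^{c}$. Because the score is built
  from per-plate control means, plate-to-plate baseline drift cancels
  exactly — the reason control normalization is preferred over Z
  scores when the library layout is non-random (a plate full of, say,
  kinases shifts $\bar{x}_p$ and corrupts Z scores, but not the
  controls).
* **B score**: the plate is arranged on its (row, column) grid, a
  two-way Tukey median polish decomposes it into
  overall + row + column effects + residuals $R_{ij}$, and
  $B_{ij} = R_{ij} / \mathrm{MAD}_p$ with
  $\mathrm{MAD}_p = \mathrm{median}|R_{ij}|$. No 1.4826 consistency
  constant is applied by default (set `mad_constant = TRUE` for the
  Gaussian-consistent scaling; it rescales every score by the same
  factor and leaves ranks unchanged).

### Median polish: numerical choices and a known limitation

`median_polish()` sweeps **row medians first, then column medians**,
repeating until the largest absolute change in any effect drops below
`tol` (default `1e-6`) or `max_iter` (default 10) full sweeps have
run. Missing wells are excluded from every median. The
reconstruction identity `overall + row + col + residual = input` holds
on non-missing cells at every iteration.

Two numerical facts are worth knowing:

* The sum of absolute residuals converges much faster than the
  residuals themselves, which keep redistributing mass between
  symmetric cells for many further sweeps. Comparisons between polish
  implementations should therefore match the number of full sweeps,
  not rely on each implementation's stopping rule.
* **Fixed points of iterated median polish are not unique.** Adding a
  row-constant offset to the input cancels exactly in the first row
  sweep, so B scores are *exactly* invariant under per-row offsets.
  Column-constant offsets, however, enter through the first row-median
  sweep (the row median of $x_{ij} + c_j$ is not the row median of
  $x_{ij}$ plus a constant); the perturbed iteration usually converges
  to the same residuals, but on a minority of plates (about 20% of
  random 16 x 24 Gaussian plates, in our seeded experiments) it
  settles on a *different* stationary decomposition, changing B scores
  by up to a few percent of a noise SD. This path dependence is
  intrinsic to rows-first Tukey polish (the reference implementation
  in `stats::medpolish` behaves identically) and is why the B score
  should be read as *robust to*, not *exactly invariant under*,
  column gradients.

## Quality control

* **Z' factor** for a positive/negative control pair:
  $Z' = 1 - 3(\sigma_p + \sigma_n)/|\mu_p - \mu_n|$ (the standard
  Zhang et al. separation statistic; 1 is a perfect assay, values at
  or below 0 mean overlapping controls). It is invariant under common
  affine transforms of both groups. `quick_analysis()` computes it for
  every ordered pair of declared control types, plus per-well-type
  box statistics (linear-interpolation quartiles, stated so they are
  testable).
* **Replicate agreement**: Pearson $r$ over pairwise-complete wells
  with the standard correlation $t$ test,
  $t = r\sqrt{n-2}/\sqrt{1-r^2}$, two-sided $p$ on $n-2$ df. The
  choice of this $t$ test (rather than, e.g., a Fisher z interval) is
  a convention we state explicitly.

## Hit calling and multi-reagent validation

`cutoff_spec()` expresses the three usual ways screeners set
thresholds — `mean(ref) ± k·SD(ref)` on samples or any control type, a
fixed value, or a rank in the ordered column — and
`finalize_threshold()` materializes the 0/1 hit column plus the
passing-gene list. The hit direction is always explicit (`ge`/`le`),
never inferred from the data.

For validation screens where each gene is re-tested with several
individual reagents, `multi_reagent_counts()` flags each reagent
against the threshold and counts passing reagents per gene; genes are
ranked by that count (ties broken lexicographically by symbol for
determinism), and `finalize_multireagent()` writes the per-reagent
flag and the per-gene count back into the table. Reagents with a
missing score are excluded from a gene's total rather than counted as
failures. The usual decision rule — a gene is validated when at least
two independent reagents pass — is left to the caller (or the
`--min-reagents` CLI flag), since it is a reporting convention, not a
computation.

## GO enrichment and PPI mining

`go_enrichment()` tests each GO category by Fisher's exact test on the
2x2 table contrasting the selected gene set against the genome
background of $N$ = 22,000 protein-coding genes:

|                    | selected  | genome      |
|--------------------|-----------|-------------|
| in category        | $g_c$     | $G_c$       |
| not in category    | $x - g_c$ | $N - G_c$   |

Note the background column counts the *whole genome*, so selected
genes are double-counted there. We keep this layout as the default for
continuity with screening practice, and provide
`background = "standard"` for the conventional disjoint-complement
table $[[g_c, G_c - g_c], [x - g_c, N - G_c - (x - g_c)]]$. For the
small $x$ and $G_c \ll N$ typical of screen selections the two differ
negligibly. The test is one-sided (enrichment) by default since that
is the question screeners ask; `alternative = "two.sided"` is
available. The odds ratio reported is the sample cross-product ratio
of the table used (0/Inf for zero cells, no continuity correction).
No multiple-testing correction is applied by default — the filtering
convention is a raw $p \le 0.01$ — but `adjust = TRUE` switches to
Benjamini-Hochberg.

Term search (`search_go()`) is a case-insensitive *substring* match on
the annotation text ("Golgi" matches "Golgi membrane"), which is what
"annotations containing the term" means operationally;
`exclude_by_go()` uses it to drop genes whose annotations make them
assay-direct confounders (e.g. proteasome components in a
reporter-degradation assay). PPI mining is deliberately simple: the
store holds a canonical undirected edge set, and
`ppi_subnetwork()` returns the edges induced by a gene list —
equivalent to looking up all $\binom{n}{2}$ pairs. Identity is keyed
on integer (Entrez-style) gene ids throughout; symbols are display
only.

## The synthetic-data generator

`generate_screen()` emulates the structure of a pre-printed 384-well
siRNA library screen:

* samples in columns 1-22; the second-to-last column holds positive
  trafficking controls (STX16, CLTC, KDELR1) and the cell-death
  control PLK1 in row blocks; the last column is the GFP negative
  control;
* readouts on a normalized luminescence scale: samples at baseline 0
  with noise SD 0.1; STX16 at 1, CLTC at 0.6, KDELR1 at 0.8, GFP at 0
  (SD 0.05 each); PLK1 at -0.5, standing in for the low signal of
  dying cells;
* planted hit genes shifted upward by 4-6 sample-SD units. Strong
  screening hits sit well clear of the calling threshold; note that a
  hit at *exactly* 3 SD would be missed ~16% of the time by a
  mean + 2 SD threshold on Gaussian noise, so recovery guarantees are
  only meaningful for effects comfortably above the threshold margin —
  which is what the 4-6 SD default models;
* optional per-plate row/column offsets (Gaussian, amplitude
  configurable), plate-to-plate baseline drift, and any number of
  replicate columns sharing gene effects with independent noise;
* `noise_scale = 0` gives the exact noiseless limit for
  construction-based tests.

`generate_deconvolution()` emulates the validation stage (default 4
reagents per gene, per-reagent potencies drawn from Uniform(0.25, 1)
to reflect single siRNAs being weaker than pools, or a fixed potency
vector such as `{1,1,1,0}` for exact constructions).
`generate_annotations()` plants an over-represented GO term (a target
set annotated at `fold` x the background rate) and fully connected
PPI cliques on top of Bernoulli background edges.

All generators are pure functions of (spec, seed): they neither read
nor perturb the global RNG state, and identical inputs give byte-identical
tables. Synthetic gene ids start at 9,000,001, far above real Entrez
ranges, so fixtures can never be mistaken for real data.

**What passing tests on synthetic screens do and do not show.** The
generator's Gaussian, additive world establishes *correctness* of the
computations (recovery of planted structure, equivalence with
independent oracles, closed-form Z' values). Real screens violate
these assumptions in known ways — heavy-tailed and heteroscedastic
readouts, spatially smooth rather than row/column-separable artifacts,
cell-death confounding of knockdown phenotypes, correlated off-target
effects across reagents sharing seed sequences — so green tests here
say the arithmetic is right, not that a particular normalization is
adequate for a particular assay.

## Problem sizes and determinism in the shipped checks

The test suite and the acceptance script run entirely on generated
data: 100 random plates for the polish-oracle comparison, 50 plates
for the surface-invariance probe, 20 replicate screens of 8 plates for
hit recovery, a 20-plate artifact-laden screen for the B-vs-Z
benchmark, 1000 x 4 deconvolution tables, and an x <= 20, G_c <= 200
grid of Fisher tables — sizes chosen so every property is measured
with comfortable Monte-Carlo margins while the whole suite stays quick
on a laptop. Every stochastic check is seeded, and the acceptance
script derives all of its streams from a single `--seed`.

## Known limitations

* The B-score fixed-point non-uniqueness described above: exact
  invariance holds for row-constant offsets only; column-gradient
  robustness is approximate.
* The provenance model stores parent tables in memory within a
  session; persistence is TSV export plus re-load, not a database.
* GO handling is flat term matching: no ontology graph, no ancestor
  propagation, so enrichment treats each term independently of its
  parents.
* The generator does not model image-derived high-content features or
  the death-driven signal collapse that makes PLK1 a transfection
  control rather than a pathway control; it is generated as just
  another control distribution.
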