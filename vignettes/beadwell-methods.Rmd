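---
title: "Models and methods behind beadwell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind beadwell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadwell)
```

## The assay beadwell models

beadwell implements the computational side of a microwell single-cell
RNA-seq chemistry in which a slide holds on the order of 160,000 wells of
roughly 20 pL; each well receives one polystyrene bead carrying a capture
oligo (a fixed 5' flank, a 25-nt poly-A stretch, a 12-nt random barcode and
a fixed 3' flank) and, with low probability, one cell.  After lysis,
polyadenylated mRNA binds the bead, and sequencing produces read pairs in
which read 1 carries the 12-nt cell barcode at its start followed by fixed
primer sequence, while read 2 is cDNA from the captured transcript.

Two properties distinguish this chemistry from droplet platforms most
pipelines assume:

* **No UMIs.** The capture oligo has no unique molecular identifier, so
  expression is quantified as *read counts per (barcode, gene)* — "tags" —
  and per-cell totals are made comparable by scaling each cell to a fixed
  tag total (300,000 by default) rather than by molecule counting.
* **Bead-level barcode collisions.** Barcodes are clonally amplified onto
  beads by emulsion PCR from randomly synthesized oligos, so two beads can
  carry the same 12-mer.  Sequencing of bead preparations put such
  overlapping barcodes below 2% of 10,000 beads; the package models the
  statistical surrogate — i.i.d. uniform sampling from the `4^12` space —
  for which the expected collision fraction is
  `1 - (1 - 4^-12)^(n-1)` (about 0.06% at n = 10,000), comfortably inside
  that bound.  The mechanistic route to collisions (several template
  molecules in one emulsion droplet) is not modeled; no published rate of
  multi-template droplets exists to calibrate it.

## Poisson loading

Cells settle into wells by gravity.  With `n` deposited cells and `W`
wells, each cell lands in a uniformly random well, so well occupancy is
binomial and, at the scales used, Poisson with mean `lambda = n / W`.  The
quantity of interest is the *fraction of cells deposited singly*, i.e. the
probability that a given deposited cell shares its well with no other:

* Poisson limit: `exp(-lambda)`;
* exact finite form: `(1 - 1/W)^(n - 1)`.

At the working cell:well ratio of 1:20 (`lambda = 0.05`),
`exp(-0.05) = 0.9512`, i.e. 95% of cells are singlets.  We read the
published 95% as a fraction *of deposited cells*; the alternative reading —
the fraction of occupied wells that hold exactly one cell,
`lambda e^-lambda / (1 - e^-lambda)` which is about 97.5% at 0.05 — does
not match the printed figure and is rejected.  `simulate_loading()` also
applies Bernoulli thinning with the measured seeding efficiency (default
0.9: 10,000 input cells deposit about 9,000) before assignment to wells.
Bead loading is squeegeed to one bead per well manually and is therefore
modeled as deterministic full occupancy, with an optional bead-occupancy
rate for sensitivity analysis.

```{r loading}
singlet_fraction_of_cells(0.05)
loading_summary(simulate_loading(loading_spec(n_cells = 10000, seed = 1)))
```

## Synthetic data: what it emulates and what it does not

`make_toy_transcriptome()`, `population_spec()`, `simulate_cells()` and
`emit_fastq_pairs()` generate a complete experiment with known ground
truth: random transcripts in two species namespaces (no 25-mer shared
between transcripts, so exact-substring assignment is unambiguous by
construction), cells drawn from configurable classes that carry a tissue
side, a species and per-gene positivity probabilities, and paired FASTQ
with the real read structure (barcode at offset 0 of read 1; read 2 drawn
from the 3'-most 300 nt of the transcript to mimic oligo-dT capture bias,
75 nt by default — read lengths are configuration, not published values).
The error model is substitution-only at a uniform per-base rate; indels,
PCR duplication, quality-score structure and adapter read-through are
deliberately out of scope.

Passing tests on these fixtures demonstrate that the pipeline's
book-keeping is exact (an error-free run reproduces the truth matrix
entry for entry) and that its statistical behaviour matches closed forms.
They do not demonstrate robustness to real-data pathologies — degraded
RNA, ambient contamination, homologous genes, intronic reads — which the
toy transcriptome cannot exhibit.

## Demultiplexing, counting, QC, normalization

* **Barcode extraction** takes the first 12 nt of read 1.  With a
  whitelist, a prefix is accepted on exact match or corrected to a unique
  Hamming-distance-1 neighbour when `max_mismatch = 1`; reads with an
  ambiguous base, no match, or an ambiguous correction are rejected with a
  reason, and the run report keeps the conservation ledger
  `assigned + rejected + unassigned = total`.
* **Gene assignment** is either the built-in toy aligner (a read is
  assigned to the unique transcript containing it exactly; multi-gene hits
  are discarded rather than fractionally assigned) or an external SAM
  stream keyed by read name, in which unmapped reads and reads whose
  alignments touch more than one gene are unassigned.  Alignment itself is
  delegated to real aligners; the package only consumes their output.
* **Cell QC** retains barcodes with *strictly more than* 20,000 reads and
  *strictly more than* 400 detected genes, the published per-cell yield
  thresholds; boundary barcodes are excluded.  For whitelist-free runs a
  top-N selection (and a knee-point heuristic) stand in for the unpublished
  cell-selection rule that produced 1,000 cells per tissue side.
* **Normalization** scales each retained cell to 300,000 tags.  Values
  stay fractional so row sums are exact to within 1e-6 relative tolerance.
  The published order of operations around cell typing is not stated; the
  package fixes QC → normalize → classify and records the order in the run
  report.

## Species mixing (barnyard)

For two-species runs, `species_counts()` totals each barcode's reads per
species namespace and `classify_species()` calls a barcode a species when
that species holds at least a `purity_threshold` share of its reads
(default 0.9 — a conventional choice; the original scatter analysis states
no threshold), otherwise "mixed".  Zero-read barcodes are excluded from
purity statistics and flagged separately.  Raising the threshold can only
grow the mixed set, which the tests assert as a monotonicity property.

## Marker-rule annotation and the EMT trichotomy

Cell typing is rule-based: a cell is *positive* for a gene when its
normalized tag count is at least the positivity threshold (default 1
normalized tag — the published analyses count "positive cells" without
defining the cutoff, so this is an explicit, global configuration value;
the boundary is inclusive).  Classes are evaluated in a configured
priority order (e.g. T cells by *CD3D*, macrophages by *CD68*, tumour
cells by epithelial markers) and the first satisfied rule wins;
multi-positive cells are logged as conflicts.

Tumour cells are then partitioned by epithelial-mesenchymal state using
the eight markers *ACTA2*, *EPCAM*, *CD44*, *THY1*, *VIM*, *FN1*, *ZEB1*,
*CDH1*: only epithelial markers → `EA`; only mesenchymal → `EA_EMT`; both
→ `EA_intEMT`; neither → `none`.  The four states are an exhaustive,
mutually exclusive partition.  The published marker list is not split into
the two sets, so the package defaults to epithelial = {EPCAM, CDH1},
mesenchymal = {ACTA2, VIM, FN1, ZEB1, THY1, CD44}, and flags CD44/THY1 as
contested (both also mark stem-like cells); the split is configuration.

## Two-side tables

`side_table()` counts positive cells per gene for two cell populations
(e.g. the endometrial E-side and myometrial-invasion M-side of a tumour),
prints integer percentages (half-up rounding) and one-decimal fold ratios
between the two sides' positive fractions.  The fold direction is an
explicit parameter because the published table that this arithmetic
reproduces uses *both* orientations under a single "Fold (E/M)" header:
its spheroid-signature panel prints E-over-M folds while its
serum-signature panel prints M-over-E folds, as verification against every
printed row shows (`published_side_table()` carries a per-row direction
column).  Folds whose denominator side has no positive cells are undefined
and reported as `NA`; the printed table is internally inconsistent for
such rows (identical 2-vs-0 rows print 1.0 and 0.0), so no behaviour is
imitated.  The comparison population (e.g. 305 and 180 estimated tumour
cells per side) is an input, not something the package guesses: the rule
that produced those totals was never published.

```{r table}
side_table_from_counts(c("FADS2", "S100B"), c(147, 61), 305,
                       c(55, 3), 180, direction = "E_over_M")
```

## Statistics

`mann_whitney_u()` computes the rank-sum U with midranks.  Exact mode
enumerates all `choose(n1 + n2, n1)` labelings of the pooled sample —
feasible for `n1 + n2 <= 16`, which is where auto mode uses it — and
returns the two-sided permutation p-value `P(|U - n1 n2/2| >= |u - n1
n2/2|)` (the permutation distribution of U is symmetric even under ties).
Approx mode uses the normal approximation with tie-corrected variance and
a 0.5 continuity correction, matching the conventional large-sample test.
For moderate samples (both groups of five or more, without massive ties)
the approximation tracks the exact p-value to within about 0.01–0.02;
for tiny or heavily tied samples it can deviate far more — exact p-values
are granular (at `n1 = n2 = 2` the smallest two-sided p is 1/3) — which is
precisely why auto mode switches to enumeration there.  Two-sided p-values
are used throughout; the published comparisons report significance stars
without stating sidedness, and two-sided is the conservative reading.

`bh_fdr()` validates inputs and applies the Benjamini-Hochberg step-up
rule (via `stats::p.adjust`); it is applied across whichever gene list the
caller supplies, since the published analyses do not state which sets
entered the correction.  `pearson_log()` correlates `log(x + 1)`-
transformed expression (pseudocount 1; the transform's offset is not
published).

## Numerical and design choices

* All stochastic operations take an explicit integer seed and restore the
  caller's RNG state; seeds are part of run metadata, never wall-clock.
* Printed-table arithmetic uses half-up rounding (`round_half_up`), the
  convention of printed percentage tables, not banker's rounding.
* Sparse matrices (Matrix package) back the expression container; MTX plus
  `barcodes.tsv`/`genes.tsv`, or dense TSV, are the on-disk forms, with a
  JSON sidecar for the sample label and normalization state.
* Hierarchical clustering runs on `log2(x + 1)` of normalized tags with
  Euclidean distance and Ward linkage by default; the published
  unsupervised analysis names neither, so both are recorded parameters.
* Problem sizes in the tests (tens of cells, hundreds of genes, ~17,000
  read pairs end-to-end; 100–200 replicate Monte-Carlo checks) were chosen
  as the smallest scales at which the closed-form comparisons have narrow
  standard errors; all statistical checks use 3-standard-error bands.

## Known limitations

* The uniform-sampling collision model bounds, but does not mechanistically
  reproduce, emulsion-PCR barcode overlap.
* The toy aligner requires exact substrings; it is a stand-in for testing,
  not an aligner.  Real data should arrive as SAM.
* Tag normalization to a fixed total ignores transcriptome-size differences
  between cell types, as the original protocol does.
* Marker-rule classification inherits the arbitrariness of its threshold
  and marker sets; defaults are documented conventions, not ground truth.
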