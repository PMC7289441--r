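---
title: "Methods: stringent AP-MS interactor calling and imaginal disc quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stringent AP-MS interactor calling and imaginal disc quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coprecip)
```

## What the package computes

`coprecip` packages three analysis procedures commonly used in studies of
protein complexes and tissue phenotypes in *Drosophila*, here motivated by
work on the TGS1 cap hypermethylase and the Smn (survival of motor neuron)
complex:

1. **Interactor calling from GFP-TRAP AP-MS.** Protein IDs co-purifying
   with a GFP-tagged bait are filtered stringently and the survivors are
   ranked by abundance.
2. **Quantification of eye-antennal imaginal disc z-stacks** stained for
   DNA (DAPI), differentiated photoreceptors (Elav) and apoptosis
   (cleaved Caspase-3).
3. **Categorical eye-size phenotype tabulation** with a conservative rule
   for ambiguous calls.

A synthetic-data module generates spike-in AP-MS tables and three-channel
disc stacks with known ground truth, so every stage of the pipeline is
exercisable and verifiable offline.

## Interactor calling

### The stringent filter

Input is a protein-level search-result table: one row per protein ID with a
search score, percent sequence coverage and per-peptide abundance areas
(assumed to be post-search, already filtered to a 5% peptide FDR upstream;
the package does not touch spectra). A protein ID is called an interactor
iff all four rules hold:

* **Peptide evidence** — at least 2 *distinct peptide sequences*. We count
  unique sequences, not peptide-spectrum matches, because repeated
  identifications of one peptide add no sequence-level evidence.
* **Coverage** — at least 20% of the protein sequence covered. The removal
  rule is "below 20%", so exactly 20.0 survives.
* **Score** — strictly above 50. The two natural readings of the score rule
  ("remove < 50" vs "keep above 50") disagree only at exactly 50; we treat
  the retention phrasing as operative, so a score of exactly 50 is removed.
* **Not blacklisted** — the accession must be absent from the accumulated
  false-positive database.

The false-positive database is the plain union of all accessions ever seen
in negative-control pull-downs (the study design accumulates eight
independent control GFP-TRAP runs). No frequency weighting is applied and
matching is exact string equality on accessions — no isoform collapsing —
because no grouping rule is defined for these identifiers; the column map in
`table_dialect()` is the extension point if a user needs one.

Every input record, survivor or casualty, receives a per-rule audit row
(`attr(calls, "audit")`), so the filter never silently drops anything:
survivors + rejected = input.

### T3PQ and ranking

Abundance is estimated by top-3 peptide quantification: the mean of the
three highest peptide areas (`t3pq()`). Records that survive filtering with
only two quantified peptides degrade gracefully to the mean of what is
available, flagged via `t3pq_n_used`; records with *no* quantified peptide
raise an undefined-quantity error rather than being zeroed, because a
silent 0 would corrupt the ranking. Missing area cells likewise parse to
`NA`, never 0.

Survivors are ranked by descending T3PQ mean area; ties break by descending
score, then lexicographic accession, making the report fully deterministic.
The bait is expected to be the most abundant protein in its own precipitate
— `verify_bait_top()` checks this and names the usurper when it fails. The
bait appears in the report flagged `is_bait` but is excluded from the
specific-interactor count in `glance()`.

## Disc image quantification

All quantities are measured on **maximum-intensity projections** (MIPs) of
the z-stack, matching common practice for these preparations; nothing is
quantified per-plane or in 3-D.

* **Disc segmentation** (`segment_disc()`): Otsu's automatic global
  threshold on the DAPI MIP, retention of the largest connected foreground
  component, hole filling. All component labeling in the package uses
  8-connectivity. The disc area is the mask pixel count times the pixel
  area; `pixel_size` (µm/pixel) is a required calibration input — the
  default 0.325 in the simulator configs is an example calibration, not a
  measured one.
* **Elav fraction** (`elav_fraction()`): Elav positivity by an Otsu
  threshold computed *inside the disc mask only*, reported as a percentage
  of disc pixels. A constant in-mask signal is degenerate for Otsu; it is
  defined as 100% when nonzero and 0% when zero.
* **Basal fluorescence** (`estimate_basal_fluorescence()`): the in-mask
  median of the Caspase MIP. The estimator is unstated in the protocols
  this models; the median is chosen because apoptotic foci are sparse
  (a few percent of disc pixels) and a median is unaffected by them. It is
  estimated per disc, not per batch — each disc carries its own basal level.
* **Focus calling** (`call_caspase_foci()`): pixels at or above 3× basal
  ("starting from 3 times the basal fluorescence" reads as inclusive, so
  exactly 3.0× is called), restricted to the disc mask (foci are per-disc
  quantities), labeled with 8-connectivity, and gated to areas strictly
  between 1 and 60 µm². The gate bounds are areas; a component of exactly
  1 or 60 µm² is rejected. Each focus reports its area, mean fluorescence
  and centroid.
* **Disc-size classification** (`classify_disc_sizes()`): test discs are
  classed below / within / above `mean ± 2 × SD` of the control areas
  (sample SD, n − 1). For test areas drawn from the control normal law the
  expected outside fraction is the analytic two-tail mass ≈ 0.0455.

## Eye phenotype tabulation

Eyes are scored visually into classes {0, 25, 50, 75, 100} (percent of
wild-type size; 0 = absent, 100 = essentially normal). The classification
is categorical by design — no image-based eye measurement is attempted.
When a call is ambiguous between two adjacent classes, the resolution is
deliberately conservative relative to the hypothesis: *without* a rescue
construct the eye is assigned to the higher class (understating the
knockdown phenotype), *with* a rescue construct to the lower class
(understating the rescue). `tabulate_classes()` emits long tidy tallies
(counts and exact percentages per genotype, genotypes ordered by first
appearance); the wide CSV rounds percentages to one decimal for display
while the long form keeps full precision.

## The synthetic-data generators

The generators define the conditions under which the pipeline is tested;
their defaults are fixed once and are not tuning knobs.

**AP-MS spike-in** (`generate_apms_experiment()`): one bait run containing
the bait, `n_true_interactors = 12` true interactors (present only in the
bait run) and `n_contaminants = 200` background contaminants;
`n_control_runs = 8` control runs in which each contaminant reappears
independently with probability 0.9, with per-run redrawn scores and areas.
Peptide areas are log-normal — true interactors `meanlog 12, sdlog 1`,
contaminants `meanlog 8, sdlog 1.5`, in arbitrary area units (chosen to
give a realistic order-of-magnitude separation between specific and
background binders; the units cancel in ranking). Score/coverage/peptide-
count laws are "clear-margin": both classes clear the thresholds, so
recovery is decided by the blacklist and the expected number of escaping
contaminants is analytically `200 × (1 − 0.9)^8 ≈ 2 × 10⁻⁶` per
experiment. The bait's areas are pinned above the maximum T3PQ of all other
records, so the bait-is-top check has ground truth true by construction.

**Disc stacks** (`generate_disc_image()`): 128 × 128 pixel planes, 15 z
planes at 0.5 µm (the acquisition geometry of the protocol), pixel size
0.325 µm. The disc is the set of pixels nearest the frame centre holding
35% of the frame; the Elav region is the concentric subset holding exactly
40% of disc pixels; six foci of 5–30 µm² at 5× basal are placed on a ring
inside the disc, each confined to one z plane so the MIP contains it in
full. Planted regions are rasterized by nearest-pixel count, and the
recorded truth is the rasterized pixel count × pixel area — not the ideal
πr² — so exact-recovery assertions are possible. A single integer seed
(base R's default Mersenne-Twister stream) governs all randomness;
identical configs reproduce identical stacks and tables.

What the simulations do **not** emulate: realistic optical point-spread
functions, z-dependent attenuation, autofluorescence gradients, touching or
out-of-focus foci, protein-level intensity correlations, or retention-time
structure in MS data. Passing the recovery tests therefore demonstrates the
correctness of the computational procedure under its stated assumptions,
not robustness to every artefact of real microscopy or spectrometry.

## Problem sizes and numerical choices

The packaged checks use 50–100 simulation seeds for spike-in recovery and
noisy focus counting, 200–500 random tables for the brute-force oracle
comparison, and 10,000 draws for the 2-SD classification check — sizes at
which the binomial/normal sampling bounds used in the assertions are tight
while a full run stays interactive on a laptop. Report writers format
doubles with 17 significant digits and re-parse with correctly rounded
`strtod`, so write → read → write cycles are byte-identical. Ranking and
tabulation are fully ordered (explicit tie-breaks, first-appearance
genotype order) so all outputs are stable across platforms.

## Interfaces

The package is a tidyverse-native library: every reader returns tibbles,
results chain with the pipe, fitted/derived objects provide `tidy()`,
`glance()` and `autoplot()` methods, and `run_demo()` provides the
end-to-end orchestration (simulate → analyse → verify → manifest) that a
shell wrapper would otherwise supply. Configuration files are YAML
(`read_pipeline_config()`), with function arguments taking precedence in
code. Delimited text (CSV/TSV, wide or long peptide layout, configurable
column map) is the supported exchange format for protein tables.

## Known limitations

* No statistical interaction scoring (SAINT/CompPASS-style models) and no
  protein grouping/parsimony inference; the filter is rule-based by design.
* Focus calling is 2-D on the MIP; overlapping foci in z merge.
* Blacklist matching is exact-accession; isoforms of a control contaminant
  with distinct accessions are not collapsed.
* The 2-SD classification assumes approximately normal control areas, as
  its analytic expectation does.
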