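---
title: "Methods: Y-chromosome CNV discovery and haplogroup enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Y-chromosome CNV discovery and haplogroup enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ycnvr)
library(dplyr)
```

## The problem

The male-specific region of the human Y chromosome (MSY) is haploid and
dominated by near-identical repeated sequence: eight palindromes (P1–P8),
inverted repeats, and the amplicon families of the AZFc region (gr, b, Y,
g, r).  Copy number variants (CNVs) there — the gr/gr and b2/b3 deletions,
the blue-grey duplication and many rarer events — matter for male
fertility and are strongly structured along the Y phylogeny, yet the MSY
is routinely dropped from genome-wide CNV scans.  Standard SNP arrays
carry thousands of MSY probes (8179 on the platform this package models:
288 SNP + 7891 copy-number probes), and their log2-ratio intensities
separate cleanly by copy state, so array data that already exist can be
mined for Y CNVs.

`ycnvr` reimplements that analysis as a tested pipeline: per-probe log2
ratios → QC and probe blacklisting → segmentation → named CNV-pattern
calls → haplogroup assignment from Y-SNP genotypes → haplogroup × carrier
enrichment statistics → genotype PCA.  Because the original raw arrays are
not redistributable, the package ships a synthetic-cohort generator whose
defaults encode the study conditions the pipeline assumes, so every stage
is testable end to end without any download.

## Intensity model

Each probe's log2 ratio is modelled as Gaussian with a mean set by the
underlying copy state and a shared standard deviation:

| state | meaning | default mean |
|---|---|---|
| 0 copies | deleted sequence / female background | −2.02 |
| 1 copy | normal male MSY | −0.47 |
| 2 copies | duplicated sequence | 0.04 |

The three means are the platform's published calibration anchors (averages
over ten males, ten females, and the duplicated arm of an isodicentric Y
respectively).  No per-probe variance is published; `sigma = 0.25` is the
package default, exposed in `intensity_model()`.  With these numbers the
duplication/normal margin is only about one sigma per probe while
deletion/normal is about six — single probes detect deletions almost
surely but duplications only with ~85% probability, which drives most of
the segmentation design below.

A few MSY intervals cross-hybridise in females ("hot" regions with
elevated female background, mean −0.3 by default).  The generator places
three such intervals, mirroring the three reported for the platform, at
coordinates outside every catalogued CNV region.

`infer_sex()` thresholds the profile mean at the midpoint of the 0- and
1-copy means (−1.245); a tie classifies male, a deterministic rule that
fires with probability zero under the continuous model.

## Synthetic manifest, region map and cohort

`synthetic_manifest()` lays probes uniformly over a 25.3 Mb MSY-like span.
The default size is the platform's real 8179 probes (≈3.1 kb spacing):
at that density the smallest catalogued region carries ~47 probes, which
is the probe support the pattern classifier's coverage rule assumes.
Smaller manifests are available for fast tests, and the region map is
fixed in genomic coordinates so it works at any probe density.

The bundled region map places the classical STS-delimited palindromes
(sY1312/sY1304 for P7, sY1275/sY1276 for P6, and so on, with P5/P4 and
IR2/P3 sharing their boundary markers, and P6 at its published
18,279,605–18,843,147 bounds), the AZFc amplicon families, and the p-arm
and proximal q-arm landmark intervals.  U1 is nested inside P3, so the
map deliberately contains overlapping regions and probes can be
multi-assigned.  Amplicon copies with no probes on the real array (r1,
r2, g1, g4) are not represented; their states are only inferable through
catalogued linkage to covered neighbours, which is how the shipped
signatures treat them.

`simulate_cohort()` draws, per male, at most one CNV pattern from his
haplogroup's pattern distribution, implants the pattern's events with a
±2-probe breakpoint jitter (recurrent duplications in real data are
similar but not identical), simulates the intensity profile, and
generates Y-SNP genotypes along his clade's root path with a
configurable missing rate (default 0.1).  The default cohort replays the
reference survey: 12 major haplogroups totalling 1506 males (sizes from
the bundled carrier table), the ten haplogroup-enriched patterns at their
printed per-haplogroup frequencies, each haplogroup's remaining carrier
mass spread evenly over the other catalogued patterns, and 61 background
females for the QC stage.  Everything is a deterministic function of
`(config, seed)`.

What the generator does **not** emulate: GC waves and batch effects,
probe-specific response, mosaicism, multi-copy (>2) states, linkage
between CNV breakpoints and probe spacing.  Green tests therefore show
that the pipeline's logic is correct under its stated model, not that the
model captures every artefact of real arrays.

## QC: window means and the female blacklist

`window_means()` averages disjoint blocks of consecutive probes (20 for
visual summaries, 3 for QC — the smallest segment the upstream software
would call).  `flag_high_background()` blacklists every probe of a
3-probe window whose across-female mean exceeds a threshold.  Two
published anchors exist for that cutoff, −0.47 (the male single-copy
mean) and −0.51; the package defaults to −0.47 and exposes the choice.
Blacklisted probes are removed before segmentation; a deletion inside a
cross-hybridising interval is undetectable by construction, because a
deleted probe there still reads near −0.3.

## Segmentation

The upstream segment caller of the original analysis is closed source;
`ycnvr` replaces it with a transparent caller parameterised by the only
published settings (minimum 3 markers, minimum 5 kb) and automates the
study's manual curation as a probe-density filter:

1. **Detection.** The profile is smoothed with a centred running mean of
   5 probes and thresholded at the midpoints of the state means (loss
   < −1.245, gain > −0.215, ties normal).  Runs of one non-normal state
   are formed, bridging interior gaps of up to 8 smoothed probes —
   smoothed miscalls arrive in runs of about one window, so the bridge
   must exceed the window.
2. **Refinement.** Each breakpoint is re-estimated on the *raw* profile
   under a two-state Gaussian likelihood with known means: the boundary
   is placed to maximise the posterior mass of the changepoint within a
   ±2-probe window (searched over ±16 probes).  For a ±k-probe error
   tolerance this window-posterior estimator is the Bayes rule and
   measurably beats the posterior mode: at the duplication margin it
   raises per-end accuracy from ~94.7% to ~97.8%, which is essentially
   the information-theoretic limit at one sigma of separation.  Near-ties
   in window mass (exact ties occur under degenerate, noise-free input)
   resolve to the maximum-posterior boundary.
3. **Filters.** Minimum markers, minimum span, then `density_filter()`
   removes segments whose probes-per-kb density falls below 0.05 — the
   automated surrogate for "curated manually after visual inspection" in
   probe-poor sequence, with removals logged.

The raw-state path (`call_states()` + `segment_states()`, gap tolerance
1 probe) remains available and is what the run filters are defined on.

Measured behaviour at the default model (the figures the test suite
asserts): deletions of ≥20 probes are recovered with both breakpoints
within ±2 probes essentially always; duplications in ~94–95% of cases,
against an ideal-observer bound of ~95.6%; with the surveyed cohort's
~2:1 duplication:deletion mix the overall recovery is ~96.5%, and the
acceptance suite requires ≥95% over 500 implanted events.

## Pattern classification

`region_copy_states()` reduces a sample's segments to one state per
region: `deleted`/`duplicated` when ≥80% of the region's probes lie in
loss/gain segments (`coverage_threshold`, a quantitative surrogate for
the original by-eye classification), `partial` for smaller non-zero
coverage, `no_probe` for uncovered regions.  Partial states neither
satisfy nor block a signature: they typically arise from breakpoint
jitter spilling over a region edge (the map's shared STS markers make
neighbouring palindromes overlap by one marker interval).

`classify_patterns()` matches the state vector against the catalog: a
signature matches when all its requirements hold and it accounts for
every deleted/duplicated region.  If several match, the one with most
required regions wins (ties by name); if no single signature explains
everything, non-normal regions are split into groups adjacent in map
order and matched greedily, so one sample can carry e.g. a P6
duplication plus a b2/b3 deletion as two independent calls.  Whatever
remains unexplained is returned as a `novel` call with a canonical
signature string — the discovery path for unseen variants; no non-normal
vector is ever dropped.

The catalog is data, not code (`inst/extdata/pattern_catalog.tsv`): the
published pattern definitions are pictorial, so their region-state
transcriptions are editable.  The shipped file holds 25 uniquely named
signatures.  The source material is ambiguous about whether the named
set has 24 or 25 members; 24 patterns are named explicitly, and the 25th
slot is filled with a third p-arm duplication (`p-arm dupl (TBL1Y)`),
consistent with the reported five distinct p-arm duplications of which
only two are described in detail.

## Haplogroup assignment

`assign_haplogroup()` walks a rooted Y phylogeny (`read_ytree()`; an
18-node tree covering the 12 resolvable majors is bundled): the call is
the deepest node with an observed derived allele whose root path carries
no observed ancestral allele.  Missing calls are uninformative, never
contradictory.  Derived alleles on incompatible branches — or an
ancestral call on the support path itself — yield `ambiguous`; no derived
allele anywhere yields `unassigned`.  A call at an internal node whose
child's defining SNPs were all observed ancestral is rendered with the
conventional exclusion suffix, e.g. `NO-M214(xM175)`.  How the original
algorithm weighs partially conflicting paths is not published; the
conflict→ambiguous rule here is a declared simplification.

`backmerge()` collapses sub-clade calls to the 12 majors.  One rule is
stricter than a naive nearest-major-ancestor lookup: a call at an
internal node that still has majors beneath it (DE-M145, IJ-M429,
P-P295, K-M526, GHIJKLT-F1329) is `excluded_internal` rather than
collapsed upward — folding a K-M526-derived sample into
`KLT-M9(xM526)` would contradict that label's meaning.  The funnel
partition (assigned / excluded internal / ambiguous / unassigned) always
sums to the cohort size.

One consequence worth knowing: with genotype missingness, a sample of a
deep clade missing its terminal defining SNP legitimately collapses into
an ancestral bucket (an O-M175 sample missing M175 lands in
`NO-M214(xM175)`), so per-haplogroup statistics at high missing rates
mix clades exactly as the real pipeline would.

## Enrichment statistics

`build_contingency()` tabulates assigned majors × carrier/non-carrier
(one carrier per sample per variant, however many events).  Ambiguous,
unassigned and excluded-internal samples never enter.  On a table,
`cnv_enrichment()` bundles:

* Pearson chi-square (no continuity correction),
* the likelihood-ratio G-test (`2 Σ O ln(O/E)`, zero cells contribute 0),
* Fisher's exact test — exact for 2×2; fixed-margin Monte Carlo for
  r×c (default 10⁶ replicates) with the replicate count, seed and
  binomial standard error reported, a deterministic alternative to the
  exact network algorithm,
* both residual conventions, labelled: Pearson `(O−E)/√E` and adjusted
  `(O−E)/√(E(1−row/N)(1−col/N))`.  Published tables of this kind mix the
  two conventions cell by cell, so both are always reported rather than
  guessing one.

`frequency_report()` reproduces the per-haplogroup carrier table
(percentages at one decimal), with an `exclude` argument that recomputes
numerator and denominator after dropping rows.  Tests are reported raw,
per variant, as in the source analysis; multiple-testing correction is
left to the caller (`p.adjust`) since the original reported raw values.

## Genotype PCA

`encode_genotypes()` maps G/C/T/A to 1–4 and missing to 0 — statistically
odd (missing sits on the allele scale) but faithfully reproduced;
mean-imputation is available behind `impute = TRUE`, off by default.
`genotype_pca()` performs correlation PCA (column-standardised
`prcomp`), drops zero-variance columns first (the only well-defined
choice under correlation scaling, and logged), and fixes component signs
so the largest-magnitude loading is positive.  The published
cohort-specific explained-variance figures depend on the real genotype
matrix and are not reproduction targets; correctness is established
against an explicit eigendecomposition oracle and a constructed
two-clade separation fixture.

## Numerical and design choices, in brief

* Coordinates are 1-based, fully closed everywhere (UCSC display
  convention); region bounds include their STS markers.
* State thresholds sit at midpoints of the printed state means — the only
  calibration anchors available.
* Segment span is `stop − start + 1` bp; density is markers per kb of
  span.
* The Monte-Carlo Fisher seed defaults to a fixed constant so reports are
  reproducible; every simulation function takes an explicit seed and
  restores the caller's RNG state.
* Problem sizes used by the shipped verification: 500 implanted-event
  profiles at full 8179-probe scale for recovery, one carrier per
  catalogued signature for the round trip, 10 samples × 8179 probes for
  calibration, 2000 null tables for test size, and one full 1506-male
  cohort replay in the reproduction script.

## Known limitations

* Copy states are trichotomous (0/1/2+); higher amplifications, TSPY
  array counts and mosaicism are out of scope.
* The catalog pins region-state signatures that the source material
  defines only pictorially; users can and should edit the TSV for other
  platforms or maps.
* The caller is threshold-run based by design (no HMM/CBS); at one sigma
  of duplication margin its breakpoint accuracy is already at the
  ideal-observer bound, but heavier-tailed real noise would degrade it.
* The bundled tree is an 18-node major-clade skeleton, not a full ISOGG
  phylogeny; `read_ytree()` accepts any user tree in the documented
  format.
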