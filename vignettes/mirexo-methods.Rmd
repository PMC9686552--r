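---
title: "mirexo: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirexo: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`mirexo` profiles miRNAs from milk-exosome small RNA sequencing and calls
differential expression between two groups of animals. This vignette is
the package's own account of the science it implements: the procedures and
their assumptions, the tunable parameters with their defaults and units,
what the synthetic-data generators do and do not emulate, and where the
design was genuinely open, what was decided and why. It states no
empirical result that the test suite and acceptance script do not
themselves compute.

## 1. Read cleaning into "valid data"

Small RNA libraries sequenced 1 × 50 bp read through the insert into the
3′ adapter, so adapter removal is what reveals the 18–26 nt tag. The
trimmer cuts at the **leftmost** position where a prefix of the adapter
aligns with at least `min_overlap = 8` matching positions and at most one
mismatch; the adapter must match through to the end of the read (or in
full), as in standard trimmers. A match at position zero means the insert
was empty — an adapter dimer — and the read is dropped as its own
category, not an error. Reads with no match are kept whole; quality-based
trimming is deliberately absent since the method this package follows
never uses base qualities.

Junk rules then remove low-complexity inserts, in a fixed precedence
order so that the reported rule id is deterministic: (a) length < 18 nt;
(b) any single base ≥ 80 % of the insert (ties reject; N counts in the
denominator); (c) three or more N, not necessarily contiguous; (d) only
A/C; (e) only G/T; (f) a perfect dinucleotide repeat covering the whole
insert (trailing partial unit allowed); (g) the same with a trinucleotide
unit. An AC-repeat such as `ACACAC…` satisfies both (d) and (f); under the
fixed precedence it reports (d). The "3N" rule is read as a count
threshold — a positional reading would make its "not necessarily
continuous" qualifier meaningless.

Surviving reads are collapsed into unique tags with per-sample copy
numbers — the pipeline's unit of quantification — and screened against a
contaminant reference whose records carry a class label (rRNA, tRNA,
snRNA, snoRNA, repeat, mRNA). A tag is a contaminant if it matches any
record full-length, ungapped, with at most one substitution, on either
strand. When several classes match, the reported class follows the fixed
priority rRNA > tRNA > snRNA > snoRNA > repeat > mRNA, so record order
never matters. Tags longer than 26 nt are excluded from identification but
retained in the accounting, which conserves reads exactly: per sample,
`raw = valid + Σ removed`.

## 2. Identification categories

Identification is sequential, and the sequence fixes the category
priority: specific-species precursors first, then other-species
precursors, then the genome.

* **known mature** — the tag aligns ungapped inside a precursor with ≤ 1
  substitution, overlaps an annotated mature, and both end shifts are
  within `max_end_shift = 4` nt. The allowance is substitution-only (no
  indels), and 4 nt spans observed isomiR end variation without letting a
  tag wander onto the wrong arm. BLAST of the original method is replaced
  by exact/1-substitution window scanning: at 18–26 nt, word-based seeding
  finds the same ungapped hits, and the scan is checked against an
  exhaustive oracle in the tests.
* **novel arm (5p/3p)** — the tag does not overlap the annotated mature
  and ≥ 80 % of it lies on the opposite side of the precursor midpoint.
  The midpoint stands in for the (unfolded) terminal loop; a tag
  straddling it counts toward neither arm.
* **known, other species** — leftover tags matched to other-species
  precursors are kept only when the *precursor* occurs exactly in the
  study genome. Whether the original method required the mature or the
  precursor to match is unstated; requiring the precursor is the stricter
  reading and is flagged as an interpretation.
* **novel candidate** — tags with exact genome hits proceed to structure
  screening. For each hit two windows are folded, `[start − 80, end)` and
  `[start, end + 80)`; folding both is the default because the method
  names "the flanking 80 nt sequences" without fixing a side.

## 3. Hairpin screening

Folding has three backends: an adapter for an external folding engine is
out of scope here, so the working backends are a **built-in
maximum-pairing dynamic program** (minimum hairpin loop 3, G·U wobble
counted as a pair, crude stacking energies of −3/−2/−1 kcal/mol for
GC/AU/GU) whose energies are labelled approximate, and a **file backend**
that passes through Vienna-style dot-bracket records — the test-suite
default, and the bypass for precomputed structures. The built-in fold is
verified against exhaustive maximum-pairing enumeration for sequences up
to 18 nt; its role is screening, not thermodynamics.

A candidate window must decompose into a *single* hairpin (exactly one
terminal loop); multi-branched structures are rejected outright. The
eleven criteria are then evaluated with observed values reported alongside
thresholds: (1) every interior loop/bulge ≤ 12 nt total; (2) ≥ 16 stem
pairs; (3) energy ≤ −15 kcal/mol; (4) hairpin span ≥ 50 nt; (5) terminal
loop ≤ 20 nt; (6) largest single one-sided bulge inside the mature region
≤ 8 nt; (7) side asymmetry of two-sided interior loops touching the
mature ≤ 4; (8) ≤ 2 one-sided bulges in the mature; (9) ≤ 7 mature
positions in mismatch-type (two-sided) loops; (10) ≥ 12 paired mature
positions; (11) ≥ 80 % of mature positions inside the stem (within the
span, outside the terminal loop).

Criteria 6–9 are reconstructions of tersely worded rules, and two
disambiguations were forced by internal consistency. First, "biased
errors" (criterion 7) is taken as the side asymmetry of *two-sided*
interior loops: a bulge is maximally asymmetric by definition and is
already counted by criterion 8, and including bulges in 7 would make any
bulge > 8 nt fail criteria 6 and 7 inseparably. Second, "errors"
(criterion 9) counts mature positions in mismatch-type loops rather than
all unpaired positions; otherwise no structure could fail criterion 6
alone, since > 8 bulge nucleotides would always exceed a ≤ 7 unpaired
bound. With these readings each criterion is independently falsifiable,
which the acceptance fixture suite demonstrates constructively (one
fixture failing exactly each criterion). Total mature unpairedness is
still bounded through criterion 10. All four reconstructions sit behind
named fields in the report so alternatives can be swapped.

A tag is an accepted novel miRNA iff at least one window passes all
eleven; the passing window with the lowest energy is reported.

## 4. Median-reference regression normalization

The normalization assumes most tags are not differentially expressed, so
each sample should sit on the identity line against a cross-sample
reference. The common set is tags with ≥ 1 copy in every sample
(`min_common_copy`, configurable); the reference is the per-tag median
across samples (even counts: mean of the middle two), on log2. Per
sample, tags with `|Δlog2| < 2` — under 4-fold change from the reference —
form the regression subset; ordinary least squares gives `(a, b)`; the
line is evaluated at `x_mid = (max + min)/2` of the subset's reference
values, and `f = 2^(x_mid − y_mid)` multiplies the sample's raw copies.

Open points decided here: the midpoint formula in the source text is
typographically garbled and is implemented as the midpoint of the range
(the half-range variant is available behind a switch); the procedure is
applied once, not iterated; no pseudo-counts are added, zeros simply fall
outside the common set. One numerical subtlety: the correction exactly
centres the fitted line, so refitting a corrected sample **over the same
subset** returns Δy = 0 to machine precision — but re-running subset
selection on corrected data can admit different tags and drift by a few
hundredths. `fit_sample()` therefore accepts a fixed subset, and the
self-consistency test uses it.

## 5. Differential expression

Group means of norm values give `log2FC = log2((mean_A + ε)/(mean_B +
ε))` with ε = 1 (configurable); ε keeps zeros finite and barely perturbs
the scale of typical copy numbers. The test is a two-sided pooled-variance
Student t-test on `log2(value + ε)` — the log transform stabilizes the
roughly multiplicative noise — with a normal-reference z variant available
for comparison. Degenerate rows (zero variance in both groups) return
p = 1 when equal and p = 0 with a flag when not. The DEM gate is exactly
`|log2FC| ≥ 1` (inclusive) and `p < 0.05` (strict); BH FDR is computed
and exported but does not gate, matching the thresholding convention of
the method reproduced. Whether fold change should use means of norm
values or per-sample logs was unstated; means-of-norm-values was chosen
and recorded in the output metadata.

At n = 3 per group the t-test has 4 degrees of freedom; the calibration
and power checks in the acceptance suite (type-I fraction 0.05 ± 0.01 on
10,000 null miRNAs; sensitivity ≥ 0.95 and false-discovery proportion
≤ 0.10 for planted 4-fold changes at log2-sd 0.2) are exactly the regime
the synthetic generator plants.

## 6. Targets and enrichment

Full context scoring and alignment scoring of the external target
predictors are out of scope; what matters to the reproduced method is the
**dual-threshold intersection**: a prediction survives only if both
channels pass, score ≥ 50 (inclusive) and energy < −10 (strict), exactly
as printed. The stand-in scorer is transparent and documented: seed sites
(8mer / 7mer-m8 / 7mer-A1 / 6mer by the standard position-2–8 rules) get
type points 45/35/25/15, plus 40 × AU fraction of the 30-nt flanks, plus
3 per 3′-supplementary pair (miRNA positions 13–17), capped at 100; the
energy channel sums −3/−2 per seed and half-weighted supplementary pair.
The score-≥-50 threshold could alternatively mean a percentile rank; the
0–100 score reading is flagged as an interpretation.

Enrichment is the upper-tail hypergeometric test per term, with BH
adjustment within each namespace (GO:BP/GO:MF/GO:CC/KEGG), terms with no
study hits omitted, and ties in the top-20 report broken by term id for
determinism. Annotations are user-supplied; no GO-graph propagation is
performed. The background defaults to all genes in the annotation table
but the pipeline passes the full UTR gene set explicitly, since genes
without annotations still belong to the population.

## 7. Milk-quality comparisons

Trait tables arrive as mean ± SD with n (the ± values are treated as SD,
the convention for such tables, configurable) or as raw long format. Both
the pooled-variance Student test (df = n₁ + n₂ − 2, the default) and
Welch's test are provided because standard statistical software reports
both. Printed p-values in the source tables are not generally recoverable
from their rounded summaries, so validation is against an independent
t-test implementation on raw data, never against printed values.

## 8. The synthetic world

The generators emulate the study's stated conditions: 1 × 50 bp
single-end reads; six samples in two groups of three animals; ~22-nt
matures on stem-loop precursors (25-bp stem, 8-nt loop, two planted stem
asymmetries); read composition 70 % known-miRNA, 5 % novel-locus, 10 %
contaminant, 10 % junk, 5 % adapter dimer; end variation ±2 nt and a 10 %
single-substitution rate; planted expression differences of 4-fold
(half up, half down) over lognormal baselines (log2 sd 1 across miRNAs,
replicate noise log2-sd 0.2). Count matrices are continuous lognormal
values because the normalization-and-test stage operates on corrected
"norm values", not raw integer counts.

Two constructional details matter. The planted stem asymmetries sit in
the arm opposite the mature: with a perfect stem the mature's reverse
complement would reoccur verbatim on the other arm, so "the planted locus
occurs exactly once in the genome" could never hold. And the planted
mature begins at hairpin position 0 so that the downstream 80-nt window
contains the entire stem-loop. Generated sequences are vetted so planted
categories are mutually exclusive: mature-derived variants are never junk
(composition margins wide enough that one substitution cannot create a
junk call), never within one substitution of a contaminant window, and
never within one substitution of the adapter prefix.

What the generator does **not** emulate: position-dependent sequencing
error, quality-score variation (qualities are constant), expression-
dependent capture bias, multi-isoform precursors, and genuine genomic
repeat structure. A green test therefore establishes that the algorithms
implement their contracts and recover planted truth under the stated
noise — not that the pipeline is robust to every artefact of real
libraries.

## 9. Determinism and numerical choices

Every generator seeds R's RNG through a derived stream-specific seed
(kept below 2³¹); the pipeline itself is RNG-free, writes floats at six
significant digits, and its reruns are byte-identical — stage manifests
record input hashes and parameters, and unchanged stages are skipped on
resume. Ties and orderings are fixed everywhere a hash-order ambiguity
could leak (tag tables by total copies then sequence, enrichment by p
then term id, junk rules by precedence). Known limitations: the built-in
fold maximizes pairings rather than free energy, so its energies are
advisory (criterion 3 is flagged approximate under that backend);
contaminant matching is window-exact rather than alignment-based; and
multi-mapping tags are assigned a single primary category by the
documented priority rather than fractionally.
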