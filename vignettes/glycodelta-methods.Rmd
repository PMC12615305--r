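---
title: "Methods: comparative N-glycoproteomics with glycodelta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative N-glycoproteomics with glycodelta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycodelta)
```

## Scope and data model

glycodelta analyzes *downstream* glycoproteomics data: it starts from
glycopeptide and protein quantification tables as produced by a search
engine, never from spectra. The atomic feature is the glycopeptide —
a distinct (protein accession, glycosite, peptide sequence, glycan
composition) tuple; the count hierarchy glycopeptides ≥ glycosites
(accession, site) ≥ glycoproteins (accession) is maintained everywhere.
Missed-cleavage variants of the same site are deliberately distinct
glycopeptides, while site identity ignores the peptide.

Glycan compositions are the four monosaccharide counts `N#H#F#S#`
(HexNAc, hexose, fucose, NeuAc). Composition is all the package ever
interprets; linkage and topology (e.g. hybrid-versus-complex branching, or
LacdiNAc isomers) are out of scope, which is why complex and hybrid
glycans form one class.

## Quantification model

**Channel normalization.** Each TMT channel of a batch is scaled so its
total intensity equals the *median* channel total of that batch. Median
rather than mean keeps one aberrant channel from dragging the target; the
choice is configurable (`target = "mean"`). This assumes the bulk of the
glycoproteome is not changing — the usual total-intensity normalization
assumption — and it removes per-channel loading and labeling-efficiency
differences.

**Reference ratioing.** In multi-batch designs each batch carries a pooled
reference channel (equal parts of all samples). Ratios
`log2(sample/reference)` are formed per feature within the batch; the
reference column, identically zero after ratioing, is dropped. A feature
whose reference intensity is missing or zero gets missing ratios for the
whole batch: substituting a pseudo-reference would be imputation, and the
pipeline's contract is that **no value is ever imputed**. Zero intensities
are treated as non-detection (missing) before any log transform.

Because normalization and ratioing together cancel any global per-batch
scale factor, the final matrix is invariant to multiplying all channels of
a batch by a constant — this is tested as a property.

**Integration and filtering.** Batches are joined on the union of
features; absence in a batch is missingness for that batch's samples. The
missingness filter retains features quantified in at least 50% of
non-reference samples (inclusive: 5/10 passes), and protein tables
additionally require ≥ 2 unique peptides. The filter only drops rows, so
it is idempotent.

**PCA.** Sample-space PCA uses complete-case features only (no
imputation), column-centered and unscaled — log2 ratios already share a
scale, so unit-variance scaling would up-weight noisy features. With
heavy missingness the complete-case set can be small; the error message
then points at the filter.

## Differential classification

Per-feature statistics are geometric fold changes `2^(mean_a − mean_b)`
of log2 ratios and two-sided Student's t-tests (pooled variance). The
unpaired test is the default, matching the generic "Student's t-test"
convention in tissue-proteomics reports; `paired = TRUE` is available
because the designs are in fact paired, and the generator induces a shared
per-pair effect precisely so the two options differ meaningfully.
Degenerate zero-variance features resolve to p = 1 when the groups are
identical and p = 0 when they are separated constants. Features with
fewer than two values in a group are excluded with a reason code rather
than tested. BH-FDR is computed and reported but the calls use raw p
thresholds — the convention for these fold-change-gated screens — and
this too is a visible, configurable choice rather than silent behavior.

The protein-corrected decision tree distinguishes glycosylation changes
from protein-abundance changes. Writing FC for linear fold change and
using thresholds up > 1.5, down < 0.67, α = 0.05 (strict inequalities):

* up gate (`FC_g > 1.5, p_g < α`):
  * **A_direct_up** if the protein is not significantly changed, not
    quantified, or rose less than the glycopeptide;
  * **D_occupancy_down** if the protein is significantly up and rose
    *more* — the glycoform lagged its protein, a relative occupancy
    decrease, labeled down;
* down gate (`FC_g < 0.67, p_g < α`): mirrored **C_direct_down** and
  **B_occupancy_up**.

Three edge policies deserve note. (1) Glycopeptides whose protein is not
in the filtered proteome are classified on their own fold change alone
(`not_quantified` behaves like "no significant protein change"): in
glycoproteomics most glycoproteins are absent from the global proteome, so
discarding them would silence most of the glycoproteome. (2) The
occupancy branches require the protein itself to be *significant* by
default: reading a noisy, non-significant protein wobble as "the protein
rose even more" would manufacture occupancy calls from noise. The
opposite reading is available (`occupancy_requires_protein_sig = FALSE`),
in which case the fold-change comparison outranks the protein-significance
clause. (3) Exact fold-change ties between glycopeptide and protein
satisfy neither comparison and fall to unchanged when the protein is
significant. Mutual exclusivity of the branches is verified by
enumeration against an independently coded rule oracle.

Single-batch cell-line screens (e.g. enzyme knockdowns) use channel-total
normalization plus log2 (no reference) and a relaxed down cutoff of 0.8
(`use_fc_down_alt = TRUE`), reflecting the smaller dynamic range of
five-replicate cell-line comparisons.

## Glycan typing and landscape statistics

The five-class partition is composition-only with terminal-decoration
precedence: any fucose and any NeuAc → fucosylated–sialylated; NeuAc
alone → sialylated; fucose alone → fucosylated; HexNAc2 with ≥ 5 hexoses
→ high-mannose; everything else → complex/hybrid. The precedence is
forced by the convention of typing branched sialo-glycans such as
`N4H5F0S2` by their terminal feature. The high-mannose floor of five
hexoses (Man5) is a genuine boundary choice — paucimannose (`N2H3`,
`N2H4`) is typed complex/hybrid — and is configurable via
`mannose_min_hex`. The partition is exhaustive and exclusive over the
whole count grid `[0, 20]^4`, tested by full enumeration.

Sequon motifs (N-X-S/T/C, X ≠ Pro) are read at the +2 residue from the
peptide; when the sequon extends past the peptide's C terminus the
flanking protein context may be supplied, otherwise the site is excluded
from motif denominators (not counted as invalid). Microheterogeneity
summaries (glycans per site, type co-occurrence subsets per site,
glycoform diversity per protein), cohort set algebra at the site-specific
and unique-composition levels, and deterministic top-N glycan rankings
(ties broken lexicographically on the canonical string) complete the
landscape stage. Cohort deduplication of "unique compositions" is joint
across conditions within a cohort.

## Immune association

ssGSEA is implemented directly (the per-sample running-sum statistic):
genes are ranked by decreasing expression per sample, the score is the sum
over the ranked list of the difference between the weighted in-set ECDF
(weights `|value|^0.25`) and the unweighted out-set ECDF, normalized by
the running sum's amplitude. Missing values are dropped per sample before
ranking. Exponent 0.25 and amplitude normalization follow the widely used
single-sample formulation; with exponent 0 the score is rank-only and
provably invariant to monotone transforms (tested). The implementation is
checked to 1e-9 against a brute-force oracle on a small instance.

Enrichment scores can be negative, so a "≥ 1.25-fold difference" is
undefined on the raw scale; scores are shifted per signature so their
minimum is 1 before folds are computed, which makes calls invariant to
adding a constant to a signature's scores. This is a pragmatic
operationalization — a difference-based effect size would be an equally
defensible alternative — and the shifted scale is only used for the gate,
never reported as the score. Composite StromaScore (fibroblasts +
endothelial cells by default) and MicroenvironmentScore (all signatures)
are plain means; membership is configurable since signature panels vary.

Spearman screens use mid-rank ties on pairwise-complete observations
(n ≥ 5) with t-approximation p-values. The default retention is
one-sided (ρ > 0.6) as used for enzyme–glycopeptide screens;
`use_abs = TRUE` serves analyses where negative associations matter
(enzyme–immune correlations). Over-representation is upper-tail
hypergeometric against a user-supplied annotation and universe, BH
corrected; no pathway database is bundled or fetched.

## The synthetic generator

`simulate_glyco_study()` emulates the targeted study design and is the
package's source of ground truth. Its defaults *are* the study
conditions and were fixed once:

* 10 tumor/NAT pairs in 3 TMT-10plex batches, pairs dealt round-robin,
  one pooled reference channel per batch (linear mean of the batch's
  members, small labeling noise of 0.05 log2 units);
* log2 intensity model: baseline N(20, 2) per feature, per-pair biological
  effect N(0, 0.3) shared by the pair's tumor and NAT, per-batch feature
  shift N(0, 0.2), measurement noise N(0, 0.4), condition effects added in
  tumor samples;
* effects: |log2FC| = 1 on 3% of glycopeptides in each direction with flat
  proteins (direct branches), and dedicated proteins shifted by ±2 whose
  glycopeptides move only ±1 (occupancy branches); 60% of the remaining
  glycoproteins appear in the protein table, emulating the partial
  proteome overlap typical of glycoproteomics;
* identification structure: sites per protein truncated-geometric with
  78% single-site proteins; glycoforms per site truncated-geometric
  (P(1) = 0.22, cap 12) giving substantial microheterogeneity; the glycan
  class mixture (34% mannose, 23% fucosylated, 17% sialylated, 15%
  fucosylated–sialylated, 11% complex/hybrid) and sequon mix
  (53.1/41.8/5.1% NXT/NXS/NXC) reflect the tumor-tissue landscape this
  package targets; compositions are drawn per class from realistic grids
  (mannose Man5–Man12, etc.) so typing round-trips exactly;
* missingness is intensity-dependent (logistic in log2 intensity centered
  at the 3rd percentile, scale 0.5): missing-not-at-random, as isobaric
  data behave;
* four immune signatures of 15 effect-free proteins each, three shifted
  down in tumor and one up, mimicking stromal/NK depletion with epithelial
  gain.

`landscape_design()` gives closed-form expected counts for validation;
the expectations ignore the rare event that a site draws more
compositions of one class than that class's grid holds, a sub-percent
deficit the generator tests allow for explicitly.

What the generator does **not** emulate: interference/ratio compression
of reporter ions, correlated glycoform families on a site, isotope
impurity, retention-time effects, or real signature biology. Passing
recovery tests therefore demonstrates that the statistical machinery is
correct under its stated model, not that the thresholds are optimal for
any particular real dataset.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately chosen
sizes: the recovery experiment uses 1,000 proteins (≈ 5,000–5,600
glycopeptides) at the design above, where classification sensitivity and
branch recovery sit near 0.98 and the false-call rate (truly unchanged
features called) near 0.002; the null calibration uses 10,000 features at
10-versus-10; combinatorial checks enumerate their full grids (the
194,481-composition partition, the 224-cell decision-tree grid). These
sizes make the checks statistically meaningful while keeping a full run in
well under a minute on one core.

Numerical conventions: fold-change cutoffs are strict inequalities; the
missingness threshold is inclusive; t statistics for zero-variance
features are defined by continuity (0 or ±∞); Spearman p-values use the
t approximation rather than exact permutation; ranking ties in top-N
tables break lexicographically so outputs are deterministic; all
simulation randomness flows from a single integer seed, and repeated runs
are byte-identical (tested via file checksums).

## Known limitations

* Composition-only typing cannot separate hybrid from complex glycans nor
  detect isomeric motifs; five classes is the resolution limit.
* The occupancy branches infer *relative* occupancy from fold-change
  comparisons; they are not a stoichiometry estimate and depend on the
  protein being quantified and significant.
* ssGSEA on proteome ratios inherits the identifier mapping of the input
  tables; no gene-identifier translation is attempted.
* Cross-cohort comparisons operate on the identification tables as given;
  differences in search engines or enrichment chemistry between cohorts
  are not modeled and such comparisons warrant caution.
* Tissue differential calls use raw p-value gates (with BH-FDR reported
  alongside); studies needing strict FDR control should filter on the
  reported `bh_fdr` column instead.
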