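---
title: "Methods: classifying and designing immunomodulatory RNA oligonucleotides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and designing immunomodulatory RNA oligonucleotides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imorn)
```

## The model and its assumptions

`imorn` treats the immunomodulatory potential of a short (17–27 nt)
single-stranded RNA as a two-class sequence classification problem. The
biological assumption is that recognition by the endosomal ssRNA sensors is
sequence-dependent, so the primary sequence carries enough signal to
separate immunomodulatory oligoribonucleotides (IMORNs, label +1) from
non-immunomodulatory ones (label −1). Chemical modifications of the backbone
or termini are outside the model: only the 4-letter sequence is used, and
DNA-form input is transparently converted (T→U) while IUPAC ambiguity codes
are rejected.

The classifier is a soft-margin SVM (`e1071`/libsvm) over one of nine
fixed-length encodings:

| encoding | features | content |
|---|---|---|
| MNC…PNC | 4, 16, 64, 256, 1024 | overlapping k-mer fractions, k = 1…5 |
| BIN5 / BIN3 | 68 | one-hot 17-nt window at the 5′ / 3′ end |
| BIN53 | 136 | both windows concatenated, 5′ block first |
| HYBRID | 200 | TNC (64) followed by BIN53 (136) |

Composition values are fractions summing to 1 (per-cent output is a
formatting option); the scale choice is absorbed by the SVM cost parameter
and fractions keep the normalization invariant simple. Feature order is
fixed lexicographically under A < C < G < U so that encodings are
reproducible across runs. The 3′ window keeps its native 5′→3′ orientation,
and for sequences shorter than 34 nt the two windows simply overlap — each
block is computed independently, so a 17-mer has identical 5′ and 3′
profiles. Prediction applies a fixed threshold (default 0) to the signed
decision score, with scores exactly at the threshold called positive; a
published operating point needs a stated tie rule, and ties-positive is the
conservative choice for a screening tool.

## Evaluation protocols

*Internal validation* is five-fold cross-validation, stratified by class
(fold sizes differ by at most one per class). Held-out predictions from the
five folds are pooled and one set of metrics is computed over the whole
dataset — this matches the convention of reporting overall performance on
the full train-test set rather than averaging per-fold metrics. Stratification
is the package's own choice; unstratified folding risks degenerate folds at
these class sizes.

*External validation* splits the data per class with
`round(0.8 · n)` records in the train-test side — nearest-integer rounding
is what maps 602 positives to 482 and 520 negatives to 416 — and evaluates a
model trained on the train-test side against the untouched remainder.

*The sampling protocol* repeats the split ten times (round *r* uses seed
`base_seed + r`), runs internal CV and external validation in each round,
and reports mean ± sd per metric. Sensitivity, specificity and accuracy are
percentages; MCC is computed from the confusion counts with the standard
convention that a zero factor in the denominator yields MCC = 0, which makes
the degenerate all-one-class predictions testable.

*Hyperparameter search* evaluates a grid ({linear, RBF} × C ∈ {0.1, 1, 10},
RBF γ ∈ {0.01, 0.1, 1} by default) by internal CV MCC, breaking ties by
accuracy and then grid order. The grid is deliberately small: on
composition features the classes here are close to linearly separable and
the search is a safeguard, not the contribution.

*Feature selection* is a filter: features are ranked by the absolute
pooled-variance two-sample t statistic between classes and the top *m* are
kept (ties broken by lower index, zero-variance features score ±∞ or 0
depending on whether the means differ). It is exposed through `m` so that
subset sizes of interest (e.g. 20 of 64 trinucleotides) are reproducible as
sizes; the ranking criterion itself is this package's documented choice.

## Composition statistics and position enrichment

`compare_composition()` uses per-sequence composition fractions as samples
and a classic pooled-variance two-sided t test per k-mer. Welch's correction
is not applied by default — the equal-variance form is the stated test — and
degenerate zero-variance-in-both-classes cells are defined to give p = 0
when the means differ and p = 1 when they agree, so extreme synthetic
fixtures behave predictably. No multiple-testing correction is applied by
default (raw per-k-mer tests are reported); Bonferroni is available via
`correction = "bonferroni"`.

The two-sample-logo style table aligns a fixed 17-nt terminal window
(sequence lengths vary, so a fixed-length view exists only at the termini)
and tests per-position, per-nucleotide occupancy indicators with the same
pooled t machinery at α = 0.05. A cell is *enriched* when the positive-class
frequency is higher and the test is significant, *depleted* in the opposite
case.

## Gapped motif mining

A gapped motif is an ordered list of literal blocks written
`AAA-AA-AA-A`. A `-` separates blocks by a *realized* gap of 1…G residues by
default (`gap_min = 0` lets blocks abut): listing `AAAAAA` and its gapped
variants as distinct motifs only makes sense if a gap is an actual
separation. Matching is existence of an in-order placement with all gap
lengths in bounds.

Discovery is level-wise: candidates grow by appending one literal to the
last block or opening a new single-literal block, and a candidate is pruned
as soon as its positive coverage drops below the support threshold —
coverage is anti-monotone under both growth operations, which also lets each
extension re-test only its parent's matching sequences. Search caps (6
blocks, 10 total literals by default) bound the enumeration; reported
motifs are re-verifiable by re-matching from scratch. Results are sorted by
positive coverage, then shorter text, then lexicographic text, making the
ranking a deterministic total order.

Default thresholds are 10% positive support and zero negative coverage
("exclusive" motifs), both exposed as arguments. One practical caveat
informs the recovery checks in this package: for permissive gapped patterns,
strict exclusivity is brittle, because even a background-only negative set
of a few hundred sequences contains occasional chance matches of a gapped
A-rich pattern. The planted-motif recovery analyses therefore allow a small
negative coverage (2% of the negative set), which keeps chance matches from
erasing genuinely discriminative motifs while still excluding anything
common in the negatives.

## Structure analysis

Structures are dot-bracket strings, validated by stack matching.
"Extended linear" is operationalized as *zero base pairs in the predicted
structure* — no energy criterion is layered on top, since none is stated for
the classification of interest. Loop counting counts hairpin loops only
(maximal unpaired runs whose immediate flanks pair with each other);
internal loops and bulges are excluded, consistent with stem-loop sequence
counts and loop counts being nearly equal in the length-binned summaries.
All coordinates are 1-based inclusive.

Folding backends are pluggable and never silently mixed: the external
RNAfold adapter (ViennaRNA) provides MFE structures with energies, and a
built-in Nussinov dynamic program provides a maximum-pairing approximation
for fully offline use. The Nussinov fold pairs {AU, UA, GC, CG, GU, UG},
enforces a minimum hairpin loop of 3 unpaired residues (the sterically
motivated standard), and uses a deterministic traceback (prefer leaving the
rightmost position unpaired on ties, then the smallest partner index), so
the same sequence always yields the same structure. Because it maximizes
pair count rather than minimizing free energy, it calls more structures
"stem-loop" than RNAfold does; class-level *comparisons* between positives
and negatives are meaningful under either backend, absolute linear fractions
are backend-dependent and labelled as such.

Bin percentages are rounded half-up to two decimals, the convention that
reproduces printed values such as 353/602 → 58.64% and 2/22 → 9.09%.

## The synthetic generator

`synthetic_spec()`/`generate_dataset()` emulate the statistical structure
that separates the two classes in curated data: A-rich positives versus
G-rich negatives (default: 0.2 probability mass moved from G to A and vice
versa, relative to uniform), lengths uniform on 17–27 nt (a length-weights
option mimics skewed length distributions for structure analyses), residues
i.i.d. within a class, and an optional gapped motif planted into a fraction
of positives by overwriting a random window with a random in-bounds
realization. `default_benchmark()` freezes one such dataset at the curated
corpus' class sizes (602/520) with the strongest curated motif
(`AAA-AA-AA-A`, G = 5) planted at rate 0.45, under the fixed seed 20678.

What the generator does **not** emulate: phylogenetic or family structure
among sequences (real negatives are miRNAs, which share biogenesis-driven
sequence features), position-dependent composition, duplicated or
near-duplicated records, and any linkage between sequence and measured
immunostimulatory strength. Consequently, passing recovery tests shows the
pipeline extracts planted class signal correctly — near-ceiling benchmark
accuracies characterise the benchmark's strong separation, not expected
performance on experimentally assembled corpora.

All generation is driven by R's default Mersenne-Twister PRNG under the
spec's seed, and library code saves and restores the caller's RNG state, so
results are reproducible and side-effect free.

## Numerical choices and degenerate inputs

- Composition vectors are validated to sum to 1 up to floating-point error;
  encodings of empty datasets return 0-row matrices with full width.
- Cross-class duplicate sequences in a labelled dataset are an error (their
  label is undefined), as are duplicate ids.
- `monte_carlo_split` refuses fractions that empty either side of either
  class; CV refuses classes smaller than the fold count.
- MCC with a zero denominator factor is 0; sensitivity/specificity with an
  empty class is `NA` rather than a silent 0.
- SVM features are not rescaled internally (`scale = FALSE`): compositions
  live in [0, 1] and binary profiles in {0, 1} already, and skipping libsvm's
  per-column scaling keeps constant columns harmless and scores
  deterministic.
- Analog enumeration, region scanning and library screening use documented
  deterministic orders (position then A<C<G<U; offset within window length;
  descending score with id tie-break).

## Problem sizes used in the checks

The bundled checks run at desk scale, chosen to exercise every code path
with comfortable statistical power: oracle suites use exhaustive
enumeration on bounded instances (motifs of ≤2 blocks and ≤4 literals,
folds of length ≤12, 1000 random confusion tables); recovery analyses use
the 602/520 benchmark for classification (five-fold CV and the full
10-round sampling protocol), 100+100 sequences for the label-permutation
null (20 permutations), and 200+200 uniform-background sequences with a
70% planting rate for motif recovery at 40% minimum support.

## Known limitations

- The SVM operating point is a fixed score threshold; no probability
  calibration is provided.
- The motif miner covers literal blocks with bounded gaps — no degenerate
  alphabets or position-specific constraints.
- The Nussinov backend is a maximum-pairing approximation; energy-level
  questions need the RNAfold backend.
- Silencing-efficacy prediction for siRNAs is out of scope; the duplex
  screen reserves an `efficacy` column and accepts a user-supplied scorer.
- The duplex immunotoxicity verdict (either strand predicted positive ⇒
  immunotoxic) is a deliberate worst-case aggregation of the per-strand
  predictions, since the strands are what the endosomal sensors encounter.
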