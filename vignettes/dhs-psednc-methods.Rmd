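---
title: "Methods: pseudo dinucleotide composition and SVM prediction of DNase I hypersensitive sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudo dinucleotide composition and SVM prediction of DNase I hypersensitive sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psedhs)
```

## The problem

DNase I hypersensitive sites (DHS) are nucleosome-depleted chromatin regions
that mark regulatory DNA — promoters, enhancers, insulators, silencers.
Because DHS show little primary-sequence conservation, classifying a bare DNA
fragment as DHS or non-DHS is a hard sequence-only problem. DHS sequences do,
however, differ in dinucleotide usage (they are enriched in CC, CG, GC and GG
steps) and in the local structural geometry those steps imply. This package
implements a classifier built on exactly that signal.

## The PseDNC descriptor

A sequence $R_1 R_2 \ldots R_L$ ($L \ge 2$, alphabet A/C/G/T) is mapped to a
vector of dimension $16 + \lambda$:

$$
d_u = \begin{cases}
\dfrac{f_u}{1 + w \sum_{j=1}^{\lambda} \theta_j} & 1 \le u \le 16,\\[2ex]
\dfrac{w\,\theta_{u-16}}{1 + w \sum_{j=1}^{\lambda} \theta_j} & 16 < u \le 16 + \lambda,
\end{cases}
$$

where $f_u$ are the 16 overlapping dinucleotide frequencies (counted over the
$L-1$ steps and normalized by $L-1$, so $\sum_u f_u = 1$), and the *tier
correlation factors*

$$
\theta_j = \frac{1}{L-1-j} \sum_{i=1}^{L-1-j}
  \Theta\!\left(R_iR_{i+1},\, R_{i+j}R_{i+j+1}\right),
\qquad j = 1, \ldots, \lambda
$$

average the structural dissimilarity of dinucleotides $j$ positions apart.
$\Theta(x, y)$ is the mean squared difference of the standardized structural
property values of $x$ and $y$ over the $\mu = 6$ properties (the type-I
pseudo-composition correlation). Every PseDNC vector is component-wise
non-negative and sums to 1; at $w = 0$ the first 16 components are exactly
the plain dinucleotide composition and the $\lambda$ tail components are 0.
Dinucleotide order in the vector is fixed lexicographic (AA, AC, ..., TT).

Two parameters shape the encoding:

* `w` (weight, dimensionless, in $[0,1]$; default 0.2) balances composition
  against sequence-order correlation mass.
* `lambda` (tier count, positive integer; default 6) sets how far along the
  sequence structural correlation is tracked; a sequence must satisfy
  $L \ge \lambda + 2$ so every tier has at least one summand. Larger `lambda`
  adds global order information but inflates dimension and invites
  overfitting.

The defaults are the operating point selected by cross-validated grid search
in the study this method follows (`w = 0.2`, `lambda = 6`, with SVM
`C = 512`, `gamma = 2^-7`).

## The structural-property table

Tier correlations are computed from six descriptors of dinucleotide-step
geometry: angular twist, tilt, roll (degrees) and translational shift, slide,
rise (Å). Each property row is z-scored across the 16 dinucleotides with the
population (divide-by-16) standard deviation before use, so all six
contribute on a common scale; standardization is idempotent and a
zero-variance property is rejected by name.

The table bundled at
`inst/extdata/dinucleotide_properties_synthetic.tsv` is a **synthetic
stand-in**: values constructed by the package authors to lie in the ranges
reported by crystallographic dinucleotide-step analyses, with
reverse-complement symmetry (tilt and shift change sign under reverse
complementation, the other four are invariant). It is *not* the measured
table of any published study. Because $\Theta$ uses only standardized
differences, every internal consistency property of the encoder (oracle
equivalence, normalization, reductions) is independent of which table is
used; to reproduce published numbers, supply the corresponding published
table via `read_property_table()` — the expected TSV dialect is documented
there, and trained-model archives record the table checksum so a model is
never silently applied with a different table.

## Redundancy filtering

Training sets are de-redundated by greedy incremental clustering: sequences
are visited longest-first (ties in input order); each joins the first
retained representative with pairwise identity at or above the threshold
(0.6 in the benchmark construction this mirrors), otherwise it founds a new
cluster. Positive and negative classes are clustered separately by default,
so signal is never deleted across classes.

Identity is defined as the matched bases of a maximal-match global alignment
(match 1, mismatch 0, gaps free) divided by the shorter length — equivalently
LCS length over the shorter length. A caveat follows from that definition:
for two *unrelated* random DNA sequences of similar length the expected
ratio is already around 0.65 (the four-letter Chvátal–Sankoff regime), above
a 0.6 threshold, so aggressive thresholds collapse even unrelated sequences.
Tools with banded alignments and word filters behave less aggressively. The
clustering contract (map completeness, self-mapping representatives, mutual
dissimilarity, idempotence, threshold monotonicity) is what this module
guarantees; bit-exact emulation of any particular tool's heuristics is out
of scope.

## SVM and joint parameter search

Classification uses the libsvm solver (via e1071) with the RBF kernel
$K(x, y) = \exp(-\gamma \lVert x - y \rVert^2)$. PseDNC components already
lie in $[0,1]$ and sum to 1, so no re-scaling is applied; classes are
unweighted. Decision values are oriented so positive favors DHS, and a
decision value of exactly 0 is resolved to the positive class (documented
tie-break).

`grid_search()` optimizes $(w, \lambda, C, \gamma)$ jointly: for each
$(w, \lambda)$ the dataset is encoded once, then every $(C, \gamma)$ is
scored by stratified k-fold (default 5) cross-validated accuracy with a
single seed-determined fold assignment shared across the whole grid. Default
grids: $w \in \{0, 0.1, \ldots, 1\}$, $\lambda \in \{1, \ldots, 10\}$,
$C \in \{2^{-5}, \ldots, 2^{15}\}$, $\gamma \in \{2^{-15}, \ldots, 2^{-5}\}$
(exponent step 1 — the reading of the search-space description that contains
the published optimum $C = 2^9$, $\gamma = 2^{-7}$). Ties in accuracy prefer
the simplest model: smaller $C$, then $\gamma$, then $\lambda$, then $w$;
this also makes the argmax invariant to grid enumeration order.

## Evaluation protocols and metrics

From the confusion counts, `compute_metrics()` reports
$Sn = TP/(TP+FN)$, $Sp = TN/(TN+FP)$, $Acc = (TP+TN)/N$ and
$MCC = (TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FN)(TN+FN)(TP+FP)(TN+FP)}$;
a zero factor in the MCC denominator yields MCC 0 with an explicit
degenerate flag. Percentages are printed to two decimals.

`jackknife()` holds out each sequence in turn and retrains on the remaining
$N-1$ with all four parameters frozen (parameter search happens before,
never inside, the loop — mirroring the optimize-then-evaluate sequence and
keeping the cost at $N$ fits). `kfold()` uses stratified seed-determined
folds; with $k = N$ every fold is a singleton and the counts coincide with
the jackknife exactly.

**A leave-one-out caveat.** On *exactly balanced* data with no class signal,
the jackknife is not centered at 50% accuracy: an underfitting classifier
(here, the RBF kernel at the tiny default $\gamma$ is nearly constant, so
the SVM approaches majority voting) predicts the majority of its *training*
set, and removing the held-out sample always demotes that sample's own class
to minority — leave-one-out accuracy collapses toward 0, not 0.5. Stratified
k-fold keeps training folds balanced and stays near chance. The test suite
asserts both behaviors; any chance-baseline comparison for this pipeline
should use stratified k-fold, while the jackknife remains the protocol of
record for signal-bearing data.

## The synthetic-data generator

`simulate_dhs_dataset()` emulates the discriminative structure the method
targets: a DHS-like class enriched in CC/CG/GC/GG dinucleotide steps.
Sequences are first-order Markov chains (first base uniform, each next base
from the previous base's transition row) because a first-order chain makes
dinucleotide frequencies — the classifier's signal — directly controllable.
The positive class adds `delta` to the log-odds of every transition into C
and into G and renormalizes; `delta = 0` makes both classes identically
distributed. Defaults: 200 positives, 200 negatives, lengths uniform in
200–400 bp (a plausible regulatory-element scale, chosen once and documented
as arbitrary), `delta = 1`. One master seed expands into a deterministic
per-sequence stream, so changing one class's count does not perturb the
other class's sequences and identical configurations give byte-identical
FASTA.

What passing tests on this generator do show: the encoder, search and
evaluation machinery recover a controlled dinucleotide-composition contrast
end to end, and report chance-level k-fold performance when no contrast
exists. What they do not show: performance on real chromatin data, whose
discriminative structure is weaker, length-heterogeneous and confounded —
the published benchmark itself is required for that (see the README's
reproduction section).

## Numerical choices

* Sum-to-one of PseDNC vectors is asserted to 1e-9 (floating accumulation
  over $\lambda$ tiers); oracle-equivalence tests use 1e-12.
* Property standardization uses the population SD; degenerate rows error.
* $\Theta$ values from the precomputed 16×16 matrix are clipped at 0 to
  absorb tiny negative rounding residues of the cross-product form.
* MCC products are computed in double precision to avoid integer overflow
  at large counts.
* Ambiguous bases: records containing N are rejected by default or dropped
  (with a count) under `drop_ambiguous = TRUE`; other letters always error
  with record and position. Lowercase is accepted and upper-cased; strand
  is taken as given.

## Problem sizes used by the packaged checks

The test suite and `scripts/acceptance.R` run entirely on generated data:
jackknife at the default operating point on 400 sequences (moderate
contrast, `delta = 1`), 200 sequences (strong contrast, `delta = 3`), 100
balanced null sequences, and a coarse 4×3×4×4 grid search under 5-fold CV —
sizes chosen so the whole acceptance run completes in well under a minute
on one core while every protocol is exercised at realistic dimension
(22-component vectors, imbalanced and balanced designs).

## Known limitations

* The bundled property table is a labelled synthetic stand-in (above);
  published operating-point numbers are only reproducible with the
  corresponding published table and benchmark sequences.
* The identity definition inflates similarity of unrelated sequences near
  the 0.6 threshold (above); representative counts are therefore not
  comparable with word-filtered clustering tools at the same nominal
  threshold.
* Only dinucleotide (K = 2), type-I correlations are implemented; no
  probability calibration, alternative kernels, or ROC analysis.
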