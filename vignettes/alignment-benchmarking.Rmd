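---
title: "Clustering-free benchmarking of protein alignment methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering-free benchmarking of protein alignment methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alnvalid)
```

## The problem and the approach

Curated protein benchmark collections organise their sequences into
families — classes with known membership. When an alignment method is good,
the sequence distances it induces should place members of the same family
close together and members of different families far apart. alnvalid scores
alignment methods on exactly that property, **without running any clustering
algorithm**: the family labels are taken as ground truth and cluster-validity
indices are computed directly on the distance matrix. This sidesteps two
classic sources of bias in alignment benchmarking — comparison against manual
reference alignments, and the choice of clustering algorithm, which affects
the outcome but has nothing to do with the alignment itself.

The pipeline has four stages:

1. **Dataset assembly.** Per-family FASTA files are pooled into one labeled
   dataset (`build_benchmark_group()`). A sequence appearing under more than
   one family would have an ambiguous class label and is excluded entirely.
2. **Alignment.** Either the built-in pairwise route — every pair of
   sequences globally aligned by Needleman–Wunsch (`all_pairs_distances()`)
   — or an external multiple aligner invoked through an adapter
   (`msa_method()` + `run_method()`), whose gapped output is projected into
   pairwise identities.
3. **Evaluation.** Percent identity `ID = matched / aligned length` per pair,
   distance `dis = 1 - ID`, then two cluster-validity indices on the distance
   matrix against the family labels: silhouette width (SW) and the RS index
   (`validity_scores()`).
4. **Significance.** Scores are recomputed on subsamples (90% of the
   sequences drawn without replacement, 10 times by default) and methods are
   compared per group with two-sided Welch t-tests (`compare_methods()`).

## The scores

For sequence $i$ in family $C$, with $a(i)$ the mean distance from $i$ to the
other members of $C$ and $b(i)$ the minimum over other families of the mean
distance from $i$ to that family,

$$S(i) = \frac{b(i) - a(i)}{\max\{a(i),\, b(i)\}}, \qquad
  SW = \frac{1}{n}\sum_{i=1}^{n} S(i).$$

SW is near 1 when every sequence sits far closer to its own family than to
the nearest other family and near $-1$ when the labeling fits the distances
poorly. A sequence that is the sole member of its family gets $S(i) = 0$, the
standard neutral convention; this keeps SW defined on subsamples that strand
a family with one member.

The RS index treats each unordered pairwise distance $x_k$ as an observation:

$$RS = \frac{SS_t - SS_w}{SS_t},$$

where $SS_t = \sum_k (x_k - \bar{x})^2$ over all pairs (global mean
$\bar{x}$) and $SS_w$ sums squared deviations of within-family distances.
Both indices are ratios, so multiplying all distances by a constant changes
neither — a method cannot look better merely by producing uniformly smaller
distances; only the *contrast* between within- and between-family distances
counts. The suite verifies this scale invariance to 1e-12.

Two genuinely open definitional points are resolved as follows, each behind
an explicit choice:

* **Squared deviations.** The sums of squares are computed with squared
  deviations. The alternative (unsquared deviations about the mean) sums
  identically to zero and would make the index vacuous, so it cannot be
  meant.
* **Within-cluster centring.** By default $SS_w$ deviates each family's
  within-pair distances about that family's own mean within-distance, the
  classical within/total decomposition; both $SS_w \le SS_t$ bounds follow,
  so $RS \in [0,1]$. `within_center = "global"` instead centres within-pairs
  on the global mean; it is offered because the definition of $\bar x$ inside
  $SS_w$ admits either reading, and the two are compared in the test suite
  (per-cluster centring always explains at least as much).
* **Degenerate case.** If all pairwise distances are equal, $SS_t = 0$ and no
  separable structure exists; RS is defined as 0.

## The alignment core

`nw_align()` is a standard global dynamic program over a substitution matrix,
with two gap models:

* **affine** (default): a gap run of length $k$ costs
  `gap_open + (k - 1) * gap_extend` (Gotoh three-state recursion). Defaults
  are BLOSUM62 with open $-10$, extend $-1$ — the community-standard protein
  settings; pairwise-alignment benchmark tools rarely publish their exact
  scoring parameters, so these are configurable throughout.
* **linear**: every gap column costs `gap_open`. This mode exists largely for
  verifiability: its optimum is checked against exhaustive enumeration of
  *all* global alignments of short sequences, an oracle that is exact rather
  than merely plausible. The affine mode is cross-checked against
  `Biostrings::pairwiseAlignment()` scores (an independent implementation)
  after translating between the two gap-cost conventions.

Traceback ties are broken deterministically (diagonal, then gap in the second
sequence, then gap in the first). Determinism matters here more than usual:
percent identity depends on *which* optimal alignment the traceback returns,
and the whole benchmark must be bit-reproducible under a fixed seed.

Ambiguity codes present in the substitution matrix (B, Z, X) are scored by
its own rows; codes the matrix lacks (e.g. U in the BLOSUM series) score 0
against everything — neutral rather than fatal on real data. Any other letter
is a scoring error naming the residue.

## Percent identity and the gap-column policy

`ID = matched / length`: `matched` counts columns carrying the same residue
letter in both rows (a residue against a gap never matches; a gap-gap column
never matches). For pairwise projections out of a multiple alignment the
denominator is genuinely ambiguous, and both readings are implemented:

* `keep-all` (default): the full row length, including columns where both
  rows are gaps. This is the literal "whole length of the aligned sequences"
  and has a real consequence: a multiple aligner can spread two identical
  sequences over gap-gap columns, so their projected identity can fall below
  1 — part of what the benchmark is designed to expose.
* `drop-dual-gap`: gap-gap columns removed first, the common convention for
  projected pairwise identity; offered for sensitivity analysis.

Pairwise alignments from `nw_align()` contain no gap-gap column, so the
policies agree there (asserted in the tests).

## The resampling and comparison protocol

`resample_dataset()` draws `floor(fraction * n)` sequences uniformly without
replacement, unstratified — family proportions are preserved in expectation
only, and a replicate can strand a family with one member (handled by the
singleton convention above). All randomness flows from one integer seed, and
the replicate draws come from a single seeded stream, so a group is fully
reproducible from `(dataset, fraction, reps, seed)`.

`compare_methods()` applies a two-sided Welch (unequal-variance) t-test by
default; because resamples are matched across methods a paired option is
provided. Identical score vectors give $p = 1$ by convention. The suite
checks the test's type-I calibration by simulation: two 10-score vectors from
the same normal distribution, 1000 replicates, rejection rate at
$\alpha = 0.05$ within binomial error of 0.05.

A deliberately scheduled full design — 8 groups, each 1 original + 10
resampled datasets, 7 method configurations — comprises
$8 \times 11 \times 7 = 616$ alignment runs (`schedule_runs()`), the
bookkeeping the reporting layer is built around.

## What the synthetic generator emulates — and what it does not

`generate_families()` produces labeled multi-family datasets by a two-level
process: a root sequence drawn i.i.d. uniform over the 20 standard residues;
per-family ancestors mutated from the root at per-site probability
`between_divergence`; members mutated from their ancestor at
`within_divergence`, with optional single-residue indels at `indel_prob`
(insertion/deletion equiprobable). A mutated site is always replaced by one
of the 19 *other* residues, which gives closed forms used for calibration:
identity between a sequence and its mutated copy is $1 - d$ in expectation,
and between two independent descendants of one ancestor
$(1-d)^2 + d^2/19$. Both are verified against Monte-Carlo simulation (and,
for the two-branch form, against realized Needleman–Wunsch identities).

Default study conditions used in the tests and the acceptance script: 4
families × 10 members, root length 200 residues, `within_divergence = 0.05`
(members ~90% identical within a family, via the two-branch form),
`between_divergence` swept over 0.1–0.9, indels off unless gap handling is
being exercised (then 1%). These sizes keep an all-pairs benchmark —
$\binom{40}{2} = 780$ alignments per dataset — comfortably fast while leaving
room for the validity scores to vary smoothly across the divergence grid.

The generator deliberately omits features of real protein families: no
among-site rate heterogeneity, no guide-tree topology (all members are
equidistant from their ancestor), no multi-residue indels, no composition
bias, and uniform substitution rather than BLOSUM-weighted exchange. Passing
tests therefore demonstrate that the framework's statistics behave correctly
on data with known structure — monotone response to the divergence dials,
separation of true from permuted labels — not that any particular aligner
will win on curated biological benchmarks.

Presets in `synthetic_presets()` target the identity bands curated
benchmarks are organised around (e.g. very divergent families under 20%
inter-family identity); they are starting points, with no claim of
reproducing any curated dataset's content.

## Numerical conventions

* Distance matrices are validated on construction (symmetry to 1e-9, range
  [0, 1], zero diagonal) and symmetrised exactly; each unordered pair is
  computed once.
* Silhouettes with $a(i) = b(i) = 0$ (all distances tie at zero) are set
  to 0.
* Scores are written to report tables with 6 decimal places; matrix files
  carry 10 decimals, so write/read round-trips agree to well under 1e-9.
* External aligner adapters verify their tool's output: every input id must
  come back, and degapping each row must reproduce the input residues;
  violations are integrity errors naming the sequences.

## Limitations

* The pairwise route is exact but quadratic in the number of sequences, with
  each alignment quadratic in length; it is a benchmark core, not a
  large-scale clustering engine (no k-mer prefiltering, no banding).
* Only percent identity is offered as the similarity measure — no
  BLOSUM-similarity fraction, no evolutionary-distance corrections — because
  the validity indices are deliberately computed on the same quantity for
  every method.
* External MSA tools are wrapped, never reimplemented; published per-dataset
  scores for specific aligner versions are not reproducible without those
  exact binaries and scoring parameters, and the package makes no attempt to
  ship them.
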