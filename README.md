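# alnvalid

Clustering-free benchmarking of protein sequence-alignment methods.

Curated protein datasets come with known family labels. A good alignment
method should induce sequence distances under which members of the same
family are close and members of different families are far apart — and that
property can be measured directly, without ever running a clustering
algorithm whose own choices would contaminate the comparison. alnvalid
implements this evaluation end to end for people who compare aligners or
build sequence-clustering pipelines:

* **Distances.** Global Needleman–Wunsch pairwise alignment (compiled code;
  BLOSUM/PAM matrices, linear or affine gaps) for the PSA route, and
  pairwise projection of any multiple aligner's gapped FASTA output for the
  MSA route. Per pair: percent identity `ID = matched / aligned length`,
  distance `dis = 1 - ID`.
* **Validity scores.** Silhouette width
  `SW = mean over i of (b(i) - a(i)) / max{a(i), b(i)}` — where `a(i)` is the
  mean within-family distance of sequence `i` and `b(i)` its smallest mean
  distance to another family — and the RS index
  `RS = (SS_t - SS_w) / SS_t` on the pairwise distances. Both are ratios, so
  uniformly shrinking all distances changes neither: only the within- versus
  between-family contrast counts.
* **Protocol.** Pool per-family FASTA files into labeled datasets, resample
  90% of the sequences 10 times, score every (dataset, method) pair, and
  compare methods per group with two-sided Welch t-tests over the matched
  resamples.
* **Simulation.** A multi-family protein sequence generator with separate
  within-family and between-family per-site divergence and single-residue
  indels, with closed-form expected identities for calibration.

Everything is tidyverse-shaped: sequence sets and label maps are tibbles,
results have `tidy()` / `glance()` methods, and `autoplot()` works on
distance matrices and validity results.

## Worked example

Simulate three families, compute pairwise-alignment distances, and score the
separation:

```r
library(alnvalid)

sim <- generate_families(n_families = 3, seqs_per_family = 4, length = 60,
                         between_divergence = 0.6, within_divergence = 0.05,
                         seed = 7)
d <- all_pairs_distances(sim$sequences)          # 12 x 12 aln_dist matrix
v <- validity_scores(d, sim$sequences[, c("id", "family")])
v
#> <aln_validity> 12 sequences, 3 families
#>   SW = 0.880751   RS = 0.997992
```

SW of 0.88 says each sequence sits far closer to its own family than to the
nearest other family; RS near 1 says nearly all squared variation in the
pairwise distances is explained by the family partition. `tidy(v)` returns
the per-sequence silhouettes, `glance(v)` the one-row summary, `autoplot(v)`
the silhouette plot.

The same run from the shell, via the bundled CLI (`inst/scripts/alnvalid`):

```sh
alnvalid simulate --families 3 --per-family 4 --length 60 --between 0.6 \
         --within 0.05 --seed 7 --out synth.fasta --labels synth.tsv
alnvalid align-psa --in synth.fasta --out dist.tsv
alnvalid validity --dist dist.tsv --labels synth.tsv --out validity.tsv
#> n        12
#> families 3
#> SW       0.880751
#> RS       0.997992
```

The full benchmark protocol on real per-family FASTA files:

```r
ds <- build_benchmark_group(c(famA = "famA.fasta", famB = "famB.fasta"))
g  <- benchmark_group(ds, "mygroup", reps = 10, fraction = 0.9, seed = 42)
scores <- evaluate_group(g, list(psa_method(),
                                 msa_method("mafft", "mafft", c("{input}"))))
compare_scores(scores)   # Welch t-tests per method pair, SW and RS
```

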