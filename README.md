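# silacswitch

Differential proteome analysis from label-switched SILAC peptide ratios,
with a codon-level read-out of translational regulation.

## The problem

SILAC quantitative proteomics compares two conditions (here: yeast grown
at 30°C vs 37°C) through per-peptide heavy/light intensity ratios. Two
error classes corrupt peptide-level quantification: wrong identifications
(low posterior identification probability) and wrong ratio measurements
(overlapping isotope envelopes). When the heavy label alternates between
conditions across biological replicates (a *label switch*), a correct
peptide's oriented ratio — design sign × log₂(H/L), fixed to the
log₂(30°C/37°C) convention — has the same expectation in every replicate,
while a measurement artefact flips sign under the switch. `silacswitch`
exploits this at the peptide level:

1. **probability threshold** at a target identification FDR
   (prefix rule: largest prefix of descending probabilities with
   Σ(1−pᵢ)/k ≤ target, default 1%);
2. **consistency filter**: keep a peptide iff its per-design mean oriented
   ratios satisfy |R₊₁ − R₋₁| < √2 × c (default c = 0.4);
3. **retention**: keep proteins with ≥ 2 retained peptides covering both
   designs; aggregate to a protein × replicate matrix (median,
   per-replicate median-centred);
4. **empirical-Bayes moderated one-sample t-test**: shrink each protein's
   variance toward a prior (d₀, s₀²) estimated by trigamma moment
   matching, s̃²ᵍ = (d₀s₀² + dᵍs²ᵍ)/(d₀ + dᵍ), t̃ᵍ = x̄ᵍ√nᵍ/s̃ᵍ, BH-adjusted
   two-sided p on d₀ + dᵍ df, directional calls at 1% FDR;
5. **codon importance**: profile the 61 sense-codon frequencies of each
   coding sequence and train a random forest (built in, C++; permutation
   importance = mean decrease in out-of-bag accuracy) to find the codons
   separating up- from down-regulated proteins, selecting codons above the
   absolute value of the lowest predictor;
6. **rescue comparison**: genes in the top 10% for AAA/CAA/GAA frequency,
   significantly down in the normal dataset but not in a rescue dataset.

A first-class synthetic-data module simulates the whole stack — truth,
coding sequences, and label-switched peptide observations with abundance-
dependent peptide counts, measurement noise and contaminating erroneous
quantifications — so every stage is testable without raw MS data.

## Worked example

```r
library(silacswitch)

cfg <- generator_config(n_proteins = 1000, seed = 42)
sim <- simulate_dataset(cfg)

qf <- quant_filter(sim$peptides)
qf$counts
#>         peptides_in  peptides_high_conf   peptides_retained proteins_quantified
#>               63531               48648               29362                1000
#>   proteins_retained
#>                 939

res <- moderated_test(qf$matrix)      # prior: d0 = 6.13, s0sq = 0.0145
tally_significant(res)
#>  total   up37 down37
#>    551    254    297

prof <- codon_frequencies(sim$orfs)
sig  <- res[res$call != "ns", ]
imp  <- rf_importance(prof[sig$protein_id, ], sig$call,
                      n_trees = 1000, seed = 7)
head(imp[order(imp$rank), c("codon", "importance", "rank", "selected")], 5)
#>    codon importance rank selected
#> 17   CAA    0.04986    1     TRUE
#> 33   GAA    0.04559    2     TRUE
#> 1    AAA    0.04000    3     TRUE
#> 53   TCG    0.00175    4     TRUE
#> 56   TGG    0.00124    5     TRUE
```

Of 63,531 simulated peptide observations, 48,648 clear the 1%-FDR
probability threshold and 29,362 survive the label-switch consistency
filter, retaining 939 of 1000 proteins. The moderated test calls 551
proteins differential at 1% FDR (297 down at 37°C); the codon-biased
genes the generator planted (AAA/GAA/CAA sampling weight ×3, true ratio
shifted by +1 log₂ unit) drive exactly those three codons to the top
importance ranks, separated by an order of magnitude from the first
unplanted codon.

Reporting helpers reproduce standard bookkeeping arithmetic:

```r
fold_change(c(2.01, 0.69, -0.58))
#>   fold direction
#> 1 4.03      down
#> 2 1.61      down
#> 3 1.49        up
coverage_summary(4612, 6717)
#> [1] 68.66
```

## Command line

An executable wrapper is installed under `exec/`:

```sh
silacswitch simulate --n-proteins 1000 --seed 42 --out simdata
silacswitch filter --in simdata/peptides.tsv --out matrix.tsv
silacswitch test --in matrix.tsv --out results.tsv
silacswitch codons --fasta simdata/orfs.fasta --out profiles.tsv
silacswitch importance --profiles profiles.tsv --results results.tsv --seed 7
silacswitch all --rescue --out run   # end-to-end with a simulated rescue arm
```

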