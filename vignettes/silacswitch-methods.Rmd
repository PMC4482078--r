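---
title: "Methods: label-switch SILAC filtering, moderated testing and codon importance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-switch SILAC filtering, moderated testing and codon importance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silacswitch)
```

## The problem

In a SILAC experiment two cultures — here, yeast grown at 30°C and at 37°C
— are labelled with light and heavy isotopes, mixed, and measured together;
each peptide yields a heavy/light intensity ratio that estimates the
relative abundance of its parent protein between the conditions. Two error
sources dominate peptide-level quantification: incorrect peptide
identifications (carrying low posterior identification probabilities) and
erroneous ratio measurements (overlapping isotopic envelopes, wrong
isotope-pair picking). A label-switch design, in which the condition
carrying the heavy label alternates across biological replicates, turns the
second class of errors into a detectable signature: a correct peptide's
*oriented* ratio (design sign × log2 heavy/light, fixed to the
log2(30°C/37°C) convention) has the same expectation in every replicate,
while a quantification artefact does not follow the label and flips sign
under the switch.

`silacswitch` implements this quantification workflow, the downstream
empirical-Bayes differential test, and a codon-level analysis that asks
which codons best predict whether a protein goes up or down — the read-out
used to link down-regulated proteins to transcripts enriched in the AAA,
GAA and CAA codons, which are decoded by tRNAs whose wobble uridines carry
a 2-thio modification.

## The quantification filter

Stages, in order:

1. **Probability threshold.** Identification probabilities are sorted in
   decreasing order; for a prefix of size $k$ the estimated false-discovery
   rate is $\sum_i (1-p_i)/k$. The threshold is the probability of the last
   element of the largest prefix with estimated FDR at most the target
   (default 1%). If no prefix qualifies, a sentinel above 1 is returned and
   nothing passes.
2. **Orientation.** Oriented ratio $=$ design $\times \log_2(H/L)$;
   positive values mean more abundant at 30°C, i.e. down-regulated at 37°C.
3. **Consistency filter.** For each peptide, the mean oriented ratio is
   formed separately over replicates of each design, $R_{+1}$ and
   $R_{-1}$; the peptide is kept iff both exist and
   $|R_{+1}-R_{-1}| < \sqrt{2}\, c$ with $c = 0.4$ by default. The bound is
   one standard deviation of the difference of two measurements that each
   carry SD $c$; the inequality is strict.
4. **Protein retention.** A protein is kept iff it has at least two
   distinct retained peptides which jointly cover both designs.
5. **Aggregation.** Cell (protein, replicate) is the median (default; mean
   available) of the retained oriented peptide ratios; each replicate
   column is then median-centred.

Design choices that were genuinely open:

* The source text writes one $R$ per design without saying how replicates
  combine; we use per-design **means** of a peptide's oriented ratios —
  symmetric and using all observations. Peptides seen under only one
  design cannot be checked for consistency and are dropped; the
  `require_both_designs` switch exposes the retention variant for
  sensitivity analysis.
* Whether the "two peptides across label-switched samples" rule requires
  each peptide individually in both designs or jointly is ambiguous; we
  implement joint coverage (each retained peptide already covers both
  designs whenever the consistency filter ran, so the distinction only
  matters in reduced pipelines).
* The aggregation statistic is not stated; the median is the robust
  default.
* Normalisation is per-replicate median-centring; the source only asserts
  absence of systematic bias, naming no correction, and centring is the
  minimal correction idempotent on unbiased data.

## The moderated t-test

Per protein $g$ with $n_g$ non-missing replicate ratios, mean
$\bar{x}_g$, sample variance $s^2_g$ and $d_g = n_g - 1$, the posterior
variance shrinks $s^2_g$ toward a prior $s_0^2$ carrying $d_0$ degrees of
freedom:

$$\tilde{s}^2_g = \frac{d_0 s_0^2 + d_g s^2_g}{d_0 + d_g},
\qquad \tilde{t}_g = \frac{\bar{x}_g}{\tilde{s}_g/\sqrt{n_g}},$$

with a two-sided p-value on $d_0 + d_g$ degrees of freedom (standard
normal when $d_0 = \infty$). The hyperparameters are estimated by moment
matching on $e_g = \log s^2_g - \psi(d_g/2) + \log(d_g/2)$: the excess of
the empirical variance of $e_g$ over $\mathrm{mean}[\psi'(d_g/2)]$ is
inverted through the trigamma function to give $d_0$, and
$s_0^2 = \exp(\bar{e} + \psi(d_0/2) - \log(d_0/2))$, since under the
scaled inverse chi-square prior
$E[e_g] = \log s_0^2 + \log(d_0/2) - \psi(d_0/2)$. When the excess
dispersion is non-positive, $d_0 = \infty$ and $s_0^2$ is the mean sample
variance. This matches the classical empirical-Bayes formulation (our unit
tests cross-check the estimates against `limma::fitFDist` and the
moderated statistics against `limma::eBayes`, which we use only as an
independent oracle).

Proteins with zero sample variance participate (their variance is shrunk
to the prior) but are excluded from prior estimation; proteins with fewer
than two replicates are excluded with a message. Multiple testing is
controlled by Benjamini–Hochberg step-up, and calls at FDR level
$\alpha = 0.01$ are directional: `down37` for positive oriented means,
`up37` for negative.

Numerical notes: the trigamma inversion is a Newton iteration on the
decreasing convex branch with asymptotic starting points ($1/\sqrt{y}$ for
large $y$, $1/y$ for small); BH adjustment uses a reverse cumulative
minimum and caps at 1; ties in p-values are handled by the sort order and
do not affect the adjusted values. The analytic limits are exact: as
$d_0 \to 0$ the statistic reduces to the ordinary one-sample t, as
$d_0 \to \infty$ to the fixed-variance z-style statistic (both are checked
at $d_0 = 10^{-6}$ and $10^{6}$ to relative error $10^{-6}$ on the
statistic; p-values converge one order slower because the tail probability
amplifies the perturbation of both the statistic and the degrees of
freedom, and are checked at $10^{-5}$).

## Codon importance

Codon profiles are relative frequencies over the 61 sense codons, counting
from the initial ATG up to but excluding the single terminal stop (the
source does not specify the treatment of the start and stop; including
ATG and excluding the stop keeps every counted codon an elongation
substrate candidate while remaining a proper composition).

A random-forest classifier separates `up37` from `down37` proteins using
the 61 frequencies. Because no random-forest package is available in the
target environment, the forest is implemented in the package (C++):
Gini-grown CART trees, bootstrap resampling, `mtry = round(sqrt(61)) = 8`
features per split, minimum node size 5, 1000 trees, mandatory seed. The
importance measure is **permutation importance** — the mean decrease in
out-of-bag accuracy when a codon's out-of-bag values are permuted,
averaged over trees — rather than impurity decrease: permutation
importance is comparable across correlated compositional features and can
go negative, which the selection rule needs. The selection threshold is
the absolute value of the most negative importance (the magnitude of the
noisiest predictor); codons strictly above it are selected. The source
names neither its importance metric nor its hyperparameters; these are the
package's declared choices, not inferred ones.

Top-percentile codon subsets rank genes by descending frequency of one
codon with ties broken by ascending gene id and take
$\lceil n \cdot q/100 \rceil$ genes. The rescue comparison intersects
three criteria — membership in the union of top-10% subsets for AAA, CAA
and GAA; a significant down-call in the normal dataset; no such call in
the rescue dataset — over the genes present in both result sets.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, so
every stage is testable without raw mass-spectrometry data:

* 3 biological replicates with alternating label designs (+1, −1, +1);
* protein abundances log-uniform over five decades (copies per cell
  $10^1$–$10^6$);
* peptides per protein increasing with abundance,
  `round(-7 + 8·log10(copies))` plus integer noise with SD 2, floored at
  1 — tuned so the corpus-wide mean is ≈ 21 peptides per protein;
* per-peptide measurement noise `sigma_meas = 0.4` on the log2 scale. The
  source does not state its measurement noise; 0.4 is chosen because the
  consistency-filter constant $\sqrt{2} \times 0.4$ is exactly one SD of a
  difference of two such measurements, making the default filter neither
  vacuous nor destructive on its own data;
* a `frac_wrong = 0.05` contaminating fraction of erroneous observations
  with ratio SD 2.0 and Beta(4, 4) identification probabilities (centred
  near 0.5), against Beta(60, 1) (concentrated above 0.95) for correct
  ones. Real identification posteriors are mixture-model outputs; only the
  behaviour of the downstream FDR threshold matters, which Beta shapes
  reproduce;
* a `frac_biased = 0.2` subset of genes whose coding sequences have the
  AAA/GAA/CAA sampling weights multiplied by 3 before renormalisation and
  whose true oriented ratio is shifted by `bias_effect = 1.0` (less
  abundant at 37°C) — the "thiolation deficiency" coupling;
* baseline biological variation `sigma_bio = 0.35`, so that both
  directions of regulation occur and the up/down classifier has two
  non-degenerate classes;
* optional per-replicate dropout (default 0) to exercise the
  missing-design branch of the filter.

Coding sequences are sampled with uniform weights over the sense codons
(modulo the bias multiplier), start with ATG and end with one stop. Real
coding sequences have amino-acid composition constraints, codon
autocorrelation and length–expression coupling that the generator does not
model; a green planted-signal test therefore establishes that the pipeline
recovers a codon-composition signal of the stated size, not that it would
rank codons identically on real genomes.

All randomness flows from one integer seed, fanned out to per-stage seeds
keyed by stage name, so re-running one stage never perturbs another; the
random forest keeps its own seeded generator and leaves R's RNG state
untouched.

## What the tests establish

The acceptance suite checks (i) the reporting arithmetic
(fold = $2^{|\log_2 r|}$, coverage percentages, significant-count
bookkeeping) exactly; (ii) BH against a brute-force oracle on 1000 random
vectors; (iii) the two analytic limits of the moderated test; (iv)
recovery of known prior hyperparameters ($d_0 = 4$, $s_0^2 = 0.04$) from
5000 simulated variances within 25%/10%; (v) empirical FDR ≤ 2% at
$\alpha = 1\%$ over 20 null simulations of 3000 proteins; (vi) recovery of
the planted AAA/GAA signal in the top-3 importance ranks in ≥ 9 of 10
seeds; (vii) bitwise invariance of all outputs under global label
negation; and (viii) monotonicity and contamination-enrichment properties
of the consistency filter. The headline protein counts of the motivating
study depend on its deposited raw data and are deliberately not targets.

## Known limitations

* No protein inference: `protein_id` is taken as given per peptide.
* One-sample design only; no covariates, no intensity-dependent variance
  trend.
* The forest is a purpose-built implementation; it supports exactly the
  binary, continuous-feature case used here and reports permutation
  importance only.
* The generator's codon model is compositionally realistic but
  sequence-naive (no amino-acid constraints, no dicodon structure).
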