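---
title: "Mapping stochastic-noise (CV) QTLs in recombinant inbred lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping stochastic-noise (CV) QTLs in recombinant inbred lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(cvqtl)
```

# The phenotype: stochastic noise as a mappable trait

Most quantitative genetics asks which loci move the *mean* of a trait.
`cvqtl` asks which loci move its *variability*: for a genetically uniform
line measured in replicate, the coefficient of variation

$$\mathrm{CV} = \frac{\sigma}{\mu}$$

of those replicates is a dimensionless summary of the line's stochastic
noise, comparable across traits with very different scales. In a population
of homozygous recombinant inbred lines (RILs), every line can be replicated
at will, so per-line CV becomes an ordinary quantitative phenotype: it can be
quantile-normalized, tested for heritability, and scanned for QTLs. Loci
found this way (variance QTLs, or "CV eQTLs" when the trait is a transcript)
are often distinct from the loci controlling the mean — a dissociation this
package is designed to detect and validate.

The pipeline has five stages, each usable on its own:

1. **Phenotyping** (`quantile_normalize`, `cv_phenotypes`, `network_values`,
   `phase_group_values`, `global_cv`): replicated trait matrices become
   per-line CV phenotypes.
2. **Heritability** (`broad_sense_h2`, `parental_h2`, `cv_heritability`): a
   one-way random-effects decomposition of the independent per-experiment CV
   measures.
3. **QTL mapping** (`build_scan_grid`, `select_cofactors`, `cim_scan`,
   `permutation_threshold`, `call_qtl`): composite interval mapping of the
   CV phenotype with genome-wide permutation thresholds.
4. **Hotspots** (`count_qtl_per_position`, `sliding_window_profile`,
   `hotspot_threshold`, `effect_sign_summary`): where do CV QTLs of many
   traits pile up beyond what uniform placement explains?
5. **Direct variance tests** (`levene_f`, `compare_distributions`,
   `parental_expectation_model`): single-locus validation and the
   transgressive-segregation check.

A synthetic-data generator (`simulate_genetic_map`,
`simulate_ril_genotypes`, `simulate_replicated_traits`) plants known mean-
and variance-effects into simulated RIL populations so every stage can be
validated end to end with known truth.

# CV phenotypes

Expression-style data arrive as replicated measurements indexed by
(line, trait, experiment, replicate). The defaults assume the classic
duplicate-in-two-experiments design: 2 independent experiments × 2
replicates, i.e. four measurements per line and trait.

Two decisions matter here:

* **CV is computed per experiment, then averaged.** Each experiment yields
  its own CV from its own replicates (sample SD with the $n-1$ denominator,
  divided by the mean), and the mapped phenotype is the arithmetic mean of
  the per-experiment CVs. Keeping the per-experiment values is what makes
  heritability estimable — they are the independent repeat measurements of
  the noise phenotype. A pooled alternative (one CV across all replicates of
  all experiments) is available via `cv_phenotypes(..., pooled = TRUE)` but
  is not the default, because pooling confounds between-experiment shifts
  with within-line noise and discards the replication structure.
* **CV lives on the absolute (normalized) scale, never on logs.** Quantile
  normalization (delegated to `limma::normalizeQuantiles`, ties sharing the
  mean reference value) equalizes the distribution of every sample; CV is
  then taken on those absolute values. A cell whose mean is zero or negative
  (possible for metabolite-like inputs after normalization) has no
  meaningful CV and is propagated as missing rather than returned negative.

Network and circadian phase-group phenotypes reuse one summary: every member
trait is z-scored across *all* samples pooled (lines × experiments ×
replicates), and a network's value in a sample is the mean of its members'
z-scores. Pooling the standardization population is a deliberate choice —
the z-transform is applied once per transcript, so line, experiment and
replicate all see the same affine map, and the network value remains a
legitimate replicated phenotype. The per-line *global* CV is the unweighted
mean of a line's trait CVs; it summarizes genome-wide noise in a single
mappable number. Note that z-scored network values are centered near zero,
so their per-line means can be small or negative; network CV cells where the
mean is non-positive are flagged undefined, exactly as for traits.

# Heritability of CV

With two (or more) independent CV measures per line, broad-sense
heritability is the plain variance ratio $H = \sigma^2_g / \sigma^2_p$
estimated by the method-of-moments one-way ANOVA decomposition:
$\hat\sigma^2_e$ is the within-line mean square, $\hat\sigma^2_g = (MS_B -
MS_W)/k_0$ with $k_0$ the harmonic-adjusted replicates per line, and
negative $\hat\sigma^2_g$ is clipped to zero so $\hat H \in [0, 1]$. A mixed
model would add machinery without changing the answer in this balanced
two-experiment design, so the closed form is used. Aggregate-only input (a
single CV per line) is refused rather than silently accepted: a variance
decomposition needs the independent measures — which is also why
heritability is simply not computable for traits where only per-experiment
summaries were never retained.

```{r herit-example}
h <- parental_h2(c(0.10, 0.12), c(0.30, 0.33))
h
```

# Composite interval mapping of CV

The scanner is Haley–Knott regression on a pseudomarker grid:

* **Grid.** Pseudomarkers every `step_cM` (default 1 cM) per chromosome. At
  each position, every line gets an expected genotype score
  $E[x] \in [-1, 1]$ from its nearest non-missing flanking markers under the
  selfed-RIL Markov transition probabilities: map distance $d$ cM becomes
  $r = (1 - e^{-2d/100})/2$ (Haldane, no interference) inflated to
  $R = 2r/(1+2r)$ for the accumulated breakpoints of repeated selfing.
  At an observed marker, $E[x]$ is the observed code.
* **Cofactors.** Background markers chosen by forward stepwise regression
  minimizing BIC, at most `max_cofactors` (default 5), ties broken by genome
  order. Cofactor choice is the one part of classic CIM software that is
  rarely documented; forward-BIC is fixed here because it is deterministic,
  scale-free and cheap enough to re-run inside every permutation. Note that
  with ~95 markers and 200 lines the BIC forward pass admits one or two
  spurious cofactors for roughly two thirds of pure-noise traits — that is
  the honest behavior of the criterion, and it is harmless because the
  permutation threshold is estimated with cofactors reselected per
  permutation, so selection-induced inflation is baked into the null.
* **Test.** At each position, the full model regresses the phenotype on
  $E[x]$ plus the active cofactors — any cofactor within `window_cM`
  (default 10 cM, closed interval) of the test position on the same
  chromosome is excluded so it cannot absorb the signal being tested. The
  statistic is $LRT = n \ln(RSS_{reduced}/RSS_{full})$, reported alongside
  $LOD = LRT / (2\ln 10)$, and the additive effect is the coefficient on
  $E[x]$: positive means the B (second-parent) allele raises the phenotype.
  With homozygous RILs and a dense map, Haley–Knott regression is an
  excellent approximation to the full mixture likelihood; EM scanning is out
  of scope.
* **Thresholds.** Genome-wide significance comes from permutations: for each
  of `n_traits` (default 100) sampled phenotypes, values are permuted across
  lines `n_perm` (default 1000) times, cofactors reselected, the genome
  rescanned and the maximum LRT recorded. The default threshold is the
  pooled $(1-\alpha)$ quantile of all `n_traits × n_perm` maxima. The
  phrase "the 95th percentile threshold across the null distributions" can
  also be read as a quantile of per-trait thresholds; both are computed and
  returned (`threshold`, `threshold_of_thresholds`), pooled being the
  default because it estimates a single marginal null for the whole trait
  ensemble and is much less noisy per trait. Results sensitive to this
  choice should report both.
* **Calls.** Greedy peak picking above the threshold with a 5 cM exclusion
  radius (no second QTL within 5 cM of a called peak; closed windows), each
  call carrying its contiguous above-threshold support region. Calls are
  classified cis if they fall within 5 cM of the trait's own locus on the
  same chromosome, else trans.

All coordinates are chromosome + cM with per-chromosome origin 0; every
window in the package is a closed interval; missing phenotypes are handled
complete-case per trait; missing genotypes by conditioning on the nearest
non-missing flanks (column-mean imputation for cofactor columns only).

# Hotspots

Counting each trait's called peaks onto the grid gives a positional count
profile, smoothed for display with a 2.5 cM sliding window (truncated at
chromosome ends). Significance of a pile-up uses a positional permutation
null: throw the observed total number of QTLs uniformly onto the grid
positions, record the per-permutation maximum count, and take the
$(1-\alpha)$ quantile of 1000 maxima. The same machinery scales down to
small phenotype families (`colocalization_threshold`). Uniform placement
treats every position as exchangeable; weighting positions (e.g. by interval
length) is available via `weights` since genome structure may argue either
way, and a counts-preserving per-trait variant (`method = "per_trait"`) is
provided because the null can also be read as shuffling each trait's QTL set
jointly. The fully-independent uniform null is the default. Near a hotspot,
`effect_sign_summary` tallies the signs of the additive effects (within the
same 2.5 cM window by default) and applies an exact binomial test — hotspots
driven by a single trans regulator tend to push most traits' CVs in one
direction.

# Direct variance tests

`levene_f` is the classic Levene test — one-way ANOVA on absolute deviations
from the group *mean* (the Brown–Forsythe median-centered variant is an
option). When every group's deviations are constant but differ between
groups the F statistic is degenerate; the result then carries an explicit
`degenerate` flag with $p = 0$ rather than a bare infinity.

`parental_expectation_model` asks whether the spread of per-line CV across
the RILs exceeds what the two parents alone can generate. Each of
`n_models` (default 1000) models assigns every simulated RIL one parent with
probability 1/2 and draws its CV by resampling a replicate set of the
original size, with replacement, from that parent's replicates; the SD of CV
across simulated RILs, averaged across traits, gives one null value per
model. An observed value above the maximum of 1000 models indicates
transgressive segregation of the noise phenotype — RILs combining variance
alleles of opposing sign that cancel in the parents. The resampling scheme
(parent-mixture bootstrap) is this package's explicit construction, recorded
in the result's `scheme` field so alternatives can be compared; because it
resamples real replicate sets it reproduces the estimation noise of the CV
itself, not only the biological spread.

# The synthetic-data generator

`simulate_ril_genotypes` draws each line as an independent homozygous mosaic
along each chromosome: first marker A/B with probability 1/2, adjacent
markers switching with probability $R(d)$ above. The generator and the
scanner share no code for genotype probabilities beyond the map function —
QTL effects attach to the *nearest marker* rather than an interpolated
pseudomarker precisely so that the generative model stays independent of the
scanner's interpolation.

`simulate_replicated_traits` plants effects per trait: the per-line mean is
$\mu_0 + \sum a_{mean} x$ and the per-line CV is $c_0 \exp(\sum a_{cv} x)$
with $x = \pm 1$ the genotype score. CV effects are additive on *log-CV* so
that any effect size leaves the CV positive. Replicates are
$N(\mu, (\mu \cdot CV)^2)$ — Gaussian noise whose SD tracks the mean times
the CV; heavier tails are out of scope. Defaults emulate a realistic
transcript-like study: baseline mean 100 (arbitrary expression units),
baseline CV 0.1, 2 experiments × 2 replicates, a 5-chromosome × 90 cM map
with 5 cM marker spacing. An `experiment_sd` argument can add an
experiment-level shift; it defaults to 0 because quantile normalization
removes exactly this kind of batch scale effect in real pipelines, and the
simulator is usually run on the post-normalization scale. A masking utility
(`mask_genotypes`) introduces missing-at-random genotypes to stress the
scanner.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: probe-level artifacts and cross-hybridization,
residual heterozygosity of real RILs, segregation distortion, epistatic or
G×E variance control, non-Gaussian replicate noise, and correlated traits
(simulated traits are conditionally independent given genotype). Recovery
rates measured here are best-case rates for the stated effect sizes.

# Numerical and testing choices

* Determinism: every randomized function takes a `seed` and restores the
  caller's RNG state; the pipeline derives per-stage sub-seeds from one
  master seed, so reruns are byte-identical.
* Degenerate designs: a cofactor collinear with the tested $E[x]$ is dropped
  at that position; constant phenotypes give LRT 0; $R^2$ is capped at
  $1 - 10^{-12}$ before the log.
* Validation sizes (chosen as the package's own test design): the reference
  population for statistical validation is 200 RILs on the 5 × 90 cM map;
  permutation thresholds for calibration use 100 null phenotypes × 300
  permutations; type-I error is checked on 300–500 fresh null traits against
  the 95% binomial interval around $\alpha = 0.05$; planted-QTL recovery
  uses $a_{cv} = 0.4$ (a CV ratio of $e^{0.8} \approx 2.2$ between genotype
  classes), which yields essentially complete power at 200 lines — the
  interesting quantity is localization, which is required to land within
  10 cM of the planted position in ≥90% of detections.
* With only 2 replicates per cell the CV estimator is noisy and biased low
  (the expected sample SD of a Gaussian pair is $\sigma\sqrt{2/\pi}$); the
  bias is flat across genotypes, so scans and heritability are unaffected,
  but absolute CV values should be read with this in mind.

# Known limitations

Single-QTL scans only (no multiple-QTL models, no epistasis); Haley–Knott
rather than EM mixture likelihood; biparental selfed RILs only (no F2,
backcross or outbred designs); Gaussian replicate noise in the generator;
the hotspot null treats grid positions as exchangeable unless weighted. The
heritability estimator assumes the per-experiment CV measures are
independent given the line, which holds in the simulated design but may be
optimistic when experiments share batches.
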