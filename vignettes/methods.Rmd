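---
title: "Models and methods behind fieldsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fieldsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldsel)
```

# The experimental design being modelled

A *sow-and-sequence* selection experiment sows equal numbers of seeds from
N inbred accessions at each field site (the default design: 200 accessions
× 40 seeds = 8,000 seeds per subplot, at 120 seeds per accession per m²)
and genotypes a sample of the individuals present one to two generations
later. Three things make the analysis non-standard:

1. sampled individuals must be *identified* against the panel from noisy,
   heavily missing low-coverage calls;
2. wild ("native") individuals of the same species occur inside the plots
   and must not contaminate fitness estimates — including the cryptic case
   where a native is genotype-identical to a panel accession collected
   nearby;
3. allele-frequency change must be judged against a null that mixes genuine
   drift (a small effective number of successful lineages) with binomial
   sampling noise of known size.

`fieldsel` implements the full chain, driven by a synthetic-data generator
so that every stage can be validated against known truth.

# The synthetic-study generator

`sim_config()` + `simulate_study()` generate: a structured panel, per-site
Wright–Fisher selection experiments, native-volunteer replacement, and
low-coverage degradation.

**Panel.** Genotypes follow a Balding–Nichols structured-population null:
per SNP an ancestral frequency is drawn Uniform(0.05, 0.95); each of the
`n_groups` groups draws its frequency from
Beta(π(1−F)/F, (1−π)(1−F)/F) with F = `differentiation`; accessions are
homozygous Bernoulli draws from their group frequency. This is the standard
generative null for differentiated populations; the default F = 0.2
produces pairwise-group Hudson F~ST~ ≈ 0.2, matching strong
group-level divergence. Collection coordinates are clustered by group along
a south-to-north gradient so genetic and geographic structure coincide, as
in the real collections.

**Selection and sampling.** Reproduction is modelled at the *accession*
level, not per SNP: stage 1 draws a multinomial of size Ne with
probabilities ∝ fitness/N (the surviving lineages), stage 2 draws the
`n_sample` genotyped individuals from the realized composition. Because
whole genotypes ride along with their accession, the genome-wide
correlations that population structure induces among SNPs arise naturally —
which is why neutral scans on these simulations show the band-like,
correlated deviations familiar from real data.

**Degradation.** Each homozygous call flips with `genotype_error_rate`
(default 0.005) and drops to missing with `missing_rate` (default 0.5,
reflecting genotyping of tiny field-collected rosettes). A configured
fraction of samples (default 8.8%) is made extensively heterozygous by
mixing in a second random accession's genome: at discordant sites, half the
calls (configurable) become heterozygous and the rest are called as either
allele at random. Outcrossing and physical sample contamination are
deliberately one class — the data cannot distinguish them, so neither does
the generator. A further 15.8% of samples are replaced by *native
volunteers*: homozygous draws from a random group's allele frequencies,
redrawn until their mismatch to every panel accession exceeds the
assignment threshold, so natives are identifiable by construction. Native
and heterozygous counts are **assigned** (rounded fractions of n, disjoint
sets), not sampled, so the truth record's class composition is exact.

**Seeding.** One root seed; every stage derives a labelled substream via
`derive_seed(seed, "stage:label")`, so adding a site or stage never
perturbs the draws of another. Identical configs give bit-identical
outputs.

**What the generator does not emulate:** read-level sequencing error
structure (errors are i.i.d. flips), linkage maps and recombination (inbred
lines transmit whole genomes), seed dormancy carried across years, and
dispersal between sites. Passing tests therefore validate the *inference
machinery* under the design's statistical structure, not robustness to
every artefact of real sequence data.

# Genotype assignment

For sample s and accession a, the mismatch rate is the fraction of
*informative* sites — sample call homozygous, accession call present — at
which the calls disagree; heterozygous and missing calls enter neither
numerator nor denominator. Classification order matters and follows the
genotyping workflow:

1. heterozygous-call fraction > `het_threshold` (default 0.05) →
   `heterozygous` — precedence over any match, since an extensively
   heterozygous individual cannot be a (selfed) experimental descendant
   however well half its genome matches;
2. best match supported by < `min_informative` sites (default 10,000) →
   `low_data`;
3. exact mismatch-rate ties at or below the threshold → `low_data` with
   both candidates reported: refusing to assign protects fitness estimates,
   which an arbitrary tie-break would bias;
4. unique best match with mismatch ≤ `mismatch_threshold` (default 0.015)
   → `experimental`; otherwise `native_volunteer`.

The 0.015 threshold is an empirically derived constant of the underlying
genotyping method and is taken as given; it is exposed in the API. The
10,000-SNP floor is the conservative real-data choice (5,000 random SNPs
already separate almost all pairs, as `min_snps_by_simulation()`
verifies on simulated panels); on down-scaled simulations the floor should
be scaled with the SNP count, e.g. 5,000 of 20,000 SNPs at 50%
missingness. With a 1% genotype error rate the expected observed mismatch
to the true accession (~0.010) sits only marginally below the 0.015
threshold — this is the stress regime the acceptance suite checks
(≥ 99% accuracy at 50% missingness on 50,000 SNPs).

The engine computes all samples × accessions mismatch and informative
counts with four matrix cross-products, so a full study assigns in seconds.

# The native-contamination filter

Identity decays fast with distance in this species' collections.
`ibd_decay()` bins genotype-identical/distinct pairs by great-circle
distance (haversine, Earth radius 6,371 km), fits a **monotone
non-increasing** curve by weighted pool-adjacent-violators — a parametric
family is deliberately not imposed, as no generating model for the decay is
known — and reports the smallest distance at which the fitted identity
probability drops below a floor, interpolating linearly between bin
midpoints. Identity between accessions reuses the 0.015 mismatch ceiling
rather than exact equality, tolerating genotyping error.

`flag_potential_natives()` flags accession × site pairs within
`cutoff_km` (default 5.6 km; boundary **inclusive**, the conservative
choice for an unspecified boundary). Missing coordinates yield an explicit
"unflaggable" record, never a silent pass. `flag_frequency_outliers()`
then excludes a potential native at its home site under either of two
modes, both exposed because the original exclusions were made by judgment:

- `ratio` (default): home frequency ≥ `min_home_freq` (0.10) **and**
  ≥ `home_away_ratio` (3.0) × its maximum away-site frequency;
- `top_home`: the potential native has the single largest frequency at the
  site.

A 33%-at-home accession with away frequencies of 5.0/2.4/7.8% is excluded
by the ratio rule (ratio 4.2); a 20%-at-home accession with an away maximum
of 7.3% (ratio 2.7) is caught only by `top_home`. Exclusion removes the
accession from the site's denominator and renormalizes the rest — other
accessions' counts are never altered.

# Fitness and exact pattern statistics

With equal sowing at 1/N, relative fitness is N × sampled frequency and
fold change is frequency/(1/N); both are computed over the
**experimental-class denominator** (natives, heterozygous and low-data
samples never dilute it). This is the estimand-consistent choice; zero
counts stay exactly 0 — fitness here is a frequency estimate, not a
likelihood, so no pseudocounts. Sites left with zero experimental samples
are dropped with a warning rather than silently producing NaNs.

Two exact statistics summarize cross-experiment group patterns:
`prob_any_group_extreme(k, m) = k(1/k)^m`, the chance under exchangeability
that *some* one group holds the same extreme rank in all m experiments
(tested against exhaustive enumeration of all k^m last-place sequences);
and `binomial_tail(s, t, p)`, the exact upper tail by summation — no
normal approximation, because the interesting values are ~10⁻⁵.

# The drift scan

Under neutrality, the experimental generation is a Wright–Fisher
multinomial of size Ne from the sown population, and the frequency estimate
adds binomial noise of known size n, giving E[Δp] = 0 and

$$\mathrm{Var}[\Delta p] = \left(\frac{1}{n} + \frac{1}{N_e} + \frac{1}{nN_e}\right)p_0(1-p_0).$$

The exact three-term form is used throughout (the cross term is negligible
at n ≥ 100 — under 2% of the total in this regime — but exactness is
free). A modelling nuance: for the literal two-stage generator
(with-replacement resampling of the realized composition) the cross term
enters with a minus sign; the difference, 2/(nNe), is orders of magnitude
below every tolerance used, and the package standardizes on the displayed
form.

`estimate_ne()` regresses per-SNP (Δp)² on p0(1−p0) **through the origin,
unbinned** — the variance law *is* the linear model, so binning would only
discard information — over SNPs with MAF ≥ 0.03 (the panel's SNP-filtering
floor), and inverts slope = 1/n + (1+1/n)/Ne. A slope ≤ 1/n (less
dispersion than pure sampling noise) is reported as invalid, never
inverted into a negative Ne.

`scan_z()` standardizes Δp by the null SD. Centring on the genome-wide
mean Δp is the default: panel-ascertained reference bias shifts all SNPs
coherently and would otherwise masquerade as signal. P-values are
**two-sided** normal tails (deviations in either direction are of
interest; a one-sided choice would be equally defensible and is obtained by
halving). SNPs with zero null variance (p0 ∈ {0,1}) are excluded and
counted. With the true Ne supplied, neutral simulations give z-variance
within [0.9, 1.1] and ~5% of SNPs at p < 0.05; the calibration acceptance
check runs at the largest-Ne site condition (Ne = 70, n = 199), where the
normal approximation to the binomial stages — the model's own assumption —
is adequate; at Ne ≈ 16 the discreteness of 16 surviving lineages makes
per-SNP normal tails rougher, a model limitation rather than an
implementation one.

`combine_experiments()` multiplies per-site p-values. The product is
reported as a **score** (with −log10), not a calibrated p-value — under
the null −ln(product) is Gamma(k, 1), and the optional `fisher_p` column
applies the corresponding chi-square transform for users who need
calibrated tails.

# The liability-threshold model

Accession i has Gaussian liability N(μᵢ, σ_site) and survives iff its
liability falls below the site threshold τ_site; a harsher site has the
lower threshold. Only two parameters are identifiable from paired survival
probabilities: α = (τ_A − τ_B)/σ_B and β = σ_A/σ_B, giving

$$p_B = \tfrac{1}{2}\,\mathrm{erfc}\!\left(\frac{\alpha}{\sqrt{2}} + \beta\,\mathrm{erfc}^{-1}(2p_A)\right).$$

α = 0, β = 1 is the identity map; α > 0 with β = 1 lowers survival
everywhere; the map is strictly increasing (0,1) → (0,1). The per-site
(τ, σ) and the μᵢ exist only in the simulator.

`fit_liability()` minimizes weighted least squares of observed harsh-site
survival against the map of observed mild-site survival, weights = harsh
trial counts (binomial precision; unweighted available since the original
fit's weighting is unknowable). Numerical choices: mild-site proportions of
exactly 0 or 1 are shrunk by a half-count correction (k+0.5)/(n+1) before
the inverse-erfc transform (the transform diverges at the boundary and the
original treatment is unstated); the optimizer is Levenberg–Marquardt
multi-started from a 7 × 5 grid over α ∈ [−3, 3], β ∈ {0.25, 0.5, 1, 2, 4}
with the best converged fit kept, because the erfc composition has local
minima for poor single starts; β is bounded below at 10⁻⁶. Degenerate
inputs (all mild survivals equal) are rejected as non-identifiable. An
accession subset argument supports fitting on a single ancestry group.
Observed mild-site survival enters as a noisy regressor
(errors-in-variables are ignored, as in the original fit); at 24 trials per
accession and a liability-mean spread of SD 1.5 — chosen to reflect the
multi-fold survival differences the design targets — the attenuation is
~3%, well inside the ±10% recovery tolerance the acceptance suite
enforces at 200 accessions × 24 trials.

# Pipeline, formats, and reproducibility

`run_pipeline()` chains simulate/load → validate → assign → natives →
fitness → scan → liability, writes every intermediate as TSV/CSV (genotypes
also as VCF: biallelic, 1-based, GT-only with placeholder REF/ALT — the
package works in 0/1 dosage space), and emits a JSON manifest (inputs,
parameters, seed, per-stage row counts) with no timestamps, so identical
configs give byte-identical output trees. Validation collects *all*
violations (SNP-grid congruence on (chrom, pos), coordinate ranges,
duplicate ids, undeclared sites) before any computation; allele-encoding
disagreements are an error, never silently flipped. Stage failures abort
naming the stage, with earlier outputs preserved. A thin wrapper
(`inst/scripts/run_pipeline.R`) exposes the same entry point to the shell;
the per-stage operations are plain exported functions, which is the
intended interactive interface.

# Problem sizes and what the tests show

The test and acceptance suites run the generator at 20,000 SNPs (50,000 for
the assignment stress case) with the design's sample sizes (n =
137–208, Ne = 16–70), 20 replicates for estimator-recovery medians and 10
for calibration means — sizes chosen so the full chain is exercised in a
few minutes on one core while leaving Monte-Carlo error far inside every
asserted tolerance. They demonstrate correct inference under the generator's
assumptions (structured panel, accession-level reproduction, i.i.d. call
degradation); they cannot certify behaviour under artefacts the generator
does not model, listed above.

# Known limitations

- The p-value product across sites is a ranking score; its null
  distribution is Gamma only under independence, which population structure
  violates in practice.
- Ne estimates under selection absorb selection-inflated variance and are
  biased low; the estimator is a *null calibration* device, not a
  demographic estimate.
- Heterozygous samples are classified but not used: parent identification
  for outcrossed individuals is out of scope.
- The isolation-by-distance cutoff mechanism is generic; the 5.6 km default
  is specific to the dense coastal collections that motivated it and should
  be re-derived (via `ibd_decay()`) for other systems.
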