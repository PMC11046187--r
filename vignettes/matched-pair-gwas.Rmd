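---
title: "Matched pen-mate GWAS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched pen-mate GWAS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penmateGWAS)
```

## The study design

Congestive heart failure in feedlot cattle clusters within pens:
pen-mates share ration, altitude, weather, management and time on feed.
A case-control design that ignores this shares its signal between
genetics and husbandry. The design supported here removes the shared
component by construction: each affected animal (case) is matched to an
unaffected pen-mate (control) from the same pen, and every statistic is
computed **within pairs**.

For one SNP and one definition of genetic exposure, each pair falls in
one of four quadrants:

|              | control exposed | control unexposed |
|--------------|:---:|:---:|
| case exposed | a | b |
| case unexposed | c | d |

Concordant pairs (a, d) carry no information about a within-pair
effect; only the discordant counts b (case-only exposed) and c
(control-only exposed) enter the test. Under the null hypothesis of no
association, b conditional on t = b + c is Binomial(t, 1/2).

## Exposure scenarios

A biallelic SNP with alleles a1 (major) and a2 (minor) is scored under
six scenarios: each allele crossed with three inheritance models —
*1-copy* (heterozygous carriers are exposed), *1-or-2 copies*
(dominant) and *2-copy* (homozygous carriers only). The scenarios are
not independent: exposure to one-or-two copies of a1 is exactly
non-exposure to two copies of a2, so those two scenario rows have b and
c swapped and identical p-values. `run_genome_scan()` computes all six
anyway because the odds-ratio orientation (risk vs. protective) differs
and downstream consumers filter on it.

## Test statistics

For a SNP with discordant counts (b, c), t = b + c, k = min(b, c), and
F, f the Binomial(t, 1/2) CDF and PMF:

- **mid-p**: `2 * (F(k) - 0.5 * f(k))`, capped at 1. The mid-p variant
  counts half the probability of the observed outcome, which removes
  most of the conservatism of discrete exact tests — important here
  because t is small (tens of pairs), so the p-value lattice is coarse.
- **exact conditional p**: `min(1, 2 * F(k))`.
- **chi-squared**: `(b - c)^2 / t`, and with continuity correction
  `(|b - c| - 1)^2 / t`, floored at 0 when `|b - c| < 1`.
- **odds ratio**: `b / c`, with Wald 95% CI
  `exp(log(b/c) ± 1.96 * sqrt(1/b + 1/c))`. When b or c is zero the OR
  and CI are flagged undefined rather than patched with a continuity
  constant; a Haldane-style +0.5 correction changes the estimate the
  matched design is built to report, so the package refuses to invent
  one.
- **Cohen's g**: `max(b, c) / t - 0.5`, an effect size on the
  probability scale.
- **per-marker risk-factor value**: `g * t / n_pairs` — the effect size
  damped by the proportion of pairs that were informative, intended as
  one additive component of a polygenic score.

```{r}
c(neglog10_mid_p = -log10(mcnemar_mid_p(42, 5)),
  g = cohens_g(42, 5),
  prs = prs_value(cohens_g(42, 5), 42, 5, 102))
```

All of these are computed by direct binomial-lattice evaluation, not by
normal approximation; `pbinom()`/`dbinom()` supply the numerics.

## SNP quality control

`apply_pre_filters()` drops SNPs before testing, attributing each
removal to the **first** failing filter in a fixed order:

1. minor allele frequency < 0.05 — rare variants give almost no
   discordant pairs and unstable ORs;
2. call-rate failures (missingness > 0.05);
3. Hardy-Weinberg exact mid-p < 1e-4, computed by full Levene–Haldane
   enumeration of the conditional distribution of heterozygote counts
   given allele counts (not the chi-squared approximation, which is
   unreliable at these sample sizes).

`apply_post_filters()` then removes scan rows with no discordant pairs
anywhere and SNPs on unmapped (0), Y and mitochondrial chromosomes; X
is kept because both pair members share a pen, not a sex guarantee, and
the matched test remains valid per pair.

## Multiplicity on a discrete lattice

Two controls are provided. The Bonferroni threshold is
`alpha / m_tests` (−log10 ≈ 7.05 at alpha = 0.05 over 561,683 tests).
Storey q-values need the proportion of true nulls, π0, estimated from
`pi0(lambda) = #{p > lambda} / (m (1 - lambda))` over a λ grid
(0, 0.95, step 0.01), using either the bootstrap minimum-MSE rule or a
cubic polynomial fit evaluated at the grid maximum. With π0 = 1 the
q-values reduce exactly to Benjamini–Hochberg adjusted p-values, which
is one of the package's invariant tests.

Because each SNP's p-value lives on its own discrete lattice (the t + 1
achievable values), a uniform Q-Q reference is wrong — it would make a
perfectly null scan look deflated. `discrete_null()` pools the
achievable p-values over all tested SNPs, weighting each by its exact
Binomial(t, 1/2) probability, and `qq_coords()` pairs deterministic
quantiles of that pooled distribution with the sorted observed
p-values.

## Population structure screening

`ibs_distance()` computes 1 − (shared alleles) / (2 × co-called SNPs)
over autosomes, and `classical_mds()` wraps `stats::cmdscale()` with a
deterministic sign convention (the largest-magnitude loading of each
axis is made positive) so that repeated runs and platforms agree.
Classical MDS is a solved linear-algebra problem; reimplementing the
eigendecomposition would only add bugs, so the package deliberately
delegates and confines itself to validation, truncation of
non-positive eigenvalues, and the sign rule.

## Two-locus risk classifier

`risk_tier()` enumerates the nine genotype configurations of two risk
loci into 1x / 8x / 28x risk tiers by the number of homozygous-risk
loci, with a breeding rank (1–5, by total risk alleles) and the
risk-allele transmission probability (25% per allele copy).
`combined_exposure_mcnemar()` treats "homozygous risk at both loci" as
a single exposure and reuses the McNemar machinery.
`predictive_values()` converts a classifier's sensitivity and
specificity to PPV/NPV at an assumed population prevalence via Bayes'
rule; at 5% prevalence even a classifier with good paired-design OR has
PPV near 0.10, which is the honest screening-use summary.

## Power analysis

A pair is discordant with probability ψ, and a discordant pair is
case-only with probability θ/(1 + θ) where θ is the discordant-pair
odds ratio. `simulate_power()` draws t ~ Binomial(n, ψ),
b ~ Binomial(t, θ/(1+θ)) and reports the rejection rate of the chosen
test (exact, mid-p, or continuity-corrected chi-squared).

`approx_power()` is the deterministic cross-check. A normal
approximation was considered and rejected: at the study's own operating
points (n = 102, α = 0.01) it disagrees with exact simulation by up to
0.07, which is larger than the agreement the simulator is being checked
against. Since the rejection region of every supported test is
computable on the (t, b) lattice, the power is instead summed exactly:

power = Σ_t P(t | n, ψ) Σ_{b : p(b,t) ≤ α} P(b | t, θ/(1+θ)).

This has no approximation error at all, so any simulator/analytic
disagreement beyond Monte-Carlo error is a genuine bug.

```{r}
sp <- power_spec(102, 0.25, 8.51, alpha = 0.01, test_variant = "exact")
c(simulated = simulate_power(sp)$power, analytic = approx_power(sp))
```

## Synthetic data generator

`generate_pairs()` produces seeded, reproducible matched-pair ped/map
data at study scale (default 102 pairs; ~10,000 SNPs runs in seconds).

- **Null SNPs**: each pair draws a pair-specific allele frequency from
  a Beta distribution whose intra-class correlation equals
  `within_pair_corr` (a Balding–Nichols-style device), then both
  members draw Hardy-Weinberg genotypes at that frequency. This makes
  pen-mates genetically more alike than random animals, which is the
  realistic stress test for a within-pair test: marginal tests would be
  confounded, the McNemar test should stay calibrated. The null suite
  verifies the mid-p values stay uniform on their lattice under this
  correlation.
- **Risk loci** are generated *exposure-first*: the exposure prevalence
  π0 is the Hardy-Weinberg prevalence of the risk genotype, the case
  member's prevalence is π1 = θπ0 / (1 − π0 + θπ0), members draw
  exposure independently, and genotypes are then filled in from the
  conditional Hardy-Weinberg distribution given exposure. This gives
  *exact* control of the discordant odds ratio the McNemar test
  estimates (E[b]/E[c] = θ), which is what makes parameter recovery a
  sharp test: 500 replicates at θ = 8 must recover a median OR near 8
  and CI coverage matching the analytically computed exact coverage.
  The cost is that within-pair correlation is not applied at risk loci;
  the package documents this rather than blurring the θ calibration.
- Alleles a1/a2 are assigned from realized frequencies (ties broken
  alphabetically), missing calls are injected at `missing_rate`, and a
  manifest attribute records the seed, risk SNP ids, risk alleles and
  target MAFs so tests can verify recovery without replaying generator
  internals.

Configurations whose implied exposure prevalence degenerates (0 or 1)
are rejected at `sim_config()` time rather than producing silently
untestable loci.

## Pipeline and reproducibility

`run_pipeline()` chains input (files or generator) → pre-filters → the
six-scenario scan → post-filters → per-scenario bootstrap q-values →
Manhattan and lattice-aware Q-Q coordinates, writing TSV artifacts and
a JSON run log. All randomness flows from a single seed; reruns are
byte-identical, which the test suite asserts file-by-file at full study
scale (102 pairs × 10,003 SNPs, ~10 s on one CPU). Plot outputs are
coordinate files, not images: numbers are a stable test surface,
rendered bytes are not.

## Limitations

- The Wald OR interval is undefined when b or c is 0; the package flags
  rather than corrects, so downstream consumers must handle the flag.
- HWE is tested on the pooled sample (cases + controls), matching the
  study protocol. A strong recessive risk locus enriches cases for the
  risk homozygote, producing a pooled heterozygote deficit — at a
  discordant OR of 8 with a common recessive allele, the pooled HWE
  mid-p can dip below the 1e-4 threshold and the filter removes the
  causal SNP. Controls-only HWE testing avoids this; users studying
  large recessive effects should consider relaxing `hwe_min` or
  pre-screening on controls.
- The generator's within-pair correlation applies to null SNPs only
  (see above).
- Linkage disequilibrium between SNPs is not simulated; spiked-locus
  retrieval tests single markers, not haplotype blocks.
- The two-locus classifier takes sensitivity/specificity as inputs; it
  does not re-derive them from genotype data.
- MDS sign conventions make axes reproducible but their orientation
  remains arbitrary in the usual MDS sense; only distances are
  meaningful.
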