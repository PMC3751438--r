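---
title: "Methods: the paired beta-binomial model and its evaluation harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the paired beta-binomial model and its evaluation harness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The evidence model

All detectors in `somaticpair` share one abstraction: at a locus (or region),
every quality-filtered read observation is a Bernoulli trial for exactly one
proposed genotype change — a base substitution to a specific alternate, an
insertion or deletion edit at an anchor, or (for structural variation) a
discordant mate-pair configuration. Counting trials `N` and successes `K`
reduces every evidence class, from single bases to fragment clusters, to the
same sufficient statistic, and the probability of the evidence under a
genotype class is a beta-binomial
`P(K | N, α, β) = C(N,K) B(K+α, N−K+β) / B(α, β)`.
The beta layer is essential: the true success proportion under, say, a
reference-homozygous genotype is not a known error rate but varies with
platform chemistry, alignment bias and local mappability, and the beta
spread absorbs exactly that overdispersion.

The normal genome is assumed diploid and scored against three genotype
classes; the tumor genome is deliberately **not** assumed diploid. Its
somatic class uses the flat beta `(1, 1)` — no expected allele fraction —
which is what keeps the caller sensitive to subclonal and admixture-diluted
variants, and its reference class is the error beta conjugately updated by
the normal counts, so deeper normal sequencing sharpens the null against
which the tumor is tested.

## Priors and tunables

Defaults (all overridable through `pair_priors()` and the `run_config()` /
detector arguments):

| parameter | default | meaning |
|---|---|---|
| `pi_ref`, `pi_het`, `pi_var` | 0.9985, 0.001, 0.0005 | diploid genotype priors; sum to 1 |
| `pi_somatic`, `pi_loh` | 1e-4, 1e-4 | per-locus prior of a somatic event / of LOH |
| `alpha_ref`, `beta_ref` | 1, 700 | error-skewed beta for reference-homozygous evidence (prior mean ≈ 0.14%) |
| `alpha_var`, `beta_var` | 700, 1 | mirror image for variant-homozygous |
| `alpha_nonhom`, `beta_nonhom` | 1, 1 | flat beta for heterozygous evidence |
| `alpha_somatic`, `beta_somatic` | 1, 1 | flat beta for the tumor somatic class |
| `alpha_ai`, `beta_ai` | 1, 1 | flat beta for the allelic-imbalance het class |
| `min_mapping_quality`, `min_base_quality` | 10, 10 | inclusive Phred filters (a read at exactly 10 is kept) |
| `min_coverage` | 5 | filtered depth required in *each* sample; shallower loci are skipped and counted |
| `emission_threshold` | 0.5 | posterior above which a candidate call is emitted |
| `phred_cap` | 255 | ceiling on reported `−10·log10(1 − posterior)` |
| `max_depth` | 10,000 | pileup depth cap, bounding cost at pathological stacks |

When a detector restricts the genotype classes (the tumor side uses only
{reference, somatic}; LOH only {heterozygous, homozygous}), the binary
posterior weights the event class by its π against the complement
`(1 − π)` — the displayed ratio normalises itself through its denominator,
so the three-class π values are never renormalised.

## Filters

Observations below the quality thresholds, or with an uncalled base, never
become trials. Two further points follow alignment-format semantics:
positions inside a deletion contribute no substitution trials (their base is
a gap), and indel evidence is anchored at the reference base immediately
preceding the left-aligned event, a read spanning the anchor without the
edit counting as a failure. The optional strand-bias filter requires at
least one supporting read per direction; a failing call is *retained* with
the filter named in its `filters_failed` / VCF `FILTER` field, because
re-filtering downstream is cheap and resurrecting suppressed records is not.
BAQ-style adjusted base qualities are consumed (never recomputed) in the
observation-level path via `filter_observations(use_adjusted_quality =
TRUE)`; the BAM count path filters on raw base quality only, a documented
limitation of the pileup engine behind it. Overlapping mates are counted as
independent trials — a simplification that slightly overstates evidence at
short-fragment loci.

## Loss of heterozygosity: the update flag

The LOH score is `P(het_n | D_n) × P(¬het_t | het_n, D_t)`. For the
heterozygous-tumor likelihood there is a genuine design fork. Conjugately
updating the flat het beta with the normal counts (the exact analogue of the
somatic formula) makes the test sharp: a clean 30/60 normal het whose allele
disappears from a 60-read tumor pileup scores above 0.99. But the relative
alignment affinity of two alleles shifts systematically between libraries
and pipeline versions, and propagating the normal's exact allele ratio into
the tumor expectation turns every such systematic shift into a confident
false positive. `update_het` therefore defaults to `FALSE`: the flat het
model is immune to those shifts, at the cost that the hom/het likelihood
ratio is then bounded (≈ `beta_ref`) and posteriors cap near
`beta_ref · pi_loh` ≈ 0.065 — the flat model ranks candidate loss sites
rather than certifying them. Analyses on well-matched libraries should set
`update_het = TRUE`; the package's own engineered-loss checks run in that
mode because only there is the >0.99 operating point attainable.

## Allelic imbalance

`ai_bayes_factor()` compares, at a heterozygous locus, a *tied* model (test
sample's allele proportion equals the reference sample's: het beta updated
by the reference counts) against an *independent* model (flat het beta),
marginalised over the three genotype classes with their priors — the
homozygous terms are common to both models and cancel as the het posterior
approaches 1. The orientation is fixed and documented in the output:
`K > 1` favours tied proportions (no imbalance), `K < 1` favours
independence (imbalance). Per-transcript aggregation multiplies locus Bayes
factors, i.e. assumes loci are independent within a transcript; with linked
reads spanning several heterozygous sites this overstates evidence, so the
per-transcript posterior odds should be read comparatively. The module is
experimental: there is no truth system for allele-specific shifts against
which its priors could be calibrated.

## Structural variation

Fragments are classified against a robust insert model (median and
normal-consistent MAD of proper FR fragments, spread floored at 1 bp) into
exactly one of: translocation (mate on another contig), inversion (FF/RR
orientation), large deletion (proper orientation, insert beyond
median + 5·spread), or concordant. The multiplier 5 is conservative — at
MAD-consistent scale it admits essentially no concordant fragments — because
a missed large deletion costs less than a flood of borderline candidates.
Abnormal fragments of one subclass are single-linkage clustered along the
reference with a 1,000 bp gap window (about three insert lengths for a
standard short-fragment library); translocation clusters must additionally
co-cluster their mates within the window on one contig, and a lone
inter-contig pair is never a cluster. Candidate regions need 3 supporting
tumor fragments before scoring. Each region's per-sample fragment counts
(all overlapping fragments as trials, subclass fragments as successes) go
through `somatic_sv_probability()`, which *is* `somatic_probability()` — the
shared code path is itself under test. Clusters are reported in the
tab-separated events catalog, not the VCF: focal variants and large events
have different consumers, and symbolic breakend records help neither.

## The simulator: what it emulates, and what it does not

`generate_pair()` draws, per site: a germline genotype (deterministic class
counts per the configured fractions, shuffled across sites), reference and
alternate bases, Poisson depths, and per-base read counts in which each read
miscalls uniformly to one of the three other bases with probability
`error_rate`. Germline sites present the same allele fraction in both
samples (0, 0.5, 1); somatic sites are heterozygous in the tumor clone, so
their tumor allele fraction is `0.5 × purity`. `admix()` implements purity
the way a read-mixing experiment does: each site's tumor pileup is resampled
at its original depth, drawing reads without replacement from the tumor and
normal pools with probability `ratio` / `1 − ratio`, holding total
throughput constant. `downsample()` is binomial thinning;
`coverage_grid()` derives every coverage level by *nested* thinning from one
128× generation, so the levels share reads and the measured trend reflects
coverage rather than re-simulation noise. `emit_bam_fixtures()` realises
every generated count as an aligned read in indexed BAMs (sites spaced so no
read spans two sites), which is what lets the end-to-end tests demand exact
agreement between the BAM walker and the generator.

Reference conditions (the `sim_config()` defaults): 12,000 independent
sites — 1,000 somatic, 5,500 germline heterozygous, 500 variant-homozygous,
5,000 reference — at 128× mean depth in both samples with a 0.1% per-base
error rate. The composition provides ≥5,000 true negatives of each
false-positive source (reference sites for error-driven calls, germline-het
sites for miscalled SNPs) alongside a somatic truth set large enough that
1 site is 0.1% of sensitivity; 12,000 sites keep the full 5×5 coverage grid
and the purity sweep in the low tens of seconds.

Deliberately absent from the generator: sequence-context error structure,
mappability and coverage heavy-tails, and linkage between sites. Passing
its experiments therefore demonstrates the statistical engine — error
absorption, the conjugate-update benefit of normal coverage, purity
dilution — not robustness to alignment artifacts, which on real data is
carried by the quality filters and the strand-bias filter. One consequence
is worth stating plainly: with Poisson(128) depth, a purity-0.5 somatic
site carries ~32 variant reads and is essentially never missed, so the
sensitivity contrast between pure and half-pure tumors at 128× is close to
zero here; on real data that contrast is driven by the coverage
distribution's lower tail, which this generator intentionally does not
model.

## Measurement operating points

Two thresholds appear in the evaluation harness, on purpose. The
coverage-grid experiment scores *confident* calls (Phred quality > 20,
posterior > 0.99) — the stratum a study would carry into validation. The
purity sweep measures sensitivity over *all emitted candidates*
(posterior > 0.5, the caller's emission threshold): at 10% purity a somatic
site presents ~6–7 variant reads in 128, which a >0.99 posterior cannot
certify under this model (that requires ~10), while the candidate list still
recovers about half of the truth set — the quantity the sweep is designed to
track. The quality-20 stratification remains available via
`evaluate_calls(quality_threshold = 20)` on any call set.

## Numerical choices

All likelihoods are computed in natural-log space (`lchoose` + `lbeta`) and
combined by log-sum-exp, so posteriors are exact to double precision at
pileups of 10⁶ trials. Subclass ties break on a fixed order
(A < C < G < T, then insertion, then deletion) to keep calls deterministic.
Phred qualities cap at 255; VCF records print the posterior at full double
precision so `QUAL = −10·log10(1 − PP)` survives the round trip to 0.01.
Degenerate inputs are contracts, not crashes: `k > n`, non-positive
hyperparameters and malformed priors raise errors; loci under the coverage
gate are skipped and counted in the run report; an empty call set still
yields a valid header-only VCF.

## Known limitations

Indel calling through the BAM count path uses the pileup engine's
insertion/deletion marks at each position, which is coarser than the
observation-level anchor semantics (exact anchored counting is available
via `summarize_pileup()` on observation tibbles). Mate de-duplication is
not performed. The allelic-imbalance module's prior odds are uncalibrated.
The simulator's omissions listed above bound what its green checks imply
about real libraries.
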