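---
title: "Conjugate-Beta model selection for introgression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conjugate-Beta model selection for introgression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfbf)
```

## The four-taxon model

The package works on the classic configuration `(((P1, P2), P3), O)`: two
sister taxa, a candidate donor, and an outgroup used to polarize alleles.
Every analysis starts from *polarized biallelic sites*: alignment or VCF
columns where exactly two alleles are observed and the outgroup is
monomorphic. The outgroup allele is labelled ancestral ("A"); the other
allele is derived ("B"); frequencies `p1, p2, p3` are derived-allele
fractions among non-missing calls per taxon. Sites failing the filters are
dropped with a counted reason (`monomorphic`, `multiallelic`,
`outgroup-polymorphic`, `insufficient-data`) rather than silently.

Two polarization details were genuinely open and are resolved as follows.
First, when the outgroup is monomorphic for the *globally minor* allele,
the outgroup allele is still ancestral — the filter conditions only on
outgroup monomorphism, not on global allele counts. Second, missing data is
handled per taxon: frequencies are computed over observed calls, and a site
is dropped only when some taxon has no observed call at all. This matches
how allele-frequency-based window scanners behave and avoids discarding
sites for sporadic missingness.

Per site, the frequency-weighted sharing patterns are

* `abba = (1−p1)·p2·p3`, `baba = p1·(1−p2)·p3` — the two introgression
  patterns;
* `bbaa = p1·p2·(1−p3)` — the species-tree pattern, used as the neutral
  background signal;
* `d13 = p1(1−p3) + p3(1−p1)` and `d23` analogously — per-site average
  pairwise differences. We adopt this standard expansion of the pairwise
  difference; with it, `p2·d13 = abba + bbaa` and `p1·d23 = baba + bbaa`
  exactly, which is what links the distance form of df to its
  pattern-count form. Both identities are enforced by tests to 1e−12.

## From df to a model-selection problem

The df estimator, `Σ(p2·d13 − p1·d23) / Σ(p2·d13 + p1·d23)`, estimates the
introgressed fraction well but its failure mode is structural: whenever one
of the two summed terms is zero — typical in low-recombination,
low-diversity windows with a handful of SNPs — df is ±1 regardless of
whether one site or one thousand support it. The remedy implemented here
is to treat the window as a choice between two models, M_ABBA (P2↔P3
sharing) and M_BABA (P1↔P3 sharing), each a Beta distribution over a latent
share parameter, with shapes accumulated from the data:

* `alpha_abba = λs · Σ p2·d13`, `alpha_baba = λs · Σ p1·d23`,
  `beta_bbaa = λs · Σ bbaa`.

`λs` converts the dimensionless frequency sums into pseudo-observation
counts; it is set to the average number of haplotypes sampled from P1–P3
(the scan derives it from the site table's per-taxon call counts unless
overridden). The symmetric Beta(λp, λp) prior encodes "no evidence yet";
each model's log marginal evidence is

`L = logΓ(λp + α) + logΓ(λp + β) − logΓ(α + β + 2·λp)`,

computed with `lgamma()` only — no raw Γ is ever evaluated, so shapes up to
1e7 and beyond remain finite. The Bayes-factor-style evidence is the
exponentiated ratio of the two log marginals, anchored at 1:
`df-BF = exp(L_num/L_den) − e + 1`, with the numerator chosen by the sign
of df and `df-BF = 1` when df is 0. The ratio-of-logs construction is kept
exactly as the method defines it (it is not a textbook marginal-likelihood
ratio); its fixed exponential scaling is what makes Jeffreys' bins
applicable.

Because both models contain the BBAA signal, the supported model's shape
ratio `α/(α+β)` lives on `[0.5, 1]`; the estimator maps it back to the full
range: `dfθ = α/(α+β)/0.5 − 1`, and 0 when df is 0. The λs factor cancels
in this ratio — a property asserted over the grid {1, 10, 46, 100, 1000} —
and `dfθ` uses the raw shape ratio without the prior pseudo-counts,
implementing the estimator's stated form literally rather than the
posterior mean `(α+λp)/(α+β+2λp)`; for the shape magnitudes a real window
produces (λs × tens of sites) the two differ negligibly, and keeping the
literal form preserves the exact `dfθ = 1` endpoint at `β = 0`. With
`signed_theta = TRUE` windows supporting M_BABA report a negative dfθ,
which is convenient for plotting scans with both directions of gene flow.

### Tunable parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `lambda_s` | pseudo-observation scale | mean haplotypes of P1–P3 | shapes grow with real sample size |
| `lambda_p` | prior pseudo-count | `lambda_s` | conservative: evidence needs ~50 fully introgressed SNPs to become very strong |
| `width`, `step` | window geometry (bp) | 10 kb, consecutive | matches the scale at which scans are usually read |
| `signed_theta` | sign convention for dfθ | `FALSE` | keep the estimate a fraction in `[0,1]` |

Lowering `lambda_p` makes the test more sensitive: with `lambda_p = 5` and
`lambda_s = 100`, ten fully introgressed SNPs already exceed the
very-strong threshold of 30 (`bf_curve()` reproduces the whole calibration
surface deterministically). `df-BF` below 1 can occur when the evidence
ratio inverts; such values are reported as computed and labelled
"no evidence" rather than clipped.

### Numerical edge cases

* df = 0 is detected at |df| ≤ 1e−12; the zero branches of df-BF and dfθ
  then apply exactly (1 and 0).
* A window whose df denominator is zero has no sharing signal at all; df,
  dfθ and df-BF are all reported `NA` — missingness is never conflated
  with "no introgression", since that conflation is precisely the df
  failure mode the method fixes. The `bf_curve()` experiment is the one
  deliberate exception: its `n_snps = 0` rows report df-BF = 1, because in
  that design zero supporting SNPs means the two models are
  indistinguishable by construction.
* If the ratio's denominator log marginal is itself within 1e−12 of zero
  (possible only in contrived prior settings), the Bayes factor is
  reported as `Inf` with a warning instead of dividing.

## The synthetic-data generator

`simulate_four_taxon()` emulates the validation design the comparators are
usually tested on: 5-kb four-taxon loci with splits at `t12 = 1`,
`t123 = 2`, `t123O = 3` (times in 4N generations), a single gene-flow pulse
P3→P2 at `t_gf = 0.1` moving a fraction `f` of lineages, and a mutation
branch-scaling of `s = 0.01` substitutions per site per 4N unit. It is a
structured Kingman coalescent written for exactly this demography: within
each population `k` lineages coalesce at total rate `k(k−1)` (ms time
scaling), the pulse moves each recipient lineage to P3 with probability
`f` backwards in time, and populations merge at the split times. Mutations
are Poisson on total branch length under infinite sites. Eight haplotypes
are sampled per taxon by default — enough for intermediate frequencies
without slowing the sweeps; the simulated 5-kb loci carry a few hundred
SNPs, comfortably above the tens-of-SNPs density of real 10-kb scan
windows.

Two deliberate simplifications, and what they imply for the tests:

* **Infinite sites instead of HKY.** The statistics consume biallelic
  frequencies only, so the substitution model is second-order; but finite
  sites homoplasy is absent. One visible consequence: at `f = 0` most
  replicates contain *no* ABBA/BABA-weighted site at all (a single
  genealogy under near-complete lineage sorting), so Patterson's D is
  undefined in ~90% of null replicates rather than scattered around 0,
  while df and dfθ are 0 there through their BBAA-bearing denominators.
  Passing tests therefore say nothing about D's null distribution under
  homoplasy-rich sequence evolution.
* **Independent-locus recombination.** The ms-style total recombination
  parameter (default `r = 0.01` over 5 kb — effectively zero) is honoured
  by splitting the locus into `1 + Poisson(r)` independently coalescing
  segments rather than by a full ancestral-recombination graph. At the
  default this is indistinguishable from no recombination; it is not a
  model of tight linkage decay.

The generator's defaults are the study conditions; the estimator-recovery
checks run 100 replicates per grid point (`f ∈ {0, 0.25, 0.5, 0.75, 1}`,
and 100 replicates at `f = 0.3` for the D-overestimation contrast) with
fixed seeds, which completes in seconds and keeps medians stable to well
within the ±0.1 tolerance used. `sweep_experiment()` produces the long
table behind these checks, and `sweep_errors()` the SSE/RMSE/MAE summaries.

## The comparators

Patterson's D and Dp are computed from the same window sums
(`(ABBA−BABA)/(ABBA+BABA)` and `(ABBA−BABA)/(ABBA+BABA+BBAA)`). fd uses
the dynamic-donor construction: the denominator recomputes the D numerator
with `pD = max(p2, p3)` substituted for *both* p2 and p3, following the
statistic's original definition. fd is defined for an ABBA excess; windows
with a negative numerator are evaluated on the mirrored configuration
(P1 as recipient, donor `max(p1, p3)`), reported with a negative sign and
flagged `fd_mirrored` so downstream consumers can tell the two regimes
apart.

## Known limitations

* Four taxa, one donor pulse; no f-branch style multi-donor attribution.
* No block-jackknife significance machinery for D — evidence assessment is
  the point of df-BF itself.
* The simulator is a validation instrument, not a general coalescent: no
  continuous migration, population-size changes, or ARG-scale
  recombination.
* dfθ inherits df's sensitivity to branch lengths and effective population
  sizes; λs/λp calibrate evidence, not the estimator's bias.
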