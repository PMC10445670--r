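# ystrkit

Forensic Y chromosomal short tandem repeats (Y-STRs) are paternally
inherited as a haplotype, so a panel of Y-STR loci identifies a
patrilineage rather than an individual. Two quantities govern their
casework value: how well haplotypes discriminate unrelated men in a
population, and how often an allele mutates between father and son.
`ystrkit` implements both sides for a 41-locus multiplex (33
single-copy markers plus the dual-copy markers DYF387S1a/b,
DYF404S1a/b, DYS385a/b and DYS527a/b), for forensic geneticists
working with capillary-electrophoresis or sequence-based Y-STR data.

## What it computes

**Haplotype statistics** over configurable panels (minimal haplotype,
SWGDAM, Yfiler, PowerPlex Y23, Yfiler Plus, Ymax, full kit), by mere
counting over samples with valid data:

- gene diversity / haplotype diversity
  `GD = [n/(n−1)] (1 − Σ pᵢ²)` over allele (resp. haplotype)
  frequencies pᵢ;
- discrimination capacity `DC = N_diff / n`;
- fraction of unique haplotypes `F_UH = N_unique / N_diff`;
- the full sharing spectrum and shared-haplotype membership lists.

**Mutation-rate estimation** from father–son pairs under the stepwise
mutation model: per-locus mutation counts, step sizes (one-, two-,
multi-step) and directions (gain/loss); rate `μ̂ = mutations /
transfers` where a dual-copy marker contributes two allele transfers
per meiosis; exact binomial (Clopper–Pearson) confidence intervals
`[B(α/2; k, n−k+1), B(1−α/2; k+1, n−k)]`. Dual-copy genotypes are
matched by the copy assignment minimizing (mutated copies, total
steps); DYS389II is scored on the adjusted value II − I so DYS389I
events are not double-counted.

**Repeat-structure parsing**: bracketed nomenclature such as
`[TAGA]11 [CAGA]2 N48 [TAGA]11 [CAGA]4` is parsed into repeat blocks,
single units and spacers; allele designations (including microvariants
such as DYS448 19.2 from a 4-bp spacer deletion) follow per-locus
counted-block rules; sequence alleles are classified as repeat-region
(RR) isoalleles vs. flanking-region (FR) variants.

**Mutation-pattern analyses**: pooled rates by repeat-unit length,
motif complexity and allele size class (25/50/25 short/moderate/long
cut of the frequency spectrum), rate-on-repeat-number regression, and
paternal-age analysis (Welch t-test, per-age regression, 10-year age
intervals).

**Synthetic data**: a pedigree simulator with per-locus allele
spectra, per-locus rates, a stepwise step distribution,
size-dependent gain/loss bias and father ages, logging every planted
mutation so the detector can be validated end-to-end.

## Worked example

Rates and exact intervals from the shipped reference per-locus count
table (2,548 Northern Han Chinese father–son pairs, 104,468 allele
transfers):

```r
library(ystrkit)
rates <- mutation_rates_from_counts(reference_mutation_counts())
subset(transform(rates, rate_e3 = rate_e3(rate),
                 ci = sprintf("%.1f-%.1f", rate_e3(ci_lower), rate_e3(ci_upper))),
       locus %in% c("DYS392", "DYS627", "Total"))[, c("locus", "transfers",
                                                      "mutations", "rate_e3", "ci")]
#>     locus transfers mutations rate_e3       ci
#> 7  DYS392      2548         0     0.0  0.0-1.4
#> 29 DYS627      2548        32    12.6 8.6-17.7
#> 38  Total    104468       356     3.4  3.1-3.8
```

DYS627 shows 32 mutations in 2,548 transfers: a rate of 12.6 × 10⁻³
with exact 95% CI 8.6–17.7 × 10⁻³ (a Wald interval would print a lower
bound of 8.2, so the exact method is visible at the reported
precision). DYS392, with zero observed mutations, gets a CI whose
lower bound is exactly 0.

Forensic parameters recomputed from a printed sharing spectrum (2,387
haplotypes seen once, 73 twice, 5 three times):

```r
haplotype_summary_from_spectrum(c(1, 2, 3), c(2387, 73, 5))
#> Haplotype summary
#>   n = 2548 (0 excluded for missing data)
#>   N_diff = 2465, N_unique = 2387
#>   F_UH = 0.9684, HD = 0.999972880, DC = 0.9674
```

So 96.84% of distinct haplotypes are unique and 96.74% of sampled men
carry a distinct haplotype.

A simulated cohort with known rates, detected by the same engine:

```r
cfg <- sim_config(n_pairs = 300, seed = 42)
sim <- simulate_pairs(cfg)
mutation_summary(sim$pairs)
#> Y-STR mutation summary: 44 mutations in 12300 allele transfers from 300 pairs
#>   overall rate 3.6 x10-3 (95% CI 2.6-4.8)
#>   40 pairs (13.33%) carry at least one mutation
```

Every detected event can be checked against `sim$truth`, the planted
ground-truth log.

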