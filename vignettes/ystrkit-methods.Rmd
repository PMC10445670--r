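---
title: "Methods and design of ystrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of ystrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrkit)
```

## Scope and data model

`ystrkit` analyses Y chromosomal STR data at two levels: population
haplotype statistics from unrelated males, and mutation-rate
estimation from confirmed father–son pairs. Alleles arrive pre-called
as repeat numbers (CE or sequence-derived); the package does no signal
processing. The locus registry describes the 41-locus multiplex: 33
single-copy markers and four dual-copy markers (DYF387S1a/b,
DYF404S1a/b, DYS385a/b, DYS527a/b), each dual-copy marker contributing
two allele copies per male and two transfers per meiosis. The registry
and the panel definitions are editable CSV configuration, because
panel composition is a kit-level convention rather than a property of
the method.

## Input validation

The readers accept the tabular dialect common to Y-STR calculators:
sample ID in the first column and one column per marker, with
dual-copy genotypes comma-separated (`13,13` homozygote, `13,20`
heterozygote); pedigree tables carry two rows per pair tagged `P`
(father) and `O` (offspring) plus an optional `BirthYear` column, the
father's age at gametogenesis being the difference of the two birth
years. Validation rules: alleles must be positive numbers with at most
one decimal place (`14.0` equals `14`; `23.2` is an intermediate
allele; `23.25` is rejected); anything else — non-numeric text,
non-positive values, wrong copy counts, empty cells — is excluded from
every downstream statistic, never imputed, and logged with exactly one
QC message per ignored cell. Two deliberate choices:

- a *single* value at a dual-copy marker is read as a homozygous pair
  (the single-peak convention of CE electropherograms) and flagged
  with an informational note rather than excluded;
- an invalid genotype drops that locus *for that pair only* — the
  pair remains usable elsewhere. Whole-pair exclusion would discard
  good data for no statistical benefit; the per-locus transfer count
  drops by the marker's copy number, which the tests verify.

## Haplotype statistics

Frequencies are maximum-likelihood counts. Gene diversity uses the
unbiased estimator

$$GD = \frac{n}{n-1}\Bigl(1 - \sum_i p_i^2\Bigr),$$

which is also the haplotype diversity HD when applied to haplotype
frequencies; discrimination capacity is $DC = N_{diff}/n$ and the
fraction of unique haplotypes $F_{UH} = N_{unique}/N_{diff}$. A
haplotype is the ordered tuple of canonical genotype strings over the
panel loci, with dual-copy genotypes sorted ascending first, so the
statistics are invariant to copy order and row order. Samples missing
any panel locus are excluded from that panel's haplotype statistics
(and counted); exclusion is the conservative choice when the
alternative is inventing alleles. $F_{UH}$ is reported as `NA` when
fewer than two distinct haplotypes exist, since a fraction of unique
haplotypes among one haplotype is not meaningful.

One known numerical discrepancy is documented rather than matched:
recomputing HD from the reference full-kit sharing spectrum (2,387
haplotypes seen once, 73 twice, 5 three times; n = 2,548) with the
formula above yields 0.9999729, whereas the reference summary prints
0.999956608. The package always reports the value implied by the
stated formula.

## Mutation detection and rate estimation

Single-copy comparison is direct: the step is the absolute repeat
difference, a gain when the son's allele is larger. Non-integral
differences (e.g. 19 → 19.2, a flanking-indel microvariant) are
counted as one mutation with the step rounded to the nearest whole
unit and flagged `nonstepwise`; a fractional-only difference records
step 0 with the flag. Steps are reported as one-, two- and multi-step
(≥3) with the raw spectrum retained.

Dual-copy genotypes are unordered, so the father–son copy
correspondence is unobserved. Of the two possible pairings the
detector takes the one minimizing first the number of mutated copies,
then the total step count — the parsimony reading of the stepwise
mutation model (e.g. {15,16} → {16,17} is one two-step event, not two
one-step events). The property tests check this against exhaustive
pairing enumeration. A consequence, reproduced deliberately by the
simulator tests: when both copies truly mutate in a compensating
pattern, parsimony may merge them, so detected events can only ever
undercount the simulated truth.

The DYS389II amplicon contains the DYS389I repeats. DYS389II is
therefore scored on the adjusted value II − I, isolating the
II-specific stretch, while the raw II comparison is retained as a
diagnostic; a record with II < I is flagged inconsistent and the pair
is skipped at both loci. All four alleles must be present for either
locus to count, which keeps the adjusted comparison well-defined.

Rates are $\hat\mu = k/n$ mutations per transfer, with dual-copy
markers counting two transfers per meiosis, reported on the
conventional ×10⁻³, one-decimal scale. Confidence intervals are exact
Clopper–Pearson intervals via the beta-quantile closed form,

$$\bigl[\,B_{\alpha/2}(k,\; n-k+1),\; B_{1-\alpha/2}(k+1,\; n-k)\,\bigr],$$

with the lower bound exactly 0 at $k=0$ and upper bound exactly 1 at
$k=n$. The implementation is cross-checked against
`stats::binom.test` and its empirical coverage is verified by
simulation at cohort-scale n and realistic rates; exact intervals are
conservative, so coverage is at or above the nominal level. At the
reported precision the exact interval is distinguishable from a normal
approximation (DYS627, 32/2548: exact lower bound 8.6 × 10⁻³, Wald
8.2 × 10⁻³).

## Repeat-structure parsing and designation rules

The parser accepts whitespace-separated tokens: `[MOTIF]k` repeat
blocks, bare uppercase motifs (single units, count 1) and `Nk` fixed
spacers. Lowercase segments, used in published tables to spell out
spacer sequence, are normalized to spacers of their base length with
the raw text preserved, so serialization round-trips. Malformed tokens
fail with their position.

An allele designation is the sum of repeat-block counts plus counted
single units; spacers never count. Two per-locus conventions are
configuration, seeded from the arithmetic of the shipped structure
table and flagged provisional where only one example exists:

- *excluded single units*: at DYS460 the `GTAT` interruption is not
  counted (`[CTAT]9 GTAT CTAT` designates 10, not 11), while at
  DYS437 both `TCTG` and `CCTG` count;
- *canonical spacer lengths*: where a locus defines one (DYS389II:
  48 bp; DYS448: 42 bp), a deviation folds into the designation in
  base pairs: with unit length $u$, counted repeats $c$ and deficit
  $d$, the designation is $\lfloor (cu-d)/u \rfloor$ whole repeats
  with the remainder as decimal suffix — reproducing DYS448 19.2 from
  a 4-bp spacer deletion.

Sequence alleles are compared as: same designation but different
repeat-region block structure → RR variant (isoallele); differing
flank-variant labels → FR variant; differing designation → length
difference. For compound/complex markers the mutated block is
classified relative to the father's variable blocks: the event is
`larger_unit` when the changed block carries the largest repeat count
among the father's repeat blocks (ties included — the reading
consistent with both worked examples available), `smaller_unit`
otherwise, `both` when two or more blocks changed.

## Pattern analyses

Allele size classes cut the sorted frequency spectrum at cumulative
0.25 and 0.75 into short/moderate/long; a boundary allele joins the
class holding the majority of its mass (ties to moderate; a lone
allele is moderate). The rule is rank-based, so it is invariant to
monotone shifts, and each class mass is within one allele's frequency
of its 25/50/25 target.

Grouped rates are *pooled*, $\sum k_\ell / \sum n_\ell$ over the
group's loci — a transfer-weighted mean bracketed by the group's locus
rates — not an unweighted mean of rates; pooling is what reproduces
the reference per-class values from the per-locus counts (tri 1.8,
tetra 4.1, penta 1.5, hexa 0.4 ×10⁻³; simple 2.7, compound 3.7,
complex 5.2 ×10⁻³). Transfers at a size class are attributed by the
*father's* allele, the allele actually at risk during transmission
(switchable in principle; the son's allele would shift boundary events
only).

The motif-complexity assignment (simple/compound/complex) for all
markers is shipped as provisional, editable configuration: the full
assignment is not derivable from the shipped structure table alone, so
the default is the assignment consistent with the reference pooled
per-class rates given the per-locus counts, anchored by the markers
whose structures are known (e.g. DYS438, DYS460, DYS533 simple;
DYS389II, DYS448, DYS635, DYF387S1a/b complex).

Regression of rate (×10⁻³, for slope comparability across studies) on
the frequency-weighted mean allele repeat number uses ordinary least
squares, with the initially defined rapidly mutating loci optionally
excluded, since their rates are outliers relative to the repeat-number
trend. The paternal-age analysis reports the age summary, a Welch
two-sample t-test of mutated vs. non-mutated pairs (degenerate groups
give `NA`), a transfer-weighted regression of per-age-year pooled
rates on age, and pooled rates within the 10-year intervals <20,
20–30, 30–40, >40. Chi-square tests are computed without continuity
correction and a Fisher exact test is always reported alongside
(Monte-Carlo for r×c tables, with an explicit seed, so every p-value
is reproducible bit-for-bit).

## The synthetic-data generator

The simulator draws fathers i.i.d. per locus from configured spectra
and transmits every allele copy independently: mutation with the
per-locus rate (optionally modulated log-linearly by father age), step
size from the mixture (one-step 344/356, two-step 8/356, remainder a
geometric ≥3 tail), direction from size-class-conditional gain
probabilities, reflection at zero so repeats stay positive. The
default profile uses the reference per-locus rates; spectra are
geometric-decay spectra (decay 0.45, halfwidth 3) around each locus'
typical modal allele, which gives realistic per-locus diversities and
a non-degenerate size-class structure; gain probabilities 0.65 / 0.50
/ 0.35 for short/moderate/long make direction size-dependent while
keeping the overall gain:loss ratio near balance, as observed in
cohort data. These defaults are illustrative of a large paternity
cohort, not a reconstruction of any particular one. The nested DYS389
pair is simulated coherently: DYS389I and the II-specific stretch
mutate independently and raw II is their sum, so a DYS389I event
shifts raw II without constituting a II event — exactly the situation
the adjusted scoring must handle.

Every planted event is logged, enabling exact end-to-end recovery
tests (detection equals truth except for parsimony-merged dual-copy
coincidences, where detection is provably a lower bound).

What the simulator does *not* emulate: linkage between loci (each
locus is independent, whereas real haplotypes carry phylogenetic
correlation), missing data and typing artifacts (added only by the QC
fixtures), microvariant creation, and population structure. Passing
recovery tests therefore validates the estimators' correctness and
calibration, not robustness to real-data artifacts — those paths are
exercised separately by the QC fixtures.

## Numerical choices and problem sizes

Allele equality uses one-decimal fixed precision; comparisons use a
1e-9 tolerance so floating-point noise cannot fabricate events.
Dual-copy pairing ties keep the ascending-order assignment. Shared-
haplotype reports are ordered by multiplicity descending then
haplotype string, making outputs byte-reproducible; the CLI writes a
manifest with input digests, and reruns with identical inputs, flags
and seed produce identical tables.

Test problem sizes were chosen to make sampling error negligible
relative to the asserted tolerances while keeping the default suite
fast: 10,000 genotypes for the pairing-enumeration equivalence, 10,000
binomial replicates per (n, p) for interval coverage, a 2,548-pair
simulation at the reference rate profile for CI recovery (at least 90%
of nonzero-rate loci must cover truth — exact intervals make the
expected fraction ≥95%), and 200–800-pair simulations for the
remaining end-to-end properties.

## Known limitations

- Panel compositions beyond the full kit are conventions; the
  PowerPlex Y23 configuration ships with the standard 23-locus kit
  definition while the reference summary counts 25 columns for it —
  the reported count is carried as metadata and the discrepancy left
  visible. The Ymax composition (29 loci) is likewise provisional.
- The motif-class configuration is provisional (see above) and should
  be replaced when authoritative per-locus structure descriptions are
  available.
- Result tables are written as plain CSV; `.xlsx` is supported on
  input (via `readxl`) but not on output, keeping all outputs
  line-diffable.
- No paternity-index computation: pairs are assumed pre-confirmed.
- Germline mutations are not distinguished from typing artifacts;
  confirmatory re-typing is upstream of this package.
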