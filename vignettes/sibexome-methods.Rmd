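---
title: "Methods: family-based variant prioritization and case-control follow-up"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based variant prioritization and case-control follow-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibexome)
```

`sibexome` implements a two-step rare-variant discovery design: prioritize
candidate variants inside a nuclear pedigree carrying an affected sibling
pair, then test the survivors in an independent case-control cohort. This
vignette is the package's own account of the models, the tunable parameters
and why their defaults are what they are, what the simulator does and does
not emulate, and the numerical choices a maintainer should know about.

## Data model

A variant is keyed by `(chrom, pos, ref, alt)` in VCF convention (1-based,
explicit alleles over `{A,C,G,T}`). Multi-allelic records are split into one
key per alternate allele *before* any filtering, and keys are normalized to
a minimal left-aligned representation (shared trailing bases trimmed, then
shared leading bases trimmed while advancing `pos`, always keeping at least
one base per allele). Normalization is idempotent and makes the set algebra
of the strategies well-defined for indels; the input data leave unstated
whether upstream callers normalize, so we always do. Genotypes are unordered
allele pairs (`"0/1"` ≡ `"1/0"`); a missing genotype is `NA` and is *never*
treated as either carrying or not carrying (see the strategy rules below).
Annotation — a functional class from a fixed vocabulary, a
segmental-duplication flag, and up to three population-database allele
frequencies — rides either in VCF INFO tags or in a side TSV keyed by the
normalized variant key; both are accepted because annotation is produced by
external tools in practice.

IBD segments are reported 1-based closed in tibbles and TSV, and 0-based
half-open when written as BED, matching each format's convention.

## The synthetic pedigree generator

The generator stands in for protected patient exomes. Per chromosome it
draws variant positions uniformly, population allele frequencies from
Beta(0.8, 0.8) (a U-shaped spectrum: many rare, many near-fixed sites),
four founder haplotypes as Bernoulli draws at those frequencies, and forms
each child's haplotypes by recombining the parental pair with
Poisson-distributed crossovers on a uniform genetic map (1 cM/Mb default, no
interference — the simplest model that produces realistic IBD-segment
structure for full sibs, whose genome-wide IBD2 expectation is 1/4).
Genotypes are emitted with a symmetric per-allele miscall probability
(default 0.005), one knob that drives all robustness checks of the IBD2
caller. Defaults are a deliberately scaled-down exome — 4 chromosomes × 100
Mb × 5,000 sites = 20,000 sites against the hundreds of thousands of calls a
real exome yields — chosen so that the full pipeline and its replicate-based
tests run in seconds while keeping per-step counts large enough for the
funnel to be meaningful. Ninety percent of sites are given database
frequencies at or above common thresholds so they fall to the frequency
filter, mirroring the order-of-magnitude reduction annotation filtering
achieves on real exomes without claiming any real dataset's exact counts;
half of the remaining rare sites are listed as rare in one database and half
are absent everywhere.

Planted candidates are requested as carrier sets over pedigree members. A
"one parent plus children" pattern (e.g. mother and both affected sons, the
segregation pattern the linkage strategy is designed to catch) is realized
by placing the alternate allele on a founder haplotype whose *realized*
transmissions match the request, preferring the eligible site deepest inside
its run so the candidate sits well inside an IBD2 segment when that is
demanded. Because specific seeds legitimately produce genomes with almost no
IBD2 territory, the generator uses rejection sampling over transmissions: if
no eligible site exists it redraws the whole family from a derived seed (25
attempts by default) before declaring the pattern inconsistent. Patterns
containing no parent are injected directly into the children (germline
mosaic / de novo scenario); patterns with both parents are rejected as
unsupported. Plants remain subject to the genotype-error channel, so
tests that depend on exact carrier patterns run the generator at error 0.

What the simulator does **not** emulate: linkage disequilibrium between
sites (sites are independent given the haplotype process), crossover
interference, non-uniform genetic or physical maps, coverage-dependent
missingness, allele-frequency differences between the family's population
and the databases, and somatic variation. Tests passing on this synthetic
data therefore validate the *logic* of the pipeline — set algebra, HMM
decoding, count bookkeeping, parameter recovery — not its performance on any
real cohort's error profile.

## The annotation reduction funnel

Steps apply in a fixed, auditable order: (1) restrict to variants the focal
member carries (missing genotype ⇒ excluded — a variant cannot be counted
as someone's call when their genotype is unknown); (2) keep functional
classes in the configured retention set (default: nonsynonymous, stopgain,
stoploss, frameshift, non-frameshift indel, splicing); (3) drop
segmental-duplication sites; (4) drop variants reported at frequency ≥ 0.01
in *any* consulted database. Every step records `(n_in, n_out)` in a
`FilterTrace`, so a run's count ladder can be compared against published
workflows box by box. The frequency step also offers a presence-based mode
(drop anything listed in any database regardless of frequency). The
threshold rule is the default because a presence rule contradicts the very
design it supports: low-frequency variants with database IDs — exactly the
kind this design exists to find — would be discarded. Survivors are
invariantly a subset of the input, the funnel is idempotent, and an unknown
functional-class label is an error naming the label rather than a silent
drop.

## The IBD2 segment caller

Under IBD = 2 the affected sibs inherited the same haplotype from each
parent, so their genotypes can disagree only through error. Each site is
classified `incompatible` (both called, unequal), `uninformative` (either
missing), or `compatible`. Decoding runs over informative sites only, with a
two-state HMM:

* Emissions: `P(incompatible | IBD2) = ε` (default 0.005, matching the
  generator's error rate in spirit — a per-site discordance caused by
  miscalls); `P(incompatible | notIBD2) = q̂`, estimated as the genome-wide
  incompatibility fraction and floored at 0.05 so the two states stay
  separated on unusually concordant data (if the estimate still falls at or
  below ε it is raised to 2ε).
* Transitions: per-site switch probability τ = 1e-4; at ~20 kb marker
  spacing this puts roughly one state change per 200 Mb a priori, which is
  deliberately sticky: segment boundaries should be driven by runs of
  evidence, not single sites.
* Decoding: Viterbi in log space; ties break toward staying in the current
  state (first-listed candidate), which cannot change the attained maximum
  probability.
* Post-filter: called IBD2 runs shorter than 1 Mb or with fewer than 25
  informative sites are demoted to notIBD2 and merged — real sib IBD2 tracts
  are long, and tiny runs are more plausibly decoding noise.

Segments span from the first to the last informative site of each run, so
segments partition the informative sites per chromosome; a chromosome with
fewer than two informative sites is called notIBD2 with a warning. Variant
filtering against segments uses closed intervals — a variant at a boundary
position is inside. Boundary *resolution* is inherently limited to the
nearest discordant flanking marker: with error-free data the decoder absorbs
compatible flanking sites into the segment, which is the honest behavior of
marker-level evidence, and the test suite asserts exactly that
characterization rather than pretending to base-pair precision. X and Y are
excluded by default since the sib-pair IBD2 argument is autosomal. The
recessive-model assumption behind the filter does not always hold — a
protective or dominant variant can segregate without confining itself to
IBD2 territory — so the pipeline exposes `use_ibd2 = FALSE` rather than
resolving that modeling tension.

## Candidate strategies

Both strategies operate on key sets from the funnel. Membership is "carries
at least one alternate allele"; subtraction is genotype-blind by default (a
key is removed when the subtracted individual carries *any* alternate
there), because published workflow counts subtract whole call sets, not
genotype-matched sets; a genotype-aware mode is available behind a flag. A
missing genotype in the subtracted individual never subtracts — absence of
evidence — and the pipeline logs how many shared keys that rule touched.
The de novo strategy subtracts the parents' **raw** call sets: subtracting
reduced parental sets would leave inherited-but-filtered variants behind and
manufacture false de novo calls. On error-free Mendelian data the de novo
result is provably empty, and the tests assert it across seeds.

## Case-control statistics

**HWE.** The exact test conditions on the observed allele counts and sums
the probabilities of all heterozygote counts of matching parity whose
conditional probability does not exceed the observed one (computed through
log-gamma; the test suite checks it against an independent `choose()`-based
enumeration for every table with n ≤ 30). Controls failing the screen are
flagged, not dropped — a deviation flags genotyping problems and deserves
eyes, not silent exclusion.

**Effect sizes.** `OR = ad/bc` with the Woolf logit interval at
z = Φ⁻¹(0.975) = 1.959964. Zero cells are an explicit error unless the
Haldane–Anscombe +0.5 correction is requested; `run_association()` applies
it automatically only where a zero cell occurs and marks the row. When a
panel supplies allele rows alongside genotypes (as printed tables sometimes
do, occasionally inconsistently), the supplied allele counts win and a
consistency warning is logged.

**Tests.** Pearson chi-square without continuity correction is the default
(1 df for 2×2 collapses, 2 df genotypic), with Yates and two-sided Fisher
(sum of hypergeometric probabilities ≤ observed) available; expected cells
below 1 trigger advice to use Fisher.

**Permutation.** Case/control labels are permuted over subjects —
reconstructed deterministically from genotype counts when only counts are
given, which is exact because subjects are exchangeable — and each SNP's
allelic chi-square is recomputed. The familywise-adjusted p-value for SNP
*s* is `(1 + #{perm : max-statistic ≥ observed_s}) / (n_perm + 1)`, the
max-statistic over the panel; per-SNP unadjusted permutation p-values use
each SNP's own statistic. Adjusted ≥ raw always. An exact mode enumerates
all label assignments on tiny cohorts and is verified against an
independent subset-enumeration oracle. Panels whose SNPs were genotyped on
slightly different subject counts (call-rate differences) are padded per
SNP with homozygous-reference entries for the joint permutation, with a
warning; the padding is conservative for the max-statistic.

**Power.** `cats_power()` derives penetrances from (prevalence K, disease
allele frequency p, GRR γ) under dominant (`f₁ = f₂ = γf₀`), recessive,
multiplicative, or additive (`f₂ = (2γ−1)f₀`) models by solving
`K = Σ gᵢfᵢ`, computes expected allele frequencies in cases and in
screened controls (non-cases), and evaluates the normal-approximation tail
probability of the allele-frequency Wald z statistic — variance estimated
under the alternative at 2·n alleles per arm, the statistic exposed as
`allele_wald_test()`. The default is one-sided in the direction of the
modelled effect, the convention under which this calculator reproduces the
power figures reported for desktop genetic power tools at genome-wide α;
`sided = 2` adds the opposite tail. With γ = 1 the one-sided power is
exactly α. `power_mc()` validates the approximation by simulating cohorts
with `simulate_cohort()` at the implied frequencies and applying the
identical Wald statistic — a deliberate pairing, since a pooled-variance
statistic (Pearson chi-square) has materially different power at large
effect sizes, and the analytic formula must be judged against the test it
models. A separate check in the test suite confirms `cats_power(sided = 2)`
against a Pearson chi-square Monte-Carlo at modest effect sizes, where
pooled and unpooled variances coincide.

**Cohort generator.** Controls are drawn in HWE at the control minor-allele
frequency; cases are tilted by the configured odds ratio on the carrier
scale (dominant), the allele scale (allelic; case genotypes HWE at the
tilted frequency), or per-genotype weights (genotypic). Parameter recovery
is tested by pooling counts across hundreds of replicates at the bundled
panel's scale.

## Numerical and design choices in brief

* Key normalization always runs; duplicate keys after normalization and
  unsorted VCFs are hard errors rather than silent dedups.
* In split multi-allelic genotypes, alleles other than the focal alternate
  are coded reference, so each split row is a proper biallelic site.
* The reduction funnel treats an `NA` database frequency as "not listed".
* The HMM's q̂ floor (0.05), τ (1e-4), and the 1 Mb / 25-site demotion
  thresholds are conservative round numbers fixed in the configuration
  object; all are user-tunable, and the monotonicity of total IBD2 length
  in ε is covered by a property test.
* Reports embed a hash of the exact configuration (`rlang::hash`) so a rerun
  can be checked for bit-identity; every generator takes an explicit integer
  seed and is byte-deterministic given it.
* Problem sizes in the test suite (20,000-site families, 100-replicate
  segment-recovery sweeps, 500-replicate type-I and recovery checks, 10,000
  default permutations) were chosen as the smallest scales at which the
  statistical assertions have comfortable Monte-Carlo margins.

## Known limitations

The IBD2 caller uses only the two affected sibs — parents are not consulted
— so it cannot distinguish IBD1 regions that happen to be genotype-concordant
over short stretches; the minimum-segment post-filter absorbs most of this.
No LD model means decoy variants are independent, likely making set
subtraction slightly *harder* than in real data (no correlated blocks to
remove wholesale). The power calculator covers one-stage designs only, and
the permutation machinery assumes complete genotypes per subject. Compound
heterozygote pairing, X-linked models, and penetrance-weighted ranking are
out of scope.
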