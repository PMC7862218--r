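---
title: "Detecting and quantifying fusion-deficient cheaters: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying fusion-deficient cheaters: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporecheat)
```

## The biological problem

During clonal propagation of *Neurospora crassa*, mutant lineages
repeatedly arise that are overrepresented among asexual spores while
lowering the total spore yield of the culture — social cheaters. The
recurrent genetic route to cheating is loss of the ability to *initiate*
hyphal fusion (mutations in *so*/*soft* and other fusion genes): a
fusion-deficient mutant still profits from fusion initiated by wild-type
hyphae, contributes less to the somatic network, and ends up
overrepresented in the reproductive aerial hyphae. Because a
cheater-rich culture fragments and sporulates poorly, the benefit is
negatively frequency-dependent and the cheater settles at an internal
equilibrium frequency rather than fixing.

`sporecheat` implements the complete computational chain used to detect
such lineages and to quantify their dynamics: a windowed
structural-variant scan over clipped and discordantly flagged reads, a
pairwise ancestor-versus-evolved variant filter, an exact binomial test
for parallel evolution, ΔCt-based qPCR genotyping, selective-plating
deconvolution, and frequency-dependent fitness estimation — plus
synthetic-data generators that emulate each assay.

## Windowed scan for large indels (`sv_scan`)

Small variants are found by a consensus caller upstream; large deletions
betray themselves instead through the *shape* of alignments near their
breakpoints. The scan extracts the union of

* reads whose CIGAR contains a soft clip (S), hard clip (H), insertion
  (I) or deletion (D) operation, and
* reads whose integer SAM flag is one of the twelve values in
  `DISCORDANT_FLAGS` (67, 131, 115, 179, 81, 161, 97, 145, 65, 129,
  113, 177), matched by exact set membership of the whole flag, not by
  bit decomposition,

as the "alternate" set. Per 100 bp window, the summed per-base depth of
alternate reads is divided by the depth of all mapped reads, giving an
alternate fraction per window; the two samples' fractions are then
compared window-by-window and the full table is ranked by the absolute
difference, deliberately without any cut-off — the endpoint is a ranked
list for visual inspection, not a genotyped call set.

Numerical conventions, chosen once and tested:

* windows are 0-based half-open `[0, w), [w, 2w), ...`, tiled from
  position 0, final window truncated — the output is BED-like;
* a read contributes depth over its reference-consuming span (M, D, N,
  `=`, X); insertions and clips consume no reference;
* windows with zero total coverage in either sample have an undefined
  fraction and are excluded from the ranking (no division by zero);
* ties in the ranking are broken by (contig, window start) ascending,
  so output order is deterministic;
* no mapping-quality filter is applied by default (a MAPQ floor belongs
  to the small-variant branch of the pipeline); `min_mapq` exposes one;
* secondary and supplementary alignments are excluded by default,
  configurable in `read_alignments()`.

Two points were genuinely open and are documented as design choices:
"filtering out" the clipped/discordant reads is interpreted as
*extracting* them into the alternate set (their coverage is then
quantified, which would be meaningless for discarded reads), and the
clip-CIGAR and flag conditions are combined as a union rather than an
intersection.

A windowed clip scan localizes a breakpoint only to within a read
length: the aligned anchor of a read clipped at a junction extends up to
`read_length` bp to either side of it, and that is where the alternate
coverage physically lands. `breakpoint_windows()` therefore defines the
truth region of a simulated breakpoint as ± one read length, the slop
conventionally used when benchmarking breakpoint detectors at window
resolution.

## Pairwise variant filter (`pairwise_diff`)

Per-clone VCF call sets (produced upstream by a consensus caller; this
package never calls variants) are compared ancestor-versus-evolved with
the stated post-calling filter: minimum absolute allele-frequency
difference 0.8 and minimum coverage 10. Conventions: thresholds are
inclusive; multi-allelic records are decomposed into per-alt rows before
comparison; a site absent from one sample counts as frequency 0 there
with depth borrowed from the sample carrying the record; by default both
samples must meet the coverage floor (`coverage_scope` exposes
evolved-only and carrier-only variants of the rule). The filter is
antisymmetric (swapping inputs swaps gained/lost but preserves the row
set) and monotone (raising either threshold never adds rows) — both are
tested as properties on randomized call sets.

Samples that are themselves genetically mixed (heterokaryotic mycelia
carrying two nuclear types) place true variants at intermediate
frequency where the stringent filter is blind by construction. Rather
than relaxing thresholds, `intermediate_frequency_calls()` reports such
calls separately for manual review.

## Parallel-evolution test (`parallel_fusion_test`)

Eight independently evolved cheater lineages all carried mutations in
known fusion genes. Under the null that each of the ~15 mutations per
line lands uniformly among ~10,000 protein-coding genes, a mutation hits
the ~75-gene fusion class with probability 75/10,000, and the number of
class hits among `8 × 15 = 120` draws is binomial. The test statistic is
the exact binomial p-value with the minimum-likelihood two-sided
convention (sum of all point probabilities no larger than the observed
one), the default convention of the standard statistical environments:

```r
parallel_fusion_test(8, 8, mut_per_line = 15,
                     class_genes = 75, total_genes = 10000)
#> 3.991418e-06
```

The complementary construction — the probability of *missing* the class,
`p = (10000 − 75)/10000` — yields a p-value around 8e-227, far below
2.2e-16. The PMF is evaluated in log space and summed with a
log-sum-exp, so p-values that small are computed accurately rather than
underflowing. For the printed inputs the two-sided and upper-tail values
coincide to four significant figures: at `k = 8`, `n·p = 0.9`, the lower
tail contributes no point of smaller likelihood. The ~15 mutations per
strain is a conservative rounding; the operation takes the count as a
parameter rather than fixing it.

## qPCR ΔCt genotyping (`frequency_from_delta_ct`)

Two amplicons are quantified from one genomic DNA sample: *hygB* (the
resistance cassette replacing *so*, marking deletion nuclei) and the
intact *so* locus (marking wild-type nuclei). Six technical replicates
per amplicon are averaged (`aggregate_ct`, which also reports the
replicate SD and warns above 0.5 cycles); the Ct difference

\[ \Delta C_t = \overline{C_t}(so) - \overline{C_t}(hygB) \]

implies a template-abundance ratio \(r = E^{\Delta C_t}\) at per-cycle
efficiency \(E\), hence a deletion-nucleus frequency \(f = r/(1+r)\).
With \(E = 2\) (perfect doubling, the default; primer efficiencies are
verified upstream in pilot runs): ΔCt = 0 gives 50/50, ΔCt = 1 gives
2:1 (66.7/33.3), ΔCt = 2 gives 80/20. The map is strictly increasing in
ΔCt and satisfies \(f(-\Delta) = 1 - f(\Delta)\) exactly.

The sign convention — positive ΔCt (earlier *hygB* amplification) means
more deletion template — is fixed, documented, and covered by a
round-trip test against the generator. Ct values are taken as
instrument-processed inputs (no amplification-curve fitting); replicates
pinned at the 40-cycle ceiling indicate a non-amplifying template and
censor the estimate to frequency 0 or 1 with a flag instead of
exponentiating ±40 cycles. Outlier replicates are not dropped.

## Selective-plating deconvolution (`deconvolve_genotypes`)

The transfer experiments mix two strains carrying complementing
auxotrophic markers (*inl*: inositol-requiring; *pan*:
pantothenate-requiring). Spores are plated on three media:
inositol-supplemented (grows *inl* homokaryons and heterokaryons),
pantothenate-supplemented (grows *pan* homokaryons and heterokaryons),
and unsupplemented (grows only heterokaryons, whose two nuclear types
complement each other). With per-medium concentrations `c_inl`,
`c_pan`, `c_none`:

```
c_het      = c_none
c_inl_homo = c_inl - c_none
c_pan_homo = c_pan - c_none
```

and frequencies are each class over the total. The model assumes
heterokaryons plate with equal efficiency on all three media. Replicate
plates (four per medium in the assay design) are pooled by summing
counts and volumes before deconvolution. Counting noise can drive a
subtraction negative; such estimates are clipped to zero, flagged, and
renormalised — never silently — and a constrained Poisson
maximum-likelihood mode (`method = "ml"`, softmax-parameterised over the
frequency simplex) is available for noisy counts. In the noise-free
limit the deconvolution is the exact inverse of the plating forward
model, which is tested as an identity.

## Competitive fitness and its frequency dependence (`fit_frequency_dependence`)

Competitive success of the mutant in a pairwise competition is

\[ S = f_{\mathrm{final}} / f_{\mathrm{initial}} \]

with the *realized* initial frequency (estimated by plating the
inoculum) in the denominator, correcting for pipetting error. \(S = 1\)
is neutrality. The assay varies the initial frequency across a grid
(10–90%), and the analysis asks where the fitted \(S(f)\) crosses 1 —
the equilibrium frequency of the cheater.

The functional form of the trend is not identified by the assay, so the
default fit is deliberately simple: least squares of \(\log S\) on
\(f_{\mathrm{initial}}\), equilibrium at the zero crossing of the fitted
line, restricted to the observed frequency range, with a nonparametric
bootstrap over competition records for the 95% confidence interval. A
quadratic-in-\(f\) option is exposed as the alternative; both are
documented as choices, neither as the assay's true model. The
equilibrium is defined as the smallest in-range root of \(S = 1\); when
the curve does not cross 1 in range the fit reports the reason
(advantage everywhere, disadvantage everywhere, flat fit) instead of a
number. `ratio_ttest()` wraps the one-sample t-test used for end/start
ratio comparisons (df = n − 1), labelled glue around `stats::t.test`.

## What the synthetic generators emulate — and what they do not

Every analysis stage has a generator that is its exact inverse in the
noise-free limit, and all stochastic outputs are reproducible from
(seed, config) alone. Defaults mirror the assay conditions: 150 bp
paired-end reads at ~25× depth; six technical qPCR replicates, 40-cycle
program, doubling efficiency; four counting plates per medium; serial
transfer of 1% of spores per 4-day cycle, four transfers; competition
grids of 10–90% initial frequency in triplicate.

* `simulate_alignments()` draws uniform error-free paired reads from a
  genome with an implanted homozygous deletion (default 300 bp at
  position 1000 of a 5 kb reference — desk-scale; the real reference is
  41.1 Mb). Reads crossing a junction are soft-clipped on the shorter
  side of their anchor; pairs straddling the deletion get discordant
  flags (97/145) from the recognised set; everything else is a proper
  pair (99/147). Sequencing error and coverage bias are deliberately
  absent: the scan consumes only CIGAR/flag structure, so base-level
  realism adds nothing to what the tests can show. The default deletion
  length (300 bp) exceeds the read length so breakpoints necessarily
  produce clips.
* `simulate_qpcr_ct()` inverts the ΔCt model
  (\(\Delta C_t = \log_E f/(1-f)\)) and adds Gaussian replicate noise
  (default SD 0.1 cycles, a typical technical-replicate spread);
  boundary frequencies produce censored measurements at the cycle
  ceiling.
* `simulate_plate_counts()` drops a multinomial draw of ~400 spores per
  plate (a countable density) and scores each plate by the classes able
  to grow on its medium.
* `simulate_competition_records()` generates (realized initial, final)
  pairs under the same log-linear \(S(f) = e^{\beta(f^* - f)}\) the
  default fit assumes (root \(f^* = 0.3\), matching the observed
  crossover near 30%; slope \(\beta = 5\), chosen once to give ~2.7-fold
  success at 10% initial frequency, the order observed at low
  frequency), with binomial counting noise at 300 colonies per
  estimate. Because generator and fit share the functional form, the
  recovery test checks *estimation*, not model identification.
* `simulate_transfer_series()` is an explicitly phenomenological
  stand-in for the mycelium-fragmentation mechanism, which the source
  assay characterizes only qualitatively: per cycle, selection by
  \(S(f)\) at the effective cheater frequency (homokaryotic cheaters
  plus half the heterokaryons), mass-action heterokaryon formation
  (`het_rate · 2 f_c f_w`, rate a free parameter, default 0.5 giving
  first-cycle heterokaryon fractions of the order of 20%), a linear
  yield decline in cheater frequency, then a multinomial bottleneck at
  1% of the yield. It is labelled a stand-in throughout, never the
  measured dynamics.

Passing tests on these generators therefore demonstrate that the
analysis chain is a correct inverse of its own assumed measurement
models at the stated noise levels — not that those models capture every
feature of real cultures (no spatial structure, no hyphal-network
simulation, no sequence-level mutation process, no marker effects).

## Problem sizes and numerical choices

The test suite and examples run at desk scale by choice: 5–8 kb
references (~800 reads) for the scan with a per-base brute-force oracle
on references up to 10 kb, 20 seeded scan simulations, 200 qPCR and
competition recoveries, 500 plating recoveries, exact PMF enumeration
up to n = 200. The binomial PMF is computed in log space; the
deconvolution never divides by an all-zero plate triple (it errors);
the comparison table never divides by zero coverage (undefined
fractions are excluded); equilibrium roots are reported only inside the
observed frequency range; bootstrap resamples that lose the minimum of
three distinct frequencies are dropped from the interval.

## Known limitations

* The scan ranks windows; it does not assemble breakpoints, realign
  split reads, or genotype events.
* Flag matching is the printed integer list, so alignments whose
  discordance is expressed through other flag values are caught only
  via their CIGAR.
* The ΔCt conversion assumes a common efficiency per amplicon pair;
  per-amplicon efficiencies can be supplied, but amplification-curve
  fitting is out of scope.
* The transfer simulator's heterokaryon kinetics are parameterized, not
  emergent; it cannot be used to infer formation rates from data.
* Experimental statistics of the original assays (figure-level t and F
  values on source data) are reproduced structurally (df arithmetic,
  power at the reported effect size), not numerically — the underlying
  raw data are not shipped.
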