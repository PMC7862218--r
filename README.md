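# sporecheat

Tools for detecting and quantifying **fusion-deficient cheater lineages**
in *Neurospora crassa* (and similar filamentous fungi). During clonal
serial transfer, mutants that have lost the ability to initiate hyphal
fusion become overrepresented among asexual spores while reducing the
total spore yield of the culture — social cheaters under negative
frequency-dependent selection. This package implements the full analysis
chain such an experiment needs, from sequencing reads to fitness curves,
for experimental-evolution and fungal-sociality researchers.

## What it computes

* **Windowed structural-variant scan** (`sv_scan`): extracts the union of
  clipped/indel-bearing reads (CIGAR S, H, I, D) and reads with one of
  twelve discordant SAM flags (exact set membership), profiles their
  per-base depth in 100 bp windows relative to total depth, and ranks
  ancestor-vs-evolved windows by |Δ alternate fraction| — no cut-off, a
  ranked list for inspection.
* **Pairwise variant filter** (`pairwise_diff`): ancestor-vs-evolved VCF
  comparison at a minimum allele-frequency difference of 0.8 and minimum
  coverage of 10 (inclusive; both configurable), with gained/lost
  direction and a separate report for intermediate-frequency calls from
  heterokaryotic samples.
* **Parallel-evolution test** (`parallel_fusion_test`): exact binomial
  probability (minimum-likelihood two-sided, log-space PMF) that `k` of
  `n` independent lines hit a gene class by chance given the per-line
  mutation count and class size.
* **qPCR ΔCt genotyping** (`frequency_from_delta_ct`,
  `qpcr_frequencies`): duplexed *so*/*hygB* Ct differences converted to
  nuclear genotype frequencies, `f = E^ΔCt / (1 + E^ΔCt)`, with
  replicate averaging and cycle-ceiling censoring.
* **Selective-plating deconvolution** (`deconvolve_genotypes`,
  `plate_frequencies`): homokaryon/heterokaryon frequencies from colony
  counts on inositol-, pantothenate-, and un-supplemented media, with
  clip-and-flag handling and an optional Poisson-ML mode.
* **Frequency-dependent fitness** (`competitive_success`,
  `fit_frequency_dependence`): competitive success `S = f_final /
  f_initial`, a log-linear (or quadratic) fit of `S` against initial
  frequency, and the equilibrium frequency where `S = 1`, with bootstrap
  confidence intervals.
* **Synthetic data** (`simulate_*`): seeded generators for alignments
  with implanted deletions, Ct tables, plate counts, competitions, and
  serial-transfer trajectories — each the exact inverse of its analysis
  stage in the noise-free limit.

## Worked example

```r
library(sporecheat)

# How surprising is it that all 8 evolved cheater lines carry a mutation
# in one of ~75 fusion genes, with ~15 mutations per line among ~10,000?
parallel_fusion_test(8, 8, mut_per_line = 15,
                     class_genes = 75, total_genes = 10000)
#> [1] 3.991418e-06        # chance alone is effectively excluded

# A 2-cycle Ct difference between the so and hygB amplicons:
frequency_from_delta_ct(2, efficiency = 2)
#> # A tibble: 1 × 3
#>   delta_ct f_dso  f_wt
#>      <dbl> <dbl> <dbl>
#> 1        2   0.8   0.2   # an 80/20 nuclear mixture

# Scan a simulated evolved clone carrying a 300 bp deletion at 1000-1300
# against its ancestor:
evo <- simulate_alignments(simulation_config(seed = 7))
anc <- simulate_alignments(simulation_config(seed = 8, deletion = NULL))
f_anc <- tempfile(fileext = ".sam"); f_evo <- tempfile(fileext = ".sam")
write_sam(anc, f_anc); write_sam(evo, f_evo)
head(sv_scan(f_anc, f_evo), 4)
#> # A tibble: 4 × 7
#>   contig start   end alt_frac_a alt_frac_b abs_diff  rank
#>   <chr>  <dbl> <dbl>      <dbl>      <dbl>    <dbl> <int>
#> 1 chrI    1300  1400          0      0.880    0.880     1
#> 2 chrI     900  1000          0      0.793    0.793     2
#> 3 chrI    1400  1500          0      0.584    0.584     3
#> 4 chrI     800   900          0      0.547    0.547     4
# the top-ranked windows flank the implanted breakpoints at 1000 and 1300

# Fit frequency dependence of competitive success and find the
# equilibrium cheater frequency:
rec <- simulate_competition_records(root = 0.3, slope = 5, seed = 3)
fit_frequency_dependence(rec, n_boot = 200)
#> Frequency dependence of competitive success (log transform, n = 27)
#>   coefficients: (Intercept) = 1.503, f_initial = -5.051
#>   equilibrium frequency (S = 1): 0.2976  [0.2852, 0.3084]
# the fitted S(f) crosses neutrality near the generating value of 0.30
```

A shell entry point for the scan is included at
`inst/scripts/svscan.R`:

```sh
Rscript inst/scripts/svscan.R --sample-a anc.bam --sample-b evo.bam \
    --window 100 --out table.tsv
```

## Further reading

The methods vignette (`vignettes/cheater-analysis.Rmd`) documents the
models and their assumptions, every tunable parameter with its default
and rationale, what the synthetic generators do and do not emulate, and
the package's numerical conventions.
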