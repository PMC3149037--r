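# cnvscreen

Case–control copy-number-variant (CNV) screening from SNP-array intensity
data, built for studies where cases and controls were genotyped on the same
array but differ in ways (DNA source, cell-line immortalization) that can
manufacture spurious CNV associations.

Genotyping arrays summarise each marker as a **Log R Ratio** (LRR; ~0 at two
copies, negative for deletions, positive for duplications) and a **B Allele
Frequency** (BAF; clustering at 0 / 0.5 / 1 for diploid genotypes).
`cnvscreen` implements the full analysis chain from those two signals to
association results — and, just as importantly, the diagnostics that tell a
true susceptibility locus apart from the two classic artifact mechanisms:
runs of rare-haplotype homozygosity that look like deletions, and
tandem-repeat (VNTR) probes confounded with DNA source.

## What it does

| Stage | Functions |
|---|---|
| Synthetic cohorts with ground truth | `sim_config()`, `build_marker_map()`, `simulate_cohort()`, `inject_artifacts()` |
| Signal/table I/O (PennCNV-style TSV, BED) | `read_signal()`, `write_signal()`, `read_pfb()`, `read_genes_bed()`, `write_calls_bed()`, … |
| Marker QC (unstable regions, sex-linked probes) | `exclude_unstable()`, `sex_model_pvalues()`, `gender_linked_scan()`, `apply_marker_exclusions()` |
| Chromosomal-arm mosaicism screen | `arm_baf_stats()`, `mosaic_scan()`, `estimate_mosaic_fraction()`, `mask_excluded_arms()` |
| Five-state HMM CNV calling | `hmm_params()`, `emission_loglik()`, `viterbi_segment()`, `call_cnvs()`, `compare_callsets()` |
| Conservative / Common / gene-centric filters | `probe_recurrence()`, `classify_calls()`, `filter_accounting()` |
| Carrier association + permutation | `carrier_status()`, `fisher_one_sided()`, `cnv_scan()`, `maxt_permutation()`, `study_wide_correction()`, `replicate_locus()` |
| Artifact diagnostics & molecular validation | `loh_check()`, `vntr_check()`, `qpcr_classify()`, `mlpa_classify()`, `gel_size_and_repeats()`, `repeat_decompose()`, `summed_allele_test()` |

The statistics at the core:

- **Carrier test.** At a locus, sample *i* is a carrier iff ≥ 1 retained
  call overlaps it. With *a/b* case carriers/non-carriers and *c/d* the
  control counts, the one-sided exact p is the hypergeometric tail
  P(X ≥ a | margins) and OR = ad/bc.
- **Genome-wide significance by max-T permutation.** Affection labels are
  permuted (margins fixed), the scan re-run, and the genome-wide minimum
  nominal p recorded; the empirical genome-wide p of a locus is
  (1 + #{permutations with min p ≤ observed p}) / (B + 1).
- **Mosaic geometry.** A mosaic event in cell fraction *f* splits the
  heterozygote BAF band to (1−f)/(2−f) and 1/(2−f) (loss) or 1/(2+f) and
  (1+f)/(2+f) (gain); the band separation *d* inverts to
  f = 2d/(1+d) (loss) or 2d/(1−d) (gain).

## Worked example

```r
library(cnvscreen)

# a 30-sample cohort with a deletion shared by three cases
cfg <- sim_config(
  chrom_lengths = c(`1` = 20e6), n_markers = 1000,
  n_cases = 15, n_controls = 15,
  implant_cnvs = tibble::tibble(
    sample_id = c("S0001", "S0002", "S0003"),
    chrom = "1", start = 5e6, end = 6e6, cn = 1L),
  seed = 7)
map   <- build_marker_map(cfg)
sim   <- simulate_cohort(map, cfg)
calls <- call_cnvs(sim$panel, hmm_params("strict"))
dplyr::count(calls, cn)
#> # A tibble: 1 × 2
#>      cn     n
#>   <int> <int>
#> 1     1     3

res <- maxt_permutation(calls, sim$samples, map,
                        mode = "position", B = 500, seed = 7)
dplyr::filter(tidy(res), a > 0)
#> # A tibble: 1 × 13
#>   chrom   start     end n_markers     a     b     c     d odds_ratio
#>   <chr>   <int>   <int>     <int> <int> <int> <int> <int>      <dbl>
#> 1 1     5025693 5985349        50     3    12     0    15        Inf
#> # ℹ 4 more variables: p_nominal <dbl>, mode <chr>, p_pointwise <dbl>,
#> #   p_genomewide <dbl>
```

The three implanted case deletions are recovered as CN = 1 calls; the locus
collapses to a single record (all 50 markers share the same carrier set)
with an infinite odds ratio sentinel (no control carriers), nominal
one-sided p = C(27,12)/C(30,15) ≈ 0.11, and an empirical genome-wide p from
the 500 label permutations. `autoplot(res)` draws the scan;
`plot_sample_track(sim$panel, "S0001", calls = calls)` shows the deletion in
the raw LRR/BAF track.

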