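---
title: "Case-control CNV screening from LRR/BAF: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-control CNV screening from LRR/BAF: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cnvscreen` analyses case-control SNP-array cohorts for copy-number-variant
(CNV) associations, starting from the two per-marker summaries every array
platform emits: the Log R Ratio (LRR), a log2 intensity ratio centred at 0
for two copies, and the B Allele Frequency (BAF), the estimated fraction of
the B allele, clustering at 0, 0.5 and 1 in diploid samples. This vignette
is the package's own account of the models behind each stage, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the design choices made where the design was genuinely open.

## The synthetic cohort generator

Every stage of the pipeline is tested against simulated cohorts with known
truth, produced by `build_marker_map()` and `simulate_cohort()` from a
`sim_config()`.

**Emission model.** At a diploid SNP with population B-allele frequency
*p*, the genotype is Binomial(2, *p*); BAF is the genotype mean (0, 0.5, 1)
plus Normal cluster noise (default sd 0.03, clipped to [0, 1]); LRR is
Normal(0, sd), with a per-sample noise sd of 0.15 by default. Inside a
germline CNV of copy number *c*, LRR is centred at the state mean
mu_c = (−3.5, −0.66, 0, 0.40, 0.68) for *c* = 0..4 and BAF at *b*/*c* for
*b* ~ Binomial(*c*, *p*) (uniform at *c* = 0, where no allelic signal
exists). The state means are config-exposed: no downstream test depends on
hidden constants. Monomorphic copy-number probes carry the PFB sentinel 2
and an uninformative uniform BAF.

**Mosaicism.** A mosaic event present in a cell fraction *f* mixes diploid
and aberrant signal. LRR uses the linear mixture f·mu_c — an acknowledged
approximation to the log-domain mixture, chosen because it is simple and
monotone in *f* — and heterozygote BAF moves to the bands
(1−f)/(2−f) and 1/(2−f) for a loss, 1/(2+f) and (1+f)/(2+f) for a gain,
which is exact BAF algebra, not an approximation.

**Raw intensities.** When `with_xy = TRUE` the generator synthesises
X/Y so that R = X + Y = 2^LRR and Theta = (2/pi)·atan2(Y, X) tracks the
allelic ratio; these feed the two intensity-based sex-prediction models.

**Artifact structures.** Three structures can be injected
(`inject_artifacts()`), each mirroring a documented failure mode of
array CNV calling:

* *Sex-cross-hybridizing markers*, three patterns. B: complete
  co-hybridization — females heterozygous-like (BAF ≈ 0.5), males
  homozygous-like with a −0.5 LRR drop. The LRR drop matters: a marker
  where males sit at BAF 0/1 and females at 0.5 is **not** linearly
  separable in BAF alone, and for a target on the X chromosome the
  hemizygous male intensity really is lower; it is the intensity axis that
  makes these markers separable "diagonally" in two dimensions. C: a
  monomorphic probe whose sexes separate in raw X/Y (Theta ≈ 0.15 vs 0.85)
  while mean LRR is equal — detectable only with raw intensities. D: a
  polymorphic probe with sex-shifted, compressed genotype clusters and a
  male LRR offset.
* *A VNTR probe group*: a contiguous run of markers (default 6) converted
  into monomorphic probes tagging one physical tandem-repeat locus —
  nested probes target one locus, so the group must be contiguous or no
  multi-marker call could ever arise. Per-sample LRR is
  slope·(summed repeats − 2·ref)/(2·ref) + shift·[cell line] + noise, with
  allele repeat counts uniform on 20–36, independent of phenotype. The
  defaults slope = 2.5 and source shift = 0.5 were fixed once, by a power
  analysis of the caller's effective call threshold, so that the
  confounded scenario produces calls on both tails and the null
  (slope = shift = 0) produces none.
* *A low-MAF tight-LD block*: k = 9 SNPs whose minor alleles all ride one
  haplotype of frequency 0.041. The haplotype count is pinned at its
  expectation so the block's sample allele frequency equals the configured
  value at every seed — the scenario's defining precondition (observed
  MAF < 0.05) must hold by construction, not by luck. The marker map
  reports `assumed_pfb = 0.5` for these SNPs, the placeholder frequency a
  manifest assigns to SNPs absent from its reference panel; the mismatch
  between that placeholder and the true rare-haplotype genetics is the
  artifact mechanism. A mild LRR depression (−0.42) applies to
  blood-derived samples over the block, emulating the source-linked
  intensity dip such loci show.

**RNG design.** Each sample draws from its own stream split from the
master seed, so adding a sample never perturbs the others; identical
config + seed reproduces every matrix bit-for-bit.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: GC-content intensity waves, plate/batch effects,
genotype-calling chemistry, X-chromosome dosage in males, sub-arm mosaic
segments, and LD structure outside the designated block. Real-data noise is
heavier-tailed than the Gaussian noise here, so real false-positive rates
will exceed the simulator's.

## Marker quality control

Markers in configured unstable regions (telomeres, centromeres,
immunoglobulin loci) are flagged and excluded (`exclude_unstable()`).

Sex-cross-hybridizing markers are found by fitting, per marker, three
two-predictor logistic regressions of sex on (X, Y), (R, Theta) and
(BAF, LRR) (`sex_model_pvalues()`). Pairs of variables are used because the
separation is diagonal in two-dimensional space: neither variable alone
need separate the sexes. A marker is removed when its minimum
per-coefficient p across the six variables falls below
0.05 / (n_markers × n_variables), recomputed from the panel at hand (with
370,404 markers and 6 variables this gives the canonical 2.2e-8).

**Why likelihood-ratio rather than Wald p-values.** The per-coefficient p
is the chi-squared tail of the deviance drop when the coefficient is
removed. Wald p-values were considered and rejected: under near-separation
— precisely the regime of a genuinely sex-linked marker — the logistic
maximum-likelihood estimate diverges, the Wald standard error grows faster
than the coefficient, and the Wald p tends to 1 (the Hauck–Donner effect),
silently *keeping* the worst markers. The deviance difference stays well
behaved. Perfectly separated fits (deviance ≈ 0) return a sentinel p = 0,
below any threshold. When raw X/Y are absent only the (BAF, LRR) model
runs, the Bonferroni denominator uses 2 variables, and a message says so.

## Chromosomal-arm mosaicism screen

For each sample-arm, the screen takes the BAF values strictly inside
(0.15, 0.85) — computed over SNP-class markers only, since monomorphic
probes carry no allelic signal and their uniform BAF would both dilute the
statistic and bias the band means — and records their standard deviation
and interquartile range (`arm_baf_stats()`; at least 30 mid-band values,
otherwise the arm is `unknown`). Arms are flagged when the robust z-score
(median/MAD across all arms, MAD floored at 0.005) of either statistic
exceeds 6 (`flag_outlier_arms()`). The two axes catch different
signatures: a faint mosaic inflates the sd before it visibly splits the
IQR. The z > 6 cut is a calibration choice (the original procedure was a
visual one) and is config-exposed; at the default it flags every simulated
arm with f ≥ 0.3 and nothing on null panels.

The mosaic fraction is estimated by splitting the mid-band at 0.5 and
inverting the band-separation algebra (`estimate_mosaic_fraction()`):
f = 2d/(1+d) for losses (direction from the arm's mean LRR sign), 2d/(1−d)
for gains. Recovery is within ±0.05 (empirically ±0.02) on the grid
f = 0.2–0.8 for losses and 0.2–0.9 for gains; losses beyond f ≈ 0.82 push
the heterozygote bands out of the (0.15, 0.85) mid-band, so the screening
statistic itself runs out of data — a geometry bound, not an
implementation limit.

Flagged arms are classified (`classify_mosaic_arms()`): covered ≥ 50% by
CNV calls → `mosaic_called_cnv`, excluded; two or more distinct band-shift
segments (counted with a windowed run rule that requires a confidently
unshifted stretch between segments) → `multi_event`, excluded; high LRR sd
→ `noisy`; estimated f < 0.15 → `faint`; otherwise `mosaic_uncalled`,
retained — mirroring the policy of excluding only mosaics that the caller
reported as CNVs. `mask_excluded_arms()` guarantees excluded arms
contribute zero calls downstream, and `excluded_arms()` feeds the
association stage so masked samples leave the margins at affected loci.

## The HMM caller

Five states (copy number 0–4; no copy-neutral-LOH state — its absence is
exactly what makes the rare-haplotype artifact reproducible, and adding one
is listed as an extension). Emission at a marker is
Normal(LRR; mu_state, lrr_sd) times a Binomial(state, pfb)-weighted mixture
of boundary-censored Normals centred at b/state for BAF (uniform for state
0, LRR-only for pfb-sentinel probes). Boundary censoring puts the clipped
mass at BAF 0/1 where homozygote clusters actually sit. Defaults:
lrr_sd = 0.2, baf_sd = 0.03.

Transitions depend on inter-marker distance d: total leave-state
probability lambda_max·(1 − exp(−d/D)) with D = 100 kb, split equally among
the other four states. Presets: `strict` (lambda_max = 1e-3, confidence
gate 10, ≥ 5 markers) and `lenient` (1e-2, gate 3) — the lenient preset
calls more and longer, the knob used to study caller discordance
(`compare_callsets()` matches calls at 50% reciprocal overlap).

Confidence is emission-only: the summed per-marker log-likelihood ratio of
the called state over the diploid state. Transition terms approximately
cancel between the called and diploid paths and are excluded, which also
makes the score independently recomputable (a test recomputes it
marker-by-marker). The confidence scale is this caller's own; equating its
gate of 10 to any other caller's "confidence 10" is nominal.

Per-sample noise QC (`call_cnvs(sample_qc = TRUE)`) re-estimates each
sample's LRR sd by MAD over its track and drops samples above 0.35,
mirroring the exclusion of samples with unacceptably high LRR dispersion.

## Filters and association

The Conservative filter keeps calls ≥ 100 kb **and** ≥ 20 markers; the
Common filter keeps calls ≥ 5 markers containing at least one probe seen
deleted or duplicated ≥ 3 times across the cohort (`probe_recurrence()`).
The recurrence count pools deletions and duplications by default (the
disjunctive reading of "deleted or duplicated 3 or more times");
a direction-specific mode sits behind `pool_directions = FALSE`. The union
feeds association; the gene-centric subset additionally requires ≥ 1 bp
overlap with any gene interval — deliberately not exon-restricted, because
sparse marker maps misplace boundaries into introns. Size uses the 1-based
inclusive convention, length = end − start + 1.

Association is carrier-based: `cnv_scan()` tests every marker position (or
a window of ± 200 kb around it) with the one-sided hypergeometric tail
P(X ≥ a), implemented directly (`fisher_one_sided()`) and cross-checked in
tests against both exhaustive enumeration and `stats::fisher.test`.
Adjacent loci with identical carrier sets collapse into one record —
results are invariant to the collapsing, and the permutation cost scales
with distinct loci. A window statistic based on event counts rather than
carriers was considered; the carrier form was kept because it is
well-defined under the same permutation engine for both analysis modes.
Deletions and duplications are pooled (dosage-mutation semantics);
stratified scans are a flag away.

`maxt_permutation()` permutes affection status with fixed margins,
records the genome-wide minimum nominal p per permutation, and reports
(1 + #{min p ≤ observed}) / (B + 1) per locus, plus a pointwise empirical
p. Small cohorts can enumerate every assignment (`exhaustive = TRUE`);
a test pins the sampled version to the exhaustive oracle at n = 6. Under
the null the genome-wide empirical p is approximately uniform; with few
carriers per locus the Fisher tail is heavily discrete and the max-T
construction is *conservative* (the calibration study at B = 500 over 100
replicates observes a ≤ 5% fraction of 0–1%), which is the safe direction
for a screen. Study-wide correction divides 0.05 by the number of analysis
approaches (strictly below; 4 approaches → 0.0125).

`replicate_locus()` is the single-locus replication design: gene-overlap
carrier definition, compound heterozygotes (two distinct calls at the
locus) excluded from both margins, one-sided Fisher and odds ratio with an
Inf sentinel when no control carries.

## Artifact diagnostics and molecular validation

`loh_check()` asks whether a deletion candidate is really a run of
rare-haplotype homozygosity: it selects the SNPs in the region with
MAF < 0.05 and pairwise composite r² > 0.75 (genotype correlation, since
phase is unavailable), then estimates the frequency of the all-minor-allele
haplotype separately in call carriers and non-carriers with a two-class EM
on unphased genotypes — each haplotype is either "all minor" or "other",
adequate under tight LD and far simpler than full phasing. The locus is
flagged when carriers show frequency ≈ 0 and zero heterozygotes while
non-carriers carry the haplotype above 1%. With a single carrier the EM
degenerates to direct counting. One honest corner: a sample homozygous for
the rare haplotype itself is deletion-like under *any* frequency-aware
emission model (two copies of a 4% haplotype are rarer than one deletion)
and is not part of the artifact; the mechanism tests therefore assert the
disappearance of calls among homozygous-major samples when the PFB is
corrected.

`vntr_check()` runs three probes of the VNTR/DNA-source mechanism: an
exact test of call-carrier status against DNA source, a re-call of the
chromosome with the probe group masked (reporting the fraction of region
calls that vanish), and, when truth repeat counts exist, the regression of
probe-mean LRR on summed repeat count. The flag is the source-association
test at alpha = 0.01.

The molecular-validation calculators follow the quoted assay rules
literally, including the asymmetry between them: qPCR proportions are
*exclusively* bounded (< 0.80 deletion, > 1.20 duplication; replicates
averaged against their own control means first), MLPA ratios *inclusively*
(0.8 ≤ r ≤ 1.2 normal). Gel sizing interpolates between the two nearest
ladder bands only — no global standard curve — and converts to repeat
units as (size − flank)/32. `repeat_decompose()` tiles a sequence into
32-mers from a fixed anchor and clusters exact variants; greedy tiling is
correct here because the repeat register is known from the reference
structure. `summed_allele_test()` is the equal-variance two-sided
Student's t, with p = 1 returned for two degenerate equal constant groups.

## Problem sizes and numerical choices

The test-suite and acceptance studies use desk-scale cohorts chosen for
statistical resolution: 200 samples × 5,000 markers for caller recovery
(F1 against ≥ 10-marker truth at 50% reciprocal overlap), two 60-sample
panels with 15 implanted arms each plus an 800-arm null panel for the
mosaic screen, 10,000 markers × 150 samples for the marker-QC null
calibration, and 100 replicates at B = 500 permutations (36 samples, 400
markers) for the calibration of empirical p-values. The LOH mechanism
scenario uses a low-noise cohort (lrr_sd = 0.10) and a deliberately
miscalibrated lenient caller (lrr_sd = 0.3): the artifact lives in the
caller's relative weighting of BAF versus LRR evidence, and a low-noise
panel isolates exactly that trade-off.

Numerical details worth knowing: likelihoods are floored at 1e-300 before
logs; BAF values within 1e-6 of the boundaries are treated as censored;
exact ties at filter and correction thresholds follow the quoted rules
(≥ for filter sizes, strict < for significance); the MAD scale in the
mosaic screen is floored to avoid division by a degenerate spread; and all
randomness flows from explicit seeds through per-sample streams.

## Known limitations

No X-chromosome calling, no trio support, no copy-neutral-LOH state, no
sub-arm mosaic segmentation, no GC-wave correction, and no attempt to match
any external caller's confidence scale. The association engine offers no
covariate adjustment — by design for this replication setting, but a real
mixed cohort would want one.
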