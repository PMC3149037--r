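Package: cnvscreen
Title: Case-Control Copy Number Variant Screening from SNP-Array Intensity Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for genome-wide copy number variant (CNV)
    analysis of case-control SNP-array cohorts from Log R Ratio (LRR) and
    B Allele Frequency (BAF) signal: marker quality control including
    detection of sex-chromosome co-hybridizing probes, whole-chromosomal-arm
    mosaicism screening from mid-band BAF dispersion, hidden Markov model
    CNV calling with confidence scoring, Conservative/Common/gene-centric
    call filtering, carrier-based association testing with max-statistic
    permutation for empirical genome-wide significance, candidate-locus
    replication, and diagnostics for two artifact mechanisms
    (rare-haplotype loss-of-heterozygosity mimicking deletions, and VNTR
    probes confounded with DNA source), plus molecular-validation
    calculators (qPCR and MLPA dosage ratios, gel sizing, tandem-repeat
    decomposition). A synthetic-data module generates intensity panels with
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
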