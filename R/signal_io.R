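#' Read a signal-intensity file
#'
#' Parses the tab-delimited per-cohort signal layout produced by array
#' software: marker columns `Name`, `Chr`, `Position`, then one pair of
#' columns per sample suffixed `".Log R Ratio"` and `".B Allele Freq"`.
#'
#' @param path file path.
#' @param samples optional sample tibble to attach (id, sex, phenotype, ...).
#' @return an `intensity_panel`.
#' @export
read_signal <- function(path, samples = NULL) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_that(all(c("Name", "Chr", "Position") %in% names(d)),
              "signal file must carry Name, Chr, Position columns")
  assert_that(!anyDuplicated(d$Name), "duplicated marker id in signal file")
  lrr_cols <- grep("\\.Log R Ratio$", names(d), value = TRUE)
  baf_cols <- grep("\\.B Allele Freq$", names(d), value = TRUE)
  sids_l <- sub("\\.Log R Ratio$", "", lrr_cols)
  sids_b <- sub("\\.B Allele Freq$", "", baf_cols)
  missing_baf <- setdiff(sids_l, sids_b)
  missing_lrr <- setdiff(sids_b, sids_l)
  assert_that(length(missing_baf) == 0,
              paste0("missing '.B Allele Freq' column for sample: ",
                     paste(missing_baf, collapse = ", ")))
  assert_that(length(missing_lrr) == 0,
              paste0("missing '.Log R Ratio' column for sample: ",
                     paste(missing_lrr, collapse = ", ")))
  assert_that(length(sids_l) > 0, "no sample columns found")

  ord <- order(match(d$Chr, unique(d$Chr)), d$Position)
  assert_that(all(ord == seq_len(nrow(d))),
              "marker positions must be sorted within chromosome")
  mono <- tapply(d$Position, d$Chr, function(p) all(diff(p) > 0))
  assert_that(all(mono), "non-increasing positions within a chromosome")

  baf <- t(as.matrix(d[baf_cols]))
  bad <- which(baf < -1e-6 | baf > 1 + 1e-6, arr.ind = TRUE)
  assert_that(nrow(bad) == 0,
              paste0("BAF outside [0,1] at marker ",
                     d$Name[bad[, 2][1]]))
  baf <- clamp(baf, 0, 1)
  lrr <- t(as.matrix(d[lrr_cols]))

  markers <- tibble::tibble(
    marker_id = d$Name, chrom = as.character(d$Chr), pos = d$Position,
    arm = if ("Arm" %in% names(d)) d$Arm else NA_character_,
    probe_class = if ("ProbeClass" %in% names(d)) d$ProbeClass else "snp",
    pfb = if ("PFB" %in% names(d)) d$PFB else 0.5,
    unstable_region = FALSE, gender_linked = FALSE
  ) %>% dplyr::relocate("arm", .after = "chrom")
  if (is.null(samples)) {
    samples <- tibble::tibble(sample_id = sids_l)
  } else {
    assert_that(all(sids_l %in% samples$sample_id),
                "signal file contains samples absent from sample table")
    samples <- samples[match(sids_l, samples$sample_id), ]
  }
  new_intensity_panel(markers, samples, lrr, baf)
}

#' Write a signal-intensity file
#'
#' Inverse of [read_signal()]; emits the `Name`/`Chr`/`Position` columns
#' (plus `Arm`, `ProbeClass`, `PFB` when present in the marker map) and one
#' `".Log R Ratio"` / `".B Allele Freq"` column pair per sample.
#'
#' @param panel an `intensity_panel`.
#' @param path output path.
#' @export
write_signal <- function(panel, path) {
  m <- panel$markers
  d <- tibble::tibble(Name = m$marker_id, Chr = m$chrom, Position = m$pos)
  if (!all(is.na(m$arm))) d$Arm <- m$arm
  if ("probe_class" %in% names(m)) d$ProbeClass <- m$probe_class
  if ("pfb" %in% names(m)) d$PFB <- m$pfb
  for (i in seq_len(nrow(panel$samples))) {
    sid <- panel$samples$sample_id[i]
    d[[paste0(sid, ".Log R Ratio")]] <- panel$lrr[i, ]
    d[[paste0(sid, ".B Allele Freq")]] <- panel$baf[i, ]
  }
  readr::write_tsv(d, path, progress = FALSE)
  invisible(path)
}

#' Read/write a population B-allele frequency table
#'
#' TSV with columns `Name`, `Chr`, `Position`, `PFB`. Monomorphic
#' copy-number probes carry the sentinel PFB value 2.
#'
#' @param path file path.
#' @return tibble.
#' @export
read_pfb <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_that(all(c("Name", "Chr", "Position", "PFB") %in% names(d)),
              "PFB table must carry Name, Chr, Position, PFB")
  assert_that(all(d$PFB == 2 | (d$PFB >= 0 & d$PFB <= 1)),
              "PFB must lie in [0,1] or equal the sentinel 2")
  d
}

#' @rdname read_pfb
#' @param marker_map marker map tibble.
#' @export
write_pfb <- function(marker_map, path) {
  readr::write_tsv(tibble::tibble(Name = marker_map$marker_id,
                                  Chr = marker_map$chrom,
                                  Position = marker_map$pos,
                                  PFB = marker_map$pfb),
                   path, progress = FALSE)
  invisible(path)
}

#' Read/write a sample table
#'
#' TSV with columns `sample_id`, `sex`, `phenotype`, `dna_source`, `study`.
#' @param path file path.
#' @return tibble.
#' @export
read_samples <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_that(all(c("sample_id", "sex", "phenotype") %in% names(d)),
              "sample table must carry sample_id, sex, phenotype")
  assert_that(!anyDuplicated(d$sample_id), "duplicated sample_id")
  d
}

#' @rdname read_samples
#' @param samples sample tibble.
#' @export
write_samples <- function(samples, path) {
  readr::write_tsv(samples, path, progress = FALSE)
  invisible(path)
}

#' Read/write a CNV call table
#'
#' TSV with columns `sample_id`, `chrom`, `start`, `end`, `cn`, `n_markers`,
#' `length_bp`, `confidence`; coordinates 1-based inclusive.
#' @param path file path.
#' @return callset tibble.
#' @export
read_calls <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(chrom = "c"))
  need <- c("sample_id", "chrom", "start", "end", "cn")
  assert_that(all(need %in% names(d)), "calls table missing required columns")
  d
}

#' @rdname read_calls
#' @param callset callset tibble.
#' @export
write_calls <- function(callset, path) {
  readr::write_tsv(callset, path, progress = FALSE)
  invisible(path)
}

#' BED export of CNV calls
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' a call (start, end) is written as (start - 1, end). The name field is
#' `sample:cn:confidence`.
#'
#' @param callset callset tibble.
#' @param path output path.
#' @export
write_calls_bed <- function(callset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# CNV calls; BED 0-based half-open; name = sample:cn:confidence",
             con)
  if (nrow(callset) > 0) {
    lines <- sprintf("%s\t%d\t%d\t%s:%d:%.2f",
                     callset$chrom, callset$start - 1L, callset$end,
                     callset$sample_id, callset$cn,
                     callset$confidence %||% rep(NA_real_, nrow(callset)))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a BED interval file into 1-based inclusive intervals
#'
#' @param path BED path (browser/track and `#` comment lines are skipped).
#' @return tibble with `chrom`, `start`, `end` (1-based inclusive) and
#'   `name` when a fourth column is present.
#' @export
read_genes_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3)
  assert_that(length(bad) == 0,
              paste0("malformed BED line ", which(keep)[bad[1]]))
  chrom <- vapply(parts, `[[`, character(1), 1)
  start0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2)))
  end0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3)))
  bad <- which(!is.finite(start0) | !is.finite(end0) | end0 <= start0)
  assert_that(length(bad) == 0,
              paste0("malformed BED line ", which(keep)[bad[1]]))
  name <- vapply(parts, function(p)
    if (length(p) >= 4) p[[4]] else NA_character_, character(1))
  tibble::tibble(chrom = chrom, start = as.integer(start0 + 1),
                 end = as.integer(end0), name = name)
}

#' Pipeline configuration from YAML
#'
#' Reads a YAML config and merges it over package defaults; unknown top-level
#' keys are rejected rather than silently ignored.
#'
#' @param path YAML path; `NULL` returns the defaults.
#' @return named list of parameter groups (`caller`, `filters`, `assoc`,
#'   `mosaic`, `diagnostics`).
#' @export
read_pipeline_config <- function(path = NULL) {
  defaults <- list(
    caller = list(preset = "strict", min_markers = 5, min_confidence = 10,
                  lrr_sd = 0.2, baf_sd = 0.03, transition_bp = 1e5),
    filters = list(conservative_bp = 1e5, conservative_markers = 20,
                   common_markers = 5, recurrence_min = 3,
                   pool_directions = TRUE),
    assoc = list(half_width = 2e5, n_perm = 10000, seed = 1,
                 n_approaches = 4),
    mosaic = list(z_threshold = 6, mad_floor = 0.005, min_mid = 30,
                  coverage_frac = 0.5),
    diagnostics = list(maf_cut = 0.05, r2_cut = 0.75,
                       qpcr_low = 0.80, qpcr_high = 1.20,
                       mlpa_low = 0.8, mlpa_high = 1.2, repeat_unit = 32)
  )
  if (is.null(path)) return(defaults)
  assert_that(requireNamespace("yaml", quietly = TRUE),
              "the yaml package is required to read config files")
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(defaults))
  assert_that(length(unknown) == 0,
              paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  for (k in names(user)) {
    unknown <- setdiff(names(user[[k]]), names(defaults[[k]]))
    assert_that(length(unknown) == 0,
                paste0("unknown config keys under ", k, ": ",
                       paste(unknown, collapse = ", ")))
    defaults[[k]] <- utils::modifyList(defaults[[k]], user[[k]])
  }
  defaults
}
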