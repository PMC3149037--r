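#' Per-probe deletion/duplication recurrence
#'
#' Counts, for every marker covered by at least one call, how many calls
#' delete it and how many duplicate it (once per sample-call). Recurrence
#' feeds the Common filter: a probe seen deleted or duplicated three or more
#' times marks a known copy-number-variable locus.
#'
#' @param callset callset tibble.
#' @param marker_map marker map tibble.
#' @return tibble (`marker_id`, `n_deleted`, `n_duplicated`).
#' @export
probe_recurrence <- function(callset, marker_map) {
  n_del <- n_dup <- integer(nrow(marker_map))
  if (nrow(callset) > 0) {
    for (j in seq_len(nrow(callset))) {
      idx <- which(marker_map$chrom == callset$chrom[j] &
                     marker_map$pos >= callset$start[j] &
                     marker_map$pos <= callset$end[j])
      assert_that(length(idx) > 0, "call spanning zero markers (corrupt input)")
      if (callset$cn[j] < 2) n_del[idx] <- n_del[idx] + 1L
      else n_dup[idx] <- n_dup[idx] + 1L
    }
  }
  tibble::tibble(marker_id = marker_map$marker_id,
                 n_deleted = n_del, n_duplicated = n_dup) %>%
    dplyr::filter(.data$n_deleted + .data$n_duplicated > 0)
}

#' Classify calls into the Conservative / Common / union / gene-centric sets
#'
#' Conservative: span >= `conservative_bp` and >= `conservative_markers`
#' markers. Common: >= `common_markers` markers and at least one covered
#' probe recurrently deleted/duplicated (`recurrence_min` or more events;
#' directions pooled by default, direction-specific behind the flag).
#' Union = Conservative or Common; gene-centric = in the union and
#' overlapping at least 1 bp of any gene interval.
#'
#' @param callset callset tibble.
#' @param marker_map marker map tibble (for probe recurrence lookup).
#' @param genes gene intervals tibble (`chrom`, `start`, `end`,
#'   1-based inclusive), e.g. from [read_genes_bed()]; `NULL` means no
#'   gene-centric classification.
#' @param recurrence result of [probe_recurrence()]; recomputed from
#'   `callset` when `NULL`.
#' @param conservative_bp,conservative_markers,common_markers,recurrence_min
#'   filter thresholds.
#' @param pool_directions count deletions and duplications together when
#'   testing recurrence (the default disjunctive reading).
#' @return `callset` with logical columns `conservative`, `common`,
#'   `in_union`, `gene_centric`.
#' @export
classify_calls <- function(callset, marker_map, genes = NULL,
                           recurrence = NULL,
                           conservative_bp = 1e5, conservative_markers = 20,
                           common_markers = 5, recurrence_min = 3,
                           pool_directions = TRUE) {
  if (is.null(recurrence)) recurrence <- probe_recurrence(callset, marker_map)
  rec <- rep(0L, nrow(marker_map))
  i <- match(recurrence$marker_id, marker_map$marker_id)
  rec_del <- rec_dup <- rec
  rec_del[i] <- recurrence$n_deleted
  rec_dup[i] <- recurrence$n_duplicated
  n <- nrow(callset)
  conservative <- common <- gene_centric <- logical(n)
  for (j in seq_len(n)) {
    conservative[j] <- callset$length_bp[j] >= conservative_bp &&
      callset$n_markers[j] >= conservative_markers
    idx <- which(marker_map$chrom == callset$chrom[j] &
                   marker_map$pos >= callset$start[j] &
                   marker_map$pos <= callset$end[j])
    max_rec <- if (pool_directions) {
      max(rec_del[idx] + rec_dup[idx], 0)
    } else if (callset$cn[j] < 2) max(rec_del[idx], 0) else max(rec_dup[idx], 0)
    common[j] <- callset$n_markers[j] >= common_markers &&
      max_rec >= recurrence_min
  }
  in_union <- conservative | common
  if (!is.null(genes) && nrow(genes) > 0) {
    for (j in seq_len(n)) {
      if (!in_union[j]) next
      g <- genes[genes$chrom == callset$chrom[j], , drop = FALSE]
      gene_centric[j] <- nrow(g) > 0 &&
        any(interval_overlap(g$start, g$end,
                             callset$start[j], callset$end[j]) >= 1)
    }
  }
  callset$conservative <- conservative
  callset$common <- common
  callset$in_union <- in_union
  callset$gene_centric <- gene_centric
  callset
}

#' Filter-set accounting
#'
#' Counts and percentages for the Conservative, Common, intersection, union,
#' unanalyzed and gene-centric sets, plus the marker-count histogram of the
#' rejected (neither-filter) calls in the 5-9 / 10-14 / 15-19 / >=20 bins.
#'
#' @param classified result of [classify_calls()].
#' @return list with one-row `counts` tibble and `rejected_bins` tibble.
#' @export
filter_accounting <- function(classified) {
  n <- nrow(classified)
  n_cons <- sum(classified$conservative)
  n_comm <- sum(classified$common)
  n_int <- sum(classified$conservative & classified$common)
  n_union <- sum(classified$in_union)
  n_rej <- n - n_union
  rej <- classified[!classified$in_union, , drop = FALSE]
  bins <- cut(rej$n_markers, c(-Inf, 9, 14, 19, Inf),
              labels = c("5-9", "10-14", "15-19", ">=20"))
  rejected_bins <- tibble::tibble(bin = levels(bins)) %>%
    dplyr::left_join(
      tibble::tibble(bin = as.character(bins), size = rej$length_bp) %>%
        dplyr::group_by(.data$bin) %>%
        dplyr::summarise(n = dplyr::n(), mean_size_bp = mean(.data$size),
                         .groups = "drop"),
      by = "bin") %>%
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  counts <- tibble::tibble(
    total = n, conservative = n_cons, common = n_comm,
    intersection = n_int, union = n_union, unanalyzed = n_rej,
    gene_centric = sum(classified$gene_centric),
    pct_conservative = 100 * n_cons / n,
    pct_common = 100 * n_comm / n,
    pct_unanalyzed = 100 * n_rej / n,
    pct_gene_centric = 100 * sum(classified$gene_centric) / n_union
  )
  list(counts = counts, rejected_bins = rejected_bins)
}

#' Filter set algebra from counts
#'
#' Inclusion-exclusion bookkeeping on filter-set sizes: union size, count
#' and share of unanalyzed calls, and the Common and gene-centric shares.
#'
#' @param n_conservative,n_common,n_intersection,n_total set sizes.
#' @param n_gene_centric optional gene-centric set size.
#' @return one-row tibble.
#' @export
filter_set_algebra <- function(n_conservative, n_common, n_intersection,
                               n_total, n_gene_centric = NA_integer_) {
  n_union <- n_conservative + n_common - n_intersection
  tibble::tibble(
    union = n_union,
    unanalyzed = n_total - n_union,
    pct_conservative = 100 * n_conservative / n_total,
    pct_common = 100 * n_common / n_total,
    pct_unanalyzed = 100 * (n_total - n_union) / n_total,
    pct_gene_centric = 100 * n_gene_centric / n_union
  )
}
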