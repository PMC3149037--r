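#' Plot one sample's LRR and BAF track
#'
#' The standard two-panel diagnostic: LRR on top (deletions dip, gains
#' rise), BAF below (diploid bands at 0/0.5/1; mosaic arms split the
#' heterozygote band).
#'
#' @param panel an `intensity_panel`.
#' @param sample_id sample to plot.
#' @param chrom chromosome to plot (default: first).
#' @param calls optional callset; overlapping calls are shaded.
#' @return a ggplot object.
#' @export
plot_sample_track <- function(panel, sample_id, chrom = NULL, calls = NULL) {
  i <- match(sample_id, panel$samples$sample_id)
  assert_that(!is.na(i), "unknown sample_id")
  chrom <- chrom %||% panel$markers$chrom[1]
  idx <- which(panel$markers$chrom == chrom)
  d <- tibble::tibble(
    pos = rep(panel$markers$pos[idx], 2),
    value = c(panel$lrr[i, idx], panel$baf[i, idx]),
    track = rep(c("LRR", "BAF"), each = length(idx))
  ) %>% dplyr::mutate(track = factor(.data$track, c("LRR", "BAF")))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::facet_wrap(~track, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = paste0("position on chr", chrom, " (bp)"), y = NULL,
                  title = sample_id) +
    ggplot2::theme_bw()
  if (!is.null(calls)) {
    cs <- calls[calls$sample_id == sample_id & calls$chrom == chrom, ,
                drop = FALSE]
    if (nrow(cs) > 0) {
      p <- p + ggplot2::geom_rect(
        data = tibble::tibble(xmin = cs$start, xmax = cs$end),
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     ymin = -Inf, ymax = Inf),
        inherit.aes = FALSE, fill = "steelblue", alpha = 0.2)
    }
  }
  p
}

#' Mosaic-scan scatter: mid-band BAF sd vs IQR
#'
#' Every point is one sample-arm; mosaic arms separate from the dense
#' normal cloud toward high dispersion. Points are coloured by class.
#'
#' @param stats result of [mosaic_scan()].
#' @return a ggplot object.
#' @export
plot_mosaic_scan <- function(stats) {
  d <- stats[!is.na(stats$baf_sd), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$baf_sd, y = .data$baf_iqr,
                                  colour = .data$arm_class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "mid-band BAF standard deviation",
                  y = "mid-band BAF IQR", colour = "arm class") +
    ggplot2::theme_bw()
}

#' @rdname plot_mosaic_scan
#' @param object a `mosaic_scan` tibble.
#' @param ... unused.
#' @export
autoplot.mosaic_scan <- function(object, ...) {
  plot_mosaic_scan(object)
}

#' Association scan plot
#'
#' -log10 of the nominal one-sided p per collapsed locus along the genome,
#' with the empirical genome-wide significance threshold implied by the
#' permutation distribution.
#'
#' @param object a `cnv_assoc` object.
#' @param alpha genome-wide level drawn as a reference (default 0.05).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cnv_assoc <- function(object, alpha = 0.05, ...) {
  d <- object$results
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                  y = -log10(.data$p_nominal),
                                  colour = .data$p_genomewide < alpha)) +
    ggplot2::geom_point() +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "-log10 nominal one-sided p",
                  colour = paste0("genome-wide p < ", alpha)) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
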