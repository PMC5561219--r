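#' ZFst track plot for one contrast
#'
#' Window mid-point against ZFst, faceted by contig, with the
#' candidate threshold drawn as a dashed line and (optionally) the
#' classified regions shaded.
#'
#' @param scan tibble from [window_scan()]; if it holds several
#'   contrasts, pass `group_a`/`group_b` to pick one.
#' @param regions optional region tibble with `classification` to
#'   overlay.
#' @param group_a,group_b contrast selection (defaults: first contrast
#'   present).
#' @param z_threshold threshold line (default 2).
#' @return a ggplot object.
#' @export
plot_zfst <- function(scan, regions = NULL, group_a = NULL,
                      group_b = NULL, z_threshold = 2) {
  if (is.null(group_a)) group_a <- scan$group_a[1]
  if (is.null(group_b)) group_b <- scan$group_b[1]
  d <- dplyr::filter(scan, .data$group_a == !!group_a,
                     .data$group_b == !!group_b, !is.na(.data$zfst))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                       y = .data$zfst)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = z_threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::facet_wrap(~contig, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)",
                  y = bquote(ZF[ST] ~ .(group_a) ~ "vs" ~ .(group_b)),
                  title = paste0("ZFst scan: ", group_a, " vs ", group_b)) +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf,
                   fill = .data$classification),
      alpha = 0.2, inherit.aes = FALSE)
  }
  p
}

#' H12 profile plot along a contig
#'
#' @param rows tibble from [h12_scan()]/[h12_subsampled()] (several
#'   groups may be bound together; one line per group).
#' @param contig optional contig to restrict to.
#' @return a ggplot object.
#' @export
plot_h12 <- function(rows, contig = NULL) {
  if (!is.null(contig)) {
    rows <- dplyr::filter(rows, .data$contig == !!contig)
  }
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$center_pos, y = .data$h12,
                                     colour = .data$group)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~contig, ncol = 1, scales = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "window center (bp)", y = "H12") +
    ggplot2::theme_minimal()
}

#' ZFst track of the domestic-vs-domestic contrast with classified
#' regions shaded
#'
#' @param object a `duosweep_run`.
#' @param ... passed on to [plot_zfst()].
#' @return a ggplot object.
#' @export
autoplot.duosweep_run <- function(object, ...) {
  plot_zfst(object$scan,
            regions = dplyr::filter(
              object$regions,
              .data$classification %in% c("unidirectional",
                                          "bidirectional")),
            group_a = object$roles$chd, group_b = object$roles$eud,
            ...)
}
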