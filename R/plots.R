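#' Plot a UPD landscape
#'
#' Draws, per chromosome, three horizontal tracks: the called UPD segments
#' (coloured by disomy type, labelled with parent of origin), the proband
#' runs of homozygosity, and a rug of supportive variants. This mirrors the
#' ideogram-with-tracks view used to present segmental UPD: isodisomy maps
#' completely onto ROH, heterodisomy does not.
#'
#' @param object An `upd_landscape` object from [run_upd_landscape()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.upd_landscape <- function(object, ...) {
  segs <- object$segments
  roh <- object$roh
  sup <- dplyr::filter(object$calls, .data$supportive)

  layers <- list()
  if (nrow(segs) > 0) {
    layers <- c(layers, list(
      ggplot2::geom_rect(
        data = dplyr::mutate(segs, start_mbp = .data$start / 1e6,
                             end_mbp = .data$end / 1e6),
        ggplot2::aes(xmin = .data$start_mbp, xmax = .data$end_mbp,
                     ymin = 2.1, ymax = 2.9, fill = .data$disomy_type)
      ),
      ggplot2::geom_text(
        data = dplyr::mutate(segs, mid = (.data$start + .data$end) / 2e6),
        ggplot2::aes(x = .data$mid, y = 2.5, label = .data$parent),
        size = 3
      )
    ))
  }
  if (nrow(roh) > 0) {
    layers <- c(layers, list(
      ggplot2::geom_rect(
        data = dplyr::mutate(roh, start_mbp = .data$start / 1e6,
                             end_mbp = .data$end / 1e6),
        ggplot2::aes(xmin = .data$start_mbp, xmax = .data$end_mbp,
                     ymin = 1.1, ymax = 1.9),
        fill = "grey35"
      )
    ))
  }
  if (nrow(sup) > 0) {
    layers <- c(layers, list(
      ggplot2::geom_point(
        data = dplyr::mutate(sup, pos_mbp = .data$pos / 1e6),
        ggplot2::aes(x = .data$pos_mbp, y = 0.5, colour = .data$parent),
        shape = "|", size = 2
      )
    ))
  }
  if (nrow(object$breakpoints) > 0) {
    layers <- c(layers, list(
      ggplot2::geom_vline(
        data = dplyr::mutate(object$breakpoints,
                             bp_mbp = .data$breakpoint / 1e6),
        ggplot2::aes(xintercept = .data$bp_mbp),
        linetype = "dashed"
      )
    ))
  }

  ggplot2::ggplot() +
    layers +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::scale_y_continuous(
      breaks = c(0.5, 1.5, 2.5),
      labels = c("supportive", "ROH", "UPD"),
      limits = c(0, 3)
    ) +
    ggplot2::labs(x = "position (Mbp)", y = NULL, fill = "disomy type",
                  colour = "parent") +
    ggplot2::theme_minimal()
}
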