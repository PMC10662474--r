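#' Plot distance versus structural-similarity bins
#'
#' Mean pair distance per TM-score bin with a one-standard-deviation
#' ribbon, the usual view of how an evolutionary distance tracks
#' structural similarity.
#'
#' @param object A [correlate_with_structure()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.structure_correlation <- function(object, ...) {
  df <- dplyr::filter(object$per_bin, .data$n > 0)
  df$tm_mid <- (df$tm_lo + df$tm_hi) / 2
  df$sd_distance[is.na(df$sd_distance)] <- 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tm_mid, y = .data$mean_distance)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_distance - .data$sd_distance,
      ymax = .data$mean_distance + .data$sd_distance), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "TM-score (bin midpoint)", y = "Mean distance",
                  title = sprintf("Pearson r = %.3f over %d pairs",
                                  object$overall_pearson, object$n_pairs)) +
    ggplot2::theme_minimal()
}

#' Plot within- vs between-family mean distances per superfamily
#'
#' Each point is a superfamily; points above the diagonal have larger
#' between-family than within-family mean distances. Colour marks
#' membership in Q (significant separation at the report's alpha).
#'
#' @param object An [rr_rd()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rrrd_report <- function(object, ...) {
  df <- object$per_superfamily
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d_same_mean,
                                   y = .data$d_diff_mean,
                                   colour = .data$in_Q)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Mean within-family distance",
                  y = "Mean between-family distance",
                  colour = sprintf("p < %g", object$alpha),
                  title = sprintf("RR = %.3f, RD = %.3f", object$RR, object$RD)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
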