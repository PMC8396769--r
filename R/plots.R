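#' Plot PCA sample scores
#'
#' @param object A `pca_weights` object.
#' @param components Two component indices to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pca_weights <- function(object, components = c(1, 2), ...) {
  d <- tibble::tibble(x = object$pc_scores[, components[1L]],
                      y = object$pc_scores[, components[2L]])
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = paste0("PC", components[1L]),
                  y = paste0("PC", components[2L])) +
    ggplot2::theme_minimal()
}

#' Plot an EHH decay curve
#'
#' @param object An `ehh_profile` from [ehh_curve()].
#' @param ... Unused.
#' @return A ggplot of EHH against physical position.
#' @export
autoplot.ehh_profile <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(.data$position, .data$ehh,
                               group = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "position (bp)", y = "EHH",
                  title = sprintf("core %s", object$core)) +
    ggplot2::theme_minimal()
}

#' Plot standardized selection-scan scores along the chromosome
#'
#' @param object A `scan_scores` tibble from [ihs_scan()] or [xpehh_scan()].
#' @param threshold Horizontal guide at the conventional |score| flag.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scan_scores <- function(object, threshold = 2, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$pos, .data$score)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed") +
    ggplot2::labs(x = "position (bp)", y = "standardized score") +
    ggplot2::theme_minimal()
}

#' Plot admixture proportions as stacked bars
#'
#' @param object An `ancestry_fit`.
#' @param ... Unused.
#' @return A ggplot with one bar per individual, ordered by the first
#'   component.
#' @export
autoplot.ancestry_fit <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::select(-"loglik", -"converged") |>
    tidyr::pivot_longer(-"sample_id", names_to = "ancestry",
                        values_to = "q")
  ord <- order(object$q[, 1L])
  d$sample_id <- factor(d$sample_id, levels = object$samples[ord])
  ggplot2::ggplot(d, ggplot2::aes(.data$sample_id, .data$q,
                                  fill = .data$ancestry)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "admixture proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Forest-style plot of association odds ratios
#'
#' @param object An `assoc_scan` tibble.
#' @param ... Unused.
#' @return A ggplot of ORs with 95% intervals per tested contrast.
#' @export
autoplot.assoc_scan <- function(object, ...) {
  d <- object[!is.na(object$or), , drop = FALSE]
  d$label <- paste(d$id, d$contrast, sep = ":")
  ggplot2::ggplot(d, ggplot2::aes(.data$or, .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$or_l95, xmax = .data$or_u95), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
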