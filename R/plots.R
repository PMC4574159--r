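#' Plot a variant-reduction funnel
#'
#' Bar chart of the surviving variant count after each reduction step.
#'
#' @param object A `reduction_result` from [reduce_variants()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.reduction_result <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(step = "input", n = object$trace$n_in[1]),
    tibble(step = object$trace$step, n = object$trace$n_out)
  )
  df$step <- factor(df$step, levels = df$step)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "variants remaining",
                  title = paste("Reduction funnel, member", object$member)) +
    ggplot2::theme_minimal()
}

#' Plot called IBD segments along the genome
#'
#' @param object An `ibd_segments` tibble from [call_ibd2_segments()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ibd_segments <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$chrom, yend = .data$chrom,
                   colour = .data$state),
      linewidth = 4) +
    ggplot2::scale_colour_manual(values = c(IBD2 = "firebrick",
                                            notIBD2 = "grey70")) +
    ggplot2::labs(x = "position (Mb)", y = "chromosome", colour = NULL,
                  title = "Sib-pair IBD state") +
    ggplot2::theme_minimal()
}

#' Forest plot of odds ratios from an association scan
#'
#' Odds ratios with Woolf confidence intervals per SNP and genetic model, on
#' a log scale (genotypic rows, which have no single OR, are omitted).
#'
#' @param object An `association_scan` from [run_association()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.association_scan <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), !is.na(.data$or))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$snp,
                                   colour = .data$model)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
      position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL,
                  title = "Case-control association") +
    ggplot2::theme_minimal()
}

#' Plot the prioritization count ladder
#'
#' @param object A `prioritization_report` from [run_prioritization()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.prioritization_report <- function(object, ...) {
  df <- object$ladder
  df$member <- ifelse(is.na(df$member), "family", df$member)
  df$step <- factor(df$step, levels = unique(df$step))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$n,
                                   group = .data$member,
                                   colour = .data$member)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "variants (log scale)", colour = "member",
                  title = "Prioritization count ladder") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
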