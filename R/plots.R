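#' Plot a genome-wide subtraction profile
#'
#' Median relapse-minus-diagnosis copy number per bin along the genome, with
#' bins significant after chromosome-wise FDR correction highlighted.
#' Positive values indicate a copy-number increase at relapse.
#'
#' @param object A `cn_subtraction` from [subtract_pairs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cn_subtraction <- function(object, ...) {
  df <- as_tibble(object)
  df$mid <- (df$start + df$end) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid / 1e6, y = .data$median_diff)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "purple"),
                                 name = "FDR significant") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (Mb)",
                  y = "median copy-number change (relapse - diagnosis)") +
    ggplot2::theme_minimal()
}

#' Plot an absolute copy-number fit
#'
#' Fitted segments on the absolute copy-number scale with integer states as
#' guide lines; the subtitle reports the fitted purity, ploidy and QC score.
#'
#' @param object An `acn_fit` from [fit_purity_ploidy()].
#' @param max_state Highest integer guide line drawn (default 8).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.acn_fit <- function(object, max_state = 8, ...) {
  segs <- as_tibble(object$segments)
  ggplot2::ggplot(segs) +
    ggplot2::geom_hline(yintercept = 0:max_state, colour = "grey85",
                        linewidth = 0.3) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                                       y = .data$value, yend = .data$value),
                          colour = "firebrick", linewidth = 1.1) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "absolute copy number",
                  subtitle = sprintf("purity %.2f, ploidy %.2f, QC score %.4f (%s)",
                                     object$purity, object$ploidy,
                                     object$qc$score,
                                     if (object$qc$pass) "pass" else "fail")) +
    ggplot2::theme_minimal()
}

#' Stacked signature-exposure spectrum
#'
#' One stacked bar per sample showing its exposure composition, optionally
#' faceted by a grouping column (e.g. role or platinum status).
#'
#' @param exposures Tibble with `sample_id` and signature columns.
#' @param group_col Optional faceting column name.
#' @return A ggplot object.
#' @export
plot_exposure_spectrum <- function(exposures, group_col = NULL) {
  sig_cols <- grep("^s[0-9]+$", names(exposures), value = TRUE)
  long <- tidyr::pivot_longer(exposures, all_of(sig_cols),
                              names_to = "signature", values_to = "exposure")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id,
                                          y = .data$exposure,
                                          fill = .data$signature)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = "signature exposure") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6))
  if (!is.null(group_col)) {
    p <- p + ggplot2::facet_grid(cols = ggplot2::vars(.data[[group_col]]),
                                 scales = "free_x", space = "free_x")
  }
  p
}

#' Plot fitted group compositions from an abundance model
#'
#' Shows the inverse-ILR-transformed group mean compositions of a fitted
#' global abundance model side by side per signature (the flat analogue of
#' the radar plots common for signature panels).
#'
#' @param object An `ilr_fit` from [fit_global_abundance_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ilr_fit <- function(object, ...) {
  means <- inverse_ilr_group_means(object)
  long <- tidyr::pivot_longer(means, -"group", names_to = "signature",
                              values_to = "exposure")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$signature, y = .data$exposure,
                                     colour = .data$group, group = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "fitted mean exposure",
                  subtitle = sprintf("global Wald p = %.3g", object$wald$p.value)) +
    ggplot2::theme_minimal()
}
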