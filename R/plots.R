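# ggplot2 displays for mapping runs and evaluations.

#' Plot the averaged precision / acceptance curves of an evaluation
#'
#' Mean precision and mean accepted count against the z-score cutoff,
#' facetted with free y scales; cutoffs where precision is undefined (no
#' accepted mapping in any run) are skipped.
#'
#' @param object A `loinc_eval` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot loinc_eval
#' @export
autoplot.loinc_eval <- function(object, ...) {
  av <- object$averaged[is.finite(object$averaged$cutoff), ]
  long <- tidyr::pivot_longer(
    dplyr::select(av, "cutoff", "mean_precision", "mean_n_accepted"),
    cols = c("mean_precision", "mean_n_accepted"),
    names_to = "metric", values_to = "value")
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cutoff, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~ .data$metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "z-score cutoff", y = NULL,
                  title = sprintf("Precision vs cutoff (mean of %d runs)",
                                  object$n_runs)) +
    ggplot2::theme_minimal()
}

#' Plot the z-score distribution of a mapping run
#'
#' Histogram of per-code z-scores coloured by acceptance; when a truth
#' table is supplied, facets split correct from incorrect mappings, the
#' view behind the separation test.
#'
#' @param object A `loinc_mapping` tibble.
#' @param truth Optional truth tibble (`local_code_id`, `true_loinc`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot loinc_mapping
#' @export
autoplot.loinc_mapping <- function(object, truth = NULL, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$z_score), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$z_score,
                                        fill = .data$accepted)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = attr(object, "cutoff"),
                        linetype = "dashed") +
    ggplot2::labs(x = "z-score of chosen mapping", y = "codes") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    df <- dplyr::left_join(df, truth, by = "local_code_id")
    df$outcome <- ifelse(df$mapped_loinc == df$true_loinc,
                         "correct", "incorrect")
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$z_score,
                                          fill = .data$accepted)) +
      ggplot2::geom_histogram(bins = 30) +
      ggplot2::geom_vline(xintercept = attr(object, "cutoff"),
                          linetype = "dashed") +
      ggplot2::facet_wrap(~ .data$outcome, ncol = 1) +
      ggplot2::labs(x = "z-score of chosen mapping", y = "codes") +
      ggplot2::theme_minimal()
  }
  p
}

#' Boxplot of correct vs incorrect mapping z-scores
#'
#' @param records A `loinc_mapping` tibble.
#' @param truth Truth tibble (`local_code_id`, `true_loinc`).
#' @return A ggplot.
#' @export
plot_zscore_separation <- function(records, truth) {
  df <- dplyr::left_join(tibble::as_tibble(records), truth,
                         by = "local_code_id")
  df <- df[!is.na(df$z_score) & !is.na(df$true_loinc), ]
  df$outcome <- ifelse(df$mapped_loinc == df$true_loinc,
                       "correct", "incorrect")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$z_score)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = "z-score of chosen mapping") +
    ggplot2::theme_minimal()
}
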