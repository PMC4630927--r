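# ggplot2 views. Each result type gets an autoplot() method plus a
# plot_*() alias taking the raw tables.

#' Plot a concordance summary
#'
#' Stacked composition of the FF/FFPE variant union by concordance
#' label.
#'
#' @param object A `concordance_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.concordance_summary <- function(object, ...) {
  df <- mutate(object$by_label,
               label = factor(.data$label, levels = rev(concordance_labels)))
  ggplot2::ggplot(df, ggplot2::aes(x = "union", y = .data$fraction,
                                   fill = .data$label)) +
    ggplot2::geom_col(width = 0.5) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::scale_fill_manual(values = c(
      SHARED = "#2c7fb8", FALSE_POSITIVE = "#d95f02",
      FALSE_NEGATIVE = "#e7b800", NOT_DETERMINED = "grey70")) +
    ggplot2::labs(x = NULL, y = "fraction of union variants",
                  fill = NULL,
                  title = "FF/FFPE variant concordance") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.concordance_summary
#' @param records Labelled records from [classify_records()].
#' @export
plot_concordance <- function(records, ...) {
  autoplot(summarize_concordance(records), ...)
}

#' Plot a substitution spectrum
#'
#' Per-class SNV counts, the standard six-class mutational profile.
#'
#' @param object A `substitution_spectrum`, or a named list of them to
#'   compare samples side by side.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.substitution_spectrum <- function(object, ...) {
  plot_spectra(list(object), ...)
}

#' @rdname autoplot.substitution_spectrum
#' @param spectra A list of `substitution_spectrum` objects.
#' @export
plot_spectra <- function(spectra, ...) {
  df <- list_rbind(map(spectra, tidy.substitution_spectrum))
  df$sample_id[is.na(df$sample_id)] <- "sample"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$n,
                                   fill = .data$sample_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "substitution class (strand-collapsed)",
                  y = "somatic SNVs", fill = NULL,
                  title = "Substitution spectrum") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot class-wise FFPE/FF enrichment
#'
#' Fold change per substitution class; classes with an undefined fold
#' (zero FF count) are omitted from the bars.
#'
#' @param object An `enrichment_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_report <- function(object, ...) {
  df <- filter(object$by_class, !is.na(.data$fold))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$fold)) +
    ggplot2::geom_col(fill = "#d95f02") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "substitution class", y = "FFPE / FF fold change",
                  title = "Substitution-class enrichment in FFPE") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot Q-ratio QC profiles
#'
#' Q129 and Q305 ratios per sample with the HQ/LQ gates drawn as
#' horizontal lines.
#'
#' @param profiles Classified profiles from [classify_quality()].
#' @param thresholds The [qc_thresholds()] used (drawn as gates).
#' @return A ggplot.
#' @export
plot_qc <- function(profiles, thresholds = qc_thresholds()) {
  df <- tidyr::pivot_longer(as_tibble(profiles),
                            dplyr::all_of(c("q129", "q305")),
                            names_to = "ratio", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$value,
                                   fill = .data$quality_class)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~ratio) +
    ggplot2::geom_hline(data = tibble(ratio = "q129",
                                      y = c(thresholds$hq_min_q129,
                                            thresholds$lq_max_q129)),
                        ggplot2::aes(yintercept = .data$y), linetype = 2) +
    ggplot2::labs(x = NULL, y = "Q-ratio", fill = NULL,
                  title = "FFPE DNA integrity (qPCR Q-ratios)") +
    ggplot2::theme_minimal()
}
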