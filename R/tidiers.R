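# broom-style views of result objects.

#' Tidy a concordance summary
#'
#' @param x A `concordance_summary` from [summarize_concordance()].
#' @param ... Unused.
#' @return A tibble with one row per concordance label: `label`, `n`,
#'   `fraction`.
#' @exportS3Method generics::tidy
tidy.concordance_summary <- function(x, ...) x$by_label

#' One-row glance at a concordance summary
#'
#' @param x A `concordance_summary`.
#' @param ... Unused.
#' @return A one-row tibble: `total`, `shared_fraction`,
#'   `fp_fraction_of_ffpe_called`, `fn_fraction_of_ff_called`,
#'   `nd_fraction`.
#' @exportS3Method generics::glance
glance.concordance_summary <- function(x, ...) {
  tibble(total = x$total, shared_fraction = x$shared_fraction,
         fp_fraction_of_ffpe_called = x$fp_fraction_of_ffpe_called,
         fn_fraction_of_ff_called = x$fn_fraction_of_ff_called,
         nd_fraction = x$nd_fraction)
}

#' Tidy a substitution spectrum
#'
#' @param x A `substitution_spectrum` from [spectrum()].
#' @param ... Unused.
#' @return A tibble with `sample_id`, `class`, `n`, `fraction`.
#' @exportS3Method generics::tidy
tidy.substitution_spectrum <- function(x, ...) {
  total <- attr(x, "total")
  tibble(sample_id = attr(x, "sample_id"), class = x$class, n = x$n,
         fraction = if (total > 0) x$n / total else NA_real_)
}

#' One-row glance at a substitution spectrum
#'
#' @param x A `substitution_spectrum`.
#' @param ... Unused.
#' @return A one-row tibble: `sample_id`, `total`, `transitions`,
#'   `transversions`, `deamination_fraction` (share of `C>T/G>A`).
#' @exportS3Method generics::glance
glance.substitution_spectrum <- function(x, ...) {
  ti <- sum(x$n[x$class %in% transition_classes])
  tibble(sample_id = attr(x, "sample_id"), total = attr(x, "total"),
         transitions = ti, transversions = attr(x, "total") - ti,
         deamination_fraction = if (attr(x, "total") > 0)
           x$n[x$class == "C>T/G>A"] / attr(x, "total") else NA_real_)
}

#' Tidy an enrichment report
#'
#' @param x An `enrichment_report` from [enrichment()].
#' @param ... Unused.
#' @return The per-class tibble (`class`, `ffpe_n`, `ff_n`, `fold`,
#'   `undefined`).
#' @exportS3Method generics::tidy
tidy.enrichment_report <- function(x, ...) x$by_class

#' One-row glance at an enrichment report
#'
#' @param x An `enrichment_report`.
#' @param ... Unused.
#' @return A one-row tibble: `transition_fold`, `transversion_fold`.
#' @exportS3Method generics::glance
glance.enrichment_report <- function(x, ...) {
  tibble(transition_fold = x$transition_fold,
         transversion_fold = x$transversion_fold)
}
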