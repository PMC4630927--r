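# Strand-collapsed substitution spectra and deamination-artifact
# quantification. Formalin fixation deaminates cytosine, which surfaces
# in sequencing as C>T (and, read from the other strand, G>A)
# substitutions at low allele fraction; an excess of that class in
# FFPE-only (false positive) calls is the artifact fingerprint.

#' The six strand-collapsed substitution classes
#'
#' Pyrimidine-reference convention: each of the 12 directional single
#' nucleotide substitutions is collapsed with its reverse complement.
#'
#' @export
substitution_classes <- c("C>A/G>T", "C>G/G>C", "C>T/G>A",
                          "T>A/A>T", "T>C/A>G", "T>G/A>C")

#' Strand-collapsed class of a single-base substitution
#'
#' Substitutions with a purine (A/G) reference are complemented to their
#' pyrimidine-reference pair, so e.g. both C>T and G>A map to `C>T/G>A`.
#'
#' @param ref,alt Single bases in `A`, `C`, `G`, `T` with `ref != alt`.
#'   Vectorised.
#' @return Factor with levels [substitution_classes].
#' @examples
#' substitution_class(c("C", "G", "T"), c("T", "A", "G"))
#' @export
substitution_class <- function(ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  bases <- c("A", "C", "G", "T")
  ok <- ref %in% bases & alt %in% bases & ref != alt
  if (!all(ok)) {
    abort("substitution_class requires single-base ACGT alleles with ref != alt (indels are rejected here)",
          class = "ffpeconcord_bad_substitution")
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, comp[ref], ref)
  a <- ifelse(purine, comp[alt], alt)
  pair <- paste0(r, ">", a)
  cls <- c("C>A" = "C>A/G>T", "C>G" = "C>G/G>C", "C>T" = "C>T/G>A",
           "T>A" = "T>A/A>T", "T>C" = "T>C/A>G", "T>G" = "T>G/A>C")[pair]
  factor(unname(cls), levels = substitution_classes)
}

#' Substitution spectrum of an SNV callset
#'
#' Counts calls in each of the six strand-collapsed classes. Indels must
#' be filtered out beforehand (rows where `ref` or `alt` is not a single
#' base raise an error).
#'
#' @param calls A data frame of SNVs with columns `ref` and `alt`.
#' @param sample_id Optional label stored with the spectrum.
#' @return An object of class `substitution_spectrum`: a tibble with
#'   columns `class` and `n` (all six classes always present) plus
#'   attributes `total` and `sample_id`.
#' @examples
#' spectrum(tibble::tibble(ref = c("C", "G", "C"), alt = c("T", "A", "A")))
#' @export
spectrum <- function(calls, sample_id = NA_character_) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) {
    cls <- factor(character(), levels = substitution_classes)
  } else {
    cls <- substitution_class(calls$ref, calls$alt)
  }
  counts <- table(cls)
  out <- tibble(class = substitution_classes, n = as.integer(counts))
  structure(out, total = sum(out$n), sample_id = sample_id,
            class = c("substitution_spectrum", class(out)))
}

#' @export
print.substitution_spectrum <- function(x, ...) {
  sid <- attr(x, "sample_id")
  cat("Substitution spectrum",
      if (!is.na(sid)) paste0("(", sid, ")"), "—",
      attr(x, "total"), "SNVs\n")
  print(as_tibble(x))
  invisible(x)
}

transition_classes <- c("C>T/G>A", "T>C/A>G")

#' FFPE/FF substitution-class enrichment
#'
#' Per-class fold change of FFPE counts over FF counts, plus pooled
#' folds for transitions (`C>T/G>A` and `T>C/A>G`) and transversions
#' (the other four classes). A fold with a zero FF denominator and a
#' non-zero FFPE numerator is undefined and flagged (`NA` +
#' `undefined = TRUE`), never reported as infinite; 0/0 gives fold `NA`
#' without the flag. Folds use raw counts, mirroring how absolute
#' per-class counts are compared across sample types; set
#' `rate_per_mb` to a two-element vector of callable sizes (FFPE, FF; in
#' Mb) to normalise to rates instead.
#'
#' @param ffpe_spec,ff_spec [spectrum()] objects for the FFPE and FF
#'   callsets.
#' @param rate_per_mb Optional numeric length-2 vector `c(ffpe_mb, ff_mb)`.
#' @return An object of class `enrichment_report`: list with `by_class`
#'   tibble (`class`, `ffpe_n`, `ff_n`, `fold`, `undefined`),
#'   `transition_fold`, `transversion_fold`.
#' @examples
#' ff <- spectrum(tibble::tibble(ref = "C", alt = "T"))
#' ffpe <- spectrum(tibble::tibble(ref = rep("C", 10), alt = rep("T", 10)))
#' enrichment(ffpe, ff)
#' @export
enrichment <- function(ffpe_spec, ff_spec, rate_per_mb = NULL) {
  if (attr(ffpe_spec, "total") == 0 && attr(ff_spec, "total") == 0) {
    abort("both spectra are empty: enrichment undefined",
          class = "ffpeconcord_undefined_metric")
  }
  ffpe_n <- as.numeric(ffpe_spec$n)
  ff_n <- as.numeric(ff_spec$n)
  scale <- c(1, 1)
  if (!is.null(rate_per_mb)) {
    stopifnot(length(rate_per_mb) == 2, all(rate_per_mb > 0))
    scale <- rate_per_mb
  }
  fold <- ifelse(ff_n > 0, (ffpe_n / scale[1]) / (ff_n / scale[2]), NA_real_)
  by_class <- tibble(
    class = substitution_classes,
    ffpe_n = as.integer(ffpe_n), ff_n = as.integer(ff_n),
    fold = fold,
    undefined = ff_n == 0 & ffpe_n > 0
  )
  is_ti <- substitution_classes %in% transition_classes
  pool_fold <- function(sel) {
    num <- sum(ffpe_n[sel]) / scale[1]
    den <- sum(ff_n[sel]) / scale[2]
    if (den > 0) num / den else NA_real_
  }
  structure(
    list(by_class = by_class,
         transition_fold = pool_fold(is_ti),
         transversion_fold = pool_fold(!is_ti)),
    class = "enrichment_report"
  )
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("FFPE/FF substitution-class enrichment\n")
  print(x$by_class)
  cat(sprintf("transitions: %.1fx  transversions: %.1fx\n",
              x$transition_fold, x$transversion_fold))
  invisible(x)
}

#' Deamination-class fraction of false-positive calls
#'
#' Fraction of FFPE-only (False Positive) SNVs in class `C>T/G>A` — the
#' fingerprint of cytosine deamination by formalin.
#'
#' @param fp_calls SNV calls labelled `FALSE_POSITIVE`, with `ref` and
#'   `alt` columns.
#' @return A single fraction in `[0, 1]`.
#' @export
deamination_fp_fraction <- function(fp_calls) {
  fp_calls <- as_tibble(fp_calls)
  if (nrow(fp_calls) == 0) {
    abort("deamination fraction undefined for an empty false-positive set",
          class = "ffpeconcord_undefined_metric")
  }
  mean(substitution_class(fp_calls$ref, fp_calls$alt) == "C>T/G>A")
}
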