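#' Quality thresholds for FFPE Q-ratio gating
#'
#' The short-vs-long amplicon concentration ratio (Q-ratio) of a qPCR DNA
#' integrity panel separates high-quality from low-quality FFPE DNA. The
#' defaults encode the published gates: high quality (HQ) requires
#' Q129/Q41 above 0.5, low quality (LQ) is below 0.25, and in strict mode
#' HQ additionally requires a measurable Q305/Q41 above 0.1. Samples whose
#' Q129 ratio falls in the band `[lq_max_q129, hq_min_q129]` (boundaries
#' included, since the published gates are strict inequalities) are
#' reported as `INTERMEDIATE` rather than forced into either class.
#'
#' @param hq_min_q129 Q129/Q41 must exceed this for class `HQ`. Default 0.5.
#' @param lq_max_q129 Q129/Q41 below this gives class `LQ`. Default 0.25.
#' @param hq_min_q305 in strict mode, Q305/Q41 must additionally exceed
#'   this for `HQ`. Default 0.1.
#' @return A list of class `qc_thresholds`.
#' @examples
#' qc_thresholds()
#' qc_thresholds(hq_min_q129 = 0.6)
#' @export
qc_thresholds <- function(hq_min_q129 = 0.5, lq_max_q129 = 0.25,
                          hq_min_q305 = 0.1) {
  if (!(lq_max_q129 >= 0 && lq_max_q129 < hq_min_q129 && hq_min_q129 <= 1)) {
    abort("thresholds must satisfy 0 <= lq_max_q129 < hq_min_q129 <= 1",
          class = "ffpeconcord_invalid_thresholds")
  }
  structure(
    list(hq_min_q129 = hq_min_q129, lq_max_q129 = lq_max_q129,
         hq_min_q305 = hq_min_q305),
    class = "qc_thresholds"
  )
}

#' Compute qPCR Q-ratios from amplicon concentrations
#'
#' DNA integrity of FFPE extracts is assayed by qPCR amplification of a
#' 41 bp, 129 bp and 305 bp fragment of a single-copy gene. Degraded DNA
#' supports amplification of the short fragment but not the long ones, so
#' the concentration of each long amplicon normalised to the 41 bp
#' amplicon (the Q-ratio) falls from about 1 (intact DNA) towards 0 with
#' increasing fragmentation.
#'
#' @param panels A data frame with one row per sample and columns
#'   `sample_id`, `conc_41`, `conc_129`, `conc_305` (concentrations in any
#'   single consistent unit; all non-negative, `conc_41` strictly
#'   positive).
#' @return The input as a tibble with columns `q129 = conc_129/conc_41`
#'   and `q305 = conc_305/conc_41` appended and `quality_class` set to
#'   `NA` (assign it with [classify_quality()]).
#' @examples
#' panels <- tibble::tibble(
#'   sample_id = c("intact", "degraded"),
#'   conc_41 = c(10, 8), conc_129 = c(10, 1.6), conc_305 = c(10, 0)
#' )
#' compute_q_ratios(panels)
#' @seealso [classify_quality()], [simulate_qpcr()]
#' @export
compute_q_ratios <- function(panels) {
  panels <- as_tibble(panels)
  required <- c("sample_id", "conc_41", "conc_129", "conc_305")
  missing_cols <- setdiff(required, names(panels))
  if (length(missing_cols) > 0) {
    abort(paste0("amplicon panel is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ffpeconcord_bad_input")
  }
  conc <- panels[, c("conc_41", "conc_129", "conc_305")]
  if (any(is.na(conc))) {
    abort("amplicon concentrations must not be NA",
          class = "ffpeconcord_bad_input")
  }
  if (any(conc < 0)) {
    abort("amplicon concentrations must be non-negative",
          class = "ffpeconcord_bad_input")
  }
  if (any(panels$conc_41 <= 0)) {
    bad <- panels$sample_id[panels$conc_41 <= 0]
    abort(paste0("sample(s) unquantifiable (41 bp amplicon concentration ",
                 "is zero): ", paste(bad, collapse = ", ")),
          class = "ffpeconcord_unquantifiable")
  }
  panels |>
    mutate(
      q129 = .data$conc_129 / .data$conc_41,
      q305 = .data$conc_305 / .data$conc_41,
      quality_class = NA_character_
    )
}

#' Classify FFPE DNA quality from Q-ratios
#'
#' Gates each sample into `HQ` (Q129 ratio above the high-quality
#' threshold), `LQ` (below the low-quality threshold) or `INTERMEDIATE`
#' (the band between, boundaries included). By default only the Q129
#' ratio decides the class and Q305 is corroborating; with
#' `strict = TRUE` a sample must also have `q305 > hq_min_q305` to be
#' called `HQ` (it is demoted to `INTERMEDIATE` otherwise).
#'
#' @param profiles A data frame with columns `q129` and `q305`, as
#'   produced by [compute_q_ratios()].
#' @param thresholds A [qc_thresholds()] object.
#' @param strict Also require `q305 > hq_min_q305` for `HQ`?
#' @return `profiles` with `quality_class` filled in.
#' @examples
#' tibble::tibble(sample_id = "s", q129 = c(0.6, 0.4, 0.2),
#'                q305 = c(0.3, 0.1, 0)) |>
#'   classify_quality()
#' @export
classify_quality <- function(profiles, thresholds = qc_thresholds(),
                             strict = FALSE) {
  if (!inherits(thresholds, "qc_thresholds")) {
    abort("`thresholds` must be a qc_thresholds() object",
          class = "ffpeconcord_bad_input")
  }
  profiles <- as_tibble(profiles)
  if (!all(c("q129", "q305") %in% names(profiles))) {
    abort("profiles must have columns q129 and q305 (run compute_q_ratios first)",
          class = "ffpeconcord_bad_input")
  }
  cls <- with(thresholds, case_when(
    profiles$q129 > hq_min_q129 ~ "HQ",
    profiles$q129 < lq_max_q129 ~ "LQ",
    TRUE ~ "INTERMEDIATE"
  ))
  if (strict) {
    cls[cls == "HQ" & !(profiles$q305 > thresholds$hq_min_q305)] <-
      "INTERMEDIATE"
  }
  mutate(profiles, quality_class = cls)
}

#' Read an amplicon-panel table
#'
#' Expects tab-delimited text with a header row and columns `sample_id`,
#' `conc_41`, `conc_129`, `conc_305`.
#'
#' @param path Path to the file.
#' @return A tibble, one row per sample.
#' @export
read_amplicon_panel <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(sample_id = "c", .default = "d"))
  required <- c("sample_id", "conc_41", "conc_129", "conc_305")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("amplicon panel file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ffpeconcord_bad_input")
  }
  x
}

#' Write a QC report
#'
#' Tab-delimited output with columns `sample_id`, `q129`, `q305`,
#' `quality_class`.
#'
#' @param profiles Classified profiles from [classify_quality()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(profiles, path) {
  readr::write_tsv(
    select(as_tibble(profiles), "sample_id", "q129", "q305", "quality_class"),
    path
  )
  invisible(path)
}
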