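# End-to-end analysis: QC -> run metrics -> target restriction ->
# union merge -> concordance labels -> somatic selection -> substitution
# spectra / enrichment, with stage-level logging of record counts so the
# filtering funnel is visible in the report.

#' Build and validate a run configuration
#'
#' @param ff_vcf,ffpe_vcf Paths to the FF and FFPE tumour VCFs
#'   (required).
#' @param targets_bed Path to the capture-target BED (required).
#' @param normal_vcf Path to the matched-normal VCF; required when
#'   `somatic = TRUE`.
#' @param ff_depths,ffpe_depths,normal_depths Optional BedGraph depth
#'   tracks, used to recover depth at uncalled sites.
#' @param qpcr_panel,read_counts Optional wet-lab summary tables (see
#'   [read_amplicon_panel()], [read_read_counts()]).
#' @param popfreq Optional population-frequency table path.
#' @param annotations Optional consequence-annotation table path.
#' @param criteria [filter_criteria()] for the high-quality gate.
#' @param qc_thresholds [qc_thresholds()] for Q-ratio gating.
#' @param min_depth Concordance depth bar (strict `>`). Default 10.
#' @param nd_policy ND policy, see [classify_records()].
#' @param somatic_min_depth Somatic depth bar (`>=`). Default 6.
#' @param max_popfreq Population-frequency cutoff. Default 0.01.
#' @param somatic Run the somatic/spectrum stages? Default `TRUE`.
#' @param out_dir Optional output directory for the report files.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(ff_vcf, ffpe_vcf, targets_bed, normal_vcf = NULL,
                       ff_depths = NULL, ffpe_depths = NULL,
                       normal_depths = NULL, qpcr_panel = NULL,
                       read_counts = NULL, popfreq = NULL,
                       annotations = NULL,
                       criteria = filter_criteria(),
                       qc_thresholds = ffpeconcord::qc_thresholds(),
                       min_depth = 10,
                       nd_policy = "noncalling",
                       somatic_min_depth = 6, max_popfreq = 0.01,
                       somatic = TRUE, out_dir = NULL) {
  paths <- list(ff_vcf = ff_vcf, ffpe_vcf = ffpe_vcf,
                targets_bed = targets_bed, normal_vcf = normal_vcf,
                ff_depths = ff_depths, ffpe_depths = ffpe_depths,
                normal_depths = normal_depths, qpcr_panel = qpcr_panel,
                read_counts = read_counts, popfreq = popfreq,
                annotations = annotations)
  for (nm in names(paths)) {
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]])) {
      abort(paste0("configured input does not exist: ", nm, " = ",
                   paths[[nm]]),
            class = "ffpeconcord_bad_config")
    }
  }
  if (somatic && is.null(normal_vcf)) {
    abort("somatic stage requested but no normal_vcf configured",
          class = "ffpeconcord_bad_config")
  }
  structure(c(paths,
              list(criteria = criteria, qc_thresholds = qc_thresholds,
                   min_depth = min_depth, nd_policy = nd_policy,
                   somatic_min_depth = somatic_min_depth,
                   max_popfreq = max_popfreq, somatic = somatic,
                   out_dir = out_dir)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [run_config()]; threshold
#' blocks `criteria:` (`accepted_filter_labels`, `min_depth`,
#' `min_alt_ratio`) and `qc_thresholds:` (`hq_min_q129`, `lq_max_q129`,
#' `hq_min_q305`) are expanded into their constructor calls. Relative
#' paths are resolved against the YAML file's directory.
#'
#' @param path Path to the YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  path_keys <- c("ff_vcf", "ffpe_vcf", "targets_bed", "normal_vcf",
                 "ff_depths", "ffpe_depths", "normal_depths", "qpcr_panel",
                 "read_counts", "popfreq", "annotations")
  for (k in intersect(path_keys, names(y))) {
    if (!is.null(y[[k]]) && !grepl("^/", y[[k]])) {
      y[[k]] <- file.path(base, y[[k]])
    }
  }
  if (!is.null(y$criteria)) y$criteria <- do.call(filter_criteria, y$criteria)
  if (!is.null(y$qc_thresholds)) {
    y$qc_thresholds <- do.call(qc_thresholds, y$qc_thresholds)
  }
  do.call(run_config, y)
}

#' Run the full FF-vs-FFPE analysis
#'
#' Executes the stages in order — DNA-quality scoring (if a qPCR panel
#' is configured), run metrics (if read counts are configured), target
#' restriction, high-quality union merge, concordance classification,
#' somatic selection against the matched normal, substitution spectra
#' and FFPE/FF enrichment — and returns everything as one report
#' object. When `out_dir` is configured the report is also written to
#' disk ([write_report()]).
#'
#' @param config A [run_config()] (or path to a YAML file for
#'   [read_run_config()]).
#' @return An object of class `ffpe_report`: a list with elements `qc`,
#'   `metrics`, `records` (labelled union records), `concordance`
#'   (a `concordance_summary`), `somatic_ff`, `somatic_ffpe`,
#'   `spectrum_ff`, `spectrum_ffpe`, `enrichment`,
#'   `deamination_fp_fraction`, `funnel` (records in/out of each stage)
#'   and `provenance` (all thresholds, for exact reruns).
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  funnel <- list()
  note <- function(stage, n) funnel[[stage]] <<- n

  qc <- NULL
  if (!is.null(config$qpcr_panel)) {
    qc <- read_amplicon_panel(config$qpcr_panel) |>
      compute_q_ratios() |>
      classify_quality(config$qc_thresholds)
  }
  metrics <- NULL
  if (!is.null(config$read_counts)) {
    metrics <- read_count_metrics(read_read_counts(config$read_counts))
  }

  targets <- read_bed(config$targets_bed)
  ff <- read_vcf(config$ff_vcf)
  ffpe <- read_vcf(config$ffpe_vcf)
  note("ff_calls_raw", nrow(ff))
  note("ffpe_calls_raw", nrow(ffpe))
  ff <- restrict_to_targets(ff, targets)
  ffpe <- restrict_to_targets(ffpe, targets)
  note("ff_calls_on_target", nrow(ff))
  note("ffpe_calls_on_target", nrow(ffpe))

  ff_depths <- if (!is.null(config$ff_depths)) read_depth_track(config$ff_depths)
  ffpe_depths <- if (!is.null(config$ffpe_depths)) read_depth_track(config$ffpe_depths)
  records <- merge_pair(ff, ffpe, ff_depths, ffpe_depths,
                        criteria = config$criteria) |>
    classify_records(min_depth = config$min_depth,
                     nd_policy = config$nd_policy)
  note("union_high_quality", nrow(records))
  concordance <- summarize_concordance(records)

  somatic_ff <- somatic_ffpe <- NULL
  spectrum_ff <- spectrum_ffpe <- enr <- NULL
  deam_fp <- NA_real_
  if (isTRUE(config$somatic)) {
    normal <- restrict_to_targets(read_vcf(config$normal_vcf), targets)
    normal_depths <- if (!is.null(config$normal_depths)) {
      read_depth_track(config$normal_depths)
    }
    pf <- if (!is.null(config$popfreq)) read_popfreq(config$popfreq)
    somatic_ff <- select_somatic(ff, normal, pf, normal_depths,
                                 config$somatic_min_depth, config$max_popfreq)
    somatic_ffpe <- select_somatic(ffpe, normal, pf, normal_depths,
                                   config$somatic_min_depth,
                                   config$max_popfreq)
    note("somatic_ff", nrow(somatic_ff))
    note("somatic_ffpe", nrow(somatic_ffpe))
    if (!is.null(config$annotations)) {
      ann <- read_annotations(config$annotations)
      somatic_ff <- select_coding_nonsynonymous(somatic_ff, ann)
      somatic_ffpe <- select_coding_nonsynonymous(somatic_ffpe, ann)
      note("somatic_ff_nonsyn", nrow(somatic_ff))
      note("somatic_ffpe_nonsyn", nrow(somatic_ffpe))
    }
    snv_ff <- filter(somatic_ff, !.data$is_indel)
    snv_ffpe <- filter(somatic_ffpe, !.data$is_indel)
    spectrum_ff <- spectrum(snv_ff, "FF")
    spectrum_ffpe <- spectrum(snv_ffpe, "FFPE")
    if (attr(spectrum_ff, "total") + attr(spectrum_ffpe, "total") > 0) {
      enr <- enrichment(spectrum_ffpe, spectrum_ff)
    }
    fp_snvs <- filter(records, .data$label == "FALSE_POSITIVE",
                      !.data$is_indel)
    if (nrow(fp_snvs) > 0) deam_fp <- deamination_fp_fraction(fp_snvs)
  }

  report <- structure(
    list(qc = qc, metrics = metrics, records = records,
         concordance = concordance, somatic_ff = somatic_ff,
         somatic_ffpe = somatic_ffpe, spectrum_ff = spectrum_ff,
         spectrum_ffpe = spectrum_ffpe, enrichment = enr,
         deamination_fp_fraction = deam_fp, funnel = funnel,
         provenance = list(
           package_version = as.character(utils::packageVersion("ffpeconcord")),
           criteria = unclass(config$criteria),
           qc_thresholds = unclass(config$qc_thresholds),
           min_depth = config$min_depth, nd_policy = config$nd_policy,
           somatic_min_depth = config$somatic_min_depth,
           max_popfreq = config$max_popfreq,
           inputs = config[c("ff_vcf", "ffpe_vcf", "normal_vcf",
                             "targets_bed")])),
    class = "ffpe_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.ffpe_report <- function(x, ...) {
  cat("FF/FFPE whole-exome concordance report\n\n")
  if (!is.null(x$qc)) {
    cat("DNA quality (Q-ratios):\n")
    print(as.data.frame(x$qc[, c("sample_id", "q129", "q305",
                                 "quality_class")]), row.names = FALSE)
    cat("\n")
  }
  print(x$concordance)
  if (!is.null(x$enrichment)) {
    cat(sprintf("\nSomatic SNVs: FF %d, FFPE %d; transitions %.1fx, transversions %.1fx (FFPE/FF)\n",
                attr(x$spectrum_ff, "total"), attr(x$spectrum_ffpe, "total"),
                x$enrichment$transition_fold, x$enrichment$transversion_fold))
  }
  if (!is.na(x$deamination_fp_fraction)) {
    cat(sprintf("C>T/G>A fraction of FFPE false positives: %.1f%%\n",
                100 * x$deamination_fp_fraction))
  }
  invisible(x)
}

#' Write a report to disk
#'
#' Emits human-readable TSVs (one-decimal percentages, mirroring how
#' such tables are conventionally printed), the labelled union records
#' as VCF + TSV, and a machine-readable `report.json` at full precision
#' including the provenance block.
#'
#' @param report An `ffpe_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$qc)) {
    write_qc_report(report$qc, file.path(dir, "qc.tsv"))
  }
  if (!is.null(report$metrics)) {
    m <- report$metrics |>
      mutate(across(dplyr::ends_with("_fraction"),
                    ~ round(100 * .x, 1)))
    readr::write_tsv(m, file.path(dir, "metrics.tsv"))
  }
  write_labeled_records(report$records,
                        vcf_path = file.path(dir, "union_labeled.vcf"),
                        tsv_path = file.path(dir, "union_labeled.tsv"))
  readr::write_tsv(report$concordance$by_label,
                   file.path(dir, "concordance.tsv"))
  if (!is.null(report$spectrum_ff)) {
    sp <- bind_rows(FF = as_tibble(report$spectrum_ff),
                    FFPE = as_tibble(report$spectrum_ffpe), .id = "sample")
    readr::write_tsv(sp, file.path(dir, "spectra.tsv"))
  }
  if (!is.null(report$enrichment)) {
    readr::write_tsv(report$enrichment$by_class,
                     file.path(dir, "enrichment.tsv"))
  }
  json <- list(
    concordance = c(as.list(setNames(report$concordance$by_label$n,
                                     report$concordance$by_label$label)),
                    list(total = report$concordance$total,
                         shared_fraction = report$concordance$shared_fraction,
                         fp_fraction_of_ffpe_called =
                           report$concordance$fp_fraction_of_ffpe_called,
                         nd_fraction = report$concordance$nd_fraction)),
    deamination_fp_fraction = report$deamination_fp_fraction,
    transition_fold = if (!is.null(report$enrichment))
      report$enrichment$transition_fold,
    transversion_fold = if (!is.null(report$enrichment))
      report$enrichment$transversion_fold,
    funnel = report$funnel,
    provenance = report$provenance
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
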