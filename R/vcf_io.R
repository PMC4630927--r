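# VCF and annotation-table I/O. Reading goes through vcfR; writing is a
# minimal VCF 4.2 text emitter whose output round-trips losslessly
# through read_vcf() for every field the pipeline consumes.

#' Read a single-sample VCF into a call table
#'
#' Parses a VCF 4.x file, decomposes multi-allelic records into
#' biallelic ones, and extracts per-call allele depths from the sample
#' AD field (with DP as total-depth fallback when only one of them is
#' present). The FILTER column is preserved verbatim as `filter_label`;
#' 1-based positions are retained and only converted at interval
#' queries.
#'
#' @param path Path to a VCF file (plain text or gzip).
#' @param sample Sample column to read (default: the first).
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `filter_label`, `ref_depth`, `alt_depth`, `is_indel`. Records
#'   without a parseable AD are excluded with a warning giving their
#'   count. An empty VCF body gives an empty tibble.
#' @export
read_vcf <- function(path, sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), filter_label = character(),
                  ref_depth = numeric(), alt_depth = numeric(),
                  is_indel = logical())
  if (nrow(v@fix) == 0) return(empty)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (ncol(v@gt) < 2) {
    abort("VCF has no sample column", class = "ffpeconcord_bad_vcf")
  }
  sample_col <- if (is.null(sample)) colnames(v@gt)[2] else sample
  if (!sample_col %in% colnames(v@gt)) {
    abort(paste0("sample '", sample_col, "' not found in VCF"),
          class = "ffpeconcord_bad_vcf")
  }
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD")[, sample_col],
                 error = function(e) rep(NA_character_, nrow(fix)))
  out <- vector("list", nrow(fix))
  n_bad <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    depths <- suppressWarnings(
      as.numeric(strsplit(as.character(ad[i]), ",", fixed = TRUE)[[1]]))
    if (length(depths) < length(alts) + 1 || any(is.na(depths))) {
      n_bad <- n_bad + 1L
      next
    }
    out[[i]] <- tibble(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      ref = fix$REF[i], alt = alts,
      filter_label = if (is.na(fix$FILTER[i])) "." else fix$FILTER[i],
      ref_depth = depths[1], alt_depth = depths[1 + seq_along(alts)],
      is_indel = nchar(fix$REF[i]) != 1 | nchar(alts) != 1
    )
  }
  if (n_bad > 0) {
    warn(paste0(n_bad, " VCF record(s) without a parseable AD field excluded"))
  }
  res <- list_rbind(out[!vapply(out, is.null, TRUE)])
  if (nrow(res) == 0) empty else res
}

#' Write a call table as a single-sample VCF
#'
#' Minimal VCF 4.2 emitter: one biallelic record per row with
#' `GT:AD:DP` sample data and the call's `filter_label` in FILTER.
#'
#' @param calls Call table (`chrom`, `pos`, `ref`, `alt`, `filter_label`,
#'   `ref_depth`, `alt_depth`).
#' @param path Output path.
#' @param sample_id Name for the sample column.
#' @param info Optional character vector (length `nrow(calls)`) for the
#'   INFO column, e.g. concordance labels; defaults to `.`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample_id = "SAMPLE", info = NULL) {
  calls <- as_tibble(calls)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=ffpeconcord",
    "##INFO=<ID=LABEL,Number=1,Type=String,Description=\"FF/FFPE concordance label\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    paste0(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
             "FORMAT", sample_id), collapse = "\t")
  )
  if (nrow(calls) > 0) {
    info_col <- if (is.null(info)) rep(".", nrow(calls)) else info
    dp <- calls$ref_depth + calls$alt_depth
    body <- paste(
      calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
      calls$filter_label, info_col, "GT:AD:DP",
      sprintf("0/1:%d,%d:%d", as.integer(calls$ref_depth),
              as.integer(calls$alt_depth), as.integer(dp)),
      sep = "\t")
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write labelled union records as a VCF plus TSV
#'
#' The VCF carries the concordance label in the `LABEL` INFO tag, with
#' FFPE depths in the sample column; the TSV carries the full paired
#' record (per-sample allele depths, depth at site, label).
#'
#' @param records Labelled records from [classify_records()].
#' @param vcf_path,tsv_path Output paths (`NULL` to skip either).
#' @return Invisibly, a list of the written paths.
#' @export
write_labeled_records <- function(records, vcf_path = NULL, tsv_path = NULL) {
  records <- as_tibble(records)
  if (!is.null(vcf_path)) {
    calls <- tibble(
      chrom = records$chrom, pos = records$pos, ref = records$ref,
      alt = records$alt,
      filter_label = if_else(records$ffpe_called, records$ffpe_filter,
                             records$ff_filter),
      ref_depth = dplyr::coalesce(records$ffpe_ref_depth, 0),
      alt_depth = dplyr::coalesce(records$ffpe_alt_depth, 0)
    )
    write_vcf(calls, vcf_path, sample_id = "FFPE",
              info = paste0("LABEL=", records$label))
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(
      select(records, "chrom", "pos", "ref", "alt", "ff_called",
             "ffpe_called", "ff_ref_depth", "ff_alt_depth", "ffpe_ref_depth",
             "ffpe_alt_depth", "ff_depth", "ffpe_depth", "label"),
      tsv_path)
  }
  invisible(list(vcf = vcf_path, tsv = tsv_path))
}

#' Read a population-frequency table
#'
#' Tab-delimited with header: `chrom`, `pos`, `ref`, `alt`, `af`
#' (allele frequency in `[0, 1]`).
#'
#' @param path Path to the file.
#' @return A tibble.
#' @export
read_popfreq <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = "c", pos = "i", ref = "c",
                                          alt = "c", af = "d"))
}

#' Read a consequence-annotation table
#'
#' Tab-delimited with header: `chrom`, `pos`, `ref`, `alt`,
#' `consequence` (see [nonsynonymous_consequences] for the controlled
#' vocabulary).
#'
#' @param path Path to the file.
#' @return A tibble.
#' @export
read_annotations <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = "c", pos = "i", ref = "c",
                                          alt = "c", consequence = "c"))
}

#' Write a simulated study to disk
#'
#' Emits every artefact of a [simulate_paired_callsets()] run in the
#' formats the pipeline reads back: three VCFs, a targets BED, three
#' BedGraph depth tracks, the truth and population-frequency TSVs, the
#' qPCR amplicon panel and the read-count summary.
#'
#' @param sim An `ffpe_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ffpe_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_vcf(sim$ff_calls, p("ff.vcf"), "FF")
  write_vcf(sim$ffpe_calls, p("ffpe.vcf"), "FFPE")
  write_vcf(sim$normal_calls, p("normal.vcf"), "NORMAL")
  readr::write_tsv(sim$targets, p("targets.bed"), col_names = FALSE)
  for (s in c("ff", "ffpe", "normal")) {
    readr::write_tsv(sim[[paste0(s, "_depths")]],
                     p(paste0(s, "_depth.bedgraph")), col_names = FALSE)
  }
  readr::write_tsv(sim$truth, p("truth.tsv"))
  readr::write_tsv(sim$popfreq, p("popfreq.tsv"))
  readr::write_tsv(sim$qpcr, p("qpcr_panel.tsv"))
  readr::write_tsv(sim$read_counts, p("read_counts.tsv"))
  paths <- c("ff.vcf", "ffpe.vcf", "normal.vcf", "targets.bed",
             "ff_depth.bedgraph", "ffpe_depth.bedgraph",
             "normal_depth.bedgraph", "truth.tsv", "popfreq.tsv",
             "qpcr_panel.tsv", "read_counts.tsv")
  invisible(setNames(as.list(file.path(dir, paths)),
                     sub("[.].*$", "", paths)))
}
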