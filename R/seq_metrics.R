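# Run-level and coverage metrics: the per-sample summaries a sequencing
# core reports for an exome run (duplicate/mapped/trimmed fractions,
# depth and breadth over the capture design, off-target rate).

#' PCR-duplicate fraction
#'
#' Fraction of raw reads flagged as PCR duplicates,
#' `(total - unique) / total`.
#'
#' @param total_reads,unique_reads Read counts before and after duplicate
#'   removal. Vectorised.
#' @return Fraction in `[0, 1]`.
#' @examples
#' pcr_duplicate_fraction(63523138, 58598506) # 0.078
#' @export
pcr_duplicate_fraction <- function(total_reads, unique_reads) {
  if (any(total_reads <= 0)) {
    abort("PCR-duplicate fraction undefined: total_reads must be > 0",
          class = "ffpeconcord_undefined_metric")
  }
  if (any(unique_reads > total_reads | unique_reads < 0)) {
    abort("unique_reads must lie in [0, total_reads]",
          class = "ffpeconcord_bad_input")
  }
  (total_reads - unique_reads) / total_reads
}

#' Mapped-read fraction
#'
#' Fraction of unique (deduplicated) reads that map to the reference,
#' `mapped / unique`. Defined against unique rather than raw reads: that
#' is the denominator under which the published per-sample percentages
#' are self-consistent.
#'
#' @param mapped_reads,unique_reads Read counts. Vectorised.
#' @return Fraction in `[0, 1]`.
#' @examples
#' mapped_fraction(57879604, 58598506) # 0.988
#' @export
mapped_fraction <- function(mapped_reads, unique_reads) {
  if (any(unique_reads <= 0)) {
    abort("mapped fraction undefined: unique_reads must be > 0",
          class = "ffpeconcord_undefined_metric")
  }
  if (any(mapped_reads > unique_reads | mapped_reads < 0)) {
    abort("mapped_reads must lie in [0, unique_reads]",
          class = "ffpeconcord_bad_input")
  }
  mapped_reads / unique_reads
}

#' Trimmed-base fraction
#'
#' Fraction of raw sequenced bases removed by adapter/quality trimming,
#' `1 - high_quality_bases / (total_reads * read_length)`.
#'
#' @param total_reads Raw read count.
#' @param high_quality_bases Bases surviving trimming.
#' @param read_length Read length in bp (default 100).
#' @return Fraction in `[0, 1]`. Vectorised.
#' @examples
#' trimmed_base_fraction(63523138, 5.84e9) # 0.081
#' @export
trimmed_base_fraction <- function(total_reads, high_quality_bases,
                                  read_length = 100) {
  if (any(total_reads <= 0) || any(read_length <= 0)) {
    abort("trimmed-base fraction undefined: total_reads and read_length must be > 0",
          class = "ffpeconcord_undefined_metric")
  }
  raw <- total_reads * read_length
  if (any(high_quality_bases > raw)) {
    abort("high_quality_bases exceeds total sequenced bases",
          class = "ffpeconcord_bad_input")
  }
  1 - high_quality_bases / raw
}

#' Per-sample run metrics table
#'
#' Applies [pcr_duplicate_fraction()], [mapped_fraction()] and
#' [trimmed_base_fraction()] row-wise to a read-count summary table.
#'
#' @param counts A data frame with columns `sample_id`, `total_reads`,
#'   `unique_reads`, `mapped_reads`, `hq_bases` and optionally
#'   `read_length` (default 100).
#' @return A tibble with the input columns plus `dup_fraction`,
#'   `mapped_fraction`, `trimmed_fraction`.
#' @examples
#' tibble::tibble(sample_id = "GIST193_FF", total_reads = 63523138,
#'                unique_reads = 58598506, mapped_reads = 57879604,
#'                hq_bases = 5.84e9) |>
#'   read_count_metrics()
#' @export
read_count_metrics <- function(counts) {
  counts <- as_tibble(counts)
  required <- c("sample_id", "total_reads", "unique_reads", "mapped_reads",
                "hq_bases")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols) > 0) {
    abort(paste0("read-count table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ffpeconcord_bad_input")
  }
  if (!"read_length" %in% names(counts)) counts$read_length <- 100
  counts |>
    mutate(
      dup_fraction = pcr_duplicate_fraction(.data$total_reads,
                                            .data$unique_reads),
      mapped_fraction = mapped_fraction(.data$mapped_reads,
                                        .data$unique_reads),
      trimmed_fraction = trimmed_base_fraction(.data$total_reads,
                                               .data$hq_bases,
                                               .data$read_length)
    )
}

#' Read a read-count summary table
#'
#' Tab-delimited with header: `sample_id`, `total_reads`, `unique_reads`,
#' `mapped_reads`, `hq_bases`, and optionally `read_length`.
#'
#' @param path Path to the file.
#' @return A tibble.
#' @export
read_read_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(sample_id = "c", .default = "d"))
}

#' Depth and breadth of coverage over target regions
#'
#' Summarises a per-base or BedGraph-style depth track over the capture
#' design: mean depth per target bp and the fraction of target positions
#' covered at or above each breadth threshold. Target positions absent
#' from the track count as depth 0.
#'
#' @param track A data frame with columns `chrom`, `start`, `end`,
#'   `depth` (0-based half-open intervals of constant depth).
#' @param targets Merged target intervals from [read_bed()] /
#'   [merge_targets()].
#' @param breadth_at Integer thresholds for breadth-of-coverage (default
#'   `c(1, 10)`).
#' @return A one-row tibble: `mean_depth`, one `breadth_ge_<k>x` column
#'   per threshold, and `target_size`.
#' @examples
#' targets <- merge_targets(tibble::tibble(chrom = "chrS1", start = 0, end = 100))
#' track <- tibble::tibble(chrom = "chrS1", start = 0, end = 50, depth = 20)
#' coverage_summary(track, targets) # mean 10, breadth_1x = breadth_10x = 0.5
#' @export
coverage_summary <- function(track, targets, breadth_at = c(1, 10)) {
  if (is.null(targets) || nrow(targets) == 0) {
    abort("target set is empty", class = "ffpeconcord_bad_input")
  }
  track <- as_tibble(track)
  tsize <- target_size(targets)
  tchrom <- normalize_chrom(targets$chrom)
  kchrom <- normalize_chrom(track$chrom)
  total_depth <- 0
  covered_ge <- setNames(numeric(length(breadth_at)),
                         paste0("breadth_ge_", breadth_at, "x"))
  for (cc in unique(tchrom)) {
    sel_t <- tchrom == cc
    sel_k <- kchrom == cc
    ir_t <- ir_from_bed(targets$start[sel_t], targets$end[sel_t])
    if (!any(sel_k)) next
    ir_k <- ir_from_bed(track$start[sel_k], track$end[sel_k])
    dep <- track$depth[sel_k]
    ov <- IRanges::findOverlaps(ir_k, ir_t)
    if (length(ov) == 0) next
    w <- IRanges::width(IRanges::pintersect(
      ir_k[S4Vectors::queryHits(ov)], ir_t[S4Vectors::subjectHits(ov)]))
    d <- dep[S4Vectors::queryHits(ov)]
    total_depth <- total_depth + sum(as.numeric(w) * d)
    for (i in seq_along(breadth_at)) {
      covered_ge[i] <- covered_ge[i] + sum(as.numeric(w)[d >= breadth_at[i]])
    }
  }
  out <- tibble(mean_depth = total_depth / tsize)
  for (i in seq_along(breadth_at)) {
    out[[names(covered_ge)[i]]] <- unname(covered_ge[i]) / tsize
  }
  out$target_size <- tsize
  out
}

#' Off-target read fraction
#'
#' Fraction of aligned reads whose interval overlaps no target interval
#' by at least 1 bp.
#'
#' @param reads A data frame of alignment intervals with columns `chrom`,
#'   `start`, `end` (0-based half-open).
#' @param targets Merged target intervals.
#' @return A single fraction in `[0, 1]`.
#' @export
off_target_fraction <- function(reads, targets) {
  reads <- as_tibble(reads)
  if (nrow(reads) == 0) {
    abort("off-target fraction undefined for an empty read set",
          class = "ffpeconcord_undefined_metric")
  }
  on <- interval_overlaps_targets(reads$chrom, reads$start, reads$end, targets)
  mean(!on)
}

#' Read a BedGraph-style depth track
#'
#' 4-column tab-delimited text (`chrom`, `start`, `end`, `depth`), no
#' header, 0-based half-open.
#'
#' @param path Path to the file.
#' @return A tibble.
#' @export
read_depth_track <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(x) < 4) {
    abort("depth track must have 4 columns (chrom, start, end, depth)",
          class = "ffpeconcord_bad_input")
  }
  x <- x[, 1:4]
  names(x) <- c("chrom", "start", "end", "depth")
  as_tibble(x)
}
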