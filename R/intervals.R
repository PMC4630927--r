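# Interval utilities. Public surface is tibbles of 0-based half-open
# intervals (BED convention: chrom, start, end); IRanges does the set
# arithmetic internally (converted to 1-based closed coordinates).

ir_from_bed <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

#' Normalise chromosome names
#'
#' Strips a leading "chr" prefix (case-insensitive) so callsets and BED
#' files using different conventions can be compared. `chrS1`-style
#' synthetic contig names keep their suffix (`S1`).
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector without the `chr` prefix.
#' @export
normalize_chrom <- function(chrom) sub("^[Cc][Hh][Rr]", "", as.character(chrom))

#' Read exome target regions from a BED file
#'
#' Reads a 3+ column BED file (0-based half-open), sorts it and merges
#' overlapping or bookended intervals per chromosome.
#'
#' @param path Path to the BED file.
#' @return A tibble of merged intervals with columns `chrom`, `start`,
#'   `end`, carrying the total target span in bp as attribute
#'   `target_size`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200", "chr1\t150\t250"), bed)
#' read_bed(bed) # one merged interval [100, 250)
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(x) < 3) {
    abort("BED file must have at least 3 columns", class = "ffpeconcord_bad_bed")
  }
  x <- x[, 1:3]
  names(x) <- c("chrom", "start", "end")
  x$chrom <- as.character(x$chrom)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  bad <- which(x$start > x$end | x$start < 0)
  if (length(bad) > 0) {
    abort(paste0("invalid BED interval (start > end or negative) at line(s): ",
                 paste(bad, collapse = ", ")),
          class = "ffpeconcord_bad_bed")
  }
  merge_targets(as_tibble(x))
}

#' Sort and merge target intervals
#'
#' @param targets A data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return Tibble of disjoint sorted intervals with attribute
#'   `target_size` (total span in bp).
#' @export
merge_targets <- function(targets) {
  targets <- as_tibble(targets)
  if (nrow(targets) == 0) {
    abort("target set is empty", class = "ffpeconcord_bad_bed")
  }
  merged <- targets |>
    group_by(.data$chrom) |>
    group_modify(~ {
      red <- IRanges::reduce(ir_from_bed(.x$start, .x$end))
      tibble(start = IRanges::start(red) - 1L, end = IRanges::end(red))
    }) |>
    ungroup() |>
    arrange(.data$chrom, .data$start)
  attr(merged, "target_size") <- sum(merged$end - merged$start)
  merged
}

#' Total span of a target set in bp
#' @param targets Merged targets from [read_bed()] or [merge_targets()].
#' @return Integer total width.
#' @export
target_size <- function(targets) {
  attr(targets, "target_size") %||% sum(targets$end - targets$start)
}

# For each (chrom, pos) query (pos 1-based), TRUE if inside any target.
# Targets must be a chrom/start/end tibble (0-based half-open).
pos_in_targets <- function(chrom, pos, targets) {
  chrom <- normalize_chrom(chrom)
  tchrom <- normalize_chrom(targets$chrom)
  hit <- logical(length(chrom))
  for (cc in unique(chrom)) {
    sel_t <- tchrom == cc
    sel_q <- chrom == cc
    if (!any(sel_t)) next
    ir_t <- ir_from_bed(targets$start[sel_t], targets$end[sel_t])
    ir_q <- IRanges::IRanges(start = pos[sel_q], width = 1L)
    hit[sel_q] <- IRanges::overlapsAny(ir_q, ir_t)
  }
  hit
}

# For interval queries (0-based half-open), TRUE if >= 1 bp overlap with
# any target interval.
interval_overlaps_targets <- function(chrom, start, end, targets) {
  chrom <- normalize_chrom(chrom)
  tchrom <- normalize_chrom(targets$chrom)
  hit <- logical(length(chrom))
  for (cc in unique(chrom)) {
    sel_t <- tchrom == cc
    sel_q <- chrom == cc
    if (!any(sel_t)) next
    ir_t <- ir_from_bed(targets$start[sel_t], targets$end[sel_t])
    ir_q <- ir_from_bed(start[sel_q], end[sel_q])
    hit[sel_q] <- IRanges::overlapsAny(ir_q, ir_t, minoverlap = 1L)
  }
  hit
}

#' Look up depth at single positions from a BedGraph-style track
#'
#' @param track A data frame with columns `chrom`, `start`, `end`,
#'   `depth` (0-based half-open; later rows win where intervals overlap,
#'   which lets site-level recounts override a coarse baseline).
#' @param chrom,pos Query positions, `pos` 1-based.
#' @return Numeric depth per query; positions not covered by the track
#'   get `NA`.
#' @export
depth_at <- function(track, chrom, pos) {
  track <- as_tibble(track)
  chrom <- normalize_chrom(chrom)
  if (length(chrom) == 1) chrom <- rep(chrom, length(pos))
  stopifnot(length(chrom) == length(pos))
  tchrom <- normalize_chrom(track$chrom)
  out <- rep(NA_real_, length(chrom))
  for (cc in unique(chrom)) {
    sel_t <- which(tchrom == cc)
    sel_q <- which(chrom == cc)
    if (length(sel_t) == 0) next
    ir_t <- ir_from_bed(track$start[sel_t], track$end[sel_t])
    ir_q <- IRanges::IRanges(start = pos[sel_q], width = 1L)
    ov <- IRanges::findOverlaps(ir_q, ir_t)
    if (length(ov) == 0) next
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    # keep the last matching track row per query (overrides beat baseline)
    keep <- tapply(seq_along(qh), qh, function(i) i[which.max(sh[i])])
    keep <- unlist(keep, use.names = FALSE)
    out[sel_q[qh[keep]]] <- track$depth[sel_t[sh[keep]]]
  }
  out
}
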