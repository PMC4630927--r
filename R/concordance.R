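# FF-vs-FFPE concordance: quality filtering of variant calls, union
# merge of the paired callsets, the Shared / False Positive / False
# Negative / Not Determined rule table, and somatic selection against a
# matched normal.

#' Quality-filter criteria for variant calls
#'
#' A call is "high quality" when its caller filter label is accepted
#' (KEEP/PASS), its re-counted depth of coverage exceeds `min_depth`
#' (strict), and its alternate-allele ratio is at least `min_alt_ratio`.
#'
#' @param accepted_filter_labels Accepted caller filter labels.
#' @param min_depth Depth of coverage must be strictly greater. Default 10.
#' @param min_alt_ratio Alternate-allele ratio `alt/(ref+alt)` must be at
#'   least this. Default 0.2.
#' @return A list of class `filter_criteria`.
#' @export
filter_criteria <- function(accepted_filter_labels = c("KEEP", "PASS"),
                            min_depth = 10, min_alt_ratio = 0.2) {
  if (min_depth < 0 || min_alt_ratio < 0 || min_alt_ratio > 1) {
    abort("min_depth must be >= 0 and min_alt_ratio in [0, 1]",
          class = "ffpeconcord_bad_input")
  }
  structure(list(accepted_filter_labels = accepted_filter_labels,
                 min_depth = min_depth, min_alt_ratio = min_alt_ratio),
            class = "filter_criteria")
}

#' Alternate-allele fraction as a percentage
#'
#' `100 * alt / (ref + alt)`, the variant allele fraction (VAF) of a site
#' from its re-counted reference and alternate read depths.
#'
#' @param ref_depth,alt_depth Read counts supporting the reference and
#'   alternate allele. Vectorised.
#' @return Percentage in `[0, 100]`.
#' @examples
#' allele_fraction(2, 160)   # 98.8 — near-homozygous in tumour
#' allele_fraction(109, 35)  # 24.3 — subclonal / low cellularity
#' allele_fraction(116, 0)   # 0   — absent in normal
#' @export
allele_fraction <- function(ref_depth, alt_depth) {
  total <- ref_depth + alt_depth
  if (any(total <= 0)) {
    abort("allele fraction undefined at zero total depth",
          class = "ffpeconcord_undefined_metric")
  }
  if (any(ref_depth < 0 | alt_depth < 0)) {
    abort("read depths must be non-negative", class = "ffpeconcord_bad_input")
  }
  100 * alt_depth / total
}

#' Does each call pass the high-quality criteria?
#'
#' @param calls A data frame of calls with columns `filter_label`,
#'   `ref_depth`, `alt_depth`.
#' @param criteria A [filter_criteria()] object.
#' @return Logical vector, one element per row of `calls`.
#' @examples
#' calls <- tibble::tibble(filter_label = c("PASS", "PASS", "REJECT"),
#'                         ref_depth = c(8, 9, 50), alt_depth = c(3, 1, 50))
#' passes_quality(calls) # TRUE FALSE FALSE
#' @export
passes_quality <- function(calls, criteria = filter_criteria()) {
  calls <- as_tibble(calls)
  total <- calls$ref_depth + calls$alt_depth
  ratio <- if_else(total > 0, calls$alt_depth / total, 0)
  calls$filter_label %in% criteria$accepted_filter_labels &
    total > criteria$min_depth &
    ratio >= criteria$min_alt_ratio
}

variant_key <- function(x) paste(normalize_chrom(x$chrom), x$pos, x$ref, x$alt)

#' Restrict calls to the capture target region
#'
#' Retains calls whose 1-based position lies inside a (0-based half-open)
#' target interval; everything else is off-target and excluded, matching
#' the analysis convention for exome data.
#'
#' @param calls A data frame of calls with columns `chrom`, `pos`.
#' @param targets Merged target intervals from [read_bed()].
#' @return The retained rows of `calls`, as a tibble.
#' @section Errors: chromosomes present in `calls` but absent from
#'   `targets` (after chr-prefix normalisation) raise an error naming
#'   them, since that almost always indicates mismatched naming schemes
#'   rather than genuine off-target calls.
#' @export
restrict_to_targets <- function(calls, targets) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) return(calls)
  unmatched <- setdiff(unique(normalize_chrom(calls$chrom)),
                       unique(normalize_chrom(targets$chrom)))
  if (length(unmatched) > 0) {
    abort(paste0("chromosome(s) in callset not present in targets: ",
                 paste(unmatched, collapse = ", ")),
          class = "ffpeconcord_chrom_mismatch")
  }
  calls[pos_in_targets(calls$chrom, calls$pos, targets), ]
}

check_no_duplicate_sites <- function(calls, sample) {
  key <- variant_key(calls)
  if (anyDuplicated(key)) {
    abort(paste0("malformed callset (", sample, "): duplicate variant record(s) ",
                 paste(unique(key[duplicated(key)]), collapse = "; ")),
          class = "ffpeconcord_duplicate_variant")
  }
}

#' Merge an FF/FFPE callset pair into union records
#'
#' Builds the union of the two callsets over the full variant identity
#' `(chrom, pos, ref, alt)` and keeps a site only if it is high quality
#' (per `criteria`) in at least one of the two samples. For the sample in
#' which a retained variant was not called, depth of coverage at the site
#' is looked up in that sample's depth track; when no track covers the
#' site the depth is `NA` and the record will classify as Not Determined.
#'
#' @param ff_calls,ffpe_calls Call tables (columns `chrom`, `pos`, `ref`,
#'   `alt`, `filter_label`, `ref_depth`, `alt_depth`; optional
#'   `is_indel`).
#' @param ff_depths,ffpe_depths Optional BedGraph-style depth tracks
#'   (`chrom`, `start`, `end`, `depth`) used for uncalled sites.
#' @param criteria A [filter_criteria()] object.
#' @return A tibble of paired records: the variant key, per-sample call
#'   status (`ff_called`, `ffpe_called`), per-sample allele depths where
#'   called, and `ff_depth` / `ffpe_depth` — total depth of coverage at
#'   the site in each sample.
#' @export
merge_pair <- function(ff_calls, ffpe_calls, ff_depths = NULL,
                       ffpe_depths = NULL, criteria = filter_criteria()) {
  ff <- as_tibble(ff_calls)
  ffpe <- as_tibble(ffpe_calls)
  check_no_duplicate_sites(ff, "FF")
  check_no_duplicate_sites(ffpe, "FFPE")
  if (!"is_indel" %in% names(ff)) {
    ff$is_indel <- nchar(ff$ref) != 1 | nchar(ff$alt) != 1
  }
  if (!"is_indel" %in% names(ffpe)) {
    ffpe$is_indel <- nchar(ffpe$ref) != 1 | nchar(ffpe$alt) != 1
  }
  ff$ff_pass <- passes_quality(ff, criteria)
  ffpe$ffpe_pass <- passes_quality(ffpe, criteria)
  # join on chr-prefix-normalised keys but keep original chromosome names
  key_cols <- c(".ckey", "pos", "ref", "alt", "is_indel")
  ff <- ff |>
    mutate(.ckey = normalize_chrom(.data$chrom)) |>
    select(dplyr::all_of(key_cols), ff_chrom = "chrom",
           ff_filter = "filter_label", ff_ref_depth = "ref_depth",
           ff_alt_depth = "alt_depth", "ff_pass")
  ffpe <- ffpe |>
    mutate(.ckey = normalize_chrom(.data$chrom)) |>
    select(dplyr::all_of(key_cols), ffpe_chrom = "chrom",
           ffpe_filter = "filter_label", ffpe_ref_depth = "ref_depth",
           ffpe_alt_depth = "alt_depth", "ffpe_pass")
  rec <- full_join(ff, ffpe, by = key_cols) |>
    mutate(
      chrom = dplyr::coalesce(.data$ff_chrom, .data$ffpe_chrom),
      ff_called = !is.na(.data$ff_filter),
      ffpe_called = !is.na(.data$ffpe_filter),
      ff_pass = if_else(is.na(.data$ff_pass), FALSE, .data$ff_pass),
      ffpe_pass = if_else(is.na(.data$ffpe_pass), FALSE, .data$ffpe_pass)
    ) |>
    filter(.data$ff_pass | .data$ffpe_pass) |>
    select(-".ckey", -"ff_chrom", -"ffpe_chrom") |>
    select("chrom", dplyr::everything())
  ff_depth <- ifelse(rec$ff_called,
                     rec$ff_ref_depth + rec$ff_alt_depth, NA_real_)
  ffpe_depth <- ifelse(rec$ffpe_called,
                       rec$ffpe_ref_depth + rec$ffpe_alt_depth, NA_real_)
  if (!is.null(ff_depths) && any(!rec$ff_called)) {
    i <- which(!rec$ff_called)
    ff_depth[i] <- depth_at(ff_depths, rec$chrom[i], rec$pos[i])
  }
  if (!is.null(ffpe_depths) && any(!rec$ffpe_called)) {
    i <- which(!rec$ffpe_called)
    ffpe_depth[i] <- depth_at(ffpe_depths, rec$chrom[i], rec$pos[i])
  }
  rec$ff_depth <- ff_depth
  rec$ffpe_depth <- ffpe_depth
  arrange(rec, .data$chrom, .data$pos, .data$ref, .data$alt)
}

concordance_labels <- c("SHARED", "FALSE_POSITIVE", "FALSE_NEGATIVE",
                        "NOT_DETERMINED")

#' Classify paired records as Shared / FP / FN / ND
#'
#' Applies the concordance rule table to each union record:
#' * depth of coverage `<= min_depth` in the decisive sample(s) — Not
#'   Determined (ND);
#' * otherwise Shared if called in both samples, FFPE False Positive if
#'   called in FFPE only, FFPE False Negative if called in FF only.
#'
#' Which sample must clear the depth bar is governed by `nd_policy`. The
#' default, `"noncalling"`, demands adequate coverage where it is
#' decisive: for a single-sample call, in the sample where the variant
#' was *not* called (an FP/FN verdict is only evidence-supported if the
#' silent sample was adequately covered); for a double call, in both.
#' `"either"` is the stricter alternative: depth `<= min_depth` in either
#' sample always gives ND. Unknown (`NA`) depth counts as insufficient.
#'
#' @param records Paired records from [merge_pair()].
#' @param min_depth Depth must be strictly greater to escape ND. Default 10.
#' @param nd_policy `"noncalling"` (default) or `"either"`.
#' @return `records` with a `label` factor column (levels `SHARED`,
#'   `FALSE_POSITIVE`, `FALSE_NEGATIVE`, `NOT_DETERMINED`).
#' @export
classify_records <- function(records, min_depth = 10,
                             nd_policy = c("noncalling", "either")) {
  nd_policy <- match.arg(nd_policy)
  records <- as_tibble(records)
  ffd <- records$ff_depth
  fpd <- records$ffpe_depth
  ff_ok <- !is.na(ffd) & ffd > min_depth
  fp_ok <- !is.na(fpd) & fpd > min_depth
  nd <- switch(nd_policy,
    noncalling = (records$ff_called & records$ffpe_called & !(ff_ok & fp_ok)) |
      (records$ff_called & !records$ffpe_called & !fp_ok) |
      (!records$ff_called & records$ffpe_called & !ff_ok),
    either = !(ff_ok & fp_ok)
  )
  lab <- case_when(
    nd ~ "NOT_DETERMINED",
    records$ff_called & records$ffpe_called ~ "SHARED",
    records$ffpe_called ~ "FALSE_POSITIVE",
    TRUE ~ "FALSE_NEGATIVE"
  )
  mutate(records, label = factor(lab, levels = concordance_labels))
}

#' Summarise concordance labels
#'
#' Per-label counts and fractions of the union total, plus the headline
#' quantities: the shared fraction of all union variants and the
#' false-positive fraction of FFPE-called variants.
#'
#' @param records Labelled records from [classify_records()].
#' @return An object of class `concordance_summary`; see [tidy()] /
#'   [glance()] for tabular views.
#' @export
summarize_concordance <- function(records) {
  records <- as_tibble(records)
  if (!"label" %in% names(records)) {
    abort("records are unlabelled: run classify_records() first",
          class = "ffpeconcord_bad_input")
  }
  lab <- factor(records$label, levels = concordance_labels)
  counts <- table(lab)
  total <- nrow(records)
  by_label <- tibble(
    label = names(counts),
    n = as.integer(counts),
    fraction = if (total > 0) as.numeric(counts) / total else rep(NA_real_, 4)
  )
  ffpe_called <- sum(records$ffpe_called & lab != "NOT_DETERMINED")
  ff_called <- sum(records$ff_called & lab != "NOT_DETERMINED")
  structure(
    list(
      by_label = by_label,
      total = total,
      shared_fraction = if (total > 0) by_label$n[1] / total else NA_real_,
      fp_fraction_of_ffpe_called =
        if (ffpe_called > 0) by_label$n[2] / ffpe_called else NA_real_,
      fn_fraction_of_ff_called =
        if (ff_called > 0) by_label$n[3] / ff_called else NA_real_,
      nd_fraction = if (total > 0) by_label$n[4] / total else NA_real_
    ),
    class = "concordance_summary"
  )
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("FF/FFPE concordance over", x$total, "union variants\n")
  df <- as.data.frame(x$by_label)
  df$fraction <- sprintf("%.1f%%", 100 * df$fraction)
  print(df, row.names = FALSE)
  if (!is.na(x$fp_fraction_of_ffpe_called)) {
    cat(sprintf("False positives: %.1f%% of FFPE-called variants\n",
                100 * x$fp_fraction_of_ffpe_called))
  }
  invisible(x)
}

#' Select somatic variants against a matched normal
#'
#' Retains tumour calls that are absent from the matched-normal callset,
#' have a catalogued population allele frequency no greater than
#' `max_popfreq` (unreported frequencies are retained), and are covered
#' at depth `>= min_somatic_depth` in both tumour and normal. The depth
#' bar is deliberately lower than the concordance bar (6X vs strictly
#' >10X) to keep sensitivity on lower-coverage normals and degraded FFPE.
#'
#' @param tumor_calls Tumour call table (`chrom`, `pos`, `ref`, `alt`,
#'   `ref_depth`, `alt_depth`, ...).
#' @param normal_calls Matched-normal call table (same columns).
#' @param popfreq Optional population-frequency table (`chrom`, `pos`,
#'   `ref`, `alt`, `af`), e.g. from dbSNP/1000 Genomes annotations.
#' @param normal_depths Optional depth track for the normal sample; when
#'   supplied, sites with normal depth `< min_somatic_depth` (or not
#'   covered by the track) are excluded.
#' @param min_somatic_depth Minimum depth in tumour (and normal, if its
#'   track is given). Default 6, inclusive.
#' @param max_popfreq Maximum population allele frequency. Default 0.01.
#' @return The retained tumour calls, as a tibble with an `af_pop` column
#'   (`NA` when unreported).
#' @export
select_somatic <- function(tumor_calls, normal_calls, popfreq = NULL,
                           normal_depths = NULL, min_somatic_depth = 6,
                           max_popfreq = 0.01) {
  tumor <- as_tibble(tumor_calls) |>
    mutate(.ckey = normalize_chrom(.data$chrom))
  normal <- as_tibble(normal_calls) |>
    mutate(.ckey = normalize_chrom(.data$chrom))
  key <- c(".ckey", "pos", "ref", "alt")
  out <- anti_join(tumor, normal[key], by = key)
  if (!is.null(popfreq) && nrow(popfreq) > 0) {
    pf <- as_tibble(popfreq) |>
      mutate(.ckey = normalize_chrom(.data$chrom)) |>
      select(dplyr::all_of(key), af_pop = "af")
    out <- left_join(out, pf, by = key) |>
      filter(is.na(.data$af_pop) | .data$af_pop <= max_popfreq)
  } else {
    out$af_pop <- NA_real_
  }
  out <- select(out, -".ckey")
  out <- filter(out, .data$ref_depth + .data$alt_depth >= min_somatic_depth)
  if (!is.null(normal_depths)) {
    nd <- depth_at(normal_depths, out$chrom, out$pos)
    out <- out[!is.na(nd) & nd >= min_somatic_depth, ]
  }
  out
}

#' Controlled vocabulary of retained variant consequences
#'
#' The consequence classes counted as coding non-synonymous in the
#' disease-relevant subset: missense, nonsense (stop-gain), stop-loss,
#' coding indels (frameshift or in-frame) and splice-site variants.
#'
#' @export
nonsynonymous_consequences <- c("missense", "nonsense", "stop_gain",
                                "stop_loss", "frameshift", "inframe_indel",
                                "coding_indel", "splice_site")

#' Restrict calls to coding non-synonymous consequences
#'
#' Joins user-supplied consequence annotations onto the calls and keeps
#' those whose consequence is in [nonsynonymous_consequences]. Calls
#' without an annotation are dropped with a warning giving their count
#' (consequence prediction itself is upstream of this package).
#'
#' @param calls Call table keyed by `chrom`, `pos`, `ref`, `alt`.
#' @param annotations Table with columns `chrom`, `pos`, `ref`, `alt`,
#'   `consequence`.
#' @return The retained calls with a `consequence` column.
#' @export
select_coding_nonsynonymous <- function(calls, annotations) {
  key <- c(".ckey", "pos", "ref", "alt")
  calls <- as_tibble(calls) |> mutate(.ckey = normalize_chrom(.data$chrom))
  ann <- as_tibble(annotations) |>
    mutate(.ckey = normalize_chrom(.data$chrom)) |>
    select(dplyr::all_of(key), "consequence")
  out <- left_join(calls, ann, by = key)
  n_missing <- sum(is.na(out$consequence))
  if (n_missing > 0) {
    warn(paste0(n_missing, " call(s) without a consequence annotation dropped"))
  }
  out |>
    filter(!is.na(.data$consequence) &
             .data$consequence %in% nonsynonymous_consequences) |>
    select(-".ckey")
}
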