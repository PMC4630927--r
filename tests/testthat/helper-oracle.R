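# Independent brute-force implementations used as oracles, written as
# plain per-site loops straight from the rule table, deliberately
# sharing no code with the package internals.

# Classify one site at a time. `sites` has per-sample call status,
# filter label, called ref/alt depths, and depth-at-site for the
# uncalled sample. Returns NA for sites not retained (high quality in
# neither sample).
oracle_classify <- function(sites, min_depth = 10) {
  out <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    hq <- function(called, lab, rd, ad) {
      if (!called) return(FALSE)
      tot <- rd + ad
      if (!(lab %in% c("KEEP", "PASS"))) return(FALSE)
      if (!(tot > 10)) return(FALSE)
      (ad / tot) >= 0.2
    }
    ff_hq <- hq(s$ff_called, s$ff_label, s$ff_ref, s$ff_alt)
    ffpe_hq <- hq(s$ffpe_called, s$ffpe_label, s$ffpe_ref, s$ffpe_alt)
    if (!ff_hq && !ffpe_hq) {
      out[i] <- NA_character_
      next
    }
    dff <- if (s$ff_called) s$ff_ref + s$ff_alt else s$ff_track
    dfp <- if (s$ffpe_called) s$ffpe_ref + s$ffpe_alt else s$ffpe_track
    deep <- function(d) !is.na(d) && d > min_depth
    if (s$ff_called && s$ffpe_called) {
      out[i] <- if (deep(dff) && deep(dfp)) "SHARED" else "NOT_DETERMINED"
    } else if (s$ffpe_called) {
      out[i] <- if (deep(dff)) "FALSE_POSITIVE" else "NOT_DETERMINED"
    } else {
      out[i] <- if (deep(dfp)) "FALSE_NEGATIVE" else "NOT_DETERMINED"
    }
  }
  out
}

# Random paired callsets over <= n_sites sites on one synthetic contig,
# with matching depth tracks, for oracle-equivalence and symmetry tests.
random_paired_sites <- function(n_sites, seed) {
  set.seed(seed)
  n <- n_sites
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  status <- sample(c("both", "ff", "ffpe"), n, replace = TRUE)
  tibble::tibble(
    chrom = "chrT1", pos = sort(sample.int(50 * n, n)),
    ref = ref, alt = alt,
    ff_called = status %in% c("both", "ff"),
    ffpe_called = status %in% c("both", "ffpe"),
    ff_label = sample(c("KEEP", "PASS", "REJECT"), n, TRUE, c(.4, .3, .3)),
    ffpe_label = sample(c("KEEP", "PASS", "REJECT"), n, TRUE, c(.4, .3, .3)),
    ff_ref = sample(0:25, n, TRUE), ff_alt = sample(0:25, n, TRUE),
    ffpe_ref = sample(0:25, n, TRUE), ffpe_alt = sample(0:25, n, TRUE),
    ff_track = sample(0:25, n, TRUE), ffpe_track = sample(0:25, n, TRUE)
  )
}

sites_to_callsets <- function(sites) {
  mk <- function(called, lab, rd, ad) {
    tibble::tibble(chrom = sites$chrom[called], pos = sites$pos[called],
                   ref = sites$ref[called], alt = sites$alt[called],
                   filter_label = lab[called], ref_depth = rd[called],
                   alt_depth = ad[called], is_indel = FALSE)
  }
  track <- function(depth) {
    tibble::tibble(chrom = sites$chrom, start = sites$pos - 1L,
                   end = sites$pos, depth = depth)
  }
  list(
    ff = mk(sites$ff_called, sites$ff_label, sites$ff_ref, sites$ff_alt),
    ffpe = mk(sites$ffpe_called, sites$ffpe_label, sites$ffpe_ref,
              sites$ffpe_alt),
    ff_track = track(sites$ff_track), ffpe_track = track(sites$ffpe_track)
  )
}

# Package classification of the same random sites, keyed for comparison
# with the oracle.
package_classify <- function(sites, min_depth = 10) {
  cs <- sites_to_callsets(sites)
  rec <- classify_records(
    merge_pair(cs$ff, cs$ffpe, cs$ff_track, cs$ffpe_track),
    min_depth = min_depth)
  lab <- rep(NA_character_, nrow(sites))
  idx <- match(paste(rec$chrom, rec$pos), paste("chrT1", sites$pos))
  lab[idx] <- as.character(rec$label)
  lab
}

# Brute-force per-base membership: is each 1-based position inside any
# 0-based half-open target interval?
oracle_pos_in <- function(pos, targets) {
  vapply(pos, function(p) {
    any(targets$start < p & p <= targets$end)
  }, logical(1))
}

table1 <- function() {
  read_read_counts(system.file("extdata/table1_read_counts.tsv",
                               package = "ffpeconcord"))
}

table3 <- function() {
  readr::read_tsv(system.file("extdata/known_mutations.tsv",
                              package = "ffpeconcord"),
                  show_col_types = FALSE)
}
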