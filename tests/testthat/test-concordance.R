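call_row <- function(pos, ref = "C", alt = "T", label = "KEEP",
                     rd = 20, ad = 20, chrom = "chrS1") {
  tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 filter_label = label, ref_depth = rd, alt_depth = ad,
                 is_indel = FALSE)
}

test_that("allele fractions reproduce every known-mutation table cell at one decimal", {
  t3 <- table3()
  vaf <- allele_fraction(t3$ref_depth, t3$alt_depth)
  expect_equal(round(vaf, 1), t3$printed_vaf_pct)
  # spot values: near-homozygous driver, subclonal driver, absent in blood
  expect_equal(round(allele_fraction(2, 160), 1), 98.8)
  expect_equal(round(allele_fraction(109, 35), 1), 24.3)
  expect_equal(allele_fraction(116, 0), 0)
  expect_error(allele_fraction(0, 0), class = "ffpeconcord_undefined_metric")
})

test_that("the high-quality gate applies label, strict depth and alt-ratio clauses", {
  calls <- tibble::tibble(
    filter_label = c("PASS", "PASS", "REJECT", "KEEP", "PASS"),
    ref_depth    = c(8,       9,      50,       40,     44),
    alt_depth    = c(3,       1,      50,       10,     11))
  # row 1: total 11 > 10 and ratio 3/11 = 0.273 >= 0.2 -> passes
  # row 2: total 10 fails the strict > 10 depth clause
  # row 3: REJECT label fails regardless of depths
  # row 4: ratio 10/50 = 0.2 passes the >= boundary
  # row 5: ratio 11/55 = 0.2 exactly on boundary, depth 55
  expect_equal(passes_quality(calls),
               c(TRUE, FALSE, FALSE, TRUE, TRUE))
})

test_that("target restriction respects half-open boundaries and flags naming mismatches", {
  targets <- merge_targets(tibble::tibble(chrom = "chrS1", start = 100,
                                          end = 200))
  calls <- call_row(c(101, 150, 200, 201, 250, 100))
  kept <- restrict_to_targets(calls, targets)
  # 1-based position p is inside [100, 200) iff 100 < p <= 200
  expect_setequal(kept$pos, c(101, 150, 200))
  expect_error(restrict_to_targets(call_row(150, chrom = "chrOther"), targets),
               class = "ffpeconcord_chrom_mismatch")
  # chr-prefix differences are normalised, not errors
  expect_equal(nrow(restrict_to_targets(call_row(150, chrom = "S1"), targets)), 1)
})

test_that("union merge keeps records that are high quality in at least one sample", {
  ff <- call_row(c(10, 20, 30))                     # all HQ in FF
  ffpe <- dplyr::bind_rows(
    call_row(10),                                   # shared site
    call_row(40, rd = 9, ad = 1, label = "PASS"),   # fails depth in FFPE
    call_row(50, rd = 4, ad = 1))                   # fails everything
  ffpe_track <- tibble::tibble(chrom = "chrS1", start = c(19, 29),
                               end = c(20, 30), depth = c(40, 5))
  rec <- merge_pair(ff, ffpe, ffpe_depths = ffpe_track)
  expect_setequal(rec$pos, c(10, 20, 30))  # 40 and 50 HQ in neither sample
  r20 <- rec[rec$pos == 20, ]
  expect_false(r20$ffpe_called)
  expect_equal(r20$ffpe_depth, 40)   # depth recovered from the track
  expect_equal(r20$ff_depth, 40)     # called: depth = ref + alt
  r30 <- rec[rec$pos == 30, ]
  expect_equal(r30$ffpe_depth, 5)
})

test_that("duplicate variant records in one callset are a malformed-input error", {
  dup <- dplyr::bind_rows(call_row(10), call_row(10))
  expect_error(merge_pair(dup, call_row(20)),
               class = "ffpeconcord_duplicate_variant")
})

test_that("the rule table labels double calls, single calls and low-coverage sites", {
  rec <- merge_pair(
    dplyr::bind_rows(call_row(1, rd = 20, ad = 20),   # both called, deep
                     call_row(3, rd = 25, ad = 25),   # FF only, FFPE deep
                     call_row(4, rd = 25, ad = 25)),  # FF only, FFPE shallow
    dplyr::bind_rows(call_row(1, rd = 15, ad = 15),
                     call_row(2, rd = 30, ad = 20)),  # FFPE only, FF deep
    ff_depths = tibble::tibble(chrom = "chrS1", start = 1, end = 2,
                               depth = 50),
    ffpe_depths = tibble::tibble(chrom = "chrS1", start = c(2, 3),
                                 end = c(3, 4), depth = c(40, 7)))
  lab <- classify_records(rec)
  expect_equal(as.character(lab$label[lab$pos == 1]), "SHARED")
  expect_equal(as.character(lab$label[lab$pos == 2]), "FALSE_POSITIVE")
  expect_equal(as.character(lab$label[lab$pos == 3]), "FALSE_NEGATIVE")
  expect_equal(as.character(lab$label[lab$pos == 4]), "NOT_DETERMINED")
})

test_that("ND policy: default judges the decisive sample, strict mode either sample", {
  # FFPE-only call deep in FFPE; FF covered at 50 vs at 7
  rec <- merge_pair(
    call_row(integer(0))[0, ],
    dplyr::bind_rows(call_row(1, rd = 30, ad = 20),
                     call_row(2, rd = 30, ad = 20)),
    ff_depths = tibble::tibble(chrom = "chrS1", start = c(0, 1),
                               end = c(1, 2), depth = c(50, 7)))
  lab <- classify_records(rec)
  expect_equal(as.character(lab$label), c("FALSE_POSITIVE", "NOT_DETERMINED"))

  # FF-only call with shallow FF but deep FFPE: the calling sample's own
  # depth only matters under the strict policy
  rec2 <- merge_pair(
    call_row(5, rd = 5, ad = 4, label = "KEEP"),   # FF depth 9, ratio ok
    call_row(integer(0))[0, ],
    ffpe_depths = tibble::tibble(chrom = "chrS1", start = 4, end = 5,
                                 depth = 40))
  expect_equal(nrow(rec2), 0)  # fails quality in FF, absent in FFPE

  rec3 <- merge_pair(
    call_row(5, rd = 6, ad = 5),                   # FF depth 11, HQ
    call_row(integer(0))[0, ],
    ffpe_depths = tibble::tibble(chrom = "chrS1", start = 4, end = 5,
                                 depth = 40))
  expect_equal(as.character(classify_records(rec3)$label), "FALSE_NEGATIVE")
  # strict policy: FF depth 11 > 10 still fine; drop FFPE coverage to 8
  rec4 <- merge_pair(
    call_row(5, rd = 6, ad = 5), call_row(integer(0))[0, ],
    ffpe_depths = tibble::tibble(chrom = "chrS1", start = 4, end = 5,
                                 depth = 8))
  expect_equal(as.character(classify_records(rec4)$label), "NOT_DETERMINED")
})

test_that("missing depth for the uncalled sample forces ND by construction", {
  rec <- merge_pair(call_row(1), call_row(integer(0))[0, ])  # no FFPE track
  expect_true(is.na(rec$ffpe_depth))
  expect_equal(as.character(classify_records(rec)$label), "NOT_DETERMINED")
})

test_that("classification agrees with the brute-force rule-table oracle", {
  for (seed in 1:8) {
    sites <- random_paired_sites(200, seed)
    expect_equal(package_classify(sites), oracle_classify(sites),
                 info = paste("seed", seed))
  }
})

test_that("swapping FF and FFPE swaps FP and FN and fixes SHARED and ND", {
  for (seed in 1:5) {
    sites <- random_paired_sites(150, seed + 100)
    swapped <- sites
    names(swapped) <- sub("^ff_", "tmp_", names(swapped))
    names(swapped) <- sub("^ffpe_", "ff_", names(swapped))
    names(swapped) <- sub("^tmp_", "ffpe_", names(swapped))
    a <- table(factor(package_classify(sites),
                      levels = c("SHARED", "FALSE_POSITIVE",
                                 "FALSE_NEGATIVE", "NOT_DETERMINED")))
    b <- table(factor(package_classify(swapped),
                      levels = c("SHARED", "FALSE_POSITIVE",
                                 "FALSE_NEGATIVE", "NOT_DETERMINED")))
    expect_equal(a[["SHARED"]], b[["SHARED"]])
    expect_equal(a[["NOT_DETERMINED"]], b[["NOT_DETERMINED"]])
    expect_equal(a[["FALSE_POSITIVE"]], b[["FALSE_NEGATIVE"]])
    expect_equal(a[["FALSE_NEGATIVE"]], b[["FALSE_POSITIVE"]])
  }
})

test_that("raising the depth bar never decreases the ND count, and labels partition", {
  sites <- random_paired_sites(200, 7)
  cs <- sites_to_callsets(sites)
  rec <- merge_pair(cs$ff, cs$ffpe, cs$ff_track, cs$ffpe_track)
  nds <- sapply(c(0, 5, 10, 15, 20, 30), function(d) {
    lab <- classify_records(rec, min_depth = d)
    expect_false(any(is.na(lab$label)))           # exactly one label each
    expect_equal(sum(table(lab$label)), nrow(rec)) # counts conserve total
    sum(lab$label == "NOT_DETERMINED")
  })
  expect_true(all(diff(nds) >= 0))
})

test_that("concordance summary reports the FP share of FFPE-called variants", {
  rec <- tibble::tibble(
    ff_called = c(rep(TRUE, 13), rep(FALSE, 20)),
    ffpe_called = TRUE,
    label = factor(c(rep("SHARED", 13), rep("FALSE_POSITIVE", 20)),
                   levels = c("SHARED", "FALSE_POSITIVE", "FALSE_NEGATIVE",
                              "NOT_DETERMINED")))
  s <- summarize_concordance(rec)
  expect_equal(s$total, 33)
  expect_equal(s$fp_fraction_of_ffpe_called, 20 / 33)   # 60.6%
  expect_gt(s$fp_fraction_of_ffpe_called, 0.60)
  g <- glance(s)
  expect_equal(g$total, 33)
  expect_equal(tidy(s)$n, c(13L, 20L, 0L, 0L))

  all_shared <- dplyr::mutate(rec, label = factor("SHARED",
    levels = levels(rec$label)))
  expect_equal(summarize_concordance(all_shared)$shared_fraction, 1)
})

test_that("somatic selection excludes germline, common and under-covered variants", {
  tumor <- dplyr::bind_rows(
    call_row(1, rd = 18, ad = 12),   # somatic, unreported -> kept
    call_row(2, rd = 15, ad = 15),   # present in normal -> germline
    call_row(3, rd = 20, ad = 10),   # popfreq 5% -> excluded
    call_row(4, rd = 20, ad = 10),   # popfreq 0.5% -> kept
    call_row(5, rd = 3, ad = 2))     # tumour depth 5 < 6 -> excluded
  normal <- call_row(2, rd = 14, ad = 16)
  pf <- tibble::tibble(chrom = "chrS1", pos = c(3, 4), ref = "C", alt = "T",
                       af = c(0.05, 0.005))
  som <- select_somatic(tumor, normal, pf)
  expect_setequal(som$pos, c(1, 4))

  # normal depth requirement bites when a track is provided
  ntrack <- tibble::tibble(chrom = "chrS1", start = c(0, 3), end = c(1, 4),
                           depth = c(30, 4))
  som2 <- select_somatic(tumor, normal, pf, normal_depths = ntrack)
  expect_equal(som2$pos, 1)  # site 4 has normal depth 4 < 6

  # boundary: depth exactly 6 is retained (>= 6 rule)
  t6 <- call_row(9, rd = 3, ad = 3)
  expect_equal(nrow(select_somatic(t6, normal[0, ])), 1)
})

test_that("coding non-synonymous restriction follows the controlled vocabulary", {
  calls <- call_row(c(1, 2, 3, 4))
  ann <- tibble::tibble(chrom = "chrS1", pos = c(1, 2, 3), ref = "C",
                        alt = "T",
                        consequence = c("missense", "synonymous", "intronic"))
  expect_warning(kept <- select_coding_nonsynonymous(calls, ann),
                 "without a consequence annotation")
  expect_equal(kept$pos, 1)
  expect_true(all(c("missense", "nonsense", "stop_loss", "splice_site") %in%
                    nonsynonymous_consequences))
})
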