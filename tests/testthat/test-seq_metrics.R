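test_that("duplicate, mapped and trimmed fractions reproduce the printed anchors", {
  # GIST193 FF row
  expect_equal(round(100 * pcr_duplicate_fraction(63523138, 58598506), 1), 7.8)
  expect_equal(round(100 * mapped_fraction(57879604, 58598506), 1), 98.8)
  expect_equal(round(100 * trimmed_base_fraction(63523138, 5.84e9), 1), 8.1)
  # GIST127 FFPE duplicate row and GIST165 FF mapped row
  expect_equal(round(100 * pcr_duplicate_fraction(14203932, 12496962), 1), 12.0)
  expect_equal(round(100 * mapped_fraction(49019552, 49587098), 1), 98.9)
})

test_that("degenerate count inputs behave as contracted", {
  expect_equal(pcr_duplicate_fraction(100, 100), 0)
  expect_equal(mapped_fraction(0, 10), 0)
  expect_equal(trimmed_base_fraction(100, 100 * 100), 0)
  expect_error(pcr_duplicate_fraction(0, 0),
               class = "ffpeconcord_undefined_metric")
  expect_error(mapped_fraction(5, 0), class = "ffpeconcord_undefined_metric")
  expect_error(trimmed_base_fraction(10, 2000, 100),
               class = "ffpeconcord_bad_input")  # more HQ bases than raw
  expect_error(pcr_duplicate_fraction(10, 20),
               class = "ffpeconcord_bad_input")
})

test_that("whole run-summary table is reproduced at printed precision", {
  m <- read_count_metrics(table1())
  expect_true(all(m$dup_fraction >= 0 & m$dup_fraction <= 1))
  expect_equal(round(100 * m$dup_fraction, 1), m$printed_dup_pct)
  # two printed mapped cells (GIST127 FFPE and PB) are known typesetting
  # artifacts; every other cell matches at one decimal
  ok <- !(m$sample_id %in% c("GIST127_FFPE", "GIST127_PB"))
  expect_equal(round(100 * m$mapped_fraction[ok], 1), m$printed_mapped_pct[ok])
  # trimmed-base: printed HQ bases carry 3 significant figures, so allow
  # their rounding half-width; the GIST127 FFPE cell is not reproducible
  # from the printed counts (recomputes to 19.7, printed 20.7)
  lq <- m$sample_id == "GIST127_FFPE"
  expect_true(all(abs(100 * m$trimmed_fraction[!lq] -
                        m$printed_trimmed_pct[!lq]) < 0.11))
  expect_equal(100 * m$trimmed_fraction[lq], 19.74, tolerance = 0.001)
})

test_that("fractions are invariant to scaling all counts", {
  expect_equal(pcr_duplicate_fraction(1000, 900),
               pcr_duplicate_fraction(7000, 6300))
  expect_equal(mapped_fraction(800, 900), mapped_fraction(5600, 6300))
})

test_that("coverage summary handles uniform and half-covered targets", {
  targets <- merge_targets(tibble::tibble(chrom = "chrS1",
                                          start = c(0, 500),
                                          end = c(200, 800)))
  expect_equal(target_size(targets), 500)

  uniform <- tibble::tibble(chrom = "chrS1", start = c(0, 500),
                            end = c(200, 800), depth = 17)
  cs <- coverage_summary(uniform, targets)
  expect_equal(cs$mean_depth, 17)
  expect_equal(cs$breadth_ge_1x, 1)
  expect_equal(cs$breadth_ge_10x, 1)

  half <- tibble::tibble(chrom = "chrS1", start = 0, end = 100, depth = 20)
  cs <- coverage_summary(half, targets)
  expect_equal(cs$mean_depth, 20 * 100 / 500)
  expect_equal(cs$breadth_ge_1x, 0.2)
  expect_equal(cs$breadth_ge_10x, 0.2)

  expect_error(coverage_summary(half, half[0, ]),
               class = "ffpeconcord_bad_input")
})

test_that("breadth at 10X of a Poisson 17X track matches the Poisson tail", {
  set.seed(101)
  n <- 20000
  targets <- merge_targets(tibble::tibble(chrom = "chrS1", start = 0, end = n))
  depths <- rpois(n, 17)
  track <- tibble::tibble(chrom = "chrS1", start = 0:(n - 1), end = 1:n,
                          depth = depths)
  cs <- coverage_summary(track, targets)
  tail10 <- ppois(9, 17, lower.tail = FALSE)  # closed-form oracle
  expect_equal(cs$breadth_ge_10x, tail10, tolerance = 0.02)
  expect_equal(cs$mean_depth, 17, tolerance = 0.02)
})

test_that("breadth is non-increasing in the threshold and obeys the layer-cake identity", {
  set.seed(102)
  for (rep in 1:5) {
    n <- 400
    targets <- merge_targets(tibble::tibble(chrom = "chrS1", start = 0, end = n))
    depths <- rnbinom(n, mu = 8, size = 2)
    track <- tibble::tibble(chrom = "chrS1", start = 0:(n - 1), end = 1:n,
                            depth = depths)
    ks <- 1:max(max(depths), 1)
    cs <- coverage_summary(track, targets, breadth_at = ks)
    breadths <- as.numeric(cs[1, paste0("breadth_ge_", ks, "x")])
    expect_true(all(diff(breadths) <= 1e-12))
    # mean depth = sum over k >= 1 of P(depth >= k) on integer tracks
    expect_equal(cs$mean_depth, sum(breadths), tolerance = 1e-12)
  }
})

test_that("off-target fraction counts reads without >= 1 bp target overlap", {
  targets <- merge_targets(tibble::tibble(chrom = "chrS1", start = 100,
                                          end = 200))
  inside <- tibble::tibble(chrom = "chrS1", start = c(100, 150, 199),
                           end = c(150, 180, 250))
  expect_equal(off_target_fraction(inside, targets), 0)
  outside <- tibble::tibble(chrom = "chrS1", start = c(0, 200, 300),
                            end = c(100, 250, 400))
  # [200, 250) touches the half-open end of [100, 200): no overlap...
  expect_equal(off_target_fraction(outside[c(1, 3), ], targets), 1)
  # ...so 3 of 10 reads fully outside gives 0.3
  reads <- tibble::tibble(
    chrom = "chrS1",
    start = c(rep(150, 7), 0, 210, 500), end = c(rep(160, 7), 50, 220, 600))
  expect_equal(off_target_fraction(reads, targets), 0.3)
  expect_error(off_target_fraction(reads[0, ], targets),
               class = "ffpeconcord_undefined_metric")
})

test_that("interval membership agrees with a brute-force per-base oracle", {
  set.seed(103)
  for (rep in 1:10) {
    s <- sort(sample.int(500, 8))
    targets <- merge_targets(tibble::tibble(
      chrom = "chrS1", start = s, end = s + sample.int(40, 8)))
    pos <- sample.int(600, 100)
    calls <- tibble::tibble(chrom = "chrS1", pos = pos)
    kept <- restrict_to_targets(calls, targets)
    expect_setequal(kept$pos, pos[oracle_pos_in(pos, targets)])
  }
})

test_that("simulated read-count summaries sit in their quality regime", {
  set.seed(104)
  hq <- purrr::map(1:10, ~ simulate_read_counts("HQ")) |> purrr::list_rbind()
  lq <- purrr::map(1:10, ~ simulate_read_counts("LQ")) |> purrr::list_rbind()
  mh <- read_count_metrics(hq); ml <- read_count_metrics(lq)
  expect_true(mean(ml$trimmed_fraction) > mean(mh$trimmed_fraction))
  expect_true(mean(ml$dup_fraction) > mean(mh$dup_fraction))
  expect_true(mean(ml$total_reads) < mean(mh$total_reads))
  expect_true(all(mh$trimmed_fraction > 0.05 & mh$trimmed_fraction < 0.15))
  expect_true(all(ml$trimmed_fraction > 0.15 & ml$trimmed_fraction < 0.28))
  for (col in c("dup_fraction", "mapped_fraction", "trimmed_fraction")) {
    expect_true(all(mh[[col]] >= 0 & mh[[col]] <= 1))
    expect_true(all(ml[[col]] >= 0 & ml[[col]] <= 1))
  }
})
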