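# Seeded generator for paired FF/FFPE/normal exome callsets with the
# statistical structure the concordance analysis assumes: germline
# polymorphisms in all three samples, clonal somatic mutations in both
# tumours, and low-allele-fraction deamination artifacts only in FFPE,
# concentrated in the C>T/G>A class. Depths are negative-binomial
# (Poisson-gamma), alternate reads binomial in the allele fraction, and
# a site is "called" when enough alternate reads are seen.

default_artifact_class_probs <- c(
  "C>A/G>T" = 0.04, "C>G/G>C" = 0.03, "C>T/G>A" = 0.75,
  "T>A/A>T" = 0.04, "T>C/A>G" = 0.10, "T>G/A>C" = 0.04
)

#' Simulation configuration
#'
#' Bundles and validates every tunable of the synthetic study. Defaults
#' emulate the design the pipeline is meant for: a captured exome of
#' small synthetic contigs (`chrS1`...), tumour coverage near 60X for FF
#' and high-quality FFPE and 17X for low-quality FFPE, clonal somatic
#' allele fractions in 0.4–1.0, and deamination artifacts with 75% of
#' their mass in `C>T/G>A`, transitions well above transversions, and
#' allele fractions Beta(2, 8) — i.e. massed near the 0.2 alt-ratio
#' filter so the filter's discriminating role is exercised.
#'
#' @param seed Integer RNG seed (mandatory; identical seeds give
#'   identical simulations).
#' @param n_contigs Number of synthetic contigs.
#' @param n_targets Total number of target intervals.
#' @param target_len_range,target_gap_range Target length / inter-target
#'   gap ranges in bp (uniform).
#' @param n_germline,n_somatic Numbers of germline and somatic variants.
#' @param germline_hom_fraction Fraction of germline sites homozygous.
#' @param somatic_vaf_range Clonal somatic allele-fraction range.
#' @param mean_depth_ff,mean_depth_ffpe_hq,mean_depth_ffpe_lq,mean_depth_normal
#'   Mean site depths per sample type.
#' @param depth_dispersion Negative-binomial size parameter; smaller
#'   means broader depth spread. The default 2 reproduces the pronounced
#'   breadth-of-coverage loss of a mean-17X exome (only ~2/3 of target
#'   positions at >=10X) while keeping 60X samples near-complete.
#' @param ffpe_quality `"HQ"` or `"LQ"` — selects the FFPE depth mean,
#'   the read-count regime and (by default) the artifact burden and
#'   lesion rate.
#' @param artifact_rate Expected number of FFPE deamination artifacts
#'   per sample (Poisson). `NULL` (default) ties it to `ffpe_quality`:
#'   5 for HQ (false positives are rare in well-preserved DNA) and 150
#'   for LQ. The absolute burden is a free parameter of the model.
#' @param artifact_class_probs Named length-6 probability vector over
#'   [substitution_classes] for artifact classes.
#' @param artifact_vaf_shape Beta shape parameters for artifact allele
#'   fractions.
#' @param caller_min_alt Alternate reads needed for a site to be called.
#' @param lesion_rate Formalin lesion rate per bp for the qPCR
#'   random-breakage model; `NULL` (default) matches it to
#'   `ffpe_quality` (0.005/bp for HQ, 0.02/bp for LQ, placing the
#'   zero-noise Q129 ratios at 0.64 and 0.17).
#' @param qpcr_noise_cv Coefficient of variation of multiplicative qPCR
#'   noise.
#' @param read_length Read length in bp.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_contigs = 4,
                              n_targets = 80,
                              target_len_range = c(150, 400),
                              target_gap_range = c(200, 1000),
                              n_germline = 300,
                              n_somatic = 30,
                              germline_hom_fraction = 0.1,
                              somatic_vaf_range = c(0.4, 1.0),
                              mean_depth_ff = 60,
                              mean_depth_ffpe_hq = 60,
                              mean_depth_ffpe_lq = 17,
                              mean_depth_normal = 45,
                              depth_dispersion = 2,
                              ffpe_quality = c("HQ", "LQ"),
                              artifact_rate = NULL,
                              artifact_class_probs = default_artifact_class_probs,
                              artifact_vaf_shape = c(2, 8),
                              caller_min_alt = 3,
                              lesion_rate = NULL,
                              qpcr_noise_cv = 0.05,
                              read_length = 100) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("a single integer `seed` is mandatory",
          class = "ffpeconcord_bad_config")
  }
  ffpe_quality <- match.arg(ffpe_quality)
  if (is.null(lesion_rate)) {
    lesion_rate <- if (ffpe_quality == "HQ") 0.005 else 0.02
  }
  if (is.null(artifact_rate)) {
    artifact_rate <- if (ffpe_quality == "HQ") 5 else 150
  }
  if (abs(sum(artifact_class_probs) - 1) > 1e-8 ||
      any(artifact_class_probs < 0) ||
      !identical(sort(names(artifact_class_probs)),
                 sort(substitution_classes))) {
    abort("artifact_class_probs must be a probability vector named by the six substitution classes and summing to 1",
          class = "ffpeconcord_bad_config")
  }
  rates <- c(mean_depth_ff, mean_depth_ffpe_hq, mean_depth_ffpe_lq,
             mean_depth_normal, artifact_rate, lesion_rate, qpcr_noise_cv,
             depth_dispersion)
  if (any(rates < 0)) {
    abort("rates, depths and dispersions must be non-negative",
          class = "ffpeconcord_bad_config")
  }
  structure(
    list(seed = as.integer(seed), n_contigs = n_contigs,
         n_targets = n_targets, target_len_range = target_len_range,
         target_gap_range = target_gap_range, n_germline = n_germline,
         n_somatic = n_somatic,
         germline_hom_fraction = germline_hom_fraction,
         somatic_vaf_range = somatic_vaf_range,
         mean_depth_ff = mean_depth_ff,
         mean_depth_ffpe_hq = mean_depth_ffpe_hq,
         mean_depth_ffpe_lq = mean_depth_ffpe_lq,
         mean_depth_normal = mean_depth_normal,
         depth_dispersion = depth_dispersion, ffpe_quality = ffpe_quality,
         artifact_rate = artifact_rate,
         artifact_class_probs = artifact_class_probs[substitution_classes],
         artifact_vaf_shape = artifact_vaf_shape,
         caller_min_alt = caller_min_alt, lesion_rate = lesion_rate,
         qpcr_noise_cv = qpcr_noise_cv, read_length = read_length),
    class = "simulation_config"
  )
}

rnb_depth <- function(n, mu, size) {
  if (mu == 0) return(integer(n))
  rnbinom(n, mu = mu, size = size)
}

# draw an alt allele for a substitution class, choosing the pyrimidine-
# or purine-reference orientation at random
draw_class_alleles <- function(cls) {
  pyr <- list("C>A/G>T" = c("C", "A"), "C>G/G>C" = c("C", "G"),
              "C>T/G>A" = c("C", "T"), "T>A/A>T" = c("T", "A"),
              "T>C/A>G" = c("T", "C"), "T>G/A>C" = c("T", "G"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- matrix("", nrow = length(cls), ncol = 2)
  flip <- runif(length(cls)) < 0.5
  for (i in seq_along(cls)) {
    ra <- pyr[[cls[i]]]
    if (flip[i]) ra <- unname(comp[ra])
    out[i, ] <- ra
  }
  out
}

#' Simulate a paired FF/FFPE/normal exome study
#'
#' Generates target regions, the three per-sample callsets, per-sample
#' depth tracks, a population-frequency table for the common germline
#' sites, and a truth table carrying each variant's origin
#' (`germline` / `somatic` / `ffpe_artifact`), allele fractions,
#' per-sample depths and call status, and the concordance label expected
#' under the rule table.
#'
#' @param config A [simulation_config()].
#' @return A list of class `ffpe_simulation` with elements `targets`,
#'   `ff_calls`, `ffpe_calls`, `normal_calls`, `ff_depths`,
#'   `ffpe_depths`, `normal_depths`, `truth`, `popfreq`, `config`.
#' @examples
#' sim <- simulate_paired_callsets(simulation_config(seed = 1))
#' dplyr::count(sim$truth, origin)
#' @export
simulate_paired_callsets <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cfg <- config

  # --- target regions on synthetic contigs ---
  contigs <- paste0("chrS", seq_len(cfg$n_contigs))
  per_contig <- diff(round(seq(0, cfg$n_targets, length.out = cfg$n_contigs + 1)))
  targets <- list_rbind(map(seq_len(cfg$n_contigs), function(i) {
    n <- per_contig[i]
    if (n == 0) return(tibble(chrom = character(), start = integer(), end = integer()))
    lens <- round(runif(n, cfg$target_len_range[1], cfg$target_len_range[2]))
    gaps <- round(runif(n, cfg$target_gap_range[1], cfg$target_gap_range[2]))
    starts <- cumsum(gaps) + cumsum(c(0, lens[-n]))
    tibble(chrom = contigs[i], start = as.integer(starts),
           end = as.integer(starts + lens))
  }))
  targets <- merge_targets(targets)

  # --- variant sites: distinct positions inside targets ---
  n_artifact <- rpois(1, cfg$artifact_rate)
  n_total <- cfg$n_germline + cfg$n_somatic + n_artifact
  pos_pool <- list_rbind(pmap(targets, function(chrom, start, end) {
    tibble(chrom = chrom, pos = seq.int(start + 1L, end))
  }))
  if (n_total > nrow(pos_pool)) {
    abort("requested more variants than available target positions",
          class = "ffpeconcord_bad_config")
  }
  sites <- pos_pool[sample.int(nrow(pos_pool), n_total), ]
  origin <- c(rep("germline", cfg$n_germline),
              rep("somatic", cfg$n_somatic),
              rep("ffpe_artifact", n_artifact))

  # --- alleles ---
  bases <- c("A", "C", "G", "T")
  ref <- character(n_total)
  alt <- character(n_total)
  plain <- origin != "ffpe_artifact"
  ref[plain] <- sample(bases, sum(plain), replace = TRUE)
  alt[plain] <- vapply(ref[plain],
                       function(r) sample(setdiff(bases, r), 1), "")
  if (n_artifact > 0) {
    cls <- sample(substitution_classes, n_artifact, replace = TRUE,
                  prob = cfg$artifact_class_probs)
    ra <- draw_class_alleles(cls)
    ref[!plain] <- ra[, 1]
    alt[!plain] <- ra[, 2]
  }

  # --- allele fractions per sample ---
  germ_hom <- runif(n_total) < cfg$germline_hom_fraction
  vaf_tumor <- dplyr::case_when(
    origin == "germline" & germ_hom ~ 1.0,
    origin == "germline" ~ 0.5,
    origin == "somatic" ~ runif(n_total, cfg$somatic_vaf_range[1],
                                cfg$somatic_vaf_range[2]),
    TRUE ~ rbeta(n_total, cfg$artifact_vaf_shape[1], cfg$artifact_vaf_shape[2])
  )
  vaf <- tibble(
    ff = if_else(origin == "ffpe_artifact", 0, vaf_tumor),
    ffpe = vaf_tumor,
    normal = if_else(origin == "germline", vaf_tumor, 0)
  )

  mean_ffpe <- if (cfg$ffpe_quality == "HQ") cfg$mean_depth_ffpe_hq else
    cfg$mean_depth_ffpe_lq
  mu <- c(ff = cfg$mean_depth_ff, ffpe = mean_ffpe,
          normal = cfg$mean_depth_normal)

  samples <- c("ff", "ffpe", "normal")
  site_tbl <- tibble(chrom = sites$chrom, pos = sites$pos,
                     ref = ref, alt = alt, origin = origin,
                     vaf_ff = vaf$ff, vaf_ffpe = vaf$ffpe,
                     vaf_normal = vaf$normal)
  for (s in samples) {
    d <- rnb_depth(n_total, mu[[s]], cfg$depth_dispersion)
    a <- rbinom(n_total, d, vaf[[s]])
    site_tbl[[paste0(s, "_depth")]] <- d
    site_tbl[[paste0(s, "_alt")]] <- a
    site_tbl[[paste0(s, "_called")]] <- a >= cfg$caller_min_alt
  }

  # --- depth tracks: per-target baseline + 1-bp site recounts ---
  make_track <- function(s) {
    base_depth <- rnb_depth(nrow(targets), mu[[s]], cfg$depth_dispersion)
    baseline <- mutate(targets, depth = base_depth)
    overrides <- tibble(chrom = site_tbl$chrom,
                        start = site_tbl$pos - 1L, end = site_tbl$pos,
                        depth = site_tbl[[paste0(s, "_depth")]])
    bind_rows(as_tibble(baseline), overrides)
  }
  tracks <- setNames(map(samples, make_track), samples)

  make_callset <- function(s) {
    called <- site_tbl[[paste0(s, "_called")]]
    tibble(
      chrom = site_tbl$chrom[called], pos = site_tbl$pos[called],
      ref = site_tbl$ref[called], alt = site_tbl$alt[called],
      filter_label = "KEEP",
      ref_depth = as.numeric(site_tbl[[paste0(s, "_depth")]][called] -
                               site_tbl[[paste0(s, "_alt")]][called]),
      alt_depth = as.numeric(site_tbl[[paste0(s, "_alt")]][called]),
      is_indel = FALSE
    ) |> arrange(.data$chrom, .data$pos)
  }

  # --- expected concordance label under the rule table (FF vs FFPE) ---
  pass <- function(s) {
    d <- site_tbl[[paste0(s, "_depth")]]
    a <- site_tbl[[paste0(s, "_alt")]]
    site_tbl[[paste0(s, "_called")]] & d > 10 & if_else(d > 0, a / d, 0) >= 0.2
  }
  ff_pass <- pass("ff"); ffpe_pass <- pass("ffpe")
  retained <- ff_pass | ffpe_pass
  ffc <- site_tbl$ff_called; fpc <- site_tbl$ffpe_called
  ffd <- site_tbl$ff_depth; fpd <- site_tbl$ffpe_depth
  nd <- (ffc & fpc & !(ffd > 10 & fpd > 10)) |
    (ffc & !fpc & !(fpd > 10)) | (!ffc & fpc & !(ffd > 10))
  expected <- case_when(
    !retained ~ NA_character_,
    nd ~ "NOT_DETERMINED",
    ffc & fpc ~ "SHARED",
    fpc ~ "FALSE_POSITIVE",
    ffc ~ "FALSE_NEGATIVE",
    TRUE ~ NA_character_   # called in neither (cannot be retained)
  )
  truth <- mutate(site_tbl, retained = retained, expected_label = expected)

  # --- population frequencies for most germline sites ---
  is_g <- origin == "germline"
  has_pf <- is_g & runif(n_total) < 0.8
  popfreq <- tibble(
    chrom = site_tbl$chrom[has_pf], pos = site_tbl$pos[has_pf],
    ref = site_tbl$ref[has_pf], alt = site_tbl$alt[has_pf],
    af = runif(sum(has_pf), 0.02, 0.5)
  )

  # --- companion wet-lab summaries (qPCR panel, run read counts) ---
  qpcr <- bind_rows(
    simulate_qpcr(0, cfg$qpcr_noise_cv, sample_id = "FF"),
    simulate_qpcr(cfg$lesion_rate, cfg$qpcr_noise_cv, sample_id = "FFPE"),
    simulate_qpcr(0, cfg$qpcr_noise_cv, sample_id = "normal")
  )
  read_counts <- bind_rows(
    simulate_read_counts("FF", "FF", cfg$read_length),
    simulate_read_counts(cfg$ffpe_quality, "FFPE", cfg$read_length),
    simulate_read_counts("FF", "normal", cfg$read_length)
  )

  structure(
    list(targets = targets,
         ff_calls = make_callset("ff"),
         ffpe_calls = make_callset("ffpe"),
         normal_calls = make_callset("normal"),
         ff_depths = tracks$ff, ffpe_depths = tracks$ffpe,
         normal_depths = tracks$normal,
         truth = truth, popfreq = popfreq,
         qpcr = qpcr, read_counts = read_counts, config = cfg),
    class = "ffpe_simulation"
  )
}

#' @export
print.ffpe_simulation <- function(x, ...) {
  cat("Synthetic FF/FFPE/normal exome study (seed", x$config$seed,
      "| FFPE", x$config$ffpe_quality, ")\n")
  cat(" targets:", nrow(x$targets), "intervals,",
      target_size(x$targets), "bp\n")
  cat(" calls: FF", nrow(x$ff_calls), "| FFPE", nrow(x$ffpe_calls),
      "| normal", nrow(x$normal_calls), "\n")
  print(count(x$truth, .data$origin))
  invisible(x)
}

#' Simulate a qPCR DNA-integrity amplicon panel
#'
#' Random-breakage model of formalin fragmentation: lesions occur as a
#' Poisson process at `lesion_rate` per bp, so the fraction of template
#' molecules amplifiable over an L-bp amplicon is `exp(-lesion_rate * L)`.
#' Measured concentrations get multiplicative log-normal noise with
#' coefficient of variation `noise_cv` (mean 1). With zero noise the
#' derived Q-ratios equal `exp(-lesion_rate * (129 - 41))` and
#' `exp(-lesion_rate * (305 - 41))` exactly.
#'
#' @param lesion_rate Lesions per bp (0 = intact DNA).
#' @param noise_cv Coefficient of variation of qPCR noise (default 0).
#' @param c0 Template concentration before degradation (arbitrary unit).
#' @param sample_id Sample label.
#' @return A one-row amplicon-panel tibble (`sample_id`, `conc_41`,
#'   `conc_129`, `conc_305`) suitable for [compute_q_ratios()].
#' @examples
#' simulate_qpcr(0)              # intact: Q-ratios 1
#' simulate_qpcr(0.02)           # heavily degraded: classifies LQ
#' @export
simulate_qpcr <- function(lesion_rate, noise_cv = 0, c0 = 10,
                          sample_id = "sim") {
  if (lesion_rate < 0 || noise_cv < 0) {
    abort("lesion_rate and noise_cv must be non-negative",
          class = "ffpeconcord_bad_config")
  }
  amp <- c(41, 129, 305)
  noise <- if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    rlnorm(3, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else rep(1, 3)
  conc <- c0 * exp(-lesion_rate * amp) * noise
  tibble(sample_id = sample_id, conc_41 = conc[1], conc_129 = conc[2],
         conc_305 = conc[3])
}

#' Simulate a run-level read-count summary
#'
#' Draws the per-sample read-count summary a sequencing core would
#' report, in the regime of the given sample type: low-quality FFPE
#' yields far fewer reads, a much higher trimmed-base fraction (short
#' inserts run into adapters) and more PCR duplicates than fresh-frozen
#' or high-quality FFPE libraries.
#'
#' @param quality_class `"FF"`, `"HQ"` or `"LQ"`.
#' @param sample_id Sample label.
#' @param read_length Read length in bp.
#' @return A one-row tibble with columns `sample_id`, `total_reads`,
#'   `unique_reads`, `mapped_reads`, `hq_bases`, `read_length`.
#' @export
simulate_read_counts <- function(quality_class = c("FF", "HQ", "LQ"),
                                 sample_id = quality_class,
                                 read_length = 100) {
  quality_class <- match.arg(quality_class)
  par <- switch(quality_class,
    FF = list(total = 55e6, trim = 0.085, dup = 0.075),
    HQ = list(total = 56e6, trim = 0.093, dup = 0.102),
    LQ = list(total = 14e6, trim = 0.207, dup = 0.120)
  )
  total <- round(par$total * rlnorm(1, 0, 0.05))
  trim <- min(max(par$trim * rlnorm(1, 0, 0.05), 0), 1)
  dup <- min(max(par$dup * rlnorm(1, 0, 0.05), 0), 1)
  unique_reads <- round(total * (1 - dup))
  mapped <- round(unique_reads * runif(1, 0.981, 0.989))
  tibble(sample_id = sample_id, total_reads = total,
         unique_reads = unique_reads, mapped_reads = mapped,
         hq_bases = round(total * read_length * (1 - trim)),
         read_length = read_length)
}
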