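---
title: "Methods: scoring FFPE DNA and classifying FF/FFPE variant concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring FFPE DNA and classifying FF/FFPE variant concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffpeconcord)
```

`ffpeconcord` asks one question of an archival tumour sample: if we had
sequenced the fresh-frozen (FF) tissue instead, would we have called the
same variants? This vignette lays out the models behind each stage, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the places where the design was genuinely open.

## DNA-integrity scoring

Formalin fixation introduces strand breaks and crosslinks roughly
uniformly along the genome. Treating lesions as a Poisson process with
rate λ (lesions per bp), a template supports amplification of an L-bp
amplicon only if it carries no lesion over those L bases, which happens
with probability e^(−λL). Normalising the measured concentration of a
long amplicon (129 or 305 bp) by a short one (41 bp) from the same
single-copy gene cancels the input amount and leaves

    Q129 = e^(−λ·(129−41)) = e^(−88λ),   Q305 = e^(−264λ),

so the Q-ratio is a monotone readout of λ: ≈1 for intact DNA, falling
towards 0 with degradation. `simulate_qpcr()` implements exactly this
model with multiplicative log-normal measurement noise (mean 1,
coefficient of variation `noise_cv`); in the zero-noise limit
`compute_q_ratios()` recovers the closed form to machine precision,
which the test suite checks on a λ grid.

Gating uses the Q129 ratio: above 0.5 the sample is high quality (HQ),
below 0.25 low quality (LQ). Three choices here were open:

* **The band [0.25, 0.5]** is reported as an explicit `INTERMEDIATE`
  class. The gates are defined by strict inequalities with a gap between
  them; silently binarising samples that fall in the gap would misreport
  exactly the samples for which the assay is least decisive. Callers who
  need a binary verdict can treat the band as either class as policy.
* **Boundary equality** (Q129 exactly 0.5 or 0.25) falls in the band,
  consistent with the strict inequalities of the gates.
* **Q305 is corroborating, not decisive**, by default: it separates the
  same samples as Q129 but saturates near zero much earlier (264 vs
  88 bp of exposure), so it adds little independent information for
  moderately degraded DNA. `classify_quality(strict = TRUE)` additionally
  demands Q305 > 0.1 for HQ, for users who want the long amplicon as a
  hard requirement.

A 41 bp concentration of zero means the sample cannot be quantified at
all and raises an error rather than returning ratios of ∞/NaN; a zero
305 bp concentration is legal (Q305 = 0 is the expected LQ phenotype).

## Run metrics

The run-level fractions are deterministic arithmetic on a core's
summary counts; the only modelling decision is denominators. The mapped
fraction divides by *unique* (post-deduplication) reads, not raw reads
— that is the convention under which published per-sample tables of
this kind are self-consistent, and it is the convention a duplicate-
aware pipeline naturally produces. The trimmed-base fraction divides
surviving bases by `total_reads × read_length` (default 100 bp).

Coverage uses BED conventions throughout: 0-based half-open intervals,
overlapping targets merged on load, VCF's 1-based positions converted
at each interval query. Mean depth divides summed depth by target size;
breadth at k counts target positions with depth ≥ k, with positions
absent from the depth track counting as zero. On integer tracks, mean
depth equals the sum of breadths over all thresholds (the layer-cake
identity), which the tests verify exactly — a useful internal
consistency check because the two sides are computed by different code
paths. A read is off-target when it overlaps no target interval by at
least 1 bp; with capture probes pulling in flanking fragments, any
overlap plausibly reflects a captured molecule, and no stricter
fraction-of-read rule is established for this metric.

## Concordance classification

A call is *high quality* when its caller filter label is accepted
(KEEP/PASS), its re-counted depth of coverage is strictly greater than
10, and its alternate-allele ratio is at least 0.2. The FF/FFPE union
over full variant identity (chrom, pos, ref, alt — multi-allelic
records are decomposed on ingest) keeps sites that are high quality in
at least one sample; depth at the site for the sample that did not call
the variant comes from its depth track (pileup semantics, no depth
cap).

The rule table then assigns exactly one label: Shared when called in
both, False Positive when FFPE-only, False Negative when FF-only, and
Not Determined (ND) when coverage is insufficient to judge. The one
genuinely open point is *which* sample's depth forces ND. The package's
default (`nd_policy = "noncalling"`) demands adequate depth where it is
decisive: for a single-sample call, an FP/FN verdict asserts the
variant's *absence* in the other sample, and that assertion is only
evidence-supported if the silent sample was covered above the bar; for
a double call both depths must clear it. The alternative
(`nd_policy = "either"`) sends any record with either depth ≤ 10 to ND.
At the default thresholds the two policies coincide (a retained
single-sample call has already passed the >10-depth quality gate in its
own sample); they diverge only when the classification bar is raised
above the quality-gate bar, and the choice is exposed rather than
hidden. A record whose uncalled-sample depth is unknown (no track
covers the site) is ND by construction: unknown coverage cannot support
a discordance verdict.

One boundary case is deliberately surfaced rather than resolved: a
variant called in FF, absent in FFPE, with FFPE depth just above the
bar but nonzero alternate reads below the caller's threshold. The rule
table as stated labels it False Negative; the per-record output keeps
both samples' allele depths so downstream users can audit such sites.

Somatic selection retains tumour calls absent from the matched normal,
with catalogued population frequency ≤ 1% or unreported, and depth ≥ 6
(inclusive) in both tumour and normal. The lower, inclusive bar — 6
rather than the concordance gate's strict 10 — trades specificity for
sensitivity where the normal is sequenced at lower multiplex depth and
degraded FFPE runs thin; applying it to both samples keeps the
"absent in normal" assertion evidence-supported, for the same reason as
the ND policy. Any supplied frequency is compared to the 1% cutoff
regardless of source catalogue, since a variant common in either major
catalogue is equally unlikely to be a tumour event.

## Substitution spectra

SNVs collapse into six strand-symmetric classes under the
pyrimidine-reference convention (C>A/G>T, C>G/G>C, C>T/G>A, T>A/A>T,
T>C/A>G, T>G/A>C): sequencing cannot tell which strand mutated, and
reporting pairs halves the table without losing information. The
directional identity of each call is retained in the input records for
diagnostics. Trinucleotide-context (96-class) spectra are out of scope;
the deamination fingerprint this package targets is visible at the
six-class level as C>T/G>A excess among FFPE-only calls.

Enrichment folds are ratios of raw class counts (FFPE/FF), matching how
absolute per-class counts are compared across sample types; a
rate-per-Mb normalisation is available but off by default. A fold with
a zero FF denominator and non-zero FFPE numerator is reported as `NA`
with an `undefined` flag — never as infinity, which would silently
dominate any downstream aggregation. Transitions pool C>T/G>A with
T>C/A>G; transversions pool the remaining four classes.

## The synthetic-data generator

`simulate_paired_callsets()` emulates the *callset-level* statistical
structure the analysis assumes — it does not simulate reads. Injecting
artifacts at the level of sites, depths and allele counts exercises
every in-scope operation; read-level simulation would add an alignment
and calling stack without testing any of them.

The generative model, per site:

* **Targets**: ~80 intervals of 150–400 bp on synthetic contigs named
  `chrS1`… (the naming precludes accidental confusion with any real
  reference).
* **Origins**: 300 germline variants (VAF 0.5, 10% homozygous at 1.0)
  present in all three samples; 30 clonal somatic variants
  (VAF ~ Uniform(0.4, 1)) in both tumours; deamination artifacts only
  in FFPE, Poisson-many with mean `artifact_rate`.
* **Depth**: negative binomial (Poisson-gamma) per site with the
  sample's mean and dispersion `size = 2`. Means default to 60X for FF
  and HQ-FFPE tumours, 45X for the normal, 17X for LQ-FFPE.
* **Alternate reads**: Binomial(depth, VAF); a site is "called" at ≥ 3
  alternate reads (configurable), with filter label KEEP.
* **Artifacts**: class drawn from `artifact_class_probs` — default 75%
  C>T/G>A, transitions well above transversions in the remainder
  (10% T>C/A>G, ~4% each transversion class) — and VAF ~ Beta(2, 8),
  which concentrates mass near the 0.2 alt-ratio gate so the filter's
  discriminating role is actually exercised rather than trivially
  passed.
* **Companions**: a qPCR panel drawn from the random-breakage model
  (lesion rate 0.005/bp for HQ, 0.02/bp for LQ — Q129 of 0.64 and 0.17,
  inside the published gates) and a read-count summary in the matching
  regime (LQ: ~14M reads, ~21% trimmed, ~12% duplicates; FF/HQ: ~55M,
  ~9%, ~8–10%).

The truth table records every site's origin, per-sample depths and call
status, and the concordance label the rule table implies, so tests can
demand exact recovery when depth is forced high and statistical
recovery (binomial/multinomial intervals) otherwise.

Two knobs deserve explicit caveats. The **absolute artifact burden** is
not identifiable from relative enrichment statements, so
`artifact_rate` is a free parameter; its default follows the qualitative
pattern that false positives are rare in well-preserved FFPE and
dominant in degraded FFPE (5 per HQ sample, 150 per LQ sample). The
**depth dispersion** is a single knob standing in for everything that
spreads real exome coverage (capture efficiency, GC, mappability);
`size = 2` reproduces the pronounced breadth loss of a 17X exome
(about two-thirds of target positions at ≥10X) while keeping 60X
samples near-complete, but no single size matches the full breadth
profile of real data at both depth regimes. Consequently the synthetic
HQ shared fraction runs in the high 80s rather than the mid-90s typical
of well-covered real pairs, and synthetic results should be read as
*directional* — LQ degrades concordance relative to HQ, artifacts
concentrate in C>T/G>A — not as calibrated absolute rates.

What passing tests therefore show: the operations implement their
definitions exactly (closed-form and brute-force oracles), the
classifier matches the rule table on arbitrary inputs, and injected
artifact parameters are recovered within sampling error. What they do
not show: performance on real BAM-derived callsets, whose error
structure (alignment artifacts, strand bias, repetitive regions) the
generator deliberately does not model.

## Numerical and testing choices

Determinism: every stochastic path flows from a single integer seed;
identical seeds give identical simulations byte for byte. Percentages
in human-readable tables are rounded to one decimal; machine-readable
JSON keeps full precision. Undefined metrics (zero denominators: empty
read sets, zero total depth, empty false-positive sets, doubly-empty
spectra) raise typed errors rather than returning NaN. Chromosome names
are compared chr-prefix-insensitively, and a callset whose chromosomes
are absent from the target BED raises an error naming them, since that
almost always indicates mismatched naming schemes.

Test problem sizes are chosen to keep the full suite fast while leaving
no estimator starved: oracle-equivalence runs use 200-site random
callsets over several seeds; spectrum recovery uses ≥ 500 artifact
draws (binomial half-width ≈ 4 percentage points at p = 0.75); the
Poisson coverage check uses a 20 kb track. The acceptance script runs
the same simulation scale.

## Known limitations

* Consequence annotation, variant calling, alignment and recalibration
  are upstream: the package consumes their outputs.
* The qPCR model ignores amplification efficiency differences between
  amplicons and cycle-threshold mechanics; it models relative
  concentrations only, which is all the Q-ratio uses.
* No copy-number, loss-of-heterozygosity or subclonal evolution in the
  simulator: a germline variant with tumour LOH will appear as a
  germline call in all samples, not as the near-homozygous tumour
  genotype such events show in practice.
* Fold-change enrichment on raw counts is sensitive to callable-size
  differences between samples; use the rate-normalised mode when
  comparing callsets restricted to different regions.
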