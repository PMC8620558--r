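test_that("count and frequency metrics follow their defining formulas", {
  expect_equal(mutation_count(tibble::tibble(pos = integer(0)), 100), 0)
  expect_equal(mutation_count(tibble::tibble(pos = c(3L, 60L, 99L)), 100), 0.03)
  # two variants at the same base count one mutated base
  expect_equal(
    mutation_count(tibble::tibble(pos = c(10L, 10L), alt_allele = c("A", "G")), 100),
    0.01
  )
  expect_message(
    by_allele <- mutation_count(
      tibble::tibble(pos = c(10L, 10L), alt_allele = c("A", "G")), 100,
      by_allele = TRUE
    ),
    "differs"
  )
  expect_equal(by_allele, 0.02)
  expect_equal(
    mutation_frequency(tibble::tibble(allele_fraction = 0.5), 4), 0.125
  )
  expect_error(mutation_count(tibble::tibble(pos = 1L), 0), "positive")
})

test_that("metrics equal the naive per-base oracle on random fixtures", {
  set.seed(21)
  for (i in 1:25) {
    glen <- sample(50:400, 1)
    n <- sample(0:80, 1)
    pos <- if (n > 0) sample(glen, n, replace = TRUE) else integer(0)
    af <- runif(n)
    v <- tibble::tibble(pos = pos, allele_fraction = af)
    expect_equal(mutation_count(v, glen), oracle_count(pos, glen), tolerance = 1e-14)
    expect_equal(mutation_frequency(v, glen), oracle_frequency(pos, af, glen),
      tolerance = 1e-14
    )
  }
  # with every allele fraction 1 and one variant per base the two coincide
  v1 <- tibble::tibble(pos = sample(100, 12), allele_fraction = 1)
  expect_equal(mutation_count(v1, 100), mutation_frequency(v1, 100))
})

test_that("region metrics normalise by region length and recombine to the genome metric", {
  ref <- tiny_ref() # D-loop is 8 bp
  v <- tibble::tibble(
    animal_id = "A1", tissue = "liver",
    pos = c(25L, 28L), ref_allele = c("C", "A"), alt_allele = c("T", "G"),
    allele_fraction = c(0.5, 0.25)
  )
  rm <- region_metrics(v, ref)
  dl <- dplyr::filter(rm, region == "D-loop")
  expect_equal(dl$count_metric, 2 / 8)
  expect_equal(dl$frequency_metric, 0.75 / 8)
  expect_equal(dplyr::filter(rm, region == "CDS")$count_metric, 0)
  # weighted recombination reproduces the genome-wide metric
  lens <- region_lengths(ref)
  gw <- genome_metrics(v, ref)
  expect_equal(
    sum(rm$count_metric * lens[rm$region]) / ref$length,
    gw$count_metric
  )
  expect_equal(
    sum(rm$frequency_metric * lens[rm$region]) / ref$length,
    gw$frequency_metric
  )
})

test_that("codon-position metrics use per-position denominators and zero empty groups", {
  ref <- tiny_ref()
  coh_v <- tibble::tibble(
    animal_id = "A1", tissue = "liver",
    pos = c(3L, 6L, 9L), # all third positions of geneP
    ref_allele = ref$chars[c(3, 6, 9)],
    alt_allele = c("A", "A", "C"),
    allele_fraction = c(0.2, 0.2, 0.2)
  )
  cls <- annotate_effect(coh_v, ref)
  cp <- codon_position_metrics(cls, ref)
  n_codons <- (12 + 9) / 3 # complete codons in geneP + geneM
  expect_equal(dplyr::filter(cp, codon_position == 3)$count_metric, 3 / n_codons)
  expect_equal(dplyr::filter(cp, codon_position == 1)$count_metric, 0)
  expect_equal(dplyr::filter(cp, codon_position == 2)$n_variants, 0L)

  # saturating every CDS base once gives equal metrics across positions
  cds_pos <- which(!is.na(ref$index$codon_position))
  sat <- tibble::tibble(
    animal_id = "A1", tissue = "liver", pos = cds_pos,
    ref_allele = ref$chars[cds_pos],
    alt_allele = chartr("ACGT", "GTAC", ref$chars[cds_pos]),
    allele_fraction = 1
  )
  cp_sat <- codon_position_metrics(annotate_effect(sat, ref), ref)
  expect_equal(length(unique(cp_sat$count_metric)), 1)
  expect_equal(length(unique(cp_sat$frequency_metric)), 1)
})

test_that("substitution spectra conserve totals across classes", {
  ref <- toy_mt_reference()
  coh <- simulate_cohort(small_config(), with_depth = FALSE)
  cls <- classify_variants(coh$calls, ref)
  sp <- substitution_spectrum(cls, ref)
  expect_setequal(unique(sp$collapsed_class), mitospectr:::COLLAPSED_CLASSES)
  expect_equal(sum(sp$n_variants), sum(cls$var_class == "SNV"))
  sp_str <- substitution_spectrum(cls, ref, stranded = TRUE)
  expect_equal(sum(sp_str$n_variants), sum(cls$var_class == "SNV"))
  expect_equal(nrow(dplyr::distinct(sp_str, stranded)), 12)

  # one variant per class fixture
  one_each <- tibble::tibble(
    animal_id = "A1", tissue = "liver",
    pos = 1:6,
    ref_allele = c("C", "T", "C", "T", "C", "T"),
    alt_allele = c("T", "C", "A", "A", "G", "G"),
    allele_fraction = 0.1,
    var_class = "SNV"
  )
  one_cls <- dplyr::bind_cols(
    one_each,
    classify_substitution(one_each$ref_allele, one_each$alt_allele)
  )
  sp1 <- substitution_spectrum(one_cls, ref)
  expect_true(all(sp1$n_variants == 1))
})

test_that("strand-bias correction rescales counts to cytosine depth", {
  spec <- tibble::tibble(
    stranded = c("C>T", "G>A", "T>C", "A>G"),
    count_metric = c(0.004, 0.002, 0.001, 0.001),
    frequency_metric = 0, n_variants = c(40L, 20L, 10L, 10L)
  )
  equal_totals <- c(A = 1e6, C = 1e6, G = 1e6, T = 1e6)
  corr <- strand_bias_correction(spec, equal_totals)
  expect_equal(corr$corrected_n, as.numeric(spec$n_variants))
  expect_true(all(corr$correction_factor == 1))

  skewed <- c(A = 1e6, C = 2e6, G = 1e6, T = 1e6)
  corr2 <- strand_bias_correction(spec, skewed)
  expect_equal(corr2$correction_factor[corr2$stranded == "C>T"], 1) # cytosine anchor
  expect_equal(
    corr2$corrected_n[corr2$stranded == "G>A"],
    2 * spec$n_variants[spec$stranded == "G>A"]
  )
  expect_error(
    strand_bias_correction(spec, c(A = 1, C = 1, G = 0, T = 1)),
    "zero total depth.*G"
  )
  # composition fallback equals depth route under uniform depth
  ref <- tiny_ref()
  dp <- depth_profile(seq_len(ref$length), rep(100L, ref$length), ref)
  corr_depth <- strand_bias_correction(spec, dp)
  corr_comp <- strand_bias_correction(spec, NULL, ref = ref)
  expect_equal(corr_depth$correction_factor, corr_comp$correction_factor)
})

test_that("genome scans average per-base, wrap circularly, and normalise to 1", {
  ref <- tiny_ref()
  v <- tibble::tibble(pos = c(10L, 10L, 30L), allele_fraction = c(0.2, 0.4, 0.8))
  scan <- genome_scan(v, ref, window_bp = 5)
  expect_equal(scan$frequency[10], 0.3) # two alts at one base are averaged
  expect_equal(scan$frequency[30], 0.8)
  expect_equal(max(scan$norm_frequency), 1)
  expect_equal(max(scan$norm_count), 1)

  # rolling means equal the naive circular windowed oracle
  set.seed(31)
  x <- runif(40)
  for (w in c(1, 2, 5, 8, 13)) {
    expect_equal(mitospectr:::roll_mean_circular(x, w), oracle_roll(x, w),
      tolerance = 1e-12
    )
  }
  # independent cross-check against stats::filter for odd windows
  expect_equal(
    mitospectr:::roll_mean_circular(x, 5),
    as.numeric(stats::filter(x, rep(1 / 5, 5), circular = TRUE)),
    tolerance = 1e-12
  )
  # wrap: signal at the origin bleeds into windows at the other end
  v_edge <- tibble::tibble(pos = 1L, allele_fraction = 1)
  scan_edge <- genome_scan(v_edge, ref, window_bp = 5)
  expect_gt(scan_edge$roll_frequency[ref$length], 0)
})

test_that("germline and somatic metrics add to the per-sample total", {
  coh <- simulate_cohort(small_config(), with_depth = FALSE)
  cls <- classify_variants(coh$calls, coh$ref)
  by_inh <- genome_metrics(cls, coh$ref)
  total <- genome_metrics(dplyr::select(cls, -inheritance), coh$ref)
  recombined <- by_inh |>
    dplyr::group_by(animal_id, tissue) |>
    dplyr::summarise(frequency_metric = sum(frequency_metric), .groups = "drop")
  expect_equal(
    recombined$frequency_metric,
    dplyr::arrange(total, animal_id, tissue)$frequency_metric
  )
})
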