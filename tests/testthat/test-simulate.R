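test_that("identical seeds produce byte-identical emitted files", {
  cfg <- small_config(seed = 99)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  emit_cohort(simulate_cohort(cfg), dir1)
  emit_cohort(simulate_cohort(cfg), dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)),
      label = f
    )
  }
  # a different seed changes the calls
  coh_b <- simulate_cohort(small_config(seed = 100), with_depth = FALSE)
  coh_a <- simulate_cohort(cfg, with_depth = FALSE)
  expect_false(identical(coh_a$calls$pos, coh_b$calls$pos))
})

test_that("degenerate configurations behave as constructed", {
  # no somatic variants: the pipeline classifies everything germline
  cfg <- small_config(seed = 5)
  cfg$n_somatic <- c(brain = 0L, liver = 0L)
  coh <- simulate_cohort(cfg, with_depth = FALSE)
  cls <- classify_variants(coh$calls, coh$ref)
  expect_true(all(cls$inheritance == "germline"))

  # full D-loop depletion: no D-loop variants at all
  cfg2 <- small_config(seed = 6, dloop_depletion = 0)
  coh2 <- simulate_cohort(cfg2, with_depth = FALSE)
  expect_false(any(region_of(coh2$ref, coh2$calls$pos) == "D-loop"))

  # more variants than available sites is an error
  tiny <- tiny_ref()
  cfg3 <- sim_config(
    seed = 7, n_animals = 1L, genome = tiny,
    n_germline = 50L, n_somatic = c(brain = 0L, liver = 0L)
  )
  expect_error(simulate_cohort(cfg3, with_depth = FALSE), "exceed available sites")
})

test_that("emitted cohorts round-trip exactly through the readers", {
  cfg <- small_config(seed = 12)
  coh <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  emit_cohort(coh, dir)

  ref <- load_reference(
    file.path(dir, "reference.fasta"),
    file.path(dir, "reference.gff3")
  )
  expect_identical(ref$sequence, coh$ref$sequence)

  samples <- dplyr::distinct(coh$calls, animal_id, tissue)
  recovered <- purrr::pmap_dfr(samples, function(animal_id, tissue) {
    read_vcf(
      file.path(dir, sprintf("%s_%s.vcf", animal_id, tissue)),
      animal_id, tissue
    )
  })
  orig <- dplyr::arrange(coh$calls, animal_id, tissue, pos, alt_allele)
  rec <- dplyr::arrange(recovered, animal_id, tissue, pos, alt_allele)
  expect_identical(rec$pos, orig$pos)
  expect_identical(rec$ref_allele, orig$ref_allele)
  expect_identical(rec$alt_allele, orig$alt_allele)
  expect_identical(rec$var_class, orig$var_class)
  expect_equal(rec$allele_fraction, orig$allele_fraction, tolerance = 1e-9)

  # depth files reload to the same profile, and totals invariant holds
  key <- sprintf("%s.%s", samples$animal_id[1], samples$tissue[1])
  dp <- read_depth(
    file.path(dir, sprintf("%s_%s.depth.tsv", samples$animal_id[1], samples$tissue[1])),
    ref, samples$animal_id[1], samples$tissue[1]
  )
  expect_equal(dp$depth$depth, coh$depth[[key]]$depth$depth)
  for (b in c("A", "C", "G", "T")) {
    expect_equal(
      dp$nucleotide_totals[[b]],
      sum(dp$depth$depth[ref$chars == b])
    )
  }
})

test_that("emitted VCFs are structurally valid VCF 4.2", {
  coh <- simulate_cohort(small_config(seed = 13))
  dir <- withr::local_tempdir()
  emit_cohort(coh, dir)
  vcf <- readLines(file.path(dir, "M01_liver.vcf"))
  expect_identical(vcf[1], "##fileformat=VCFv4.2")
  header_at <- grep("^#CHROM", vcf)
  expect_length(header_at, 1)
  expect_identical(
    strsplit(vcf[header_at], "\t")[[1]][1:9],
    c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT")
  )
  body <- vcf[(header_at + 1):length(vcf)]
  fields <- strsplit(body, "\t")
  expect_true(all(lengths(fields) == 10))
  pos <- as.integer(vapply(fields, `[`, character(1), 2))
  expect_false(is.unsorted(pos))
  expect_true(all(pos >= 1 & pos <= coh$ref$length))
})

test_that("simulated depth matches the configured mean within 1%", {
  cfg <- small_config(seed = 14)
  coh <- simulate_cohort(cfg)
  key <- names(coh$depth)[1]
  total <- sum(coh$depth[[key]]$depth$depth)
  expected <- cfg$mean_depth * coh$ref$length
  expect_lt(abs(total - expected) / expected, 0.01)
})

test_that("null cohorts yield near-zero burden and no germline calls", {
  cfg <- small_config(seed = 15)
  zero <- null_cohort(cfg, rate = 0)
  expect_equal(nrow(zero$calls), 0)
  gm <- genome_metrics(zero$calls, zero$ref)
  expect_true(nrow(gm) == 0 || all(gm$count_metric == 0))

  # Poisson mean check over seeds, pooled across samples
  counts <- unlist(lapply(1:5, function(s) {
    coh <- null_cohort(small_config(seed = s), rate = 3)
    tab <- dplyr::count(coh$calls, animal_id, tissue)
    # samples that drew zero calls are absent from the table
    c(tab$n, rep(0, 6 - nrow(tab)))
  }))
  expect_lt(abs(mean(counts) - 3), 3 * sqrt(3 / length(counts)))

  coh3 <- null_cohort(small_config(seed = 16), rate = 3)
  if (nrow(coh3$calls) > 0) {
    cls <- classify_variants(coh3$calls, coh3$ref)
    expect_true(all(cls$inheritance == "somatic"))
  }
})

test_that("spectrum weights must be valid and config validates", {
  expect_error(
    small_config(spectrum_weights = c("C:T/G:A" = 1)),
    "named by the 6"
  )
  w <- c(
    "C:T/G:A" = 0.5, "T:C/A:G" = 0.2, "C:A/G:T" = 0.1,
    "T:A/A:T" = 0.1, "C:G/G:C" = 0.05, "T:G/A:C" = 0.1
  )
  expect_error(small_config(spectrum_weights = w), "sum to 1")
  expect_error(small_config(dloop_depletion = 1.5), "probability")
  expect_error(
    sim_config(n_somatic = c(10, 10)),
    "named vector"
  )
})

test_that("simulation configs load from flat JSON and YAML files", {
  json <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "seed": 3, "n_animals": 2, "n_germline": 5,
    "n_somatic": {"brain": 2, "liver": 4},
    "somatic_af_dist": {"family": "beta", "shape1": 1, "shape2": 9},
    "dloop_depletion": 0.5
  }', json)
  cfg <- sim_config_from_file(json)
  expect_s3_class(cfg, "mt_sim_config")
  expect_equal(cfg$n_somatic, c(brain = 2, liver = 4))
  expect_equal(cfg$somatic_af_dist$shape2, 9)
  expect_equal(cfg$dloop_depletion, 0.5)
  # same config through YAML gives the same cohort
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 3", "n_animals: 2", "n_germline: 5",
    "n_somatic:", "  brain: 2", "  liver: 4",
    "somatic_af_dist: {family: beta, shape1: 1, shape2: 9}",
    "dloop_depletion: 0.5"
  ), yml)
  cfg_y <- sim_config_from_file(yml)
  expect_identical(
    simulate_cohort(cfg_y, with_depth = FALSE)$calls,
    simulate_cohort(cfg, with_depth = FALSE)$calls
  )
  # unknown keys are refused
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"seed": 1, "bogus": 2}', bad)
  expect_error(sim_config_from_file(bad), "unknown config key")
})
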