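test_that("tissue pairing labels shared tuples germline, private ones somatic", {
  brain <- tibble::tibble(
    animal_id = "A1", tissue = "brain",
    pos = c(5L, 9L), ref_allele = c("C", "T"), alt_allele = c("T", "A")
  )
  liver <- tibble::tibble(
    animal_id = "A1", tissue = "liver",
    pos = c(5L, 12L), ref_allele = c("C", "G"), alt_allele = c("T", "A")
  )
  paired <- pair_tissues(brain, liver)
  expect_identical(
    paired$inheritance[paired$pos == 5],
    c("germline", "germline") # one row per tissue
  )
  expect_identical(paired$inheritance[paired$pos == 9], "somatic")
  expect_identical(paired$inheritance[paired$pos == 12], "somatic")

  # same base, different change: both somatic
  liver2 <- dplyr::mutate(liver, alt_allele = ifelse(pos == 5, "A", alt_allele))
  paired2 <- pair_tissues(brain, liver2)
  expect_true(all(paired2$inheritance == "somatic"))

  expect_error(
    pair_tissues(brain, dplyr::mutate(liver, animal_id = "A2")),
    "single animal"
  )
})

test_that("pairing matches exhaustive tuple intersection on a random fixture", {
  set.seed(11)
  mk <- function(tissue, n) {
    tibble::tibble(
      animal_id = "A1", tissue = tissue,
      pos = sample(1:30, n, replace = TRUE),
      ref_allele = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alt_allele = sample(c("A", "C", "G", "T"), n, replace = TRUE)
    ) |> dplyr::distinct()
  }
  brain <- mk("brain", 10)
  liver <- mk("liver", 10)
  paired <- pair_tissues(brain, liver)
  key <- function(d) paste(d$pos, d$ref_allele, d$alt_allele)
  shared <- intersect(key(brain), key(liver))
  expect_identical(
    paired$inheritance,
    ifelse(key(paired) %in% shared, "germline", "somatic")
  )
})

test_that("the 12 stranded changes collapse 2-to-1 onto 6 classes", {
  bases <- c("A", "C", "G", "T")
  all_changes <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE) |>
    dplyr::filter(ref != alt)
  cls <- classify_substitution(all_changes$ref, all_changes$alt)
  expect_equal(nrow(cls), 12)
  expect_equal(length(unique(cls$collapsed_class)), 6)
  expect_true(all(table(cls$collapsed_class) == 2))
  # a change and its reverse complement share a class
  rc <- function(b) chartr("ACGT", "TGCA", b)
  for (i in seq_len(nrow(all_changes))) {
    expect_identical(
      classify_substitution(all_changes$ref[i], all_changes$alt[i])$collapsed_class,
      classify_substitution(rc(all_changes$ref[i]), rc(all_changes$alt[i]))$collapsed_class
    )
  }
  expect_identical(classify_substitution("G", "A")$collapsed_class, "C:T/G:A")
  expect_identical(classify_substitution("G", "A")$stranded, "G>A")
  expect_identical(
    classify_substitution("C", "A")$collapsed_class,
    classify_substitution("G", "T")$collapsed_class
  )
  expect_error(classify_substitution("C", "C"), "identical")
})

test_that("codon effects by substitution match the whole-gene retranslation oracle", {
  ref <- tiny_ref()
  bases <- c("A", "C", "G", "T")
  for (gene in c("geneP", "geneM")) {
    f <- ref$features[ref$features$name == gene, ]
    for (pos in f$start:f$end) {
      for (alt in setdiff(bases, ref$chars[pos])) {
        got <- annotate_effect(
          tibble::tibble(pos = pos, ref_allele = ref$chars[pos], alt_allele = alt),
          ref
        )
        expect_identical(got$effect, oracle_effect(ref, gene, pos, alt),
          label = sprintf("%s pos %d %s>%s", gene, pos, ref$chars[pos], alt)
        )
      }
    }
  }
})

test_that("effect annotation distinguishes silent, nonsense and noncoding", {
  # wobble: GAT -> GAC at a third position stays aspartate
  ref <- tiny_ref()
  silent <- annotate_effect(
    tibble::tibble(pos = 9L, ref_allele = "T", alt_allele = "C"), ref
  )
  expect_identical(silent$effect, "silent")
  expect_identical(silent$aa_ref, silent$aa_alt)
  expect_equal(silent$codon_position, 3L)

  # TAC (Tyr) -> TAG is a premature stop on a plus-strand codon
  stop_ref <- mt_reference(
    "ATGTACAAA",
    data.frame(name = "g", kind = "CDS", start = 1, end = 9, strand = "+")
  )
  nonsense <- annotate_effect(
    tibble::tibble(pos = 6L, ref_allele = "C", alt_allele = "G"), stop_ref
  )
  expect_identical(nonsense$effect, "nonsense")
  expect_identical(nonsense$aa_alt, "*")

  noncoding <- annotate_effect(
    tibble::tibble(pos = 28L, ref_allele = "A", alt_allele = "G"), ref
  )
  expect_identical(noncoding$effect, "noncoding")
  expect_true(is.na(noncoding$codon_position))

  # REF disagreement with the reference sequence is an error
  expect_error(
    annotate_effect(tibble::tibble(pos = 1L, ref_allele = "C", alt_allele = "G"), ref),
    "disagrees"
  )
})

test_that("incomplete terminal codons are excluded and reported", {
  ref <- wrap_ref() # 10-base CDS: one trailing base beyond 3 codons
  expect_message(
    out <- annotate_effect(
      tibble::tibble(pos = 7L, ref_allele = ref$chars[7], alt_allele = "C"), ref
    ),
    "incomplete terminal codon"
  )
  expect_true(is.na(out$effect))
})

test_that("property changes pair ordered classes with stop as destination", {
  expect_identical(
    annotate_property_change("A", "V"),
    tibble::tibble(property_ref = "hydrophobic", property_alt = "hydrophobic")
  )
  expect_identical(annotate_property_change("T", "I")$property_alt, "hydrophobic")
  expect_identical(annotate_property_change("T", "I")$property_ref, "hydrophilic")
  expect_identical(annotate_property_change("D", "E")$property_alt, "acidic")
  expect_identical(annotate_property_change("Y", "*")$property_alt, "stop")
})

test_that("indels classify by length with frameshift on non-multiples of three", {
  del2 <- classify_indel("CAA", "C")
  expect_identical(del2$indel_direction, "deletion")
  expect_equal(del2$indel_length, 2L)
  expect_true(del2$frameshift)
  expect_false(classify_indel("CAAA", "C")$frameshift)
  ins6 <- classify_indel("C", "CAAAAAA")
  expect_identical(ins6$indel_direction, "insertion")
  expect_false(ins6$frameshift)
  expect_error(classify_indel("CA", "CG"), "equal length")
  # region flag marks where frameshift status is meaningful
  flagged <- classify_indel(c("CAA", "CAA"), c("C", "C"), region = c("CDS", "D-loop"))
  expect_identical(flagged$frameshift_applicable, c(TRUE, FALSE))
})

test_that("classified cohorts partition into germline + somatic consistently", {
  coh <- simulate_cohort(small_config(), with_depth = FALSE)
  cls <- classify_variants(coh$calls, coh$ref)
  expect_true(all(cls$inheritance %in% c("germline", "somatic")))
  expect_identical(cls$inheritance, coh$truth$true_inheritance)
  # per animal and tissue: germline + somatic rows = all rows
  per <- cls |>
    dplyr::count(animal_id, tissue, inheritance) |>
    tidyr::pivot_wider(names_from = inheritance, values_from = n, values_fill = 0L)
  totals <- dplyr::count(cls, animal_id, tissue)
  expect_equal(per$germline + per$somatic, totals$n)
  # effect-level invariants
  snv <- dplyr::filter(cls, var_class == "SNV", region == "CDS", !is.na(effect))
  expect_true(all(snv$aa_ref[snv$effect == "silent"] == snv$aa_alt[snv$effect == "silent"]))
  mis <- dplyr::filter(snv, effect == "missense")
  expect_true(all(mis$aa_ref != mis$aa_alt))
  expect_true(all(mis$aa_alt != "*" | mis$aa_ref == "*"))
  non <- dplyr::filter(snv, effect == "nonsense")
  expect_true(all(non$aa_alt == "*"))
  # frameshift defined exactly for indels
  expect_true(all(is.na(cls$frameshift[cls$var_class == "SNV"])))
  expect_true(all(!is.na(cls$frameshift[cls$var_class != "SNV"])))
})
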