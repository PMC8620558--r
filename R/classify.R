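COLLAPSED_CLASSES <- c(
  "C:T/G:A", "T:C/A:G", "C:A/G:T", "T:A/A:T", "C:G/G:C", "T:G/A:C"
)

## The 12 stranded single-base changes map 2-to-1 onto 6 collapsed classes:
## a change and its reverse complement are indistinguishable in
## double-stranded sequencing data and are reported as one category.
stranded_to_collapsed <- function() {
  c(
    "C>T" = "C:T/G:A", "G>A" = "C:T/G:A",
    "T>C" = "T:C/A:G", "A>G" = "T:C/A:G",
    "C>A" = "C:A/G:T", "G>T" = "C:A/G:T",
    "T>A" = "T:A/A:T", "A>T" = "T:A/A:T",
    "C>G" = "C:G/G:C", "G>C" = "C:G/G:C",
    "T>G" = "T:G/A:C", "A>C" = "T:G/A:C"
  )
}

#' Classify a single-base substitution
#'
#' Maps a reference/alternate base pair to its stranded change (as seen on
#' the reference L-strand, e.g. `"G>A"`) and its collapsed class, in which
#' a change and its reverse-complement partner are combined (e.g. C>T with
#' G>A), giving the six categories used throughout the mutation-spectrum
#' summaries. The stranded change is preserved for strand-asymmetry
#' analysis.
#'
#' @param ref_allele,alt_allele Single bases over `{A,C,G,T}` (vectorised).
#' @return Tibble with columns `stranded` and `collapsed_class`.
#' @export
#' @examples
#' classify_substitution("G", "A")
classify_substitution <- function(ref_allele, alt_allele) {
  ref_allele <- toupper(ref_allele)
  alt_allele <- toupper(alt_allele)
  bad <- !grepl("^[ACGT]$", ref_allele) | !grepl("^[ACGT]$", alt_allele)
  if (any(bad)) abort("substitution alleles must be single bases over {A,C,G,T}")
  if (any(ref_allele == alt_allele)) abort("ref and alt allele are identical")
  stranded <- paste0(ref_allele, ">", alt_allele)
  tibble(
    stranded = stranded,
    collapsed_class = unname(stranded_to_collapsed()[stranded])
  )
}

#' Label variants as germline or somatic by tissue pairing
#'
#' Within each animal, a variant is germline when an identical
#' (position, ref, alt) tuple was called in both tissues, and somatic
#' otherwise. Germline variants keep one row per tissue — each with its
#' own allele fraction — so tissue-level frequency metrics remain
#' computable even though the count metric cannot separate tissues for
#' germline mutations. No allele-fraction similarity is required for the
#' germline label; detection thresholds live upstream in the caller.
#'
#' @param calls Tibble of variant calls with columns `animal_id`,
#'   `tissue`, `pos`, `ref_allele`, `alt_allele`. Both tissues of an
#'   animal should be present; animals are processed independently.
#' @return `calls` with an added `inheritance` column
#'   (`"germline"`/`"somatic"`).
#' @export
classify_inheritance <- function(calls) {
  required <- c("animal_id", "tissue", "pos", "ref_allele", "alt_allele")
  missing_cols <- setdiff(required, names(calls))
  if (length(missing_cols) > 0) {
    abort(sprintf("calls lack column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  n_tissues <- calls |>
    dplyr::distinct(.data$animal_id, .data$tissue, .data$pos, .data$ref_allele, .data$alt_allele) |>
    dplyr::count(.data$animal_id, .data$pos, .data$ref_allele, .data$alt_allele, name = "n_tissues")
  calls |>
    dplyr::left_join(
      n_tissues,
      by = c("animal_id", "pos", "ref_allele", "alt_allele")
    ) |>
    dplyr::mutate(
      inheritance = ifelse(.data$n_tissues >= 2, "germline", "somatic"),
      n_tissues = NULL
    )
}

#' Pair one animal's brain and liver calls
#'
#' Convenience wrapper around [classify_inheritance()] taking the two
#' tissue call sets of a single animal separately.
#'
#' @param brain_calls,liver_calls Call tibbles for the two tissues of one
#'   animal (see [read_vcf()]).
#' @return Combined tibble with the `inheritance` column set.
#' @export
pair_tissues <- function(brain_calls, liver_calls) {
  calls <- dplyr::bind_rows(brain_calls, liver_calls)
  if (dplyr::n_distinct(calls$animal_id) > 1) {
    abort("pair_tissues() expects calls from a single animal")
  }
  classify_inheritance(calls)
}

#' Annotate codon effects of SNVs
#'
#' For each single-nucleotide variant, determines the region and — inside
#' protein-coding genes — the codon position and the effect of the change:
#' `silent` (same amino acid), `missense` (different amino acid, not a
#' stop gain), or `nonsense` (premature stop). The reference codon is read
#' on the gene's coding strand; for minus-strand genes the alternate base
#' is complemented before substitution. Non-CDS SNVs get effect
#' `noncoding`. Loss of a reference stop codon is counted as missense.
#' SNVs falling in an incomplete terminal codon cannot be annotated: their
#' codon fields stay `NA` and a message reports how many were skipped.
#'
#' @param variants Tibble with columns `pos`, `ref_allele`, `alt_allele`
#'   (SNV rows are annotated; indel rows pass through with `NA` effect
#'   fields).
#' @param ref An [mt_reference()].
#' @param property_map Amino-acid property scheme, see [mt_property_map()].
#' @return `variants` with added columns `region`, `codon_position`,
#'   `aa_ref`, `aa_alt`, `effect`, `property_ref`, `property_alt`.
#' @export
annotate_effect <- function(variants, ref, property_map = mt_property_map()) {
  stopifnot(inherits(ref, "mt_reference"))
  n <- nrow(variants)
  out <- variants
  out$region <- region_of(ref, variants$pos)
  out$codon_position <- rep(NA_integer_, n)
  out$aa_ref <- rep(NA_character_, n)
  out$aa_alt <- rep(NA_character_, n)
  out$effect <- rep(NA_character_, n)

  is_snv <- nchar(variants$ref_allele) == 1 & nchar(variants$alt_allele) == 1
  mismatch <- is_snv & ref_base(ref, variants$pos) != toupper(variants$ref_allele)
  if (any(mismatch)) {
    abort(sprintf(
      "REF allele disagrees with the reference sequence at position(s) %s",
      paste(head(variants$pos[mismatch], 5), collapse = ", ")
    ))
  }
  out$effect[is_snv & out$region != "CDS"] <- "noncoding"

  cds <- which(is_snv & out$region == "CDS")
  if (length(cds) > 0) {
    ctx <- codon_context(ref, variants$pos[cds])
    annotatable <- !is.na(ctx$codon_position)
    n_skipped <- sum(!annotatable)
    if (n_skipped > 0) {
      message(sprintf(
        "%d CDS SNV(s) fall in an incomplete terminal codon and were left unannotated",
        n_skipped
      ))
    }
    k <- cds[annotatable]
    ctx <- ctx[annotatable, ]
    if (length(k) > 0) {
      alt_coding <- toupper(variants$alt_allele[k])
      minus <- ctx$strand == "-"
      alt_coding[minus] <- comp_base(alt_coding[minus])
      alt_codon <- ctx$codon
      substr(alt_codon, ctx$codon_position, ctx$codon_position) <- alt_coding
      aa_ref <- translate_mt(ctx$codon)
      aa_alt <- translate_mt(alt_codon)
      out$codon_position[k] <- ctx$codon_position
      out$aa_ref[k] <- aa_ref
      out$aa_alt[k] <- aa_alt
      out$effect[k] <- dplyr::case_when(
        aa_ref == aa_alt ~ "silent",
        aa_alt == "*" & aa_ref != "*" ~ "nonsense",
        TRUE ~ "missense"
      )
    }
  }
  out$property_ref <- ifelse(is.na(out$aa_ref), NA_character_,
    aa_property(dplyr::coalesce(out$aa_ref, "A"), property_map)
  )
  out$property_alt <- ifelse(is.na(out$aa_alt), NA_character_,
    aa_property(dplyr::coalesce(out$aa_alt, "A"), property_map)
  )
  out
}

#' Property change of an amino-acid substitution
#'
#' Ordered pair of side-chain property classes for a reference/variant
#' amino-acid pair; the stop class is used for nonsense variants so stop
#' gains appear as a property destination.
#'
#' @param aa_ref,aa_alt One-letter amino-acid codes or `"*"` (vectorised).
#' @param property_map See [mt_property_map()].
#' @return Tibble with columns `property_ref`, `property_alt`.
#' @export
#' @examples
#' annotate_property_change("T", "I")
annotate_property_change <- function(aa_ref, aa_alt, property_map = mt_property_map()) {
  tibble(
    property_ref = aa_property(aa_ref, property_map),
    property_alt = aa_property(aa_alt, property_map)
  )
}

#' Classify indels by direction, length and frameshift status
#'
#' Indels are VCF-anchored (left-aligned with a shared leading base);
#' length is the absolute difference of allele lengths. A frameshift is an
#' insertion or deletion of a length that is not a multiple of three.
#' Frameshift status is computed for every indel but only meaningful for
#' coding sequence; pass `region` to flag non-CDS indels.
#'
#' @param ref_allele,alt_allele Allele strings (vectorised); each pair
#'   must differ in length.
#' @param region Optional region labels; non-CDS rows get
#'   `frameshift_applicable = FALSE`.
#' @return Tibble with columns `indel_direction`, `indel_length`,
#'   `frameshift`, and `frameshift_applicable` when `region` is given.
#' @export
#' @examples
#' classify_indel("CAA", "C") # 2-bp deletion: frameshift
classify_indel <- function(ref_allele, alt_allele, region = NULL) {
  len_diff <- nchar(alt_allele) - nchar(ref_allele)
  if (any(len_diff == 0)) abort("not an indel: alleles have equal length")
  out <- tibble(
    indel_direction = ifelse(len_diff > 0, "insertion", "deletion"),
    indel_length = abs(len_diff),
    frameshift = abs(len_diff) %% 3L != 0L
  )
  if (!is.null(region)) {
    out$frameshift_applicable <- region == "CDS"
  }
  out
}

#' Classify a table of variant calls end to end
#'
#' One-stop wrapper running the full mutation taxonomy: germline/somatic
#' labelling by tissue pairing ([classify_inheritance()]), region and
#' codon-effect annotation ([annotate_effect()]), stranded and collapsed
#' substitution classes ([classify_substitution()]), and indel
#' direction/length/frameshift ([classify_indel()]; indels take the region
#' of their anchor position). The result has the full mutation-table
#' schema accepted by [write_mutation_table()].
#'
#' @param calls Tibble of variant calls (see [read_vcf()]); may hold many
#'   animals and tissues.
#' @param ref An [mt_reference()].
#' @param property_map See [mt_property_map()].
#' @return Tibble of classified variants.
#' @export
classify_variants <- function(calls, ref, property_map = mt_property_map()) {
  out <- classify_inheritance(calls)
  if (!"var_class" %in% names(out)) {
    out$var_class <- var_class_of(out$ref_allele, out$alt_allele)
  }
  if (!"depth" %in% names(out)) out$depth <- NA_integer_
  out <- annotate_effect(out, ref, property_map)

  is_snv <- out$var_class == "SNV"
  out$stranded <- NA_character_
  out$collapsed_class <- NA_character_
  if (any(is_snv)) {
    sub <- classify_substitution(out$ref_allele[is_snv], out$alt_allele[is_snv])
    out$stranded[is_snv] <- sub$stranded
    out$collapsed_class[is_snv] <- sub$collapsed_class
  }

  out$indel_direction <- NA_character_
  out$indel_length <- NA_integer_
  out$frameshift <- NA
  if (any(!is_snv)) {
    ind <- classify_indel(out$ref_allele[!is_snv], out$alt_allele[!is_snv])
    out$indel_direction[!is_snv] <- ind$indel_direction
    out$indel_length[!is_snv] <- ind$indel_length
    out$frameshift[!is_snv] <- ind$frameshift
  }
  out
}
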