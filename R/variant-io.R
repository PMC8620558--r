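var_class_of <- function(ref_allele, alt_allele) {
  dplyr::case_when(
    nchar(ref_allele) == 1 & nchar(alt_allele) == 1 ~ "SNV",
    nchar(alt_allele) > nchar(ref_allele) ~ "insertion",
    nchar(alt_allele) < nchar(ref_allele) ~ "deletion",
    TRUE ~ NA_character_
  )
}

extract_format_field <- function(format, sample_field, key) {
  keys <- strsplit(format, ":", fixed = TRUE)
  vals <- strsplit(sample_field, ":", fixed = TRUE)
  mapply(function(k, v) {
    i <- match(key, k)
    if (is.na(i) || i > length(v)) NA_character_ else v[i]
  }, keys, vals, USE.NAMES = FALSE)
}

#' Read variant calls from a VCF file
#'
#' Reads a single-contig VCF 4.2 file (Mutect2 mitochondria-mode style)
#' into a tidy call table, one row per ALT allele. Multi-allelic records
#' are split into separate calls at the same position. The allele fraction
#' is taken from the sample `AF` field when present (the caller's model
#' estimate), otherwise computed as alt `AD` divided by the summed `AD`;
#' set `prefer_af = FALSE` to invert the precedence. By default only
#' records with FILTER `PASS` or `.` are kept.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param animal_id,tissue Sample identity attached to every call.
#' @param keep_filter FILTER values to retain; `NULL` keeps everything.
#' @param prefer_af Use `AF` over `AD` when both are present.
#' @return Tibble with columns `animal_id`, `tissue`, `pos`, `ref_allele`,
#'   `alt_allele`, `allele_fraction`, `depth`, `var_class`.
#' @export
read_vcf <- function(path, animal_id, tissue,
                     keep_filter = c("PASS", "."), prefer_af = TRUE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix) # single-record VCFs drop to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(
      animal_id = character(), tissue = character(), pos = integer(),
      ref_allele = character(), alt_allele = character(),
      allele_fraction = double(), depth = integer(), var_class = character()
    ))
  }
  if (length(unique(fix$CHROM)) > 1) {
    abort("expected a single-contig VCF")
  }
  gt <- vcf@gt
  if (is.null(gt) || ncol(gt) < 2) {
    abort("VCF has no sample column carrying AF/AD")
  }
  af_str <- extract_format_field(gt[, 1], gt[, 2], "AF")
  ad_str <- extract_format_field(gt[, 1], gt[, 2], "AD")
  dp_str <- extract_format_field(gt[, 1], gt[, 2], "DP")

  calls <- tibble(
    record = seq_len(nrow(fix)),
    pos = as.integer(fix$POS),
    ref_allele = fix$REF,
    alt = fix$ALT,
    filter = fix$FILTER %||% ".",
    af_str = af_str, ad_str = ad_str, dp_str = dp_str
  )
  if (!is.null(keep_filter)) {
    calls <- dplyr::filter(calls, is.na(.data$filter) | .data$filter %in% keep_filter)
  }
  calls <- tidyr::separate_rows(calls, "alt", sep = ",") |>
    dplyr::group_by(.data$record) |>
    dplyr::mutate(alt_index = dplyr::row_number()) |>
    dplyr::ungroup()

  n <- nrow(calls)
  af <- rep(NA_real_, n)
  dp <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    k <- calls$alt_index[i]
    afs <- if (!is.na(calls$af_str[i])) {
      suppressWarnings(as.numeric(strsplit(calls$af_str[i], ",", fixed = TRUE)[[1]]))
    }
    ads <- if (!is.na(calls$ad_str[i])) {
      suppressWarnings(as.numeric(strsplit(calls$ad_str[i], ",", fixed = TRUE)[[1]]))
    }
    af_from_af <- if (!is.null(afs) && length(afs) >= k) afs[k] else NA_real_
    af_from_ad <- if (!is.null(ads) && length(ads) >= k + 1 && sum(ads) > 0) {
      ads[k + 1] / sum(ads)
    } else {
      NA_real_
    }
    af[i] <- if (prefer_af) {
      if (!is.na(af_from_af)) af_from_af else af_from_ad
    } else {
      if (!is.na(af_from_ad)) af_from_ad else af_from_af
    }
    dp[i] <- if (!is.na(calls$dp_str[i])) {
      suppressWarnings(as.integer(calls$dp_str[i]))
    } else if (!is.null(ads)) {
      as.integer(sum(ads))
    } else {
      NA_integer_
    }
  }
  if (anyNA(af)) {
    bad <- calls$pos[which(is.na(af))]
    abort(sprintf(
      "record(s) at position(s) %s carry neither AF nor usable AD",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  tibble(
    animal_id = animal_id,
    tissue = tissue,
    pos = calls$pos,
    ref_allele = calls$ref_allele,
    alt_allele = calls$alt,
    allele_fraction = af,
    depth = dp,
    var_class = var_class_of(calls$ref_allele, calls$alt)
  )
}

#' Read a per-base depth table
#'
#' Reads `samtools depth`-style three-column text (contig, 1-based
#' position, depth) into a full-genome depth profile. Positions absent
#' from the file (samtools omits zero-depth sites by default) get depth 0.
#' Per-nucleotide depth totals — the input of the strand-asymmetry
#' correction — are computed against the reference base at each position.
#'
#' @param path Path to the depth file (no header).
#' @param ref An [mt_reference()].
#' @param animal_id,tissue Optional sample identity attached to the profile.
#' @return An object of class `mt_depth`: list with `depth` (tibble `pos`,
#'   `depth` covering every position), `nucleotide_totals` (named numeric,
#'   A/C/G/T), `animal_id`, `tissue`.
#' @export
read_depth <- function(path, ref, animal_id = NA_character_, tissue = NA_character_) {
  stopifnot(inherits(ref, "mt_reference"))
  tab <- readr::read_tsv(path,
    col_names = c("contig", "pos", "depth"),
    col_types = "cii", progress = FALSE
  )
  if (nrow(tab) > 0 && any(tab$pos < 1 | tab$pos > ref$length)) {
    abort(sprintf(
      "depth file has position(s) outside [1, %d]",
      ref$length
    ))
  }
  depth_profile(tab$pos, tab$depth, ref, animal_id = animal_id, tissue = tissue)
}

#' Build a depth profile from vectors
#'
#' @param pos,depth Parallel vectors of 1-based positions and depths;
#'   positions not listed get depth 0.
#' @param ref An [mt_reference()].
#' @param animal_id,tissue Optional sample identity.
#' @return An `mt_depth` object (see [read_depth()]).
#' @export
depth_profile <- function(pos, depth, ref, animal_id = NA_character_, tissue = NA_character_) {
  stopifnot(inherits(ref, "mt_reference"))
  full <- rep(0L, ref$length)
  if (length(pos) > 0) {
    pos <- check_positions(ref, pos)
    if (any(depth < 0)) abort("negative depth")
    full[pos] <- as.integer(depth)
  }
  totals <- vapply(
    c("A", "C", "G", "T"),
    function(b) sum(as.numeric(full[ref$chars == b])),
    numeric(1)
  )
  structure(
    list(
      depth = tibble(pos = seq_len(ref$length), depth = full),
      nucleotide_totals = totals,
      animal_id = animal_id,
      tissue = tissue
    ),
    class = "mt_depth"
  )
}

#' @export
print.mt_depth <- function(x, ...) {
  cat(sprintf(
    "<mt_depth> %s/%s: %d positions, mean depth %.1f\n",
    x$animal_id, x$tissue, nrow(x$depth), mean(x$depth$depth)
  ))
  invisible(x)
}

MUTATION_TABLE_COLS <- c(
  "animal_id", "tissue", "pos", "ref_allele", "alt_allele", "var_class",
  "allele_fraction", "depth", "inheritance", "region", "stranded",
  "collapsed_class", "codon_position", "aa_ref", "aa_alt", "effect",
  "property_ref", "property_alt", "indel_direction", "indel_length",
  "frameshift"
)

#' Write a classified mutation table
#'
#' Writes classified variants ([classify_variants()]) as TSV with a
#' stable, documented column order, sorted by (animal, tissue, pos,
#' alt allele). The file round-trips losslessly through
#' [read_mutation_table()].
#'
#' @param variants Tibble of classified variants.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(variants, path) {
  missing_cols <- setdiff(MUTATION_TABLE_COLS, names(variants))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "variants table lacks column(s): %s (classify first)",
      paste(missing_cols, collapse = ", ")
    ))
  }
  out <- variants[, MUTATION_TABLE_COLS] |>
    dplyr::arrange(.data$animal_id, .data$tissue, .data$pos, .data$alt_allele)
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read back a classified mutation table
#'
#' @param path Path written by [write_mutation_table()].
#' @return Tibble with the documented mutation-table schema.
#' @export
read_mutation_table <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      animal_id = "c", tissue = "c", pos = "i", ref_allele = "c",
      alt_allele = "c", var_class = "c", allele_fraction = "d",
      depth = "i", inheritance = "c", region = "c", stranded = "c",
      collapsed_class = "c", codon_position = "i", aa_ref = "c",
      aa_alt = "c", effect = "c", property_ref = "c", property_alt = "c",
      indel_direction = "c", indel_length = "i", frameshift = "l"
    ),
    progress = FALSE
  )
}
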