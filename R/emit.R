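write_sample_vcf <- function(calls, ref, path) {
  calls <- dplyr::arrange(calls, .data$pos, .data$alt_allele)
  dp <- ifelse(is.na(calls$depth), 1000L, calls$depth)
  ad_alt <- pmin(dp, round(calls$allele_fraction * dp))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", ref$name, ref$length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    sprintf(
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t%s_%s",
      calls$animal_id[1] %||% "sample", calls$tissue[1] %||% "tissue"
    )
  )
  records <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD:AF:DP\t0/1:%d,%d:%.10g:%d",
    ref$name, calls$pos, calls$ref_allele, calls$alt_allele,
    dp - ad_alt, ad_alt, calls$allele_fraction, dp
  )
  readr::write_lines(c(header, records), path)
  invisible(path)
}

write_sample_depth <- function(depth, ref, path) {
  readr::write_lines(
    sprintf("%s\t%d\t%d", ref$name, depth$depth$pos, depth$depth$depth),
    path
  )
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Emits a cohort as the file set the analysis side of the package
#' consumes: one VCF 4.2 and (when simulated) one three-column depth file
#' per animal x tissue, the reference FASTA and GFF, a `truth.tsv` with
#' every injected parameter realisation, and a `manifest.json` listing the
#' run. Files round-trip exactly through [read_vcf()] / [read_depth()].
#'
#' @param cohort An `mt_cohort` from [simulate_cohort()] or
#'   [null_cohort()].
#' @param dir Output directory (created if needed).
#' @return Tibble manifest of written files, invisibly.
#' @export
emit_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mt_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ref <- cohort$ref
  files <- list()
  write_reference_fasta(ref, file.path(dir, "reference.fasta"))
  write_reference_gff(ref, file.path(dir, "reference.gff3"))
  files[["reference.fasta"]] <- "reference FASTA"
  files[["reference.gff3"]] <- "feature annotation"

  samples <- dplyr::distinct(cohort$calls, .data$animal_id, .data$tissue)
  for (i in seq_len(nrow(samples))) {
    a <- samples$animal_id[i]
    tis <- samples$tissue[i]
    stem <- sprintf("%s_%s", a, tis)
    calls <- dplyr::filter(cohort$calls, .data$animal_id == a, .data$tissue == tis)
    write_sample_vcf(calls, ref, file.path(dir, paste0(stem, ".vcf")))
    files[[paste0(stem, ".vcf")]] <- sprintf("%d calls", nrow(calls))
    key <- paste(a, tis, sep = ".")
    if (!is.null(cohort$depth) && key %in% names(cohort$depth)) {
      write_sample_depth(cohort$depth[[key]], ref, file.path(dir, paste0(stem, ".depth.tsv")))
      files[[paste0(stem, ".depth.tsv")]] <- "per-base depth"
    }
  }
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  files[["truth.tsv"]] <- sprintf("%d truth rows", nrow(cohort$truth))
  manifest <- tibble(file = names(files), contents = unlist(files))
  jsonlite::write_json(
    list(
      seed = cohort$config$seed,
      n_animals = cohort$config$n_animals,
      genome = ref$name,
      genome_length = ref$length,
      files = manifest
    ),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}
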