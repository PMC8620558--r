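## Mouse-like mitochondrial layout: gene order, strands and approximate
## lengths follow the mouse mtDNA gene map (CDS lengths rounded to complete
## codons); sequence content is simulated, not mouse.
toy_mt_layout <- function() {
  tribble_rows <- list(
    c("tRNA-Phe", "tRNA", "+", 68), c("rRNA-12S", "rRNA", "+", 955),
    c("tRNA-Val", "tRNA", "+", 69), c("rRNA-16S", "rRNA", "+", 1580),
    c("tRNA-Leu1", "tRNA", "+", 75), c("ND1", "CDS", "+", 957),
    c("tRNA-Ile", "tRNA", "+", 69), c("tRNA-Gln", "tRNA", "-", 71),
    c("tRNA-Met", "tRNA", "+", 69), c("ND2", "CDS", "+", 1038),
    c("tRNA-Trp", "tRNA", "+", 67), c("tRNA-Ala", "tRNA", "-", 69),
    c("tRNA-Asn", "tRNA", "-", 71), c("tRNA-Cys", "tRNA", "-", 67),
    c("tRNA-Tyr", "tRNA", "-", 68), c("COX1", "CDS", "+", 1545),
    c("tRNA-Ser1", "tRNA", "-", 69), c("tRNA-Asp", "tRNA", "+", 70),
    c("COX2", "CDS", "+", 684), c("tRNA-Lys", "tRNA", "+", 65),
    c("ATP8", "CDS", "+", 204), c("ATP6", "CDS", "+", 681),
    c("COX3", "CDS", "+", 783), c("tRNA-Gly", "tRNA", "+", 68),
    c("ND3", "CDS", "+", 348), c("tRNA-Arg", "tRNA", "+", 68),
    c("ND4L", "CDS", "+", 297), c("ND4", "CDS", "+", 1377),
    c("tRNA-His", "tRNA", "+", 68), c("tRNA-Ser2", "tRNA", "+", 59),
    c("tRNA-Leu2", "tRNA", "+", 71), c("ND5", "CDS", "+", 1824),
    c("ND6", "CDS", "-", 519), c("tRNA-Glu", "tRNA", "-", 69),
    c("CYTB", "CDS", "+", 1143), c("tRNA-Thr", "tRNA", "+", 67),
    c("tRNA-Pro", "tRNA", "-", 67), c("D-loop", "D-loop", "+", 877)
  )
  tibble(
    name = vapply(tribble_rows, `[`, character(1), 1),
    kind = vapply(tribble_rows, `[`, character(1), 2),
    strand = vapply(tribble_rows, `[`, character(1), 3),
    length = as.integer(vapply(tribble_rows, `[`, character(1), 4))
  )
}

## L-strand base composition approximating mouse mtDNA (cytosine about
## twice as frequent as guanine -- the asymmetry the strand-bias
## correction exists for).
TOY_BASE_FREQ <- c(A = 0.345, C = 0.245, G = 0.123, T = 0.287)

MT_STOP_CODONS <- c("TAA", "TAG", "AGA", "AGG")

sample_nonstop_codons <- function(n, base_freq) {
  bases <- names(base_freq)
  codons <- character(0)
  while (length(codons) < n) {
    cand <- paste0(
      sample(bases, n, replace = TRUE, prob = base_freq),
      sample(bases, n, replace = TRUE, prob = base_freq),
      sample(bases, n, replace = TRUE, prob = base_freq)
    )
    codons <- c(codons, cand[!cand %in% MT_STOP_CODONS])
  }
  codons[seq_len(n)]
}

#' Simulated mouse-like mitochondrial reference
#'
#' Builds a deterministic ~16.4-kb circular reference whose gene order,
#' strands, and approximate feature lengths mimic the mouse mitochondrial
#' genome (13 CDS including one on the minus strand, 22 tRNAs, 2 rRNAs,
#' one D-loop control region). The sequence is simulated: bases are drawn
#' from an L-strand-like composition (C roughly twice G), and CDS regions
#' are filled with random complete codons free of internal stops on their
#' coding strand. It is the default genome for [simulate_cohort()] and for
#' package examples; it carries no real mouse sequence.
#'
#' @param seed Integer seed making the genome reproducible; the global RNG
#'   state is left untouched.
#' @param intergenic_gap Bases of intergenic spacer between consecutive
#'   features.
#' @return An [mt_reference()].
#' @export
#' @examples
#' ref <- toy_mt_reference()
#' region_lengths(ref)
toy_mt_reference <- function(seed = 104729L, intergenic_gap = 2L) {
  layout <- toy_mt_layout()
  start <- cumsum(c(1L, head(layout$length + intergenic_gap, -1)))
  layout$start <- start
  layout$end <- start + layout$length - 1L
  glen <- layout$end[nrow(layout)] + intergenic_gap
  withr::with_seed(seed, {
    chars <- sample(names(TOY_BASE_FREQ), glen, replace = TRUE, prob = TOY_BASE_FREQ)
    for (i in which(layout$kind == "CDS")) {
      codons <- sample_nonstop_codons(layout$length[i] %/% 3L, TOY_BASE_FREQ)
      coding <- strsplit(paste(codons, collapse = ""), "", fixed = TRUE)[[1]]
      p <- feature_coding_positions(layout$start[i], layout$end[i], layout$strand[i], glen)
      if (layout$strand[i] == "-") {
        chars[p] <- comp_base(coding)
      } else {
        chars[p] <- coding
      }
    }
    mt_reference(
      sequence = paste(chars, collapse = ""),
      features = layout[, c("name", "kind", "start", "end", "strand")],
      name = "toyM"
    )
  })
}

## ---- plain-text writers (fixtures, synthetic cohorts) ----

write_reference_fasta <- function(ref, path, width = 70L) {
  starts <- seq(1L, ref$length, by = width)
  lines <- substring(ref$sequence, starts, pmin(starts + width - 1L, ref$length))
  readr::write_lines(c(paste0(">", ref$name), lines), path)
  invisible(path)
}

write_reference_gff <- function(ref, path) {
  f <- ref$features
  rows <- sprintf(
    "%s\tmitospectr\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
    ref$name, f$kind, f$start, f$end, f$strand, f$name, f$name
  )
  readr::write_lines(c("##gff-version 3", rows), path)
  invisible(path)
}

write_reference_bed <- function(ref, path) {
  f <- ref$features
  rows <- sprintf(
    "%s\t%d\t%d\t%s\t0\t%s\t%s",
    ref$name, f$start - 1L, f$end, f$name, f$strand, f$kind
  )
  readr::write_lines(rows, path)
  invisible(path)
}
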