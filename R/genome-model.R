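REGION_KINDS <- c("CDS", "tRNA", "rRNA", "D-loop")

#' Vertebrate mitochondrial genetic code
#'
#' Returns the 64-codon vertebrate mitochondrial genetic code (NCBI
#' translation table 2) as a named character vector mapping codons
#' (e.g. `"TGA"`) to single-letter amino acids, with `"*"` for stop.
#' Under this code `TGA` encodes tryptophan, `ATA` methionine, and
#' `AGA`/`AGG` are stops.
#'
#' @return Named character vector of length 64.
#' @export
#' @examples
#' mt_codon_table()[["TGA"]]
mt_codon_table <- function() {
  Biostrings::getGeneticCode("2")
}

#' Amino-acid property scheme
#'
#' Side-chain property classes used to summarise how missense and nonsense
#' mutations alter protein chemistry. Each amino acid (and stop, `"*"`)
#' belongs to exactly one of five classes: hydrophobic, hydrophilic,
#' acidic, basic, or stop. The default assignment can be overridden by
#' supplying a complete named vector wherever a `property_map` argument is
#' accepted.
#'
#' @return Named character vector mapping one-letter amino-acid codes
#'   (plus `"*"`) to a property class.
#' @export
#' @examples
#' mt_property_map()[["D"]]
mt_property_map <- function() {
  c(
    A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
    I = "hydrophobic", P = "hydrophobic", F = "hydrophobic",
    M = "hydrophobic", W = "hydrophobic", G = "hydrophobic",
    S = "hydrophilic", T = "hydrophilic", C = "hydrophilic",
    Y = "hydrophilic", N = "hydrophilic", Q = "hydrophilic",
    D = "acidic", E = "acidic",
    K = "basic", R = "basic", H = "basic",
    `*` = "stop"
  )
}

#' Translate codons under the vertebrate mitochondrial code
#'
#' @param codon Character vector of 3-mers over `{A,C,G,T}`.
#' @return Character vector of one-letter amino acids (`"*"` = stop).
#' @export
#' @examples
#' translate_mt(c("TGA", "ATA", "AGA"))
translate_mt <- function(codon) {
  codon <- toupper(codon)
  bad <- is.na(codon) | !grepl("^[ACGT]{3}$", codon)
  if (any(bad)) {
    abort(sprintf(
      "codons must be 3-mers over {A,C,G,T}; offending: %s",
      paste(unique(codon[bad]), collapse = ", ")
    ))
  }
  unname(mt_codon_table()[codon])
}

#' Look up amino-acid property class
#'
#' @param aa Character vector of one-letter amino-acid codes or `"*"`.
#' @param property_map Named character vector; defaults to
#'   [mt_property_map()].
#' @return Character vector of property classes.
#' @export
#' @examples
#' aa_property(c("D", "K", "*"))
aa_property <- function(aa, property_map = mt_property_map()) {
  aa <- toupper(aa)
  bad <- is.na(aa) | !aa %in% names(property_map)
  if (any(bad)) {
    abort(sprintf(
      "unknown amino-acid code(s): %s",
      paste(unique(aa[bad]), collapse = ", ")
    ))
  }
  unname(property_map[aa])
}

comp_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

revcomp <- function(x) {
  vapply(
    strsplit(comp_base(x), "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  )
}

## Reference positions covered by a (possibly origin-wrapping) feature,
## in reference order; `start > end` wraps through position `glen`.
feature_ref_positions <- function(start, end, glen) {
  if (start <= end) seq.int(start, end) else c(seq.int(start, glen), seq.int(1L, end))
}

## Same positions in coding (5'->3') order for the feature's strand.
feature_coding_positions <- function(start, end, strand, glen) {
  p <- feature_ref_positions(start, end, glen)
  if (strand == "+") p else rev(p)
}

validate_features <- function(features, glen) {
  features <- as_tibble(features)
  required <- c("name", "kind", "start", "end", "strand")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols) > 0) {
    abort(sprintf("features table lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (!"reading_frame_origin" %in% names(features)) {
    features$reading_frame_origin <- NA_integer_
  }
  bad_kind <- !features$kind %in% REGION_KINDS
  if (any(bad_kind)) {
    i <- which(bad_kind)[1]
    abort(sprintf(
      "feature '%s' (row %d) has unknown kind '%s'; expected one of %s",
      features$name[i], i, features$kind[i], paste(REGION_KINDS, collapse = ", ")
    ))
  }
  bad_strand <- !features$strand %in% c("+", "-")
  if (any(bad_strand)) {
    i <- which(bad_strand)[1]
    abort(sprintf("feature '%s' has invalid strand '%s'", features$name[i], features$strand[i]))
  }
  oob <- features$start < 1 | features$start > glen | features$end < 1 | features$end > glen
  if (any(oob)) {
    i <- which(oob)[1]
    abort(sprintf(
      "feature '%s' [%d, %d] lies outside the %d-bp genome",
      features$name[i], features$start[i], features$end[i], glen
    ))
  }
  features
}

## Per-position lookup tables: region label (with CDS > tRNA > rRNA > D-loop
## precedence), and for CDS positions the codon frame on the coding strand.
build_position_index <- function(sequence_chars, features, glen) {
  region <- rep("intergenic", glen)
  covered_twice <- rep(FALSE, glen)
  seen <- rep(FALSE, glen)
  ## paint lowest-precedence first so higher precedence overwrites
  for (kind in rev(REGION_KINDS)) {
    rows <- which(features$kind == kind)
    for (i in rows) {
      p <- feature_ref_positions(features$start[i], features$end[i], glen)
      covered_twice[p[seen[p]]] <- TRUE
      seen[p] <- TRUE
      region[p] <- kind
    }
  }

  gene <- rep(NA_character_, glen)
  strand <- rep(NA_character_, glen)
  codon_position <- rep(NA_integer_, glen)
  codon_p1 <- rep(NA_integer_, glen)
  codon_p2 <- rep(NA_integer_, glen)
  codon_p3 <- rep(NA_integer_, glen)
  incomplete_codon <- rep(FALSE, glen)

  cds_rows <- which(features$kind == "CDS")
  for (i in cds_rows) {
    cp <- feature_coding_positions(features$start[i], features$end[i], features$strand[i], glen)
    origin <- features$reading_frame_origin[i]
    if (!is.na(origin)) {
      k <- match(origin, cp)
      if (is.na(k)) {
        abort(sprintf(
          "reading_frame_origin %d of CDS '%s' is not inside the feature",
          origin, features$name[i]
        ))
      }
      cp <- cp[k:length(cp)]
    }
    fresh <- is.na(gene[cp]) # first CDS wins on (degenerate) CDS/CDS overlap
    n_complete <- length(cp) %/% 3L
    idx <- seq_along(cp)
    in_frame <- idx <= 3L * n_complete
    gene[cp[fresh]] <- features$name[i]
    strand[cp[fresh]] <- features$strand[i]
    sel <- fresh & in_frame
    codon_position[cp[sel]] <- ((idx[sel] - 1L) %% 3L) + 1L
    codon_id <- ((idx - 1L) %/% 3L) + 1L
    codon_p1[cp[sel]] <- cp[3L * (codon_id[sel] - 1L) + 1L]
    codon_p2[cp[sel]] <- cp[3L * (codon_id[sel] - 1L) + 2L]
    codon_p3[cp[sel]] <- cp[3L * codon_id[sel]]
    incomplete_codon[cp[fresh & !in_frame]] <- TRUE
  }

  list(
    region = region, gene = gene, strand = strand,
    codon_position = codon_position,
    codon_p1 = codon_p1, codon_p2 = codon_p2, codon_p3 = codon_p3,
    incomplete_codon = incomplete_codon,
    overlap = covered_twice
  )
}

#' Construct a circular mitochondrial reference
#'
#' Builds the reference object used throughout the package: the L-strand
#' sequence (the strand reported by the VCF/reference), a stranded feature
#' table, and precomputed per-position region and codon-frame lookups.
#' Position arithmetic is circular; a feature with `start > end` wraps the
#' origin. Where degenerate annotations overlap, region labels follow the
#' precedence CDS > tRNA > rRNA > D-loop (flagged in `index$overlap`).
#'
#' @param sequence Nucleotide string over `{A,C,G,T}` (L-strand).
#' @param features Data frame with columns `name`, `kind` (one of CDS,
#'   tRNA, rRNA, D-loop), `start`, `end` (1-based inclusive), `strand`
#'   (`+` = reference/L-strand), and optionally `reading_frame_origin`
#'   (first base of the first codon, on the coding strand; defaults to the
#'   feature's 5' end). CDS whose length is not a multiple of three have
#'   their trailing partial codon excluded from codon annotation (mouse
#'   mtDNA genes completed by polyadenylation behave this way).
#' @param name Contig identifier.
#' @return An object of class `mt_reference`: a list with elements `name`,
#'   `sequence`, `length`, `features` (tibble), and `index` (per-position
#'   lookups).
#' @export
#' @examples
#' ref <- mt_reference("AGCTTAGCATTAGCCA",
#'   features = data.frame(
#'     name = "toy1", kind = "CDS", start = 1, end = 12, strand = "+"
#'   )
#' )
#' region_of(ref, c(5, 14))
mt_reference <- function(sequence, features, name = "chrM") {
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) {
    abort("reference sequence contains characters outside {A,C,G,T}")
  }
  glen <- nchar(sequence)
  if (glen < 3) abort("reference sequence is implausibly short")
  features <- validate_features(features, glen)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  structure(
    list(
      name = name,
      sequence = sequence,
      length = glen,
      features = features,
      index = build_position_index(chars, features, glen),
      chars = chars
    ),
    class = "mt_reference"
  )
}

#' @export
print.mt_reference <- function(x, ...) {
  cat(sprintf(
    "<mt_reference> %s: %d bp, %d features (%s)\n",
    x$name, x$length, nrow(x$features),
    paste(sprintf("%s: %d", REGION_KINDS, tabulate(factor(x$features$kind, REGION_KINDS), 4)),
      collapse = ", "
    )
  ))
  invisible(x)
}

parse_gff_attr <- function(attr) {
  for (key in c("Name=", "ID=", "gene=")) {
    hit <- regmatches(attr, regexpr(paste0(key, "[^;]+"), attr))
    if (length(hit) == 1 && nzchar(hit)) {
      return(sub(key, "", hit, fixed = TRUE))
    }
  }
  attr
}

read_annotation_gff <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 8)
  if (length(bad) > 0) {
    abort(sprintf("malformed GFF row %d: fewer than 8 tab-separated fields", bad[1]))
  }
  tibble(
    name = vapply(fields, function(f) if (length(f) >= 9) parse_gff_attr(f[9]) else f[3], character(1)),
    kind = vapply(fields, `[`, character(1), 3),
    start = as.integer(vapply(fields, `[`, character(1), 4)),
    end = as.integer(vapply(fields, `[`, character(1), 5)),
    strand = vapply(fields, `[`, character(1), 7)
  )
}

read_annotation_bed <- function(path) {
  tab <- readr::read_tsv(path,
    col_names = FALSE, comment = "#",
    show_col_types = FALSE, progress = FALSE
  )
  if (ncol(tab) < 7) {
    abort("BED-like annotation needs 7 columns: chrom start end name score strand kind")
  }
  tibble(
    name = as.character(tab[[4]]),
    kind = as.character(tab[[7]]),
    start = as.integer(tab[[2]]) + 1L, # 0-based half-open -> 1-based inclusive
    end = as.integer(tab[[3]]),
    strand = as.character(tab[[6]])
  )
}

#' Load a mitochondrial reference from FASTA + annotation files
#'
#' Reads a single-record FASTA and a feature annotation, and returns a
#' validated [mt_reference()]. The annotation dialect is chosen by file
#' extension: `.gff`/`.gff3`/`.gtf` are treated as 1-based inclusive
#' (column 3 = kind, feature name parsed from `Name=`/`ID=`/`gene=`
#' attributes); `.bed` is 0-based half-open with columns
#' `chrom start end name score strand kind` and is converted on read.
#'
#' @param fasta_path Path to a single-record FASTA file.
#' @param annotation_path Path to a GFF- or BED-style annotation.
#' @return An `mt_reference`.
#' @export
load_reference <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1) {
    abort(sprintf("expected a single-record FASTA, found %d records", length(seqs)))
  }
  ext <- tolower(tools::file_ext(annotation_path))
  features <- switch(ext,
    gff = ,
    gff3 = ,
    gtf = read_annotation_gff(annotation_path),
    bed = read_annotation_bed(annotation_path),
    abort(sprintf("unrecognised annotation extension '.%s' (use .gff/.gff3/.gtf or .bed)", ext))
  )
  mt_reference(
    sequence = as.character(seqs[[1]]),
    features = features,
    name = sub("\\s.*$", "", names(seqs)[1])
  )
}

check_positions <- function(ref, pos) {
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > ref$length)) {
    abort(sprintf("position(s) outside [1, %d]", ref$length))
  }
  pos
}

#' Region label of genome positions
#'
#' Returns the region class (CDS, tRNA, rRNA, D-loop, or intergenic for
#' positions covered by no feature) containing each position, with
#' overlaps resolved by the precedence CDS > tRNA > rRNA > D-loop.
#'
#' @param ref An [mt_reference()].
#' @param pos Integer vector of 1-based positions.
#' @return Character vector of region labels, same length as `pos`.
#' @export
region_of <- function(ref, pos) {
  stopifnot(inherits(ref, "mt_reference"))
  pos <- check_positions(ref, pos)
  ref$index$region[pos]
}

#' Region lengths of a reference
#'
#' Summed feature length per region class (circular-aware), plus the
#' remaining intergenic length. Because region labels follow the overlap
#' precedence, lengths are counted per position, so they always sum to the
#' genome length.
#'
#' @param ref An [mt_reference()].
#' @return Named numeric vector over CDS, tRNA, rRNA, D-loop, intergenic.
#' @export
region_lengths <- function(ref) {
  tab <- table(factor(ref$index$region, levels = c(REGION_KINDS, "intergenic")))
  stats::setNames(as.numeric(tab), names(tab))
}

#' Codon context of CDS positions
#'
#' For each position inside a protein-coding feature, returns the codon it
#' belongs to read on the coding strand (reverse complement of the
#' reference slice for minus-strand genes), the 1-based offset of the
#' position within that codon, and the gene. Positions in an incomplete
#' terminal codon get `NA` codon fields and are flagged.
#'
#' @param ref An [mt_reference()].
#' @param pos Integer vector of 1-based positions; all must lie in a CDS.
#' @return Tibble with columns `pos`, `gene`, `strand`, `codon`,
#'   `codon_position`, `incomplete_codon`.
#' @export
codon_context <- function(ref, pos) {
  stopifnot(inherits(ref, "mt_reference"))
  pos <- check_positions(ref, pos)
  not_cds <- ref$index$region[pos] != "CDS"
  if (any(not_cds)) {
    abort(sprintf(
      "position(s) not in a CDS: %s",
      paste(head(pos[not_cds], 5), collapse = ", ")
    ))
  }
  idx <- ref$index
  codon <- rep(NA_character_, length(pos))
  complete <- !is.na(idx$codon_position[pos])
  if (any(complete)) {
    p <- pos[complete]
    b1 <- ref$chars[idx$codon_p1[p]]
    b2 <- ref$chars[idx$codon_p2[p]]
    b3 <- ref$chars[idx$codon_p3[p]]
    minus <- idx$strand[p] == "-"
    b1[minus] <- comp_base(b1[minus])
    b2[minus] <- comp_base(b2[minus])
    b3[minus] <- comp_base(b3[minus])
    codon[complete] <- paste0(b1, b2, b3)
  }
  tibble(
    pos = pos,
    gene = idx$gene[pos],
    strand = idx$strand[pos],
    codon = codon,
    codon_position = idx$codon_position[pos],
    incomplete_codon = idx$incomplete_codon[pos]
  )
}

#' Reference base at genome positions
#'
#' @param ref An [mt_reference()].
#' @param pos Integer vector of 1-based positions.
#' @return Character vector of reference (L-strand) bases.
#' @export
ref_base <- function(ref, pos) {
  stopifnot(inherits(ref, "mt_reference"))
  ref$chars[check_positions(ref, pos)]
}
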