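## Hand-built 40-bp reference exercising every region kind and both CDS
## strands. geneP (+, 1-12) codes ATG ACC GAT TTA; geneM (-, 32-40) codes
## ATG CCC TAT on its coding strand (reference slice holds the reverse
## complement ATAGGGCAT).
tiny_ref <- function() {
  mt_reference(
    sequence = paste0(
      "ATGACCGATTTA", # 1-12  CDS +
      "G", # 13    intergenic
      "CCC", # 14-16 tRNA
      "AAGGTT", # 17-22 rRNA
      "A", # 23    intergenic
      "CCCCAAAA", # 24-31 D-loop
      "ATAGGGCAT" # 32-40 CDS -
    ),
    features = data.frame(
      name = c("geneP", "trnX", "rrnS", "dloop", "geneM"),
      kind = c("CDS", "tRNA", "rRNA", "D-loop", "CDS"),
      start = c(1L, 14L, 17L, 24L, 32L),
      end = c(12L, 16L, 22L, 31L, 40L),
      strand = c("+", "+", "+", "+", "-")
    ),
    name = "tiny"
  )
}

## 16-bp genome whose single CDS wraps the circular origin (+ strand,
## starts at 14, runs through 16 and on to 7: ten bases, three complete
## codons plus one incomplete terminal base).
wrap_ref <- function() {
  mt_reference(
    sequence = "ACGTTTGGAAACCATG",
    features = data.frame(
      name = "wrapCDS", kind = "CDS", start = 14L, end = 7L, strand = "+"
    ),
    name = "wrap"
  )
}

## ---- independent oracles ----

## Brute-force circular containment: positions of a feature enumerated
## one step at a time, wrapping modulo the genome length.
oracle_feature_positions <- function(start, end, glen) {
  p <- start
  out <- p
  while (p != end) {
    p <- if (p == glen) 1L else p + 1L
    out <- c(out, p)
  }
  out
}

## Whole-gene translation oracle: extract the full gene on its coding
## strand with Biostrings and translate codon by codon.
oracle_gene_protein <- function(ref, feature_name, mutate_pos = NULL, mutate_alt = NULL) {
  f <- ref$features[ref$features$name == feature_name, ]
  p <- oracle_feature_positions(f$start, f$end, ref$length)
  chars <- ref$chars
  if (!is.null(mutate_pos)) chars[mutate_pos] <- mutate_alt
  gene <- paste(chars[p], collapse = "")
  if (f$strand == "-") {
    gene <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(gene)))
  }
  n_codons <- nchar(gene) %/% 3
  codons <- substring(gene, 3 * seq_len(n_codons) - 2, 3 * seq_len(n_codons))
  unname(Biostrings::getGeneticCode("2")[codons])
}

## Effect of one SNV by re-translating the whole mutated gene.
oracle_effect <- function(ref, feature_name, pos, alt) {
  aa_ref <- oracle_gene_protein(ref, feature_name)
  aa_alt <- oracle_gene_protein(ref, feature_name, mutate_pos = pos, mutate_alt = alt)
  changed <- which(aa_ref != aa_alt)
  if (length(changed) == 0) {
    return("silent")
  }
  if (aa_alt[changed[1]] == "*" && aa_ref[changed[1]] != "*") {
    return("nonsense")
  }
  "missense"
}

## Naive per-base metric oracles.
oracle_count <- function(pos, glen) {
  hit <- rep(FALSE, glen)
  for (p in pos) hit[p] <- TRUE
  sum(hit) / glen
}

oracle_frequency <- function(pos, af, glen) {
  acc <- rep(0, glen)
  for (i in seq_along(pos)) acc[pos[i]] <- acc[pos[i]] + af[i]
  sum(acc) / glen
}

## Naive circular windowed mean with the package's centring convention
## (floor((w-1)/2) behind, the rest ahead).
oracle_roll <- function(x, w) {
  n <- length(x)
  back <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    idx <- ((i - back - 1L):(i - back + w - 2L)) %% n + 1L
    mean(x[idx])
  }, numeric(1))
}

## Small fast cohort for structural tests.
small_config <- function(seed = 7L, ...) {
  sim_config(
    seed = seed, n_animals = 3L, n_germline = 10L,
    n_somatic = c(brain = 8L, liver = 15L), ...
  )
}
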