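#' Mutation count metric
#'
#' Number of bases where a mutation was detected, divided by the
#' applicable length: two different alternate alleles at one base count as
#' one mutated base. `by_allele = TRUE` switches to counting unique
#' (position, alt) variants instead; when the two conventions disagree on
#' a table the difference is reported via a message.
#'
#' @param variants Tibble with a `pos` column (and `alt_allele` when
#'   `by_allele = TRUE`); typically one sample's calls.
#' @param length Applicable length in bp (genome or region length).
#' @param by_allele Count unique (pos, alt) pairs instead of unique bases.
#' @return Scalar count metric.
#' @export
#' @examples
#' mutation_count(data.frame(pos = c(5, 5, 9)), length = 100)
mutation_count <- function(variants, length, by_allele = FALSE) {
  if (length <= 0) abort("length must be positive")
  if (nrow(variants) == 0) {
    return(0)
  }
  n_bases <- dplyr::n_distinct(variants$pos)
  if (by_allele) {
    n <- nrow(dplyr::distinct(variants, .data$pos, .data$alt_allele))
    if (n != n_bases) {
      message(sprintf(
        "allele-level count differs from base-level count (%d vs %d)", n, n_bases
      ))
    }
  } else {
    n <- n_bases
  }
  n / length
}

#' Mutation frequency metric
#'
#' Summed allele fractions over all variants, divided by the applicable
#' length — a measure of mutation saturation. With every allele fraction
#' equal to 1 and one variant per base it equals the count metric.
#'
#' @param variants Tibble with an `allele_fraction` column.
#' @param length Applicable length in bp.
#' @return Scalar frequency metric.
#' @export
#' @examples
#' mutation_frequency(data.frame(allele_fraction = 0.5), length = 4)
mutation_frequency <- function(variants, length) {
  if (length <= 0) abort("length must be positive")
  if (nrow(variants) == 0) {
    return(0)
  }
  sum(variants$allele_fraction) / length
}

sample_keys_present <- function(variants) {
  intersect(c("animal_id", "tissue", "inheritance"), names(variants))
}

## Shared engine: per-sample, per-group count/frequency with a
## group-specific denominator.
summarise_metrics <- function(variants, group_col, levels, denominators,
                              sample_keys, by_allele = FALSE) {
  grid <- tidyr::expand_grid(
    dplyr::distinct(variants[, sample_keys, drop = FALSE]),
    !!group_col := levels
  )
  if (nrow(variants) == 0) {
    out <- grid[0, , drop = FALSE]
    out$count_metric <- double(0)
    out$frequency_metric <- double(0)
    out$n_variants <- integer(0)
    class(out) <- c("mt_spectrum_summary", class(out))
    attr(out, "grouping") <- group_col
    return(out)
  }
  got <- variants |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(sample_keys, group_col)))) |>
    dplyr::summarise(
      count_metric = mutation_count(
        dplyr::pick(dplyr::everything()),
        denominators[[as.character(dplyr::cur_group()[[group_col]])]],
        by_allele = by_allele
      ),
      frequency_metric = mutation_frequency(
        dplyr::pick(dplyr::everything()),
        denominators[[as.character(dplyr::cur_group()[[group_col]])]]
      ),
      n_variants = dplyr::n(),
      .groups = "drop"
    )
  out <- grid |>
    dplyr::left_join(got, by = c(sample_keys, group_col)) |>
    dplyr::mutate(
      count_metric = dplyr::coalesce(.data$count_metric, 0),
      frequency_metric = dplyr::coalesce(.data$frequency_metric, 0),
      n_variants = dplyr::coalesce(.data$n_variants, 0L)
    )
  class(out) <- c("mt_spectrum_summary", class(out))
  attr(out, "grouping") <- group_col
  out
}

#' Genome-wide metrics per sample
#'
#' Count and frequency metrics over the whole genome, grouped by whichever
#' of `animal_id`, `tissue`, `inheritance` are present in the table. For
#' germline rows (one per tissue) the count metric should be computed per
#' animal rather than per tissue; drop or ignore the tissue key for that
#' use (the metric deduplicates positions, so identical germline tuples
#' collapse automatically).
#'
#' @param variants Classified variant tibble.
#' @param ref An [mt_reference()].
#' @param by_allele See [mutation_count()].
#' @return Tibble of per-sample `count_metric`, `frequency_metric`,
#'   `n_variants`.
#' @export
genome_metrics <- function(variants, ref, by_allele = FALSE) {
  stopifnot(inherits(ref, "mt_reference"))
  keys <- sample_keys_present(variants)
  variants$.genome <- "genome"
  out <- summarise_metrics(
    variants, ".genome",
    levels = "genome",
    denominators = c(genome = ref$length),
    sample_keys = keys, by_allele = by_allele
  )
  out$.genome <- NULL
  out
}

#' Metrics per genome region
#'
#' Count and frequency per region class (CDS, tRNA, rRNA, D-loop,
#' intergenic), each normalised by the summed length of that region, per
#' sample.
#'
#' @inheritParams genome_metrics
#' @return `mt_spectrum_summary` tibble keyed by sample and `region`.
#' @export
region_metrics <- function(variants, ref, by_allele = FALSE) {
  stopifnot(inherits(ref, "mt_reference"))
  if (!"region" %in% names(variants)) {
    variants$region <- region_of(ref, variants$pos)
  }
  lens <- region_lengths(ref)
  lens <- lens[lens > 0]
  summarise_metrics(
    variants, "region",
    levels = names(lens), denominators = lens,
    sample_keys = sample_keys_present(variants), by_allele = by_allele
  )
}

#' Metrics per codon position
#'
#' Count and frequency of CDS SNVs grouped by codon position 1/2/3. The
#' denominator for each position is the number of complete codons in the
#' reference CDS (one third of the annotatable CDS length); incomplete
#' terminal codons are excluded on both sides of the ratio.
#'
#' @inheritParams genome_metrics
#' @return `mt_spectrum_summary` tibble keyed by sample and
#'   `codon_position`.
#' @export
codon_position_metrics <- function(variants, ref, by_allele = FALSE) {
  stopifnot(inherits(ref, "mt_reference"))
  if (!"codon_position" %in% names(variants)) {
    abort("variants lack codon_position; run annotate_effect()/classify_variants() first")
  }
  n_codons <- sum(!is.na(ref$index$codon_position)) / 3
  cds_snv <- variants |>
    dplyr::filter(!is.na(.data$codon_position))
  summarise_metrics(
    cds_snv, "codon_position",
    levels = c(1L, 2L, 3L),
    denominators = stats::setNames(rep(n_codons, 3), c("1", "2", "3")),
    sample_keys = sample_keys_present(variants), by_allele = by_allele
  )
}

#' Substitution spectrum
#'
#' Counts and metrics of SNVs by substitution category: either the six
#' collapsed classes (a change combined with its reverse complement) or
#' the twelve stranded changes as seen on the reference L-strand. Metrics
#' are normalised by genome length.
#'
#' @inheritParams genome_metrics
#' @param stranded Group by the 12 stranded changes instead of the 6
#'   collapsed classes.
#' @return `mt_spectrum_summary` tibble keyed by sample and
#'   `collapsed_class` (or `stranded`).
#' @export
substitution_spectrum <- function(variants, ref, stranded = FALSE, by_allele = FALSE) {
  stopifnot(inherits(ref, "mt_reference"))
  if (!all(c("stranded", "collapsed_class") %in% names(variants))) {
    abort("variants lack substitution classes; run classify_variants() first")
  }
  snv <- dplyr::filter(variants, !is.na(.data$collapsed_class))
  group_col <- if (stranded) "stranded" else "collapsed_class"
  levels <- if (stranded) names(stranded_to_collapsed()) else COLLAPSED_CLASSES
  summarise_metrics(
    snv, group_col,
    levels = levels,
    denominators = stats::setNames(rep(ref$length, length(levels)), levels),
    sample_keys = sample_keys_present(variants), by_allele = by_allele
  )
}

#' Metrics per codon effect
#'
#' Count and frequency of CDS SNVs grouped by effect (silent, missense,
#' nonsense), normalised by total annotatable CDS length, per sample.
#'
#' @inheritParams genome_metrics
#' @return `mt_spectrum_summary` tibble keyed by sample and `effect`.
#' @export
effect_metrics <- function(variants, ref, by_allele = FALSE) {
  stopifnot(inherits(ref, "mt_reference"))
  if (!"effect" %in% names(variants)) {
    abort("variants lack effect; run annotate_effect()/classify_variants() first")
  }
  cds_len <- sum(!is.na(ref$index$codon_position))
  lv <- c("silent", "missense", "nonsense")
  summarise_metrics(
    dplyr::filter(variants, .data$effect %in% lv), "effect",
    levels = lv,
    denominators = stats::setNames(rep(cds_len, 3), lv),
    sample_keys = sample_keys_present(variants), by_allele = by_allele
  )
}

#' Correct a stranded spectrum for nucleotide composition
#'
#' The reference L-strand carries roughly twice as many cytosines as
#' guanines, so raw stranded counts confound mutational asymmetry with
#' base availability. Following the depth-based normalisation, the total
#' sequencing depth over reference positions of each nucleotide is
#' summed, and counts of changes from base N are rescaled by
#' `total_depth(C) / total_depth(N)` — cytosine-source changes are
#' unchanged by construction. When no depth profile is available, the
#' documented fallback rescales by depth-unweighted reference base counts.
#'
#' @param spectrum Stranded `mt_spectrum_summary`
#'   (`substitution_spectrum(..., stranded = TRUE)`).
#' @param depth An `mt_depth` profile, a named A/C/G/T totals vector, or
#'   `NULL` to fall back to reference base composition.
#' @param ref Required for the composition fallback.
#' @return `spectrum` with added columns `source_base`,
#'   `correction_factor`, `corrected_n`, `corrected_count_metric`.
#' @export
strand_bias_correction <- function(spectrum, depth = NULL, ref = NULL) {
  if (!"stranded" %in% names(spectrum)) {
    abort("spectrum must be stranded; use substitution_spectrum(stranded = TRUE)")
  }
  totals <- if (inherits(depth, "mt_depth")) {
    depth$nucleotide_totals
  } else if (is.numeric(depth) && all(c("A", "C", "G", "T") %in% names(depth))) {
    depth
  } else if (is.null(depth)) {
    if (is.null(ref)) abort("with no depth profile, supply ref for the composition fallback")
    vapply(c("A", "C", "G", "T"), function(b) sum(ref$chars == b), numeric(1))
  } else {
    abort("depth must be an mt_depth, a named A/C/G/T totals vector, or NULL")
  }
  source_base <- substr(spectrum$stranded, 1, 1)
  needed <- unique(source_base)
  zero <- needed[totals[needed] == 0]
  if (length(zero) > 0) {
    abort(sprintf("zero total depth for nucleotide(s): %s", paste(zero, collapse = ", ")))
  }
  factor <- unname(totals[["C"]] / totals[source_base])
  out <- spectrum
  out$source_base <- source_base
  out$correction_factor <- factor
  out$corrected_n <- out$n_variants * factor
  out$corrected_count_metric <- out$count_metric * factor
  out
}

## Circular rolling mean: window of width w centred on each position
## (floor((w-1)/2) positions behind, the rest ahead), wrapping the origin.
roll_mean_circular <- function(x, w) {
  n <- length(x)
  w <- as.integer(w)
  if (w < 1) abort("window must be >= 1")
  if (w > n) abort("window longer than the sequence")
  back <- (w - 1L) %/% 2L
  fwd <- w - 1L - back
  head_pad <- if (back > 0) x[(n - back + 1L):n] else numeric(0)
  tail_pad <- if (fwd > 0) x[1:fwd] else numeric(0)
  cs <- cumsum(c(0, head_pad, x, tail_pad))
  (cs[(1:n) + w] - cs[1:n]) / w
}

#' Rolling genome scan of mutation signal
#'
#' Per-position mutation frequency (mean allele fraction over variants at
#' that base, 0 where none — frequencies are averaged when more than one
#' mutation occupies one base pair) and a mutated-base indicator, smoothed
#' with a circular rolling mean (default 250 bp, wrapping the origin of
#' the circular genome) and normalised by each track's maximum so both
#' lie in \[0, 1\].
#'
#' @param variants Tibble with `pos` and `allele_fraction`; typically
#'   pooled over samples.
#' @param ref An [mt_reference()].
#' @param window_bp Rolling window width in bp.
#' @return `mt_genome_scan` tibble with columns `pos`, `frequency`,
#'   `count`, `roll_frequency`, `roll_count`, `norm_frequency`,
#'   `norm_count`.
#' @export
genome_scan <- function(variants, ref, window_bp = 250L) {
  stopifnot(inherits(ref, "mt_reference"))
  if (window_bp < 1) abort("window_bp must be >= 1")
  freq <- rep(0, ref$length)
  cnt <- rep(0, ref$length)
  if (nrow(variants) > 0) {
    pos <- check_positions(ref, variants$pos)
    per_base <- tibble(pos = pos, af = variants$allele_fraction) |>
      dplyr::group_by(.data$pos) |>
      dplyr::summarise(af = mean(.data$af), .groups = "drop")
    freq[per_base$pos] <- per_base$af
    cnt[unique(pos)] <- 1
  }
  roll_f <- roll_mean_circular(freq, window_bp)
  roll_c <- roll_mean_circular(cnt, window_bp)
  norm <- function(x) if (max(x) > 0) x / max(x) else x
  out <- tibble(
    pos = seq_len(ref$length),
    frequency = freq, count = cnt,
    roll_frequency = roll_f, roll_count = roll_c,
    norm_frequency = norm(roll_f), norm_count = norm(roll_c)
  )
  class(out) <- c("mt_genome_scan", class(out))
  attr(out, "window_bp") <- window_bp
  out
}

#' Write a genome-scan track as BedGraph-style text
#'
#' Four-column (contig, 0-based start, end, value) text of one scan track.
#'
#' @param scan An `mt_genome_scan`.
#' @param path Output path.
#' @param track Which column to write.
#' @param contig Contig name for column 1.
#' @return `path`, invisibly.
#' @export
write_scan_bedgraph <- function(scan, path, track = "norm_frequency", contig = "chrM") {
  if (!track %in% names(scan)) abort(sprintf("unknown track '%s'", track))
  readr::write_lines(
    sprintf("%s\t%d\t%d\t%g", contig, scan$pos - 1L, scan$pos, scan[[track]]),
    path
  )
  invisible(path)
}
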