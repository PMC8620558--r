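---
title: "Quantifying heteroplasmic mtDNA mutation spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying heteroplasmic mtDNA mutation spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitospectr)
library(dplyr)
```

## The analysis model

`mitospectr` analyses heteroplasmic mitochondrial variant calls from a
paired-tissue design: each animal contributes one call set per tissue
(brain and liver in the motivating design), and each call carries a
position, a ref/alt pair, and an allele fraction — the fraction of reads
supporting the variant at that site. The package deliberately begins
*after* variant calling: alignment and calling are upstream concerns, and
the operational definitions below are agnostic to the caller as long as
allele fractions (AF) or allelic depths (AD) are available.

Three definitions carry the whole analysis:

* **Germline vs somatic.** A variant is germline when the identical
  (position, ref, alt) tuple is called in both tissues of one animal;
  anything else is somatic. This is an operational definition: a mutation
  present in both tissues was most plausibly inherited through the
  zygote, though a recurrent early mutation can masquerade as germline.
  No correction is applied for that, and no allele-fraction similarity
  between tissues is required — detection thresholds belong to the
  caller. Germline variants keep one row per tissue so that tissue-level
  frequency remains computable; the count metric cannot separate tissues
  for germline mutations (the deduplication over positions makes the two
  tissue rows one mutated base).

* **Mutation count** = distinct mutated bases / applicable length. Two
  alternate alleles at one base are one mutated base. A configuration
  switch (`by_allele = TRUE`) counts unique (position, alt) variants
  instead, and reports when the two conventions disagree.

* **Mutation frequency** = summed allele fractions / applicable length.
  With every AF equal to 1 and one variant per base, frequency equals
  count; in general frequency is a saturation measure.

"Applicable length" is the genome length for genome-wide metrics, the
summed feature length for per-region metrics, and one third of the
annotatable CDS length for per-codon-position metrics. Whether the
genome-wide denominator should exclude the D-loop is not something the
definitions force; we use the full genome length throughout.

## Genome model

The reference is circular: all position arithmetic wraps, features may
span the origin (`start > end`), and rolling-window scans wrap too. The
reference sequence is the L-strand — the strand that VCF coordinates and
alleles refer to. Regions come in four annotated classes (CDS, tRNA,
rRNA, D-loop) plus intergenic; in the degenerate case of overlapping
annotations a position takes the class of precedence CDS > tRNA > rRNA >
D-loop, and the overlap is flagged in the position index. Real mouse
mtDNA features are essentially non-overlapping (the small ATP8/ATP6 and
ND4L/ND4 overlaps being the exceptions), so the precedence rule guards
rare corner cases rather than driving results.

Codon effects use the vertebrate mitochondrial genetic code
(transl_table 2; TGA=Trp, ATA=Met, AGA/AGG=stop), reading codons on the
gene's coding strand: for minus-strand genes the reference slice is
reverse-complemented and the alternate base complemented before
substitution. Genes whose length is not a multiple of three (real mouse
mtDNA genes completed by post-transcriptional polyadenylation) have the
trailing partial codon excluded from codon annotation; affected variants
are reported and carry `NA` effects. Loss of a reference stop codon is
counted as missense, and stop gains as nonsense; the amino-acid property
scheme (hydrophobic = A,V,L,I,P,F,M,W,G; hydrophilic = S,T,C,Y,N,Q;
acidic = D,E; basic = K,R,H; stop = \*) is packaged as data and
overridable, since property partitions vary across the literature.

## Substitution classes and strand correction

Double-stranded sequencing cannot distinguish a change from its reverse
complement, so the 12 stranded changes collapse 2-to-1 into 6 classes.
The stranded representation is kept because strand asymmetry is itself a
question of interest: the L-strand carries roughly twice as many
cytosines as guanines, so raw C>T counts exceed raw G>A counts even for
a mutational process with no strand preference. The correction
multiplies the count of changes from base N by
`total_depth(C) / total_depth(N)`, where the totals sum per-base
sequencing depth over reference positions of each nucleotide — cytosine
is the anchor, with factor exactly 1. When no depth profile is
available, depth-unweighted reference base counts are the documented
fallback (identical under uniform depth). Zero total depth for a needed
base is an error naming the base.

## Rolling genome scans

Per-base signal is the mean allele fraction over variants at that base
(frequencies are averaged when several mutations occupy one base pair)
and a mutated-base indicator. Both tracks are smoothed with a circular
rolling mean — default window 250 bp, centred with `floor((w-1)/2)`
positions behind and the rest ahead — and normalised by each track's
maximum so they lie in [0, 1]; an all-zero track stays zero rather than
dividing by zero. The rolling mean is cumulative-sum based and is checked
against both a naive windowed-loop oracle and `stats::filter(...,
circular = TRUE)` in the tests.

## Statistical layer

Metric summaries are strongly right-skewed (many animals with small
values, a few large), so responses are cube-root transformed before
linear modelling by convention — the cube root maps zero to zero, needs
no offset, and largely normalises these metrics. Shapiro-Wilk checks are
recorded for the logs but do not gate the transform.

* `paired_tissue_test()` — paired t-test of per-animal tissue totals,
  n−1 df. Degenerate inputs are handled explicitly: identical vectors
  give t = 0, p = 1; a constant non-zero difference (zero-variance
  denominator) is flagged `degenerate` with an infinite statistic rather
  than erroring.
* `fit_mixed()` — linear mixed model with a random intercept per animal
  (`lmerTest`), Satterthwaite degrees of freedom for fixed-effect
  p-values. When the lmerTest machinery cannot process a degenerate fit
  the package falls back to `lme4` with a Wald normal approximation, and
  the method used is recorded in the result. Singular fits (random-effect
  variance estimated at zero) are recorded, not errors; their fixed
  effects coincide with ordinary least squares, a limit the tests verify
  numerically. Interactions are full-factorial with main effects.
  `drop_zero_animals = TRUE` excludes animals with an empty category
  before fitting, the documented row filter used for the hydrophobicity
  models.
* `anova_tukey()` — one-way ANOVA with all pairwise comparisons on the
  studentised-range distribution, reporting both Tukey-adjusted and
  unadjusted p-values from the same pooled fit (the tests check
  agreement with `TukeyHSD` and the two-group reduction F = t²).

## The synthetic cohort generator

The generator emulates the data *structure* a mutator-mouse cohort
produces, at desk scale, so that every pipeline stage has an input with
known truth. Defaults (all `sim_config()` arguments):

| parameter | default | rationale |
|---|---|---|
| `n_animals` | 14 | paired brain/liver per animal |
| `n_germline` | 40 / animal | Poisson mean; shared by both tissues |
| `n_somatic` | brain 30, liver 60 | liver carries roughly twice the somatic burden |
| `spectrum_weights` | C:T/G:A 0.50, T:C/A:G 0.17, C:A/G:T 0.13, T:A/A:T 0.13, T:G/A:C 0.05, C:G/G:C 0.02 | replication-error-dominated spectrum: the C:T/G:A class ~3x the T:C/A:G class, C:G/G:C and T:G/A:C rare |
| `germline_af_dist` | Beta(1.5, 6), mean 0.2 | germline variants ride higher allele fractions |
| `somatic_af_dist` | Beta(1, 12), mean ~0.077 | somatic variants stay low-frequency |
| `dloop_depletion` | 0.21 | per-base mutation probability multiplier in the D-loop |
| `missense_germline_penalty` | 0.5 | probability a candidate germline missense SNV is transmitted |
| `indel_fraction` | 0.15 | indels a minority of calls |
| `indel_length_prob` | 0.55 (geometric) | short indels, mean length ~1.8 bp |
| `deletion_bias` | 0.85 | deletions dominate indels |
| `mean_depth` | 8200 | per-base Poisson depth |

Counts are per-animal Poisson draws by default (`poisson_counts =
FALSE` restores exact counts), giving the between-animal burden
variation real cohorts show. Sites are drawn without replacement within
an animal, so injected inheritance labels coincide exactly with what
tissue pairing recovers; substitution classes are drawn from the
weights, with the stranded direction fixed by the reference base at the
drawn site; germline missense candidates are transmitted with
probability `missense_germline_penalty`, rejected candidates being
redrawn — the source of the inheritance-by-effect interaction the mixed
models detect. The default genome is `toy_mt_reference()`: a
deterministic ~16.4-kb layout whose gene order, strands and approximate
lengths mimic the mouse mitochondrial genome, with simulated sequence
(L-strand-like composition, C ≈ 2G; CDS filled with stop-free random
codons). It carries no real mouse sequence.

What the generator does **not** emulate: read-level error processes and
alignment artefacts (simulation starts at the variant-call level),
linked or recurrent mutations shared across related animals,
region-specific spectra beyond the D-loop multiplier, allele-fraction
correlation between tissues for germline variants, or structural
variants and large multimers. Passing tests therefore validate the
analysis layer's arithmetic and inference on data with the assumed
structure — not the upstream calling pipeline, and not effect sizes of
any real cohort.

A `uniform_site_model` switch replaces the spectrum weights with equal
per-site mutation probability and uniform alternate alleles — the null
under which corrected C>T and G>A counts must agree, used to validate
the strand correction.

## Numerical choices and problem sizes

Oracle-equivalence tests (count/frequency vs naive per-base loops,
rolling means vs windowed loops) assert agreement to 1e-12. Codon-effect
annotation is validated exhaustively: every possible SNV over a plus-
and a minus-strand gene (tiny hand-built genes plus ATP8- and ND6-like
toy genes, ~2,200 substitutions) must match a whole-gene retranslation
oracle. Recovery tests run at cohort scale — 14 animals, ~2,000 variants
— with 3-SD tolerances from the corresponding binomial or delta-method
standard errors; the mixed-model interaction check uses 50 seeded
replicates. The full test suite runs in about a minute, the acceptance
script in about another; these sizes were chosen to keep seeded
tolerances meaningful while staying fast enough to run on every change.

VCF emission writes `GT:AD:AF:DP` with allele fractions printed to 10
significant digits; round-trip tests on allele fractions therefore use a
1e-9 tolerance while positions and alleles round-trip exactly.

## Known limitations

* Germline status is presence-based; allele-fraction-aware pairing (or
  a probabilistic model of recurrence) is out of scope.
* Indels take the region of their VCF anchor base; an indel spanning a
  region boundary is assigned to the anchor's region.
* Overlapping-gene assignment follows the fixed precedence rule; a
  variant in a genuine gene overlap is annotated against one gene only.
* The statistical layer reproduces model *families* (paired t, mixed
  models with animal intercepts, ANOVA/Tukey); it does not attempt to
  reproduce any particular study's printed statistics, which depend on
  the underlying sequencing data.
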