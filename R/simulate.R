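## collapsed class "X:Y/P:Q" = stranded X>Y together with its reverse
## complement P>Q; each class therefore has two source bases, one from
## {C,T} and one from {G,A}.
class_alt_map <- function() {
  lapply(stats::setNames(nm = COLLAPSED_CLASSES), function(cls) {
    halves <- strsplit(strsplit(cls, "/", fixed = TRUE)[[1]], ":", fixed = TRUE)
    stats::setNames(
      c(halves[[1]][2], halves[[2]][2]),
      c(halves[[1]][1], halves[[2]][1])
    )
  })
}

draw_af <- function(dist, n) {
  af <- switch(dist$family,
    beta = rbeta(n, dist$shape1, dist$shape2),
    uniform = runif(n, dist$min, dist$max),
    fixed = rep(dist$value, n),
    abort(sprintf("unknown AF distribution family '%s'", dist$family))
  )
  pmin(pmax(af, 1e-6), 1)
}

check_prob <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("%s must be a single probability in [0, 1]", nm))
  }
  x
}

#' Configuration of a synthetic paired-tissue cohort
#'
#' Bundles every parameter of the cohort generator. The defaults emulate
#' the structure of a mutator-mouse heteroplasmy study at desk scale: 14
#' animals, brain and liver sampled per animal; germline mutations drawn
#' once per animal and present in both tissues while somatic mutations
#' are tissue-private, with liver carrying more somatic mutations than
#' brain; a substitution spectrum dominated by the C:T/G:A transition
#' class (~3x the T:C/A:G class); germline allele fractions about twice
#' somatic ones (Beta(1.5, 6) vs Beta(1, 12)); strong depletion of
#' mutations in the D-loop; reduced germline transmission of missense
#' variants; and indels that are mostly short deletions.
#'
#' @param seed Integer seed; fully determines the cohort.
#' @param n_animals Number of animals.
#' @param genome An [mt_reference()]; default [toy_mt_reference()].
#' @param n_germline Germline variants per animal (shared by both
#'   tissues).
#' @param n_somatic Named integer vector of somatic variants per tissue.
#' @param poisson_counts Treat `n_germline`/`n_somatic` as per-animal
#'   Poisson means rather than exact counts (default), giving the
#'   between-animal burden variation real cohorts show; set `FALSE` for
#'   exact per-animal counts.
#' @param spectrum_weights Named weights over the 6 collapsed classes,
#'   summing to 1.
#' @param germline_af_dist,somatic_af_dist Allele-fraction distribution
#'   specs: `list(family = "beta", shape1, shape2)`, `list(family =
#'   "uniform", min, max)` or `list(family = "fixed", value)`.
#' @param dloop_depletion Multiplier (<= 1) on per-base mutation
#'   probability inside the D-loop.
#' @param missense_germline_penalty Probability that a candidate germline
#'   missense SNV survives transmission (< 1 mirrors purifying germline
#'   selection).
#' @param indel_fraction Fraction of variants drawn as indels.
#' @param indel_length_prob Geometric success probability for indel
#'   length (length = geometric + 1; larger = shorter indels).
#' @param deletion_bias Probability that an indel is a deletion.
#' @param mean_depth Mean per-base sequencing depth (Poisson).
#' @param uniform_site_model If `TRUE`, ignore `spectrum_weights`: every
#'   site is equally likely to mutate and the alternate base is uniform
#'   over the three alternatives (the null used to validate the
#'   strand-asymmetry correction).
#' @return A validated `mt_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_animals = 14L,
                       genome = NULL,
                       n_germline = 40L,
                       n_somatic = c(brain = 30L, liver = 60L),
                       poisson_counts = TRUE,
                       spectrum_weights = c(
                         "C:T/G:A" = 0.50, "T:C/A:G" = 0.17,
                         "C:A/G:T" = 0.13, "T:A/A:T" = 0.13,
                         "C:G/G:C" = 0.02, "T:G/A:C" = 0.05
                       ),
                       germline_af_dist = list(family = "beta", shape1 = 1.5, shape2 = 6),
                       somatic_af_dist = list(family = "beta", shape1 = 1.0, shape2 = 12),
                       dloop_depletion = 0.21,
                       missense_germline_penalty = 0.5,
                       indel_fraction = 0.15,
                       indel_length_prob = 0.55,
                       deletion_bias = 0.85,
                       mean_depth = 8200,
                       uniform_site_model = FALSE) {
  if (!is.null(genome)) stopifnot(inherits(genome, "mt_reference"))
  if (is.null(names(n_somatic)) || any(!nzchar(names(n_somatic)))) {
    abort("n_somatic must be a named vector, e.g. c(brain = 30, liver = 60)")
  }
  if (!setequal(names(spectrum_weights), COLLAPSED_CLASSES)) {
    abort("spectrum_weights must be named by the 6 collapsed classes")
  }
  if (abs(sum(spectrum_weights) - 1) > 1e-9) {
    abort("spectrum_weights must sum to 1")
  }
  check_prob(dloop_depletion, "dloop_depletion")
  check_prob(missense_germline_penalty, "missense_germline_penalty")
  check_prob(indel_fraction, "indel_fraction")
  check_prob(indel_length_prob, "indel_length_prob")
  check_prob(deletion_bias, "deletion_bias")
  structure(
    list(
      seed = as.integer(seed), n_animals = as.integer(n_animals),
      genome = genome, n_germline = as.integer(n_germline),
      n_somatic = n_somatic, poisson_counts = isTRUE(poisson_counts),
      spectrum_weights = spectrum_weights[COLLAPSED_CLASSES],
      germline_af_dist = germline_af_dist, somatic_af_dist = somatic_af_dist,
      dloop_depletion = dloop_depletion,
      missense_germline_penalty = missense_germline_penalty,
      indel_fraction = indel_fraction, indel_length_prob = indel_length_prob,
      deletion_bias = deletion_bias, mean_depth = mean_depth,
      uniform_site_model = uniform_site_model
    ),
    class = "mt_sim_config"
  )
}

## Scalar codon-effect lookup used inside the rejection sampler.
snv_effect_fast <- function(ref, pos, alt, codon_table) {
  idx <- ref$index
  if (idx$region[pos] != "CDS" || is.na(idx$codon_position[pos])) {
    return("noncoding")
  }
  b <- ref$chars[c(idx$codon_p1[pos], idx$codon_p2[pos], idx$codon_p3[pos])]
  if (idx$strand[pos] == "-") {
    b <- comp_base(b)
    alt <- comp_base(alt)
  }
  codon <- paste(b, collapse = "")
  b[idx$codon_position[pos]] <- alt
  alt_codon <- paste(b, collapse = "")
  aa_ref <- codon_table[[codon]]
  aa_alt <- codon_table[[alt_codon]]
  if (aa_ref == aa_alt) {
    "silent"
  } else if (aa_alt == "*" && aa_ref != "*") {
    "nonsense"
  } else {
    "missense"
  }
}

#' Simulate a paired-tissue heteroplasmic cohort
#'
#' Draws a full synthetic cohort under a [sim_config()]: germline variants
#' are drawn once per animal and copied to both tissues with
#' tissue-specific allele fractions; somatic variants are drawn
#' independently per tissue; sites respect the D-loop depletion
#' multiplier; substitution classes follow the spectrum weights, with the
#' stranded direction fixed by the reference base at the chosen site;
#' candidate germline missense SNVs are transmitted only with probability
#' `missense_germline_penalty` (rejected candidates are redrawn). All
#' variant positions are distinct within an animal, so the truth
#' inheritance labels coincide with what tissue pairing recovers.
#'
#' @param config A [sim_config()].
#' @param with_depth Also simulate per-base Poisson depth profiles (one
#'   per animal x tissue); disable for speed in replicate studies.
#' @return An object of class `mt_cohort`: list with `calls` (tidy call
#'   table ready for [classify_variants()]), `truth` (calls plus injected
#'   `true_*` columns), `depth` (named list of `mt_depth`, or `NULL`),
#'   `ref`, and `config`.
#' @export
simulate_cohort <- function(config, with_depth = TRUE) {
  stopifnot(inherits(config, "mt_sim_config"))
  set.seed(config$seed)
  ref <- config$genome %||% toy_mt_reference()
  glen <- ref$length
  codon_table <- mt_codon_table()
  alt_map <- class_alt_map()
  site_w <- ifelse(ref$index$region == "D-loop", config$dloop_depletion, 1)
  pos_by_base <- lapply(
    stats::setNames(nm = c("A", "C", "G", "T")),
    function(b) which(ref$chars == b)
  )
  tissues <- names(config$n_somatic)
  animals <- sprintf("M%02d", seq_len(config$n_animals))

  draw_one <- function(used, germline) {
    repeat {
      if (runif(1) < config$indel_fraction) {
        is_del <- runif(1) < config$deletion_bias
        len <- rgeom(1, config$indel_length_prob) + 1L
        pool <- which(!used & site_w > 0)
        if (is_del) pool <- pool[pool + len <= glen]
        if (length(pool) == 0) abort("requested mutations exceed available sites")
        p <- if (length(pool) == 1) pool else sample(pool, 1, prob = site_w[pool])
        anchor <- ref$chars[p]
        if (is_del) {
          ref_a <- substr(ref$sequence, p, p + len)
          alt_a <- anchor
        } else {
          ref_a <- anchor
          alt_a <- paste0(anchor, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
        }
        return(list(
          pos = p, ref = ref_a, alt = alt_a,
          var_class = if (is_del) "deletion" else "insertion",
          class = NA_character_, effect = NA_character_
        ))
      }
      if (config$uniform_site_model) {
        pool <- which(!used & site_w > 0)
        if (length(pool) == 0) abort("requested mutations exceed available sites")
        p <- if (length(pool) == 1) pool else sample(pool, 1, prob = site_w[pool])
        base <- ref$chars[p]
        alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
        cls <- unname(stranded_to_collapsed()[paste0(base, ">", alt)])
      } else {
        cls <- sample(COLLAPSED_CLASSES, 1, prob = config$spectrum_weights)
        sources <- names(alt_map[[cls]])
        pool <- c(pos_by_base[[sources[1]]], pos_by_base[[sources[2]]])
        pool <- pool[!used[pool] & site_w[pool] > 0]
        if (length(pool) == 0) abort("requested mutations exceed available sites")
        p <- if (length(pool) == 1) pool else sample(pool, 1, prob = site_w[pool])
        base <- ref$chars[p]
        alt <- unname(alt_map[[cls]][base])
      }
      eff <- snv_effect_fast(ref, p, alt, codon_table)
      if (germline && eff == "missense" &&
        runif(1) > config$missense_germline_penalty) {
        next # purifying germline selection: candidate not transmitted
      }
      return(list(
        pos = p, ref = ref$chars[p], alt = alt, var_class = "SNV",
        class = cls, effect = eff
      ))
    }
  }

  draw_n <- function(mean_n) {
    if (config$poisson_counts) rpois(1, mean_n) else as.integer(mean_n)
  }
  rows <- vector("list", config$n_animals)
  for (a in seq_along(animals)) {
    used <- rep(FALSE, glen)
    n_germ <- draw_n(config$n_germline)
    germ <- vector("list", n_germ)
    for (i in seq_len(n_germ)) {
      v <- draw_one(used, germline = TRUE)
      used[v$pos] <- TRUE
      germ[[i]] <- v
    }
    animal_rows <- list()
    if (n_germ > 0) {
      germ_tab <- tibble(
        pos = vapply(germ, `[[`, integer(1), "pos"),
        ref_allele = vapply(germ, `[[`, character(1), "ref"),
        alt_allele = vapply(germ, `[[`, character(1), "alt"),
        var_class = vapply(germ, `[[`, character(1), "var_class"),
        true_class = vapply(germ, `[[`, character(1), "class"),
        true_effect = vapply(germ, `[[`, character(1), "effect")
      )
      for (tis in tissues) {
        t_tab <- germ_tab
        t_tab$tissue <- tis
        t_tab$allele_fraction <- draw_af(config$germline_af_dist, nrow(t_tab))
        t_tab$true_inheritance <- "germline"
        animal_rows <- c(animal_rows, list(t_tab))
      }
    }
    for (tis in tissues) {
      n_som <- draw_n(config$n_somatic[[tis]])
      if (n_som == 0) next
      som <- vector("list", n_som)
      for (i in seq_len(n_som)) {
        v <- draw_one(used, germline = FALSE)
        used[v$pos] <- TRUE
        som[[i]] <- v
      }
      som_tab <- tibble(
        pos = vapply(som, `[[`, integer(1), "pos"),
        ref_allele = vapply(som, `[[`, character(1), "ref"),
        alt_allele = vapply(som, `[[`, character(1), "alt"),
        var_class = vapply(som, `[[`, character(1), "var_class"),
        true_class = vapply(som, `[[`, character(1), "class"),
        true_effect = vapply(som, `[[`, character(1), "effect"),
        tissue = tis,
        allele_fraction = draw_af(config$somatic_af_dist, n_som),
        true_inheritance = "somatic"
      )
      animal_rows <- c(animal_rows, list(som_tab))
    }
    tab <- dplyr::bind_rows(animal_rows)
    tab$animal_id <- animals[a]
    rows[[a]] <- tab
  }
  truth <- dplyr::bind_rows(rows) |>
    dplyr::mutate(true_region = region_of(ref, .data$pos)) |>
    dplyr::arrange(.data$animal_id, .data$tissue, .data$pos) |>
    dplyr::relocate(
      "animal_id", "tissue", "pos", "ref_allele", "alt_allele",
      "allele_fraction", "var_class"
    )

  depth <- NULL
  truth$depth <- NA_integer_
  if (with_depth) {
    depth <- list()
    for (a in animals) {
      for (tis in tissues) {
        d <- rpois(glen, config$mean_depth)
        depth[[paste(a, tis, sep = ".")]] <-
          depth_profile(seq_len(glen), d, ref, animal_id = a, tissue = tis)
        sel <- truth$animal_id == a & truth$tissue == tis
        truth$depth[sel] <- d[truth$pos[sel]]
      }
    }
  }
  calls <- truth[, c(
    "animal_id", "tissue", "pos", "ref_allele", "alt_allele",
    "allele_fraction", "depth", "var_class"
  )]
  structure(
    list(calls = calls, truth = truth, depth = depth, ref = ref, config = config),
    class = "mt_cohort"
  )
}

#' @export
print.mt_cohort <- function(x, ...) {
  cat(sprintf(
    "<mt_cohort> %d animals, %d calls (%d germline rows, %d somatic), seed %d\n",
    x$config$n_animals, nrow(x$calls),
    sum(x$truth$true_inheritance == "germline"),
    sum(x$truth$true_inheritance == "somatic"),
    x$config$seed
  ))
  invisible(x)
}

#' Simulate a wild-type-like null cohort
#'
#' Near-zero mutation burden: per animal and tissue, a small Poisson
#' number of somatic SNVs (no germline component), used to verify that
#' the pipeline reports near-zero metrics and no germline calls on null
#' input. `rate = 0` yields a cohort with no variants at all.
#'
#' @param config A [sim_config()] (its genome, AF distribution and seed
#'   are used).
#' @param rate Poisson mean number of somatic SNVs per sample.
#' @return An `mt_cohort` (without depth profiles).
#' @export
null_cohort <- function(config, rate = 3) {
  stopifnot(inherits(config, "mt_sim_config"))
  set.seed(config$seed + 1L)
  ref <- config$genome %||% toy_mt_reference()
  glen <- ref$length
  tissues <- names(config$n_somatic)
  animals <- sprintf("M%02d", seq_len(config$n_animals))
  rows <- list()
  for (a in animals) {
    used <- rep(FALSE, glen)
    for (tis in tissues) {
      n <- rpois(1, rate)
      if (n == 0) next
      pool <- which(!used)
      p <- sample(pool, n)
      used[p] <- TRUE
      base <- ref$chars[p]
      alt <- vapply(base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      rows[[length(rows) + 1]] <- tibble(
        animal_id = a, tissue = tis, pos = p,
        ref_allele = base, alt_allele = unname(alt),
        allele_fraction = draw_af(config$somatic_af_dist, n),
        depth = NA_integer_, var_class = "SNV",
        true_inheritance = "somatic"
      )
    }
  }
  truth <- if (length(rows) > 0) {
    dplyr::bind_rows(rows) |> dplyr::arrange(.data$animal_id, .data$tissue, .data$pos)
  } else {
    tibble(
      animal_id = character(), tissue = character(), pos = integer(),
      ref_allele = character(), alt_allele = character(),
      allele_fraction = double(), depth = integer(), var_class = character(),
      true_inheritance = character()
    )
  }
  structure(
    list(
      calls = truth[, setdiff(names(truth), "true_inheritance")],
      truth = truth, depth = NULL, ref = ref, config = config
    ),
    class = "mt_cohort"
  )
}

#' Read a simulation configuration from a JSON or YAML file
#'
#' Loads a flat configuration file whose keys are [sim_config()] argument
#' names (distribution specs as nested maps with a `family` key,
#' `n_somatic` and `spectrum_weights` as named maps) and validates it
#' through [sim_config()]. The dialect is chosen by extension
#' (`.json` vs `.yaml`/`.yml`).
#'
#' @param path Path to the configuration file.
#' @return A validated `mt_sim_config`.
#' @export
sim_config_from_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    abort(sprintf("unrecognised config extension '.%s' (use .json or .yaml)", ext))
  )
  unknown <- setdiff(names(raw), names(formals(sim_config)))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (key in c("n_somatic", "spectrum_weights")) {
    if (!is.null(raw[[key]])) raw[[key]] <- unlist(raw[[key]])
  }
  do.call(sim_config, raw)
}
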