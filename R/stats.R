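cube_root <- function(x) sign(x) * abs(x)^(1 / 3)

apply_transform <- function(x, transform) {
  switch(transform,
    cube_root = cube_root(x),
    none = x,
    abort(sprintf("unknown transform '%s'", transform))
  )
}

#' Paired comparison of tissue totals
#'
#' Paired t-test between liver and brain per-animal totals (count or
#' frequency metric). Animals are paired by vector order. The degenerate
#' zero-variance cases are handled explicitly: identical vectors give
#' t = 0, p = 1; a constant non-zero difference is flagged as degenerate
#' (infinite statistic, p = 0) rather than erroring.
#'
#' @param liver,brain Equal-length numeric vectors of per-animal values.
#' @return An object of class `mt_paired_test` with [tidy()] and
#'   [glance()] methods.
#' @export
paired_tissue_test <- function(liver, brain) {
  if (length(liver) != length(brain)) abort("paired vectors must have equal length")
  n <- length(liver)
  if (n < 2) abort("need at least two pairs")
  d <- liver - brain
  degenerate <- stats::sd(d) == 0
  if (degenerate && all(d == 0)) {
    # identical vectors: no difference at all
    statistic <- 0
    p <- 1
    est <- 0
    degenerate <- FALSE
  } else if (degenerate) {
    statistic <- Inf * sign(d[1])
    p <- 0
    est <- mean(d)
  } else {
    tt <- stats::t.test(liver, brain, paired = TRUE)
    statistic <- unname(tt$statistic)
    p <- tt$p.value
    est <- unname(tt$estimate)
  }
  structure(
    list(
      estimate = est, statistic = statistic, df = n - 1, p.value = p,
      n = n, degenerate = degenerate, method = "paired t-test"
    ),
    class = "mt_paired_test"
  )
}

#' @export
print.mt_paired_test <- function(x, ...) {
  cat(sprintf(
    "<mt_paired_test> mean difference %.4g, t(%d) = %.3f, p = %.4g%s\n",
    x$estimate, x$df, x$statistic, x$p.value,
    if (x$degenerate) " [degenerate: zero-variance differences]" else ""
  ))
  invisible(x)
}

#' Linear mixed model on mutation metrics
#'
#' Fits a linear mixed-effects model with a random intercept per animal,
#' the workhorse for comparing metric summaries across factors (e.g.
#' inheritance, effect, region) while accounting for repeated measures
#' within animals. The response is cube-root transformed by default —
#' metric distributions are strongly right-skewed and the cube root
#' largely normalises them while keeping zeros at zero (no offset is
#' added). Fixed-effect p-values use the Satterthwaite degrees-of-freedom
#' approximation. Interactions are included with `interaction = TRUE`
#' (full factorial with main effects). A singular fit (random-effect
#' variance estimated at zero) is recorded, not an error; its fixed
#' effects coincide with ordinary least squares.
#'
#' @param data Long-format tibble, one row per animal x factor cell.
#' @param response Name of the response column (e.g. `"count_metric"`).
#' @param fixed Character vector of fixed-effect column names.
#' @param random Grouping column for the random intercept.
#' @param transform `"cube_root"` (default) or `"none"`.
#' @param interaction Include all interactions among the fixed effects.
#' @param drop_zero_animals Drop animals that have a zero response in any
#'   factor cell before fitting (used for the hydrophobicity models,
#'   where animals with empty categories are excluded).
#' @return An object of class `mt_mixed` wrapping the `lmerModLmerTest`
#'   fit, with [tidy()] and [glance()] methods.
#' @export
fit_mixed <- function(data, response, fixed, random = "animal_id",
                      transform = c("cube_root", "none"),
                      interaction = FALSE, drop_zero_animals = FALSE) {
  transform <- match.arg(transform)
  cols <- c(response, fixed, random)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("data lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (drop_zero_animals) {
    keep <- data |>
      dplyr::group_by(dplyr::across(dplyr::all_of(random))) |>
      dplyr::summarise(all_nonzero = all(.data[[response]] > 0), .groups = "drop") |>
      dplyr::filter(.data$all_nonzero)
    data <- dplyr::semi_join(data, keep, by = random)
  }
  n_animals <- dplyr::n_distinct(data[[random]])
  if (n_animals < 2) abort("need at least two animals")
  data$.y <- apply_transform(data[[response]], transform)
  op <- if (interaction) " * " else " + "
  fml <- stats::as.formula(paste(
    ".y ~", paste(fixed, collapse = op), "+ (1 |", random, ")"
  ))
  quiet_fit <- function(expr) {
    withCallingHandlers(expr, message = function(m) invokeRestart("muffleMessage"))
  }
  ## Satterthwaite df when the lmerTest machinery can handle the fit;
  ## Wald normal approximation as fallback on degenerate fits
  df_method <- "Satterthwaite"
  fit <- tryCatch(
    quiet_fit(lmerTest::lmer(fml, data = data)),
    error = function(e) {
      df_method <<- "Wald"
      quiet_fit(lme4::lmer(fml, data = data))
    }
  )
  singular <- lme4::isSingular(fit)
  structure(
    list(
      fit = fit, response = response, fixed = fixed, random = random,
      transform = transform, interaction = interaction,
      n_animals = n_animals, n_obs = nrow(data),
      singular = singular, df_method = df_method
    ),
    class = "mt_mixed"
  )
}

#' @export
print.mt_mixed <- function(x, ...) {
  cat(sprintf(
    "<mt_mixed> %s(%s) ~ %s + (1 | %s), %d animals, %d rows%s\n",
    x$transform, x$response,
    paste(x$fixed, collapse = if (x$interaction) " * " else " + "),
    x$random, x$n_animals, x$n_obs,
    if (x$singular) " [singular fit: random-effect variance ~ 0]" else ""
  ))
  print(tidy(x))
  invisible(x)
}

#' One-way ANOVA with Tukey post-hoc comparisons
#'
#' Omnibus one-way ANOVA of a value across groups followed by all
#' pairwise comparisons with Tukey honest-significant-difference
#' adjustment (studentised-range distribution on the pooled residual
#' error). Both adjusted and unadjusted pairwise p-values are reported.
#'
#' @param data Long-format tibble.
#' @param response Name of the value column.
#' @param group Name of the grouping column (>= 2 levels, >= 2
#'   observations per level).
#' @param transform `"cube_root"` or `"none"` (default none; metric
#'   responses are usually transformed upstream or here explicitly).
#' @return An object of class `mt_anova`: omnibus `statistic` (F),
#'   `p.value`, df, and a `pairwise` tibble; [tidy()] returns the
#'   pairwise table, [glance()] the omnibus row.
#' @export
anova_tukey <- function(data, response, group, transform = c("none", "cube_root")) {
  transform <- match.arg(transform)
  y <- apply_transform(data[[response]], transform)
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("need at least two groups")
  if (any(table(g) < 2)) abort("need at least two observations per group")
  fit <- stats::aov(y ~ g)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  df_res <- an["Residuals", "Df"]
  k <- nlevels(g)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  pairs <- utils::combn(levels(g), 2)
  diff <- means[pairs[2, ]] - means[pairs[1, ]]
  se <- sqrt(mse * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
  tstat <- diff / se
  pairwise <- tibble(
    contrast = paste(pairs[2, ], "-", pairs[1, ]),
    estimate = as.numeric(diff),
    std_error = as.numeric(se),
    statistic = as.numeric(tstat),
    p.value = as.numeric(2 * stats::pt(-abs(tstat), df_res)),
    adj.p.value = as.numeric(stats::ptukey(sqrt(2) * abs(tstat), k, df_res, lower.tail = FALSE))
  )
  structure(
    list(
      statistic = an["g", "F value"], p.value = an["g", "Pr(>F)"],
      df = c(an["g", "Df"], df_res), pairwise = pairwise,
      n_groups = k, transform = transform, fit = fit
    ),
    class = "mt_anova"
  )
}

#' @export
print.mt_anova <- function(x, ...) {
  cat(sprintf(
    "<mt_anova> F(%d, %d) = %.3f, p = %.4g; %d Tukey pairwise comparisons\n",
    x$df[1], x$df[2], x$statistic, x$p.value, nrow(x$pairwise)
  ))
  print(x$pairwise)
  invisible(x)
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper recording the Shapiro-Wilk statistic and p-value for
#' pipeline logs. The result does not gate the cube-root transform, which
#' is applied by convention to metric responses regardless.
#'
#' @param values Numeric vector, 3 <= n <= 5000.
#' @return Object of class `mt_shapiro` with [tidy()] support.
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) {
    abort(sprintf("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", n))
  }
  sw <- stats::shapiro.test(values)
  structure(
    list(statistic = unname(sw$statistic), p.value = sw$p.value, n = n),
    class = "mt_shapiro"
  )
}

#' @export
print.mt_shapiro <- function(x, ...) {
  cat(sprintf(
    "<mt_shapiro> W = %.4f, p = %.4g (n = %d)\n", x$statistic, x$p.value, x$n
  ))
  invisible(x)
}

#' Serialize a model result to JSON
#'
#' Writes the tidied coefficient table and the glance summary of a fitted
#' result object (`mt_paired_test`, `mt_mixed`, `mt_anova`) as a JSON
#' file for downstream logging.
#'
#' @param x A fitted result object with [tidy()] and [glance()] methods.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(x, path) {
  jsonlite::write_json(
    list(coefficients = tidy(x), summary = glance(x)),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
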