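#' @exportS3Method generics::tidy
tidy.mt_paired_test <- function(x, ...) {
  tibble(
    term = "liver - brain",
    estimate = x$estimate,
    statistic = x$statistic,
    df = x$df,
    p.value = x$p.value
  )
}

#' @exportS3Method generics::glance
glance.mt_paired_test <- function(x, ...) {
  tibble(
    statistic = x$statistic, df = x$df, p.value = x$p.value,
    n = x$n, degenerate = x$degenerate, method = x$method
  )
}

#' @exportS3Method generics::tidy
tidy.mt_mixed <- function(x, ...) {
  co <- tryCatch(summary(x$fit)$coefficients, error = function(e) NULL)
  if (is.null(co)) {
    # fully degenerate fit (e.g. zero-variance response): report estimates only
    fe <- lme4::fixef(x$fit)
    return(tibble(
      term = names(fe), estimate = unname(fe), std_error = NA_real_,
      df = NA_real_, statistic = NA_real_, p.value = NA_real_
    ))
  }
  if ("df" %in% colnames(co)) {
    df <- co[, "df"]
    p <- co[, "Pr(>|t|)"]
  } else {
    # Wald fallback: normal approximation on the t statistic
    df <- rep(Inf, nrow(co))
    p <- 2 * stats::pnorm(-abs(co[, "t value"]))
  }
  tibble(
    term = rownames(co),
    estimate = unname(co[, "Estimate"]),
    std_error = unname(co[, "Std. Error"]),
    df = unname(df),
    statistic = unname(co[, "t value"]),
    p.value = unname(p)
  )
}

#' @exportS3Method generics::glance
glance.mt_mixed <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tibble(
    n_obs = x$n_obs,
    n_animals = x$n_animals,
    sigma_animal = vc$sdcor[vc$grp == x$random],
    sigma_resid = vc$sdcor[vc$grp == "Residual"],
    logLik = as.numeric(stats::logLik(x$fit)),
    singular = x$singular,
    transform = x$transform,
    df_method = x$df_method
  )
}

#' @exportS3Method generics::tidy
tidy.mt_anova <- function(x, ...) {
  x$pairwise
}

#' @exportS3Method generics::glance
glance.mt_anova <- function(x, ...) {
  tibble(
    statistic = x$statistic, df = x$df[1], df_residual = x$df[2],
    p.value = x$p.value, n_groups = x$n_groups, transform = x$transform
  )
}

#' @exportS3Method generics::tidy
tidy.mt_shapiro <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value, n = x$n)
}
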