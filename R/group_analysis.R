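#' Lilliefors-style Kolmogorov-Smirnov normality check
#'
#' One-sample KS test against a normal distribution with the sample's own
#' mean and SD (Lilliefors correction). Returns `TRUE` ("normal") when the
#' test does not reject at the 0.05 level.
#'
#' @param values Numeric vector (n >= 8).
#' @param alpha Rejection level (default 0.05).
#' @return Logical: treat the variable as normal?
#' @export
ks_normality <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 8L) stop("need at least 8 observations")
  if (var(values) == 0) {
    warning("constant input: not normal")
    return(FALSE)
  }
  nortest::lillie.test(values)$p.value > alpha
}

#' Covariate-adjusted group comparison
#'
#' Compares a dependent variable between cognitive groups adjusted for age,
#' sex and education. Normally distributed variables (per [ks_normality()])
#' take the parametric route: fixed-effects least squares
#' `dv ~ group + age + sex + education` with a partial F-test for the group
#' factor, and the CI-vs-CP contrast (`reference` = CP) with its 95% CI.
#' Non-normal variables take [quade_ancova()]. Complete-case analysis: rows
#' with missing dv or covariates are dropped and reflected in `n_complete`.
#'
#' @param dv Numeric dependent variable.
#' @param group Factor or character group labels.
#' @param covariates Data.frame of covariates (age, sex, education), same
#'   rows as `dv`; may have zero columns for an unadjusted comparison.
#' @param force_method `"linear"`, `"quade"` or `NULL` (decide by normality).
#' @param reference Reference group for the contrast (default `"CP"`).
#' @param contrast Group contrasted against the reference (default `"CI"`).
#' @param measure Optional measure name carried into the result.
#' @return One-row data.frame: `measure`, `method`, `F`, `p_raw`,
#'   `p_bonferroni` (NA until a family correction is applied), `beta`,
#'   `ci_low`, `ci_high`, `n_complete`.
#' @export
compare_groups <- function(dv, group, covariates = NULL, force_method = NULL,
                           reference = "CP", contrast = "CI",
                           measure = NA_character_) {
  if (is.null(covariates)) covariates <- data.frame(row.names = seq_along(dv))
  covariates <- as.data.frame(covariates)
  cc <- if (ncol(covariates)) complete.cases(dv, group, covariates) else
    complete.cases(dv, group)
  dv <- dv[cc]
  group <- factor(as.character(group[cc]))
  covariates <- covariates[cc, , drop = FALSE]
  tab <- table(group)
  if (length(tab) < 2L || any(tab < 3L)) {
    stop("need >= 2 groups with >= 3 complete cases each")
  }
  if (reference %in% levels(group)) group <- stats::relevel(group, reference)
  method <- force_method %||%
    (if (ks_normality(dv)) "linear" else "quade")
  if (method == "quade") {
    return(quade_ancova(dv, group, covariates, reference = reference,
                        contrast = contrast, measure = measure))
  }
  dat <- cbind(data.frame(dv = dv, group = group), covariates)
  full <- lm(dv ~ ., data = dat)
  reduced <- lm(dv ~ . - group, data = dat)
  an <- anova(reduced, full)
  beta <- ci_lo <- ci_hi <- NA_real_
  cname <- paste0("group", contrast)
  if (cname %in% names(coef(full))) {
    beta <- unname(coef(full)[cname])
    ci <- suppressMessages(confint(full, cname, level = 0.95))
    ci_lo <- ci[1L]
    ci_hi <- ci[2L]
  }
  data.frame(measure = measure, method = "linear",
             F = an$F[2L], p_raw = an$`Pr(>F)`[2L],
             p_bonferroni = NA_real_, beta = beta,
             ci_low = ci_lo, ci_high = ci_hi,
             n_complete = length(dv), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quade's nonparametric analysis of covariance
#'
#' Rank-based ANCOVA: the dependent variable and each covariate are
#' rank-transformed (midranks for ties) across the full sample; the ranked
#' dv is regressed on the ranked covariates by least squares; the residuals
#' are compared across groups with a one-way ANOVA F-test. With zero
#' covariates this collapses to a one-way ANOVA on ranks. The CI-vs-CP
#' contrast is reported on the rank-residual scale.
#'
#' @inheritParams compare_groups
#' @return One-row data.frame, as [compare_groups()].
#' @export
quade_ancova <- function(dv, group, covariates = NULL,
                         reference = "CP", contrast = "CI",
                         measure = NA_character_) {
  if (is.null(covariates)) covariates <- data.frame(row.names = seq_along(dv))
  covariates <- as.data.frame(covariates)
  cc <- if (ncol(covariates)) complete.cases(dv, group, covariates) else
    complete.cases(dv, group)
  dv <- dv[cc]
  group <- factor(as.character(group[cc]))
  covariates <- covariates[cc, , drop = FALSE]
  if (reference %in% levels(group)) group <- stats::relevel(group, reference)
  if (anyDuplicated(dv)) {
    warning("ties in the dependent variable: using midranks")
  }
  rdv <- rank(dv)
  if (ncol(covariates) > 0L) {
    rcov <- as.data.frame(lapply(covariates, rank))
    res <- stats::residuals(lm(rdv ~ ., data = rcov))
  } else {
    res <- rdv - mean(rdv)
  }
  fit <- lm(res ~ group)
  an <- anova(fit)
  beta <- ci_lo <- ci_hi <- NA_real_
  cname <- paste0("group", contrast)
  if (cname %in% names(coef(fit))) {
    beta <- unname(coef(fit)[cname])
    ci <- suppressMessages(confint(fit, cname, level = 0.95))
    ci_lo <- ci[1L]
    ci_hi <- ci[2L]
  }
  data.frame(measure = measure, method = "quade",
             F = an$`F value`[1L], p_raw = an$`Pr(>F)`[1L],
             p_bonferroni = NA_real_, beta = beta,
             ci_low = ci_lo, ci_high = ci_hi,
             n_complete = length(dv), stringsAsFactors = FALSE)
}

#' Partial correlation adjusted for covariates
#'
#' Residualises `x` and `y` on the covariates by least squares and reports
#' the Pearson correlation of the residuals with a t-test p-value on
#' `n - 2 - n_covariates` degrees of freedom. With no covariates this is the
#' plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional data.frame of covariates.
#' @return List with `r`, `p` and `n` (complete cases used).
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) covariates <- data.frame(row.names = seq_along(x))
  covariates <- as.data.frame(covariates)
  cc <- if (ncol(covariates)) complete.cases(x, y, covariates) else
    complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  covariates <- covariates[cc, , drop = FALSE]
  q <- ncol(covariates)
  n <- length(x)
  if (n <= q + 2L) stop("too few complete cases for the partial correlation")
  if (q > 0L) {
    x <- stats::residuals(lm(x ~ ., data = covariates))
    y <- stats::residuals(lm(y ~ ., data = covariates))
  }
  if (var(x) == 0 || var(y) == 0) {
    warning("zero residual variance: partial correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- cor(x, y)
  df <- n - 2L - q
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), df), n = n)
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)` with `m` the family size.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @param m Family size (defaults to `length(p_values)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  if (m < 1L) stop("family size must be >= 1")
  out <- pmin(1, p_values * m)
  names(out) <- names(p_values)
  out
}
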