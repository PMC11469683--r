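#' Covariate-adjust and z-score cognitive domain scores against controls
#'
#' For each domain, a least-squares linear model of the raw score on age,
#' sex and (binary) education is fitted in the healthy controls only; all
#' subjects are residualised with the control-fitted coefficients, and the
#' residuals are z-scored using the control residual mean and (sample) SD.
#' A covariate that is constant within the controls makes the design
#' singular and is dropped with a warning.
#'
#' @param scores Subjects x domains numeric matrix or data.frame of raw
#'   scores (row names or `subject_id` used for output rows).
#' @param covariates Data.frame with columns `age`, `sex`, `education`, one
#'   row per subject in the same order.
#' @param is_hc Logical vector flagging the healthy-control subjects
#'   (>= 3 required).
#' @return Subjects x domains matrix of control-referenced z-scores.
#' @export
adjust_and_zscore <- function(scores, covariates, is_hc) {
  scores <- as.matrix(scores)
  if (sum(is_hc) < 3L) stop("need at least 3 control subjects")
  if (nrow(covariates) != nrow(scores) || length(is_hc) != nrow(scores)) {
    stop("scores, covariates and is_hc must cover the same subjects")
  }
  covs <- c("age", "sex", "education")
  if (!all(covs %in% names(covariates))) {
    stop("covariates must contain age, sex and education")
  }
  X <- as.data.frame(covariates[covs])
  keep <- vapply(X[is_hc, , drop = FALSE], function(v) var(v) > 0, logical(1))
  if (!all(keep)) {
    warning("dropping constant-in-controls covariate(s): ",
            paste(covs[!keep], collapse = ", "))
  }
  X <- X[, keep, drop = FALSE]
  z <- matrix(NA_real_, nrow(scores), ncol(scores),
              dimnames = dimnames(scores))
  for (j in seq_len(ncol(scores))) {
    dat <- cbind(score = scores[, j], X)
    fit <- lm(score ~ ., data = dat[is_hc, , drop = FALSE])
    res <- scores[, j] - predict(fit, newdata = X)
    mu <- mean(res[is_hc])
    # residual SD on the regression's residual degrees of freedom; the naive
    # n-1 denominator understates the control spread and inflates |z|
    sdv <- sqrt(sum((res[is_hc] - mu)^2) / fit$df.residual)
    if (sdv == 0) stop("zero control residual SD in domain ",
                       colnames(scores)[j])
    z[, j] <- (res - mu) / sdv
  }
  z
}

#' Classify cognitive status from control-referenced domain z-scores
#'
#' Cognitively impaired (CI) when at least 2 of the 7 domains score
#' `Z < -2`; else mildly impaired (MCI) when at least 2 domains score
#' `Z < -1.5`; else cognitively preserved (CP). Both thresholds are strict
#' inequalities, so a score of exactly -2.0 does not count toward CI.
#'
#' @param z Numeric vector of 7 domain z-scores, or a subjects x 7 matrix.
#' @return Character label(s) in `{"CP", "MCI", "CI"}`.
#' @export
classify_cognition <- function(z) {
  if (is.matrix(z) || is.data.frame(z)) {
    return(apply(as.matrix(z), 1L, classify_cognition))
  }
  if (length(z) != 7L) stop("expected 7 domain z-scores")
  if (anyNA(z)) stop("missing domain z-score")
  if (sum(z < -2) >= 2L) return("CI")
  if (sum(z < -1.5) >= 2L) return("MCI")
  "CP"
}
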