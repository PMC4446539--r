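#' Wald tests for the fixed effects of a fitted mixed model
#'
#' Standard errors come from the inverse of the assembled GLS information
#' matrix \eqn{\sum_i X_i' \hat V_i^{-1} X_i}; each statistic
#' `estimate / se` is referred to the standard normal, two-sided.
#'
#' @param fit an [fit_lmm()] result.
#' @return data.frame with columns `term`, `estimate`, `se`, `z`, `p`, plus
#'   attribute `reliable` (`FALSE` when the fit did not converge or sits on
#'   the variance boundary).
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  out <- fit$fixed
  attr(out, "reliable") <- fit$converged && !fit$boundary
  if (!attr(out, "reliable"))
    warning("Wald statistics from a non-converged or boundary fit are unreliable")
  out
}

#' Likelihood-ratio (deviance) test between nested mixed models
#'
#' `delta_deviance = deviance(small) - deviance(big)` referred to the
#' chi-square with df equal to the difference in free parameter counts
#' (fixed coefficients plus variance-covariance parameters, covariances
#' included). The naive chi-square reference is used even when the smaller
#' model sits on the variance boundary; there the test is conservative (the
#' true null distribution is a chi-square mixture).
#'
#' @param fit_small,fit_big nested [fit_lmm()] results on the same data.
#'   Both must be ML fits; REML deviances are only comparable between
#'   identical fixed parts, and comparisons across different fixed parts are
#'   refused.
#' @return list of class `"lrt_result"`: `delta_deviance`, `df`, `p_value`.
#' @export
lrt <- function(fit_small, fit_big) {
  stopifnot(inherits(fit_small, "lmm_fit"), inherits(fit_big, "lmm_fit"))
  if (fit_small$method != fit_big$method)
    stop("cannot compare an ML fit with a REML fit")
  if (fit_small$method == "REML" &&
      !identical(fit_small$spec$fixed, fit_big$spec$fixed))
    stop("REML deviances are not comparable across different fixed parts; refit with ML")
  if (fit_small$n_obs != fit_big$n_obs)
    stop("fits use different data")
  if (!all(fit_small$spec$fixed %in% fit_big$spec$fixed) ||
      !all(fit_small$spec$random %in% fit_big$spec$random))
    stop("models are not nested (every term of the smaller model must appear in the larger)")
  df <- fit_big$n_params - fit_small$n_params
  dd <- fit_small$deviance - fit_big$deviance
  # identical parameterizations: nothing to test, the "difference" is noise
  p <- if (df == 0L) 1 else stats::pchisq(max(dd, 0), df, lower.tail = FALSE)
  structure(list(delta_deviance = dd, df = df, p_value = p),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: delta deviance = %.4f on %d df, p = %.4g\n",
              x$delta_deviance, x$df, x$p_value))
  invisible(x)
}

#' Information criteria of an ML fit
#'
#' `AIC = deviance + 2 p` and `BIC = deviance + p log(n_obs)` with `p` the
#' number of free parameters (fixed coefficients + variance-covariance
#' parameters including the level-1 variance) and `n_obs` the level-1
#' observation count.
#'
#' @param fit an [fit_lmm()] result.
#' @return named numeric vector `c(aic = , bic = )`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  c(aic = fit$aic, bic = fit$bic)
}

#' Subject-specific (empirical-Bayes) predictions
#'
#' Random effects are predicted by their conditional means
#' \eqn{\hat b_i = \hat\Psi Z_i' \hat V_i^{-1} (y_i - X_i \hat\beta)} (the
#' BLUPs) and the prediction for each row is \eqn{X_i \hat\beta + Z_i \hat
#' b_i}. Subjects absent from the fitting data get the population-level
#' prediction and are flagged.
#'
#' @param fit an [fit_lmm()] result.
#' @param data rows to predict; defaults to the fitting data.
#' @return data.frame with `subject`, `d`, `u`, `fit` (population
#'   prediction), `pred` (subject-specific prediction) and logical
#'   `population_only`.
#' @export
predict_subjects <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (is.null(data)) data <- fit$data
  data <- as_gradient_data(data)
  spec <- fit$spec
  beta <- fit$fixed$estimate
  X <- build_X(spec$fixed, data$d, data$u)
  pop <- drop(X %*% beta)
  q <- length(spec$random)
  out <- data.frame(subject = data$subject, d = data$d, u = data$u,
                    fit = pop, pred = pop, population_only = TRUE)
  if (q == 0L) return(out)

  fit_subjects <- levels(droplevels(fit$data$subject))
  fidx <- split(seq_len(nrow(fit$data)), droplevels(fit$data$subject))
  for (s in levels(droplevels(data$subject))) {
    rows <- which(data$subject == s)
    if (!s %in% fit_subjects) next
    fi <- fidx[[s]]
    Zi <- build_X(spec$random, fit$data$d[fi], fit$data$u[fi])
    Xi <- build_X(spec$fixed, fit$data$d[fi], fit$data$u[fi])
    Vi <- Zi %*% fit$Psi %*% t(Zi) + diag(fit$sigma2, length(fi))
    resid <- fit$data$y[fi] - drop(Xi %*% beta)
    bi <- drop(fit$Psi %*% t(Zi) %*% solve(Vi, resid))
    Znew <- build_X(spec$random, data$d[rows], data$u[rows])
    out$pred[rows] <- pop[rows] + drop(Znew %*% bi)
    out$population_only[rows] <- FALSE
  }
  out
}
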