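#' The seven-model ladder for gradient data
#'
#' Fits, by maximum likelihood, the canonical sequence of two-level models
#' for a generalization gradient with a subject-level moderator:
#'
#' 1. random intercept, fixed linear gradient (`1 + d`, random `1`)
#' 2. adds the random slope (`random 1 + d`)
#' 3. adds the moderator and cross-level interaction (`+ u + d:u`)
#' 4. quadratic fixed gradient on the random-slope model (`1 + d + d2`)
#' 5. adds the random quadratic term (`random 1 + d + d2`)
#' 6. quadratic model with moderator interactions at both orders
#'    (`+ u + d:u + d2:u`)
#' 7. drops the quadratic interaction (`+ u + d:u`) — the usual final model
#'
#' and reports the deviance comparisons that drive the model choice:
#' random slope (1 vs 2, 2 df: slope variance + covariance), moderator
#' fixed terms (2 vs 3, 2 df), quadratic fixed term (2 vs 4, 1 df), random
#' quadratic (4 vs 5, 3 df: variance + two covariances), moderator terms in
#' the quadratic model (4 vs 6, 3 df) and the dropped quadratic interaction
#' (7 vs 6, 1 df).
#'
#' @param data a gradient dataset.
#' @return list of class `"model_ladder"` with `fits` (named list
#'   `model1`..`model7` of [fit_lmm()] results) and `comparisons`
#'   (data.frame: comparison, delta_deviance, df, p_value).
#' @export
model_ladder <- function(data) {
  data <- as_gradient_data(data)
  specs <- list(
    model1 = lmm_spec("1 + d", "1", "ML"),
    model2 = lmm_spec("1 + d", "1 + d", "ML"),
    model3 = lmm_spec("1 + d + u + d:u", "1 + d", "ML"),
    model4 = lmm_spec("1 + d + d2", "1 + d", "ML"),
    model5 = lmm_spec("1 + d + d2", "1 + d + d2", "ML"),
    model6 = lmm_spec("1 + d + d2 + u + d:u + d2:u", "1 + d", "ML"),
    model7 = lmm_spec("1 + d + d2 + u + d:u", "1 + d", "ML"))
  fits <- lapply(specs, function(s) fit_lmm(data, spec = s))
  pairs <- list(
    c("model1", "model2", "random slope"),
    c("model2", "model3", "moderator (u, d:u)"),
    c("model2", "model4", "quadratic fixed term"),
    c("model4", "model5", "random quadratic"),
    c("model4", "model6", "moderator in quadratic model"),
    c("model7", "model6", "quadratic interaction d2:u"))
  comp <- do.call(rbind, lapply(pairs, function(pr) {
    t <- lrt(fits[[pr[1L]]], fits[[pr[2L]]])
    data.frame(comparison = paste(pr[1L], "vs", pr[2L]),
               effect = pr[3L],
               delta_deviance = t$delta_deviance, df = t$df,
               p_value = t$p_value)
  }))
  structure(list(fits = fits, comparisons = comp), class = "model_ladder")
}

#' @export
print.model_ladder <- function(x, ...) {
  cat("Model ladder (ML fits)\n")
  sel <- do.call(rbind, lapply(names(x$fits), function(nm) {
    f <- x$fits[[nm]]
    data.frame(model = nm,
               fixed = paste(f$spec$fixed, collapse = "+"),
               random = paste(f$spec$random, collapse = "+"),
               deviance = round(f$deviance, 1),
               AIC = round(f$aic, 2), BIC = round(f$bic, 2),
               params = f$n_params)
  }))
  print(sel, row.names = FALSE)
  cat("\nDeviance comparisons:\n")
  comp <- x$comparisons
  comp$delta_deviance <- signif(comp$delta_deviance, 5)
  comp$p_value <- signif(comp$p_value, 4)
  print(comp, row.names = FALSE)
  invisible(x)
}
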