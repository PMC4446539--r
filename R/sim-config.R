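#' Simulation configuration for the two-level gradient generator
#'
#' Bundles every generating parameter of the two-level Gaussian model for
#' generalization-gradient data,
#' \deqn{Y_{ij} = \beta_{0i} + \beta_{1i} d_j + \epsilon_{ij},}
#' \deqn{\beta_{0i} = \gamma_{00} + \gamma_{01} u_i + U_{0i}, \qquad
#'       \beta_{1i} = \gamma_{10} + \gamma_{11} u_i + U_{1i},}
#' with \eqn{(U_{0i}, U_{1i})} bivariate normal with covariance
#' \eqn{[[\tau_{00}, \tau_{01}], [\tau_{01}, \tau_{11}]]} and
#' \eqn{\epsilon_{ij} \sim N(0, \sigma^2_\epsilon)} independent of the random
#' effects.
#'
#' @param n_subjects number of level-2 units (subjects); at least 2.
#' @param gamma00,gamma10,gamma01,gamma11 fixed effects: intercept, slope of
#'   the stimulus dimension `d`, main effect of the subject covariate `u` on
#'   the intercept, and the cross-level interaction `d:u` acting on the slope.
#' @param tau00,tau11,tau01 random-intercept variance, random-slope variance
#'   and their covariance; `[[tau00, tau01], [tau01, tau11]]` must be positive
#'   semi-definite.
#' @param sigma2_eps level-1 residual variance, strictly positive.
#' @param d_values ordered stimulus codes along the dimension (default
#'   `0:9`, the conditioned stimulus at `d = 0`).
#' @param u_spec distribution of the subject covariate: a list with element
#'   `kind` (`"uniform"`, `"normal"` or `"fixed"`) and parameters `min`/`max`,
#'   `mean`/`sd`, or `values` respectively.
#' @param seed optional integer seed; when supplied, [simulate_dataset()]
#'   seeds the generator so identical configs give identical data.
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @seealso [reference_config()] for the parameter set used throughout the
#'   Monte-Carlo study, [simulate_dataset()].
#' @export
sim_config <- function(n_subjects,
                       gamma00, gamma10,
                       gamma01 = 0, gamma11 = 0,
                       tau00 = 0, tau11 = 0, tau01 = 0,
                       sigma2_eps,
                       d_values = 0:9,
                       u_spec = list(kind = "uniform", min = 0, max = 10),
                       seed = NULL) {
  stopifnot(length(n_subjects) == 1L, is.finite(n_subjects))
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L)
    stop("`n_subjects` must be at least 2: a single subject permits no between-subject analysis")
  if (!is.numeric(sigma2_eps) || length(sigma2_eps) != 1L || sigma2_eps <= 0)
    stop("`sigma2_eps` must be a single strictly positive number")
  if (tau00 < 0 || tau11 < 0)
    stop("variances `tau00` and `tau11` must be non-negative")
  G <- matrix(c(tau00, tau01, tau01, tau11), 2L, 2L)
  # PSD up to a tolerance scaled by the largest entry
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(1, max(abs(G))))
    stop("random-effects covariance [[tau00, tau01], [tau01, tau11]] is not positive semi-definite")
  d_values <- as.numeric(d_values)
  if (length(d_values) < 1L || anyNA(d_values))
    stop("`d_values` must be a non-empty numeric vector")
  u_spec <- validate_u_spec(u_spec, n_subjects)
  structure(
    list(n_subjects = n_subjects, n_stimuli = length(d_values),
         gamma00 = gamma00, gamma10 = gamma10,
         gamma01 = gamma01, gamma11 = gamma11,
         tau00 = tau00, tau11 = tau11, tau01 = tau01,
         sigma2_eps = sigma2_eps,
         d_values = d_values, u_spec = u_spec,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config")
}

validate_u_spec <- function(u_spec, n_subjects) {
  if (!is.list(u_spec) || is.null(u_spec$kind))
    stop("`u_spec` must be a list with a `kind` element")
  switch(u_spec$kind,
    uniform = {
      if (is.null(u_spec$min)) u_spec$min <- 0
      if (is.null(u_spec$max)) u_spec$max <- 10
      stopifnot(u_spec$min < u_spec$max)
    },
    normal = {
      if (is.null(u_spec$mean)) u_spec$mean <- 0
      if (is.null(u_spec$sd)) u_spec$sd <- 1
      stopifnot(u_spec$sd >= 0)
    },
    fixed = {
      if (is.null(u_spec$values))
        stop("u_spec kind 'fixed' requires `values`")
      if (length(u_spec$values) != n_subjects)
        stop("u_spec$values must have one entry per subject")
    },
    stop("unknown u_spec kind: ", u_spec$kind)
  )
  u_spec
}

draw_u <- function(u_spec, n) {
  switch(u_spec$kind,
    uniform = stats::runif(n, u_spec$min, u_spec$max),
    normal  = stats::rnorm(n, u_spec$mean, u_spec$sd),
    fixed   = as.numeric(u_spec$values))
}

#' Generating parameters of the Monte-Carlo study
#'
#' The reference parameter set for the simulation study: a decreasing linear
#' gradient over 10 stimuli with a moderator `u` on the intercept, correlated
#' random intercepts and slopes (so the repeated-measures covariance violates
#' sphericity), and a cross-level interaction `gamma11` that is swept over
#' 0 (null), 0.05 (moderate) and 0.10 (large) in the study grid.
#'
#' @param n_subjects number of subjects (the study uses 20, 38 and 55).
#' @param gamma11 cross-level interaction coefficient.
#' @param seed optional seed stored in the config.
#' @return A [sim_config()] object.
#' @export
reference_config <- function(n_subjects = 20, gamma11 = 0, seed = NULL) {
  sim_config(
    n_subjects = n_subjects,
    gamma00 = 7.91871, gamma10 = -0.58322,
    gamma01 = -0.37375, gamma11 = gamma11,
    tau00 = 2.5324, tau11 = 0.1345, tau01 = -0.46,
    sigma2_eps = 2.4348,
    d_values = 0:9,
    u_spec = list(kind = "uniform", min = 0, max = 10),
    seed = seed)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Two-level gradient simulation config\n")
  cat(sprintf("  %d subjects x %d stimuli (d = %s)\n", x$n_subjects, x$n_stimuli,
              paste(range(x$d_values), collapse = "..")))
  cat(sprintf("  fixed:  g00 = %.5g, g10 = %.5g, g01 = %.5g, g11 = %.5g\n",
              x$gamma00, x$gamma10, x$gamma01, x$gamma11))
  cat(sprintf("  random: tau00 = %.5g, tau11 = %.5g, tau01 = %.5g, sigma2_eps = %.5g\n",
              x$tau00, x$tau11, x$tau01, x$sigma2_eps))
  cat(sprintf("  u ~ %s\n", x$u_spec$kind))
  invisible(x)
}
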