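#' Simulate a balanced gradient dataset from the two-level model
#'
#' Draws `u_i` from the configured covariate distribution, subject random
#' effects `(U_0i, U_1i)` from the bivariate normal with covariance
#' `[[tau00, tau01], [tau01, tau11]]`, forms the subject intercept and slope
#' `b0i = gamma00 + gamma01 u_i + U_0i`, `b1i = gamma10 + gamma11 u_i + U_1i`,
#' and generates `y = b0i + b1i d_j + eps` with i.i.d. Gaussian level-1 noise.
#'
#' @param config a [sim_config()] object.
#' @param seed optional integer overriding `config$seed`. When neither is
#'   given the current RNG stream is used (so a caller can embed the
#'   simulator in its own seeded loop).
#' @return A `data.frame` of class `"gradient_data"` with columns `subject`
#'   (factor), `d`, `u`, `y`, one row per subject-stimulus pair
#'   (`n_subjects * n_stimuli` rows), plus the per-subject truth in
#'   `attr(, "effects")` (`u`, `U0`, `U1`, `b0`, `b1`).
#' @examples
#' dat <- simulate_dataset(reference_config(n_subjects = 20, seed = 1))
#' nrow(dat)  # 200
#' @export
simulate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  else if (!is.null(config$seed)) set.seed(config$seed)

  n <- config$n_subjects
  d <- config$d_values
  k <- length(d)

  u <- draw_u(config$u_spec, n)
  G <- matrix(c(config$tau00, config$tau01, config$tau01, config$tau11), 2L, 2L)
  U <- rmvnorm2(n, G)                      # n x 2, columns U0, U1
  b0 <- config$gamma00 + config$gamma01 * u + U[, 1L]
  b1 <- config$gamma10 + config$gamma11 * u + U[, 2L]

  eps <- stats::rnorm(n * k, 0, sqrt(config$sigma2_eps))
  # subject-major order: rows 1..k are subject 1, etc.
  y <- rep(b0, each = k) + rep(b1, each = k) * rep(d, times = n) + eps

  out <- data.frame(
    subject = factor(rep(seq_len(n), each = k)),
    d = rep(d, times = n),
    u = rep(u, each = k),
    y = y)
  attr(out, "effects") <- data.frame(
    subject = factor(seq_len(n)), u = u,
    U0 = U[, 1L], U1 = U[, 2L], b0 = b0, b1 = b1)
  class(out) <- c("gradient_data", "data.frame")
  out
}

# Exact bivariate (or degenerate) normal draw via the symmetric square root,
# so tau11 = 0 or a singular G is handled without a Cholesky failure.
rmvnorm2 <- function(n, G) {
  e <- eigen(G, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  A <- e$vectors %*% (sqrt(lam) * t(e$vectors))
  matrix(stats::rnorm(2L * n), n, 2L) %*% A
}

#' Emulate a Cyberball-style social-exclusion generalization study
#'
#' Generates data shaped like the social-exclusion generalization study that
#' motivates the model ladder: 52 subjects rate US-expectancy on a 0-10 scale
#' for 10 players (`d = 0` the excluding player CS+, `d = 9` the fair player
#' CS-), with a decreasing quadratic mean gradient, a moderator `u` on
#' `[0, 10]` that flattens the gradient, and correlated random intercepts and
#' linear slopes. This is a synthetic emulator of an unpublished study, not
#' the study data; its defaults sit near the final quadratic moderator model
#' a ladder analysis of such data selects.
#'
#' @param n_subjects number of subjects (default 52).
#' @param seed optional integer seed.
#' @param coefficients named numeric vector overriding any of `gamma00`,
#'   `gamma10`, `gamma20` (quadratic term), `gamma01`, `gamma11`.
#' @param tau00,tau11,tau01,sigma2_eps variance components of the random
#'   intercept/linear-slope structure and the level-1 noise.
#' @param clip clip responses to the 0-10 rating scale (default `TRUE`).
#'   Clipping censors the Gaussian tails, so parameter-recovery exercises on
#'   the latent model should set `clip = FALSE`.
#' @return A `"gradient_data"` data.frame with `52 * 10 = 520` rows under the
#'   defaults.
#' @export
simulate_worked_example <- function(n_subjects = 52, seed = NULL,
                                    coefficients = NULL,
                                    tau00 = 2.82, tau11 = 0.14, tau01 = -0.46,
                                    sigma2_eps = 2.24, clip = TRUE) {
  if (n_subjects < 2) stop("`n_subjects` must be at least 2")
  co <- c(gamma00 = 8.69, gamma10 = -0.51, gamma20 = -0.05,
          gamma01 = -0.29, gamma11 = 0.09)
  if (!is.null(coefficients)) {
    bad <- setdiff(names(coefficients), names(co))
    if (length(bad)) stop("unknown coefficient(s): ", paste(bad, collapse = ", "))
    co[names(coefficients)] <- coefficients
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  n <- as.integer(n_subjects); d <- 0:9; k <- 10L
  u <- stats::runif(n, 0, 10)
  G <- matrix(c(tau00, tau01, tau01, tau11), 2L, 2L)
  U <- rmvnorm2(n, G)
  b0 <- co[["gamma00"]] + co[["gamma01"]] * u + U[, 1L]
  b1 <- co[["gamma10"]] + co[["gamma11"]] * u + U[, 2L]

  y <- rep(b0, each = k) + rep(b1, each = k) * rep(d, n) +
    co[["gamma20"]] * rep(d^2, n) +
    stats::rnorm(n * k, 0, sqrt(sigma2_eps))
  if (clip) y <- pmin(pmax(y, 0), 10)

  out <- data.frame(
    subject = factor(rep(seq_len(n), each = k)),
    d = rep(d, n), u = rep(u, each = k), y = y)
  attr(out, "effects") <- data.frame(
    subject = factor(seq_len(n)), u = u,
    U0 = U[, 1L], U1 = U[, 2L], b0 = b0, b1 = b1)
  attr(out, "emulator") <- TRUE
  class(out) <- c("gradient_data", "data.frame")
  out
}
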