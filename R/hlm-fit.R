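# Two-level Gaussian linear mixed model fitter.
#
# The marginal model per subject i is y_i ~ N(X_i beta, V_i) with
# V_i = Z_i Psi Z_i' + sigma2 I. Writing Psi = sigma2 * Lambda Lambda'
# (Lambda the relative Cholesky factor), beta and sigma2 are profiled out:
# only the q(q+1)/2 parameters of Lambda are optimized, on the log-Cholesky
# scale (log of diagonal entries, free off-diagonals). For each candidate
# Lambda, V*_i = Z_i Lambda Lambda' Z_i' + I is factored, the data are
# whitened, beta is the GLS solution and sigma2 the scaled residual sum of
# squares; the profiled -2 log-likelihood (ML) or restricted likelihood
# (REML) is returned. Balanced designs (all subjects share one d pattern,
# the common case here) use a vectorized path with a single k x k Cholesky
# per evaluation.

# theta -> lower-triangular relative Cholesky factor (q x q)
theta_to_Lambda <- function(theta, q) {
  L <- matrix(0, q, q)
  diag(L) <- exp(theta[seq_len(q)])
  if (q > 1L) L[lower.tri(L)] <- theta[-seq_len(q)]
  L
}

# Profiled objective pieces shared by ML and REML:
# returns list(A, bvec, sumyy, sumlogdet) for a given Lambda.
# Fast path: all subjects share Z (k x q) and X_i = [W | u_i * W2].
lmm_profile_parts <- function(st, Lambda) {
  if (st$balanced) {
    k <- nrow(st$Z)
    Vs <- diag(k)
    if (ncol(Lambda)) {
      ZL <- st$Z %*% Lambda
      Vs <- Vs + tcrossprod(ZL)
    }
    R <- chol(Vs)
    sumlogdet <- st$n_subj * 2 * sum(log(diag(R)))
    Yt <- backsolve(R, st$Yk, transpose = TRUE)       # k x n whitened responses
    Wt <- backsolve(R, st$W, transpose = TRUE)
    p1 <- ncol(st$W); p2 <- ncol(st$W2)
    if (p2) {
      W2t <- backsolve(R, st$W2, transpose = TRUE)
      A <- rbind(
        cbind(st$n_subj * crossprod(Wt), st$sum_u * crossprod(Wt, W2t)),
        cbind(st$sum_u * crossprod(W2t, Wt), st$sum_u2 * crossprod(W2t)))
      bvec <- c(crossprod(Wt, Yt %*% rep(1, st$n_subj)),
                crossprod(W2t, Yt %*% st$u_subj))
    } else {
      A <- st$n_subj * crossprod(Wt)
      bvec <- drop(crossprod(Wt, Yt %*% rep(1, st$n_subj)))
    }
    list(A = A, bvec = drop(bvec), sumyy = sum(Yt^2), sumlogdet = sumlogdet)
  } else {
    p <- ncol(st$X_list[[1L]])
    A <- matrix(0, p, p); bvec <- numeric(p)
    sumyy <- 0; sumlogdet <- 0
    for (i in seq_along(st$y_list)) {
      Zi <- st$Z_list[[i]]
      Vs <- diag(nrow(Zi))
      if (ncol(Lambda)) {
        ZL <- Zi %*% Lambda
        Vs <- Vs + tcrossprod(ZL)
      }
      R <- chol(Vs)
      sumlogdet <- sumlogdet + 2 * sum(log(diag(R)))
      yt <- backsolve(R, st$y_list[[i]], transpose = TRUE)
      Xt <- backsolve(R, st$X_list[[i]], transpose = TRUE)
      A <- A + crossprod(Xt)
      bvec <- bvec + drop(crossprod(Xt, yt))
      sumyy <- sumyy + sum(yt^2)
    }
    list(A = A, bvec = bvec, sumyy = sumyy, sumlogdet = sumlogdet)
  }
}

lmm_objective <- function(st, reml) {
  N <- st$n_obs; p <- st$p
  function(theta) {
    Lambda <- theta_to_Lambda(theta, st$q)
    parts <- tryCatch(lmm_profile_parts(st, Lambda), error = function(e) NULL)
    if (is.null(parts)) return(1e10)
    Ach <- tryCatch(chol(parts$A), error = function(e) NULL)
    if (is.null(Ach)) return(1e10)
    beta <- backsolve(Ach, backsolve(Ach, parts$bvec, transpose = TRUE))
    rss <- max(parts$sumyy - sum(parts$bvec * beta), 1e-300)
    if (reml) {
      s2 <- rss / (N - p)
      (N - p) * log(2 * pi * s2) + parts$sumlogdet +
        2 * sum(log(diag(Ach))) + (N - p)
    } else {
      s2 <- rss / N
      N * log(2 * pi * s2) + parts$sumlogdet + N
    }
  }
}

# Assemble per-subject state from a gradient dataset and an lmm_spec.
lmm_state <- function(data, spec) {
  data <- as_gradient_data(data)
  sub <- data$subject
  subs <- levels(droplevels(sub))
  idx <- split(seq_len(nrow(data)), droplevels(sub))
  q <- length(spec$random)
  d_list <- lapply(idx, function(ii) data$d[ii])
  same_d <- length(unique(vapply(d_list, paste, "", collapse = ","))) == 1L
  n_subj <- length(idx)
  if (n_subj < q + 1L)
    stop("need more subjects (", n_subj, ") than random-effect dimensions (", q, ")")
  # fixed columns split into d-only terms and u-interaction terms
  f_dwise <- intersect(spec$fixed, c("1", "d", "d2"))
  f_uwise <- intersect(spec$fixed, c("u", "d:u", "d2:u"))
  u_map <- c(u = "1", "d:u" = "d", "d2:u" = "d2")
  st <- list(q = q, p = length(spec$fixed), spec = spec,
             n_obs = nrow(data), n_subj = n_subj, subjects = subs,
             balanced = same_d)
  if (same_d) {
    # rows of Yk, Z, W, W2 all use ascending-d order
    d <- sort(d_list[[1L]])
    zeros <- rep(0, length(d))
    st$Z <- build_X(spec$random, d, u = zeros)
    st$W <- build_X(f_dwise, d, u = zeros)
    st$W2 <- build_X(unname(u_map[f_uwise]), d, u = zeros)
    st$Yk <- vapply(idx, function(ii) data$y[ii][order(data$d[ii])],
                    numeric(length(d)))               # k x n, columns subjects
    st$u_subj <- vapply(idx, function(ii) data$u[ii][1L], 0)
    st$sum_u <- sum(st$u_subj); st$sum_u2 <- sum(st$u_subj^2)
    st$fixed_names <- c(f_dwise, f_uwise)
  } else {
    st$y_list <- lapply(idx, function(ii) data$y[ii])
    st$X_list <- lapply(idx, function(ii)
      build_X(spec$fixed, data$d[ii], data$u[ii]))
    st$Z_list <- lapply(idx, function(ii)
      if (q) build_X(spec$random, data$d[ii], data$u[ii]) else
        matrix(0, length(ii), 0L))
    st$fixed_names <- spec$fixed
    st$u_subj <- vapply(idx, function(ii) data$u[ii][1L], 0)
  }
  st$idx <- idx
  st
}

# Moment-based starting value for Lambda from per-subject OLS fits.
lmm_start <- function(st, data) {
  q <- st$q
  if (!q) return(numeric(0))
  theta0 <- c(rep(0, q), rep(0, q * (q - 1L) / 2L))
  est <- tryCatch({
    coefs <- matrix(NA_real_, st$n_subj, q)
    s2s <- numeric(0)
    for (i in seq_along(st$idx)) {
      ii <- st$idx[[i]]
      Zi <- if (st$balanced) st$Z else st$Z_list[[i]]
      yi <- if (st$balanced) st$Yk[, i] else data$y[ii]
      if (length(ii) > q + 1L) {
        f <- stats::lm.fit(Zi, yi)
        coefs[i, ] <- f$coefficients
        s2s <- c(s2s, sum(f$residuals^2) / (length(ii) - q))
      }
    }
    ok <- stats::complete.cases(coefs)
    if (sum(ok) < q + 2L) stop("too few")
    s2 <- max(stats::median(s2s), 1e-8)
    Psi_rel <- stats::cov(coefs[ok, , drop = FALSE]) / s2
    # deflate by a nominal sampling contribution, keep PSD
    e <- eigen(Psi_rel, symmetric = TRUE)
    lam <- pmax(e$values * 0.8, 1e-4)
    L <- t(chol(e$vectors %*% (lam * t(e$vectors)) + diag(1e-6, q)))
    c(log(pmax(diag(L), 1e-4)), L[lower.tri(L)])
  }, error = function(e) NULL)
  if (is.null(est)) theta0 else est
}

# Unprofiled -2 log-likelihood at user-supplied (beta, Psi, sigma2):
# sum over subjects of the Gaussian log-density with V_i = Z_i Psi Z_i' +
# sigma2 I, each evaluated through a per-subject Cholesky factor.
lmm_neg2ll <- function(data, spec, beta, Psi, sigma2) {
  data <- as_gradient_data(data)
  idx <- split(seq_len(nrow(data)), droplevels(data$subject))
  q <- length(spec$random)
  total <- 0
  for (ii in idx) {
    Xi <- build_X(spec$fixed, data$d[ii], data$u[ii])
    Zi <- build_X(spec$random, data$d[ii], data$u[ii])
    Vi <- diag(sigma2, length(ii))
    if (q) Vi <- Vi + Zi %*% Psi %*% t(Zi)
    R <- chol(Vi)
    r <- data$y[ii] - drop(Xi %*% beta)
    w <- backsolve(R, r, transpose = TRUE)
    total <- total + 2 * sum(log(diag(R))) + sum(w^2) +
      length(ii) * log(2 * pi)
  }
  total
}

#' Fit a two-level linear mixed model to gradient data
#'
#' Maximum-likelihood or REML estimation of the Gaussian two-level model
#' \eqn{y_i \sim N(X_i \beta, Z_i \Psi Z_i' + \sigma^2 I)} by profiling
#' \eqn{\beta} (generalized least squares) and \eqn{\sigma^2} out of the
#' likelihood and optimizing the relative random-effects Cholesky factor on
#' the log-Cholesky scale with a deterministic quasi-Newton search
#' (`nlminb`, objective tolerance 1e-8, Nelder-Mead fallback). An empty
#' random part reduces to ordinary least squares.
#'
#' @param data a gradient dataset (long format; balance is not required).
#' @param fixed,random,method passed to [lmm_spec()], or give a ready
#'   `spec`.
#' @param spec an [lmm_spec()] object (overrides `fixed`/`random`/`method`).
#' @return An object of class `"lmm_fit"` with components `fixed`
#'   (data.frame: term, estimate, se, z, p), `Psi` (random-effects
#'   covariance), `sigma2`, `loglik`, `deviance` (-2 loglik), `aic`, `bic`,
#'   `n_obs`, `n_clusters`, `n_params`, `converged`, `boundary`, `method`,
#'   `spec`, and internal state for [predict_subjects()].
#' @examples
#' dat <- simulate_dataset(reference_config(n_subjects = 30, seed = 7))
#' fit <- fit_lmm(dat, fixed = "1 + d + u + d:u", random = "1 + d")
#' fit$fixed
#' @export
fit_lmm <- function(data, fixed = "1 + d", random = "1",
                    method = c("ML", "REML"), spec = NULL) {
  if (is.null(spec)) spec <- lmm_spec(fixed, random, match.arg(method))
  stopifnot(inherits(spec, "lmm_spec"))
  data <- as_gradient_data(data)
  st <- lmm_state(data, spec)
  reml <- spec$method == "REML"
  q <- st$q
  n_theta <- q * (q + 1L) / 2L
  lower_diag <- log(1e-6)

  if (n_theta == 0L) {
    theta_hat <- numeric(0)
    converged <- TRUE
    boundary <- FALSE
  } else {
    obj <- lmm_objective(st, reml)
    start <- lmm_start(st, data)
    lower <- c(rep(lower_diag, q), rep(-1e3, n_theta - q))
    upper <- rep(1e3, n_theta)
    opt <- stats::nlminb(start, obj, lower = lower, upper = upper,
                         control = list(rel.tol = 1e-10, abs.tol = 1e-12,
                                        iter.max = 500L, eval.max = 1000L))
    # fallback / polish with Nelder-Mead if nlminb struggled
    if (opt$convergence != 0 || !is.finite(opt$objective)) {
      nm <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 2000L, reltol = 1e-10))
      if (is.finite(nm$value) && nm$value <= opt$objective) {
        opt$par <- pmin(pmax(nm$par, lower), upper)
        opt$objective <- nm$value
        opt$convergence <- nm$convergence
      }
    }
    theta_hat <- opt$par
    converged <- opt$convergence == 0
    boundary <- any(theta_hat[seq_len(q)] <= lower_diag + 1e-4)
  }

  Lambda <- theta_to_Lambda(theta_hat, q)
  parts <- lmm_profile_parts(st, Lambda)
  Ach <- chol(parts$A)
  beta <- backsolve(Ach, backsolve(Ach, parts$bvec, transpose = TRUE))
  rss <- max(parts$sumyy - sum(parts$bvec * beta), 1e-300)
  N <- st$n_obs; p <- st$p
  if (reml) {
    sigma2 <- rss / (N - p)
    dev <- (N - p) * log(2 * pi * sigma2) + parts$sumlogdet +
      2 * sum(log(diag(Ach))) + (N - p)
  } else {
    sigma2 <- rss / N
    dev <- N * log(2 * pi * sigma2) + parts$sumlogdet + N
  }
  Psi <- sigma2 * tcrossprod(Lambda)
  if (q) dimnames(Psi) <- list(spec$random, spec$random)

  vcov_beta <- sigma2 * chol2inv(Ach)
  se <- sqrt(diag(vcov_beta))
  zstat <- beta / se
  fixed_tab <- data.frame(
    term = st$fixed_names,
    estimate = beta, se = se, z = zstat,
    p = 2 * stats::pnorm(-abs(zstat)),
    row.names = NULL)
  # report in canonical spec order
  fixed_tab <- fixed_tab[match(spec$fixed, fixed_tab$term), ]
  rownames(fixed_tab) <- NULL
  vcov_beta <- vcov_beta[match(spec$fixed, st$fixed_names),
                         match(spec$fixed, st$fixed_names), drop = FALSE]
  dimnames(vcov_beta) <- list(spec$fixed, spec$fixed)

  n_params <- p + n_theta + 1L
  structure(list(
    fixed = fixed_tab, vcov_fixed = vcov_beta,
    Psi = Psi, sigma2 = sigma2, Lambda = Lambda, theta = theta_hat,
    loglik = -dev / 2, deviance = dev,
    aic = dev + 2 * n_params, bic = dev + n_params * log(N),
    n_obs = N, n_clusters = st$n_subj, n_params = n_params,
    converged = converged, boundary = boundary,
    method = spec$method, spec = spec,
    data = data),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Two-level LMM (%s): fixed = %s; random = %s\n",
              x$method, paste(x$spec$fixed, collapse = " + "),
              if (length(x$spec$random)) paste(x$spec$random, collapse = " + ")
              else "(none)"))
  ft <- x$fixed
  ft$estimate <- signif(ft$estimate, 5); ft$se <- signif(ft$se, 4)
  ft$z <- signif(ft$z, 4); ft$p <- signif(ft$p, 4)
  print(ft, row.names = FALSE)
  if (length(x$spec$random)) {
    cat("Random-effects covariance (Psi):\n")
    print(signif(x$Psi, 5))
  }
  cat(sprintf("sigma2 = %.5g | deviance = %.6g | AIC = %.6g | BIC = %.6g\n",
              x$sigma2, x$deviance, x$aic, x$bic))
  cat(sprintf("N = %d obs, %d subjects, %d parameters; converged: %s%s\n",
              x$n_obs, x$n_clusters, x$n_params, x$converged,
              if (x$boundary) " (variance at boundary)" else ""))
  invisible(x)
}
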