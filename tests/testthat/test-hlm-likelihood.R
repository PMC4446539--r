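small_fixture <- function() {
  # 2 subjects x 3 observations, hand-fixed values
  data.frame(
    subject = factor(rep(1:2, each = 3)),
    d = rep(0:2, 2),
    u = rep(c(2, 7), each = 3),
    y = c(5.1, 4.0, 3.2, 8.3, 6.9, 6.1))
}

test_that("unprofiled -2 loglik equals a dense multivariate-normal evaluation", {
  dat <- as_gradient_data(small_fixture())
  spec <- lmm_spec("1 + d + u", "1 + d", "ML")
  beta <- c(4.5, -0.9, 0.35)
  Psi <- matrix(c(1.2, -0.3, -0.3, 0.4), 2)
  sigma2 <- 0.8
  impl <- gengrad:::lmm_neg2ll(dat, spec, beta, Psi, sigma2)

  # oracle: one dense 6x6 covariance, direct determinant and solve
  X <- cbind(1, dat$d, dat$u)
  V <- matrix(0, 6, 6)
  for (s in 1:2) {
    ii <- which(dat$subject == s)
    Zi <- cbind(1, dat$d[ii])
    V[ii, ii] <- Zi %*% Psi %*% t(Zi) + diag(sigma2, 3)
  }
  r <- dat$y - drop(X %*% beta)
  oracle <- as.numeric(determinant(V, logarithm = TRUE)$modulus) +
    drop(t(r) %*% solve(V, r)) + 6 * log(2 * pi)
  expect_equal(impl, oracle, tolerance = 1e-10)
})

test_that("profiled objective equals the dense profiled criterion, ML and REML", {
  dat <- simulate_dataset(reference_config(n_subjects = 6, seed = 61))
  for (specstr in list(c("1 + d + u + d:u", "1 + d"), c("1 + d + d2", "1"))) {
    for (reml in c(FALSE, TRUE)) {
      spec <- lmm_spec(specstr[1], specstr[2], if (reml) "REML" else "ML")
      st <- gengrad:::lmm_state(dat, spec)
      obj <- gengrad:::lmm_objective(st, reml)
      q <- length(spec$random)
      for (theta in list(rep(0.1, q * (q + 1) / 2),
                         seq(-0.4, by = 0.3, length.out = q * (q + 1) / 2))) {
        Lambda <- gengrad:::theta_to_Lambda(theta, q)
        expect_equal(obj(theta),
                     dense_profiled_neg2ll(dat, spec, Lambda, reml),
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("reported deviance is the unprofiled -2 loglik at the reported estimates", {
  dat <- simulate_dataset(reference_config(n_subjects = 15, seed = 62))
  fit <- fit_lmm(dat, "1 + d + u + d:u", "1 + d")
  dev_at_hat <- gengrad:::lmm_neg2ll(dat, fit$spec, fit$fixed$estimate,
                                     fit$Psi, fit$sigma2)
  expect_equal(fit$deviance, dev_at_hat, tolerance = 1e-8)
  expect_equal(fit$loglik, -fit$deviance / 2)
})

test_that("ML optimum agrees with the reference mixed-model implementation", {
  skip_if_not_installed("lme4")
  dat <- simulate_dataset(reference_config(n_subjects = 25, seed = 63))
  df <- as.data.frame(dat)
  fit <- fit_lmm(dat, "1 + d + u + d:u", "1 + d")
  m <- suppressWarnings(
    lme4::lmer(y ~ 1 + d + u + d:u + (1 + d | subject), data = df,
               REML = FALSE))
  expect_equal(fit$deviance, unname(deviance(m)), tolerance = 1e-6)
  expect_equal(fit$fixed$estimate, unname(lme4::fixef(m)), tolerance = 1e-5)
  expect_equal(fit$fixed$se,
               unname(stats::coef(summary(m))[, "Std. Error"]), tolerance = 1e-3)
  vc <- lme4::VarCorr(m)$subject
  expect_equal(unclass(fit$Psi), vc[1:2, 1:2], tolerance = 1e-3,
               ignore_attr = TRUE)

  fitR <- fit_lmm(dat, "1 + d + u + d:u", "1 + d", method = "REML")
  mR <- suppressWarnings(
    lme4::lmer(y ~ 1 + d + u + d:u + (1 + d | subject), data = df,
               REML = TRUE))
  expect_equal(fitR$deviance, unname(lme4::REMLcrit(mR)), tolerance = 1e-6)
})

test_that("empty random part reduces to ordinary least squares", {
  dat <- simulate_dataset(reference_config(n_subjects = 10, seed = 64))
  fit <- fit_lmm(dat, "1 + d + u", random = NULL)
  ols <- stats::lm(y ~ d + u, data = as.data.frame(dat))
  expect_equal(fit$fixed$estimate, unname(stats::coef(ols)), tolerance = 1e-10)
  expect_equal(fit$loglik, unname(as.numeric(stats::logLik(ols))), tolerance = 1e-8)
})

test_that("unbalanced data (missing rows) are tolerated and match the reference", {
  skip_if_not_installed("lme4")
  dat <- simulate_dataset(reference_config(n_subjects = 15, seed = 65))
  dat2 <- as_gradient_data(as.data.frame(dat)[-c(3, 27, 101, 140), ])
  fit <- fit_lmm(dat2, "1 + d + u + d:u", "1 + d")
  m <- lme4::lmer(y ~ 1 + d + u + d:u + (1 + d | subject),
                  data = as.data.frame(dat2), REML = FALSE)
  expect_equal(fit$deviance, unname(deviance(m)), tolerance = 1e-6)
})

test_that("the likelihood is invariant to shifting the stimulus coding", {
  dat <- simulate_dataset(reference_config(n_subjects = 20, seed = 66))
  fit0 <- fit_lmm(dat, "1 + d + u + d:u", "1 + d")
  shifted <- as.data.frame(dat); shifted$d <- shifted$d - 4
  fit1 <- fit_lmm(as_gradient_data(shifted), "1 + d + u + d:u", "1 + d")
  expect_equal(fit0$deviance, fit1$deviance, tolerance = 1e-5)
  expect_equal(fit0$sigma2, fit1$sigma2, tolerance = 1e-4)
  # slope-level quantities are unchanged by the intercept reparameterization
  expect_equal(fit0$fixed$p[fit0$fixed$term == "d:u"],
               fit1$fixed$p[fit1$fixed$term == "d:u"], tolerance = 1e-4)
})

test_that("adding free parameters never increases the ML deviance", {
  dat <- simulate_dataset(reference_config(n_subjects = 20, seed = 67))
  ladder <- list(
    fit_lmm(dat, "1 + d", "1"),
    fit_lmm(dat, "1 + d", "1 + d"),
    fit_lmm(dat, "1 + d + u + d:u", "1 + d"),
    fit_lmm(dat, "1 + d + d2 + u + d:u", "1 + d"))
  devs <- vapply(ladder, function(f) f$deviance, 0)
  expect_true(all(diff(devs) <= 1e-4))
})

test_that("reference generator parameters are recovered at n = 2000", {
  cfg <- reference_config(n_subjects = 2000, gamma11 = 0.10, seed = 68)
  dat <- simulate_dataset(cfg)
  fit <- fit_lmm(dat, "1 + d + u + d:u", "1 + d")
  truth <- c(7.91871, -0.58322, -0.37375, 0.10)
  expect_true(all(abs(fit$fixed$estimate - truth) / fit$fixed$se < 3))
  expect_equal(fit$Psi[1, 1], 2.5324, tolerance = 0.05)
  expect_equal(fit$Psi[2, 2], 0.1345, tolerance = 0.05)
  expect_equal(fit$Psi[1, 2], -0.46, tolerance = 0.05)
  expect_equal(fit$sigma2, 2.4348, tolerance = 0.05)
})
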