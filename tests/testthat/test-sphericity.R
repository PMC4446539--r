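fixture_8x4 <- function() {
  # fixed 8-subject x 4-level integer matrix, two groups of 4
  Y <- matrix(c(7, 5, 4, 1,
                6, 6, 3, 2,
                8, 4, 4, 3,
                5, 5, 2, 1,
                9, 6, 5, 2,
                7, 7, 3, 1,
                6, 4, 2, 2,
                8, 5, 6, 4), nrow = 8, byrow = TRUE)
  list(Y = Y, group = factor(rep(c("a", "b"), each = 4)))
}

wide_of <- function(Y, group = NULL) {
  dat <- data.frame(
    subject = factor(rep(seq_len(nrow(Y)), each = ncol(Y))),
    d = rep(seq_len(ncol(Y)) - 1, nrow(Y)),
    u = rep(0, length(Y)),
    y = as.vector(t(Y)))
  pivot_wide(as_gradient_data(dat), group = group)
}

test_that("Mauchly W matches the eigenvalue route and the reference implementation", {
  fx <- fixture_8x4()
  w <- wide_of(fx$Y, fx$group)
  mt <- mauchly_test(w)

  # eigenvalue oracle: W = prod(lambda) / (mean(lambda))^p on the pooled
  # contrast covariance, built here from scratch
  ctr <- fx$Y
  for (g in levels(fx$group)) {
    idx <- fx$group == g
    ctr[idx, ] <- sweep(fx$Y[idx, ], 2, colMeans(fx$Y[idx, ]))
  }
  S_full <- crossprod(ctr) / (8 - 2)
  C <- t(qr.Q(qr(stats::contr.helmert(4))))
  lam <- eigen(C %*% S_full %*% t(C), symmetric = TRUE, only.values = TRUE)$values
  p <- 3
  W_eig <- prod(lam) / mean(lam)^p
  expect_equal(mt$W, W_eig, tolerance = 1e-12)
  expect_equal(mt$df, p * (p + 1) / 2 - 1)
  expect_equal(mt$chi2, -(6 - (2 * p^2 + p + 2) / (6 * p)) * log(W_eig),
               tolerance = 1e-12)

  # reference implementation on the same pooled SSD (statistic only: the
  # reference p-value uses a higher-order chi-square expansion)
  mlm <- stats::lm(fx$Y ~ fx$group)
  ref <- stats::mauchly.test(mlm, X = ~1)
  expect_equal(unname(mt$W), unname(ref$statistic), tolerance = 1e-10)
})

test_that("two within levels are trivially spherical", {
  w <- wide_of(matrix(rnorm(12), 6, 2), factor(rep(c("a", "b"), 3)))
  mt <- mauchly_test(w)
  expect_equal(mt$W, 1)
  expect_equal(mt$df, 0L)
  expect_equal(mt$p_value, 1)
  expect_equal(mt$flag, "trivially_spherical")
})

test_that("epsilon estimates: trace formula == eigenvalue formula, car agreement, bounds", {
  fx <- fixture_8x4()
  w <- wide_of(fx$Y, fx$group)
  eps <- epsilon_estimates(w)

  ctr <- fx$Y
  for (g in levels(fx$group)) {
    idx <- fx$group == g
    ctr[idx, ] <- sweep(fx$Y[idx, ], 2, colMeans(fx$Y[idx, ]))
  }
  C <- t(qr.Q(qr(stats::contr.helmert(4))))
  lam <- eigen(C %*% (crossprod(ctr) / 6) %*% t(C), symmetric = TRUE,
               only.values = TRUE)$values
  expect_equal(eps$gg, sum(lam)^2 / (3 * sum(lam^2)), tolerance = 1e-12)
  expect_equal(eps$lower_bound, 1 / 3)
  expect_gte(eps$hf, eps$gg)
  expect_lte(eps$gg, 1)

  skip_if_not_installed("car")
  mlm <- stats::lm(fx$Y ~ fx$group)
  idata <- data.frame(lev = factor(1:4))
  A <- summary(car::Anova(mlm, idata = idata, idesign = ~lev, type = 3),
               multivariate = FALSE)
  expect_equal(unname(eps$gg), unname(A$pval.adjustments[1, "GG eps"]),
               tolerance = 1e-10)
  expect_equal(unname(eps$hf), unname(min(A$pval.adjustments[1, "HF eps"], 1)),
               tolerance = 1e-10)
})

test_that("lower bound with 10 stimuli is 1/9", {
  dat <- simulate_dataset(reference_config(n_subjects = 12, seed = 31))
  w <- pivot_wide(dat, group = median_split(attr(dat, "effects")$u))
  eps <- epsilon_estimates(w)
  expect_equal(eps$lower_bound, 1 / 9)
})

test_that("an exactly spherical covariance gives epsilon = 1 and W = 1", {
  # construct responses whose column covariance is exactly the identity
  set.seed(17)
  n <- 12; k <- 4
  M <- scale(matrix(rnorm(n * k), n, k), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(M))
  Y <- Q * sqrt(n - 1)                       # cov(Y) == I_k exactly
  w <- wide_of(Y)                            # one-sample pooled covariance
  eps <- epsilon_estimates(w)
  mt <- mauchly_test(w)
  expect_equal(eps$gg, 1, tolerance = 1e-10)
  expect_equal(mt$W, 1, tolerance = 1e-10)
})

test_that("Mauchly and epsilons are invariant to the orthonormal contrast basis", {
  dat <- simulate_dataset(reference_config(n_subjects = 25, seed = 41))
  w <- pivot_wide(dat, group = median_split(attr(dat, "effects")$u))
  expect_equal(mauchly_test(w, basis = "helmert")$W,
               mauchly_test(w, basis = "poly")$W, tolerance = 1e-12)
  expect_equal(epsilon_estimates(w, basis = "helmert")$gg,
               epsilon_estimates(w, basis = "poly")$gg, tolerance = 1e-12)
})

test_that("Mauchly rejects at the nominal rate under compound symmetry", {
  set.seed(53)
  reps <- 2000
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    Y <- simulate_compound_symmetry(200, 4)
    w <- wide_of(Y)
    rej[r] <- mauchly_test(w)$p_value < 0.05
  }
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
})

test_that("too few error df for the contrast dimension is a clear error", {
  Y <- matrix(rnorm(4 * 6), 4, 6)
  w <- wide_of(Y, factor(rep(c("a", "b"), each = 2)))
  expect_error(mauchly_test(w), "more subjects")
})
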