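toy_wide <- function() {
  # 2 groups x 3 subjects x 3 stimuli, small integers
  Y <- matrix(c(5, 4, 2,
                6, 5, 3,
                7, 5, 4,
                3, 3, 1,
                4, 2, 2,
                5, 3, 1), nrow = 6, byrow = TRUE,
              dimnames = list(paste0("s", 1:6), c("d0", "d1", "d2")))
  list(Y = Y, group = factor(rep(c("low", "high"), each = 3),
                             levels = c("low", "high")))
}

wide_from_matrix <- function(Y, group, d = seq_len(ncol(Y)) - 1) {
  dat <- data.frame(
    subject = factor(rep(seq_len(nrow(Y)), each = ncol(Y))),
    d = rep(d, nrow(Y)),
    u = rep(seq_len(nrow(Y)), each = ncol(Y)),
    y = as.vector(t(Y)))
  pivot_wide(as_gradient_data(dat), group = group)
}

test_that("split-plot SS equal a brute-force mean decomposition on a toy table", {
  tw <- toy_wide()
  w <- wide_from_matrix(tw$Y, tw$group)
  res <- split_plot_anova(w)
  bf <- brute_force_split_plot(tw$Y, tw$group)
  tab <- res$table
  expect_equal(tab$SS[tab$effect == "Group"], bf$group)
  expect_equal(tab$SS[tab$effect == "Subjects-within-groups"], bf$subj)
  expect_equal(tab$SS[tab$effect == "Stimulus"], bf$stim)
  expect_equal(tab$SS[tab$effect == "Stimulus:Group"], bf$inter)
  expect_equal(tab$SS[tab$effect == "Within-error"], bf$err)
  expect_equal(tab$df, c(1, 4, 2, 2, 8))
})

test_that("split-plot table matches aov strata on random fixtures, equal and unequal groups", {
  for (n in c(12, 15)) {                       # 15 -> unequal 7/8 split
    set.seed(100 + n)
    cfg <- reference_config(n_subjects = n)
    dat <- simulate_dataset(cfg, seed = 100 + n)
    grp <- median_split(attr(dat, "effects")$u)
    w <- pivot_wide(dat, group = grp)
    res <- split_plot_anova(w)

    df <- as.data.frame(dat)
    df$grp <- grp[as.integer(df$subject)]
    df$ds <- factor(df$d)
    a <- summary(stats::aov(y ~ grp * ds + Error(subject / ds), data = df))
    btw <- a[["Error: subject"]][[1]]
    wth <- a[["Error: subject:ds"]][[1]]
    tab <- res$table
    expect_equal(tab$SS[tab$effect == "Group"], btw["grp", "Sum Sq"], tolerance = 1e-10)
    expect_equal(tab$SS[tab$effect == "Subjects-within-groups"],
                 btw["Residuals", "Sum Sq"], tolerance = 1e-10)
    expect_equal(tab$SS[tab$effect == "Stimulus"], wth["ds", "Sum Sq"], tolerance = 1e-10)
    expect_equal(tab$SS[tab$effect == "Stimulus:Group"],
                 wth["grp:ds", "Sum Sq"], tolerance = 1e-10)
    expect_equal(tab$F[tab$effect == "Stimulus:Group"],
                 wth["grp:ds", "F value"], tolerance = 1e-10)
    expect_equal(tab$p[tab$effect == "Stimulus:Group"],
                 wth["grp:ds", "Pr(>F)"], tolerance = 1e-10)
    # conservation on every fixture
    expect_equal(res$ss_total, sum(tab$SS), tolerance = 1e-10)
  }
})

test_that("degenerate inputs are flagged, not silently divided", {
  Y <- matrix(5, nrow = 4, ncol = 3)
  w <- wide_from_matrix(Y, factor(rep(c("low", "high"), each = 2)))
  res <- split_plot_anova(w)
  expect_equal(res$flag, "undefined")
  expect_true(all(res$table$SS == 0))
  expect_true(all(is.na(res$table$F[c(1, 3, 4)])))

  # single group is rejected
  w1 <- wide_from_matrix(matrix(rnorm(12), 4), factor(rep("low", 4)))
  expect_error(split_plot_anova(w1), "at least two groups")
})

test_that("pivot_wide round-trips values and rejects unbalanced input", {
  dat <- simulate_dataset(reference_config(n_subjects = 5, seed = 2))
  w <- pivot_wide(dat)
  expect_equal(dim(w$matrix), c(5, 10))
  # every y value preserved
  for (s in 1:5)
    expect_equal(unname(w$matrix[s, ]), dat$y[dat$subject == s][order(dat$d[dat$subject == s])])
  broken <- as.data.frame(dat)[-7, ]            # drops a row of subject 1
  expect_error(pivot_wide(as_gradient_data(broken)), "subject.*1")
})

test_that("epsilon-corrected p-values behave as the correction dictates", {
  tw <- toy_wide()
  w <- wide_from_matrix(tw$Y, tw$group)
  res <- split_plot_anova(w)
  # epsilon = 1 is the identity correction
  ct1 <- corrected_tests(res, 1)
  tab <- res$table
  expect_equal(ct1$p, tab$p[match(c("Stimulus", "Stimulus:Group"), tab$effect)])
  # out-of-range epsilon rejected
  expect_error(corrected_tests(res, 0.2), "1/\\(k-1\\)")
  expect_error(corrected_tests(res, 1.2), "1/\\(k-1\\)")
  # monotonicity: for F > 1, smaller epsilon -> larger p (sweep over a grid)
  for (F_ in c(1.5, 3, 10)) for (eps in c(0.6, 0.8, 0.95)) {
    p_unc <- stats::pf(F_, 9, 90, lower.tail = FALSE)
    p_cor <- stats::pf(F_, 9 * eps, 90 * eps, lower.tail = FALSE)
    expect_gt(p_cor, p_unc)
  }
})
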