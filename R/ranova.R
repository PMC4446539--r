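#' Median split of a continuous subject covariate
#'
#' Dichotomizes `u` at its sample median (midpoint of the central order
#' statistics). Two tie-handling conventions are in circulation and they can
#' disagree whenever observations sit exactly at the median:
#' `"low_strict"` assigns `low` iff `u < median(u)` (ties at the median go to
#' `high`); `"low_inclusive"` assigns `low` iff `u <= median(u)` (ties go to
#' `low`). The choice looks trivial but can flip downstream ANOVA
#' conclusions; see [split_sensitivity()].
#'
#' @param u per-subject numeric values.
#' @param convention `"low_strict"` or `"low_inclusive"`.
#' @return factor with levels `low`, `high`, same length as `u`.
#' @examples
#' median_split(c(1, 2, 2, 3), "low_strict")     # low high high high
#' median_split(c(1, 2, 2, 3), "low_inclusive")  # low low  low  high
#' @export
median_split <- function(u, convention = c("low_strict", "low_inclusive")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(u), !anyNA(u))
  if (length(u) < 2L) stop("need at least 2 subjects to split")
  m <- stats::median(u)
  low <- if (convention == "low_strict") u < m else u <= m
  if (all(low) || !any(low))
    warning("median split produced a single group (all `u` on one side of the median)")
  factor(ifelse(low, "low", "high"), levels = c("low", "high"))
}

#' Pivot long gradient data to a subjects-by-stimuli response matrix
#'
#' @param data a gradient dataset (see [as_gradient_data()]); must be
#'   complete and balanced — every subject observed once at every `d`.
#' @param group optional per-subject labels (in subject order) attached for
#'   the split-plot analysis.
#' @return A list of class `"wide_responses"`: `matrix` (subjects x stimuli,
#'   columns in ascending `d` order), `d_values`, `subjects`, `group`
#'   (possibly `NULL`), `u` (per subject).
#' @export
pivot_wide <- function(data, group = NULL) {
  data <- as_gradient_data(data)
  d_levels <- sort(unique(data$d))
  subjects <- levels(data$subject)
  tab <- table(data$subject, factor(data$d, levels = d_levels))
  bad <- rownames(tab)[apply(tab != 1L, 1L, any)]
  if (length(bad))
    stop("incomplete or duplicated cells for subject(s): ",
         paste(bad, collapse = ", "),
         " — the split-plot ANOVA requires complete balanced data")
  ord <- order(data$subject, data$d)
  m <- matrix(data$y[ord], nrow = length(subjects), ncol = length(d_levels),
              byrow = TRUE, dimnames = list(subjects, paste0("d", d_levels)))
  u <- data$u[ord][seq(1L, by = length(d_levels), length.out = length(subjects))]
  if (!is.null(group)) {
    if (length(group) != length(subjects))
      stop("`group` must have one label per subject")
    group <- factor(group)
  }
  structure(list(matrix = m, d_values = d_levels, subjects = subjects,
                 group = group, u = u),
            class = "wide_responses")
}

#' Balanced split-plot (mixed between/within) ANOVA
#'
#' Classical sums-of-squares decomposition for one between-subject group
#' factor and one within-subject stimulus factor, subjects nested in groups,
#' every subject measured at every stimulus. The between stratum tests Group
#' against subjects-within-groups; the within stratum tests Stimulus and the
#' Stimulus-by-Group interaction against the within error. Group sizes may
#' differ (the within factor is still balanced), in which case group and cell
#' means are weighted by group size.
#'
#' @param wide a [pivot_wide()] result with a `group` factor of at least two
#'   levels, each with at least 2 subjects.
#' @return An object of class `"ranova"`: `table` (data.frame with rows
#'   Group, Subjects-within-groups, Stimulus, Stimulus:Group, Within-error
#'   and columns SS, df, MS, F, p), `ss_total`, plus the design sizes.
#'   `F` and `p` are `NA` with `flag = "undefined"` when an error mean square
#'   is zero.
#' @export
split_plot_anova <- function(wide) {
  stopifnot(inherits(wide, "wide_responses"))
  Y <- wide$matrix
  g <- wide$group
  if (is.null(g)) stop("`wide` carries no group labels; attach one via pivot_wide(group=)")
  g <- droplevels(factor(g))
  n <- nrow(Y); k <- ncol(Y); glev <- levels(g); ng <- length(glev)
  if (ng < 2L) stop("need at least two groups with subjects; got ", ng)
  sizes <- table(g)
  if (any(sizes < 2L)) stop("every group needs at least 2 subjects")

  grand <- mean(Y)
  subj_means <- rowMeans(Y)
  stim_means <- colMeans(Y)
  grp_means <- tapply(subj_means, g, mean)          # per-group mean over all cells
  cell_means <- apply(Y, 2L, function(col) tapply(col, g, mean))  # ng x k

  ss_total <- sum((Y - grand)^2)
  ss_between_subj <- k * sum((subj_means - grand)^2)
  ss_group <- k * sum(sizes * (grp_means - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_stim <- n * sum((stim_means - grand)^2)
  ss_inter <- sum(as.numeric(sizes) *
                    (cell_means - outer(as.numeric(grp_means), rep(1, k)) -
                       outer(rep(1, ng), stim_means) + grand)^2)
  ss_err <- ss_total - ss_between_subj - ss_stim - ss_inter

  df_group <- ng - 1L
  df_subj  <- n - ng
  df_stim  <- k - 1L
  df_inter <- (k - 1L) * (ng - 1L)
  df_err   <- (n - ng) * (k - 1L)

  ms <- c(ss_group / df_group, ss_subj_within / df_subj,
          ss_stim / df_stim, ss_inter / df_inter, ss_err / df_err)
  f_group <- if (ms[2L] > 0) ms[1L] / ms[2L] else NA_real_
  f_stim  <- if (ms[5L] > 0) ms[3L] / ms[5L] else NA_real_
  f_inter <- if (ms[5L] > 0) ms[4L] / ms[5L] else NA_real_

  tab <- data.frame(
    effect = c("Group", "Subjects-within-groups", "Stimulus",
               "Stimulus:Group", "Within-error"),
    SS = c(ss_group, ss_subj_within, ss_stim, ss_inter, ss_err),
    df = c(df_group, df_subj, df_stim, df_inter, df_err),
    MS = ms,
    F = c(f_group, NA, f_stim, f_inter, NA),
    p = c(if (is.na(f_group)) NA_real_ else
            stats::pf(f_group, df_group, df_subj, lower.tail = FALSE),
          NA,
          if (is.na(f_stim)) NA_real_ else
            stats::pf(f_stim, df_stim, df_err, lower.tail = FALSE),
          if (is.na(f_inter)) NA_real_ else
            stats::pf(f_inter, df_inter, df_err, lower.tail = FALSE),
          NA),
    row.names = NULL)

  structure(list(table = tab, ss_total = ss_total,
                 n_subjects = n, n_stimuli = k, n_groups = ng,
                 flag = if (ms[5L] == 0 || ms[2L] == 0) "undefined" else "ok"),
            class = "ranova")
}

#' @export
print.ranova <- function(x, ...) {
  cat(sprintf("Split-plot ANOVA: %d subjects, %d groups, %d stimuli\n",
              x$n_subjects, x$n_groups, x$n_stimuli))
  tab <- x$table
  tab$SS <- signif(tab$SS, 6); tab$MS <- signif(tab$MS, 6)
  tab$F <- signif(tab$F, 5); tab$p <- signif(tab$p, 4)
  print(tab, row.names = FALSE)
  if (!is.null(x$sphericity)) {
    cat(sprintf("Mauchly W = %.4g, chi2(%d) = %.4g, p = %.4g\n",
                x$sphericity$W, x$sphericity$df, x$sphericity$chi2,
                x$sphericity$p_value))
    cat(sprintf("epsilon: GG = %.4g, HF = %.4g, lower bound = %.4g\n",
                x$epsilons$gg, x$epsilons$hf, x$epsilons$lower_bound))
  }
  invisible(x)
}

# Orthonormal contrast basis: p x k matrix with orthonormal rows, each
# orthogonal to the unit vector (normalized Helmert contrasts by default).
contrast_basis <- function(k, type = c("helmert", "poly")) {
  type <- match.arg(type)
  C <- switch(type,
    helmert = stats::contr.helmert(k),
    poly = stats::contr.poly(k))
  C <- qr.Q(qr(C))          # orthonormal columns, already orthogonal to 1
  t(C)
}

# Pooled within-group covariance of the k responses, divisor n - g.
pooled_covariance <- function(wide) {
  Y <- wide$matrix
  g <- wide$group
  if (is.null(g)) g <- factor(rep(1L, nrow(Y)))
  g <- droplevels(factor(g))
  n <- nrow(Y); ng <- nlevels(g)
  ctr <- Y
  for (lev in levels(g)) {
    idx <- g == lev
    ctr[idx, ] <- sweep(Y[idx, , drop = FALSE], 2L,
                        colMeans(Y[idx, , drop = FALSE]))
  }
  list(S = crossprod(ctr) / (n - ng), n_e = n - ng)
}

#' Mauchly's test of sphericity
#'
#' Tests whether the covariance of orthonormal within-subject contrasts is
#' proportional to the identity. With `S = C Sigma C'` the p x p contrast
#' covariance (p = k - 1, `Sigma` the pooled within-group covariance on
#' `n_e = n - g` error df), the statistic is
#' `W = det(S) / (tr(S)/p)^p`, referred to chi-square via
#' `-(n_e - (2p^2 + p + 2)/(6p)) log W` on `p(p+1)/2 - 1` df.
#'
#' @param wide a [pivot_wide()] result; group labels, when present, define
#'   the pooled covariance.
#' @param basis orthonormal contrast family; the statistic is invariant to
#'   this choice.
#' @return list of class `"sphericity_test"` with `W`, `chi2`, `df`,
#'   `p_value`, `n_e`, and `flag` (`"ok"` or `"trivially_spherical"` when
#'   k = 2).
#' @export
mauchly_test <- function(wide, basis = c("helmert", "poly")) {
  stopifnot(inherits(wide, "wide_responses"))
  k <- ncol(wide$matrix)
  if (k < 2L) stop("need at least 2 within-subject levels")
  pc <- pooled_covariance(wide)
  if (k == 2L)
    return(structure(list(W = 1, chi2 = 0, df = 0L, p_value = 1,
                          n_e = pc$n_e, flag = "trivially_spherical"),
                     class = "sphericity_test"))
  p <- k - 1L
  if (pc$n_e < p)
    stop("error df (n - g = ", pc$n_e, ") below the ", p,
         " contrast dimensions; the contrast covariance is singular — ",
         "more subjects than within-factor levels are required")
  C <- contrast_basis(k, match.arg(basis))
  S <- C %*% pc$S %*% t(C)
  detS <- det(S)
  if (detS <= 0)
    stop("singular contrast covariance; more subjects than within-factor levels are required")
  W <- detS / (sum(diag(S)) / p)^p
  chi2 <- -(pc$n_e - (2 * p^2 + p + 2) / (6 * p)) * log(W)
  df <- as.integer(p * (p + 1) / 2 - 1)
  structure(list(W = W, chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 n_e = pc$n_e, flag = "ok"),
            class = "sphericity_test")
}

#' Sphericity-correction factors (epsilon estimates)
#'
#' Greenhouse-Geisser `eps = (tr S)^2 / (p tr(S^2))`, the Huynh-Feldt
#' refinement `((n_e + 1) p eps - 2) / (p (n_e - p eps))` capped at 1, and
#' the lower bound `1/p`, with `S` the orthonormal-contrast covariance of
#' [mauchly_test()] and `p = k - 1`.
#'
#' @inheritParams mauchly_test
#' @return list of class `"epsilon_estimates"` with `gg`, `hf`,
#'   `lower_bound`.
#' @export
epsilon_estimates <- function(wide, basis = c("helmert", "poly")) {
  stopifnot(inherits(wide, "wide_responses"))
  k <- ncol(wide$matrix)
  if (k < 2L) stop("need at least 2 within-subject levels")
  p <- k - 1L
  pc <- pooled_covariance(wide)
  if (k == 2L)
    return(structure(list(gg = 1, hf = 1, lower_bound = 1), class = "epsilon_estimates"))
  if (pc$n_e < p)
    stop("error df below contrast dimension; epsilon undefined")
  C <- contrast_basis(k, match.arg(basis))
  S <- C %*% pc$S %*% t(C)
  tr <- sum(diag(S))
  gg <- tr^2 / (p * sum(S * S))           # tr(S^2) = sum of squared entries (S symmetric)
  hf <- ((pc$n_e + 1) * p * gg - 2) / (p * (pc$n_e - p * gg))
  structure(list(gg = gg, hf = min(hf, 1), lower_bound = 1 / p),
            class = "epsilon_estimates")
}

#' Epsilon-corrected within-stratum p-values
#'
#' Recomputes the Stimulus and Stimulus-by-Group p-values from the unchanged
#' F statistics with both degrees of freedom multiplied by `epsilon`.
#'
#' @param result a [split_plot_anova()] result.
#' @param epsilon correction factor in `[1/(k-1), 1]`.
#' @return data.frame with rows Stimulus and Stimulus:Group and columns
#'   `F`, `df1`, `df2`, `p` (corrected).
#' @export
corrected_tests <- function(result, epsilon) {
  stopifnot(inherits(result, "ranova"))
  p <- result$n_stimuli - 1L
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon < 1 / p - 1e-12 || epsilon > 1 + 1e-12)
    stop("`epsilon` must lie in [1/(k-1), 1]")
  tab <- result$table
  rows <- match(c("Stimulus", "Stimulus:Group"), tab$effect)
  df_err <- tab$df[tab$effect == "Within-error"]
  out <- data.frame(
    effect = tab$effect[rows],
    F = tab$F[rows],
    df1 = tab$df[rows] * epsilon,
    df2 = df_err * epsilon,
    p = ifelse(is.na(tab$F[rows]), NA_real_,
               stats::pf(tab$F[rows], tab$df[rows] * epsilon,
                         df_err * epsilon, lower.tail = FALSE)),
    row.names = NULL)
  out
}

#' One-shot split-plot analysis of a gradient dataset
#'
#' Convenience wrapper: median-splits `u`, pivots wide, runs the split-plot
#' ANOVA, Mauchly's test, the epsilon estimates, and attaches GG-, HF- and
#' lower-bound-corrected p-values for the within-stratum effects.
#'
#' @param data a gradient dataset.
#' @param convention tie convention for [median_split()].
#' @return A `"ranova"` object with elements `sphericity`, `epsilons` and
#'   `corrected` (list of data.frames `gg`, `hf`, `lb`) added.
#' @export
ranova <- function(data, convention = c("low_strict", "low_inclusive")) {
  data <- as_gradient_data(data)
  convention <- match.arg(convention)
  u_subj <- tapply(data$u, data$subject, function(v) v[1L])
  grp <- median_split(as.numeric(u_subj), convention)
  wide <- pivot_wide(data, group = grp)
  res <- split_plot_anova(wide)
  res$sphericity <- mauchly_test(wide)
  res$epsilons <- epsilon_estimates(wide)
  res$corrected <- list(
    gg = corrected_tests(res, res$epsilons$gg),
    hf = corrected_tests(res, res$epsilons$hf),
    lb = corrected_tests(res, res$epsilons$lower_bound))
  res$convention <- convention
  res
}
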