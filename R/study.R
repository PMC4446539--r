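#' Design of the Monte-Carlo comparison study
#'
#' The study crosses sample size with the size of the cross-level
#' interaction `gamma11` (3 x 3 = 9 conditions under the defaults), draws
#' `replicates` datasets per condition from the two-level generator, and on
#' each dataset runs four tests at level `alpha`: Mauchly's sphericity test,
#' the uncorrected split-plot interaction F test (moderator median-split into
#' two groups), the Greenhouse-Geisser-corrected version of the same test,
#' and the mixed-model Wald z test of the cross-level interaction with the
#' moderator kept continuous.
#'
#' @param sample_sizes subject counts (default `c(20, 38, 55)`).
#' @param gamma11_levels interaction sizes (default `c(0, 0.05, 0.10)`).
#' @param replicates Monte-Carlo samples per condition (default 1500).
#' @param alpha test level (default 0.05).
#' @param base_config generating parameters; `n_subjects` and `gamma11` are
#'   overridden per condition (default [reference_config()]).
#' @param master_seed integer; per-condition seeds are derived from it
#'   deterministically so any condition can be re-run in isolation.
#' @param convention median-split tie convention used for the ANOVA arm.
#' @return list of class `"study_design"`.
#' @export
study_design <- function(sample_sizes = c(20L, 38L, 55L),
                         gamma11_levels = c(0, 0.05, 0.10),
                         replicates = 1500L,
                         alpha = 0.05,
                         base_config = reference_config(),
                         master_seed = 1L,
                         convention = c("low_strict", "low_inclusive")) {
  stopifnot(replicates >= 1L, alpha > 0, alpha < 1,
            inherits(base_config, "sim_config"))
  structure(list(sample_sizes = as.integer(sample_sizes),
                 gamma11_levels = gamma11_levels,
                 replicates = as.integer(replicates),
                 alpha = alpha, base_config = base_config,
                 master_seed = as.integer(master_seed),
                 convention = match.arg(convention)),
            class = "study_design")
}

# Deterministic per-condition substream seed, kept within 32-bit range.
condition_seed <- function(master_seed, n, gamma11) {
  s <- (as.double(master_seed) * 1000003 + as.double(n) * 7919 +
          round(gamma11 * 1000) * 104729 + 17) %% 2147483647
  as.integer(s)
}

#' Run one condition of the Monte-Carlo study
#'
#' @param n number of subjects.
#' @param gamma11 cross-level interaction size.
#' @param design a [study_design()].
#' @return one-row data.frame: `n`, `gamma11`,
#'   `prop_sphericity_reject`, `prop_ranova_reject`,
#'   `prop_ranova_gg_reject`, `prop_hlm_reject`, `n_failed_fits`.
#'   Proportions are computed over successful analyses; failures are
#'   counted in `n_failed_fits` and excluded from their own denominator.
#' @export
run_condition <- function(n, gamma11, design) {
  stopifnot(inherits(design, "study_design"))
  bc <- design$base_config
  cfg <- sim_config(
    n_subjects = n,
    gamma00 = bc$gamma00, gamma10 = bc$gamma10,
    gamma01 = bc$gamma01, gamma11 = gamma11,
    tau00 = bc$tau00, tau11 = bc$tau11, tau01 = bc$tau01,
    sigma2_eps = bc$sigma2_eps, d_values = bc$d_values,
    u_spec = bc$u_spec)
  set.seed(condition_seed(design$master_seed, n, gamma11))
  alpha <- design$alpha
  R <- design$replicates
  sph <- ran <- gg <- hlm <- logical(0)
  n_failed <- 0L
  for (r in seq_len(R)) {
    dat <- simulate_dataset(cfg, seed = NULL)
    res <- tryCatch({
      u_subj <- attr(dat, "effects")$u
      grp <- median_split(u_subj, design$convention)
      wide <- pivot_wide(dat, group = grp)
      an <- split_plot_anova(wide)
      mt <- mauchly_test(wide)
      eps <- epsilon_estimates(wide)
      ct <- corrected_tests(an, eps$gg)
      p_int <- an$table$p[an$table$effect == "Stimulus:Group"]
      p_gg <- ct$p[ct$effect == "Stimulus:Group"]
      fit <- fit_lmm(dat, spec = lmm_spec("1 + d + u + d:u", "1 + d", "ML"))
      if (!fit$converged) stop("mixed-model fit did not converge")
      p_g11 <- fit$fixed$p[fit$fixed$term == "d:u"]
      c(mt$p_value, p_int, p_gg, p_g11)
    }, error = function(e) NULL)
    if (is.null(res) || anyNA(res)) {
      n_failed <- n_failed + 1L
    } else {
      sph <- c(sph, res[1L] < alpha)
      ran <- c(ran, res[2L] < alpha)
      gg  <- c(gg,  res[3L] < alpha)
      hlm <- c(hlm, res[4L] < alpha)
    }
  }
  data.frame(n = n, gamma11 = gamma11,
             prop_sphericity_reject = mean(sph),
             prop_ranova_reject = mean(ran),
             prop_ranova_gg_reject = mean(gg),
             prop_hlm_reject = mean(hlm),
             n_failed_fits = n_failed)
}

#' Run the full study grid
#'
#' @param design a [study_design()].
#' @param verbose print per-condition progress.
#' @return data.frame of class `"study_table"`, one row per condition,
#'   ordered by (`n`, `gamma11`).
#' @export
run_grid <- function(design, verbose = interactive()) {
  stopifnot(inherits(design, "study_design"))
  rows <- list()
  for (n in sort(design$sample_sizes)) {
    for (g11 in sort(design$gamma11_levels)) {
      t0 <- Sys.time()
      row <- run_condition(n, g11, design)
      if (isTRUE(verbose))
        message(sprintf("condition n=%d gamma11=%.2f done in %.1fs", n, g11,
                        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("study_table", class(out))
  out
}
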