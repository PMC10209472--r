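# Seeded generator of two-sample GWAS summary statistics with known causal
# effect and pleiotropy structure, plus a parameter-recovery harness.
#
# Statistics are generated directly on the (beta, se) scale - the object the
# analysis consumes - rather than from individual-level genotypes. Default
# noise ranges put per-variant F-statistics roughly in the 10-100 range
# typical of genome-wide significant instruments for a common trait.

#' Simulation configuration
#'
#' Describes one synthetic two-sample world: `k` independent instruments with
#' true gene-exposure effects `gamma_j` (default `|Normal(0, 0.1^2)| + 0.1`,
#' so instruments are never null), a causal slope `beta_true` on the log-odds
#' scale, per-variant standard errors drawn uniformly from `se_x_range` /
#' `se_y_range`, and a pleiotropy scenario for the direct effects `alpha_j`:
#'
#' * `none`: `alpha_j = 0`;
#' * `balanced`: `alpha_j ~ Normal(0, tau^2)` (InSIDE holds, mean zero);
#' * `directional`: `alpha_j ~ Normal(mu_alpha, tau^2)` (InSIDE holds,
#'   nonzero mean — biases IVW, not Egger);
#' * `correlated`: `alpha_j = rho * gamma_j + Normal(0, tau^2)` (violates
#'   InSIDE).
#'
#' Additionally `n_outliers` variants can be given a large fixed direct
#' effect `outlier_alpha * gy_se_j` (sign alternating), planted to exceed
#' the Bonferroni Q-contribution threshold by construction.
#'
#' @param k number of instruments (>= 3).
#' @param beta_true causal log odds ratio of exposure on outcome.
#' @param gamma_dist function(k) returning k true gene-exposure effects;
#'   default `|Normal(0, 0.1^2)| + 0.1`. Together with the default
#'   `se_x_range` this puts per-variant F-statistics roughly in the 10-100+
#'   band of genome-wide significant instruments.
#' @param se_x_range,se_y_range length-2 positive uniform ranges for the
#'   gene-exposure and gene-outcome standard errors.
#' @param pleiotropy scenario name (see above).
#' @param tau standard deviation of the pleiotropic effects (default 0).
#' @param mu_alpha mean pleiotropic effect for `directional` (default 0).
#' @param rho gamma-alpha coupling for `correlated` (default 0).
#' @param n_outliers number of planted outlier variants (default 0).
#' @param outlier_alpha outlier direct effect in units of the variant's
#'   gene-outcome standard error (default 15: contribution ~ 225 against a
#'   Bonferroni chi-squared(1) threshold near 12).
#' @param seed integer root seed; all randomness flows from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(k = 30L, beta_true = 0.3,
                       gamma_dist = NULL,
                       se_x_range = c(0.02, 0.04),
                       se_y_range = c(0.05, 0.15),
                       pleiotropy = c("none", "balanced", "directional",
                                      "correlated"),
                       tau = 0, mu_alpha = 0, rho = 0,
                       n_outliers = 0L, outlier_alpha = 15,
                       seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(k >= 3L, length(se_x_range) == 2L, length(se_y_range) == 2L,
            all(se_x_range > 0), all(se_y_range > 0), tau >= 0,
            n_outliers >= 0L, n_outliers < k)
  if (is.null(gamma_dist)) {
    gamma_dist <- function(n) abs(stats::rnorm(n, 0, 0.1)) + 0.1
  }
  structure(list(k = as.integer(k), beta_true = beta_true,
                 gamma_dist = gamma_dist,
                 se_x_range = se_x_range, se_y_range = se_y_range,
                 pleiotropy = pleiotropy, tau = tau, mu_alpha = mu_alpha,
                 rho = rho, n_outliers = as.integer(n_outliers),
                 outlier_alpha = outlier_alpha, seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic replicate-seed splitting: stream r of root seed s is
# (s * 48271 + r) mod (2^31 - 1), kept strictly positive.
split_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 48271 + r) %% 2147483647) + 1L
}

#' Simulate two-sample GWAS summary statistics
#'
#' Draws true effects and sampling noise per the configuration:
#' `gx_hat_j = gamma_j + Normal(0, gx_se_j)` and
#' `gy_hat_j = beta_true * gamma_j + alpha_j + Normal(0, gy_se_j)`, with
#' exposure and outcome noise independent (the two-sample design). Variants
#' are written as non-palindromic A/G records with uniform allele
#' frequencies; p-values are two-sided normal. Fully reproducible from the
#' seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `exposure` and `outcome` ([gwas_table()] objects) and
#'   `truth` (list of class `sim_truth`: `beta_true`, `gamma`, `alpha`,
#'   `outlier_ids`).
#' @export
simulate_two_sample <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  k <- cfg$k
  gamma <- cfg$gamma_dist(k)
  se_x <- stats::runif(k, cfg$se_x_range[1], cfg$se_x_range[2])
  se_y <- stats::runif(k, cfg$se_y_range[1], cfg$se_y_range[2])
  alpha <- switch(cfg$pleiotropy,
    none = rep(0, k),
    balanced = stats::rnorm(k, 0, cfg$tau),
    directional = stats::rnorm(k, cfg$mu_alpha, cfg$tau),
    correlated = cfg$rho * gamma + stats::rnorm(k, 0, cfg$tau)
  )
  ids <- sprintf("rs%04d", seq_len(k))
  outlier_ids <- character(0)
  if (cfg$n_outliers > 0L) {
    oi <- seq_len(cfg$n_outliers)       # first variants, ids recorded
    # Each planted direct effect is outlier_alpha gene-outcome SEs, so its
    # Q contribution is ~ outlier_alpha^2 regardless of weight. Signs are
    # assigned greedily (largest influence on the pooled IVW estimate
    # first) so the planted set stays near-neutral for the pooled fit and
    # does not swamp clean variants.
    influence <- gamma[oi] / se_y[oi]
    sgn <- integer(cfg$n_outliers)
    running <- 0
    for (j in order(influence, decreasing = TRUE)) {
      sgn[j] <- if (running > 0) -1L else 1L
      running <- running + sgn[j] * influence[j]
    }
    alpha[oi] <- alpha[oi] + cfg$outlier_alpha * se_y[oi] * sgn
    outlier_ids <- ids[oi]
  }
  gx_hat <- gamma + stats::rnorm(k, 0, se_x)
  gy_hat <- cfg$beta_true * gamma + alpha + stats::rnorm(k, 0, se_y)
  eaf <- stats::runif(k, 0.1, 0.9)

  mk <- function(beta, se, label) {
    gwas_table(data.frame(
      variant_id = ids, effect_allele = "A", other_allele = "G",
      eaf = eaf, beta = beta, se = se,
      pval = pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin),
      stringsAsFactors = FALSE), trait_label = label)
  }
  list(exposure = mk(gx_hat, se_x, "sim_exposure"),
       outcome = mk(gy_hat, se_y, "sim_outcome"),
       truth = structure(list(beta_true = cfg$beta_true, gamma = gamma,
                              alpha = alpha, outlier_ids = outlier_ids,
                              variant_id = ids),
                         class = "sim_truth"))
}

#' Write simulation truth as a sidecar TSV
#'
#' @param truth a `sim_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  df <- data.frame(variant_id = truth$variant_id, gamma = truth$gamma,
                   alpha = truth$alpha, beta_true = truth$beta_true,
                   planted_outlier = truth$variant_id %in% truth$outlier_ids,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

RECOVERY_METHODS <- c("IVW-FE", "IVW-RE", "WMe", "WMo", "Egger",
                      "Egger-SIMEX")

#' Parameter-recovery experiment
#'
#' Simulates `replicates` independent datasets from one configuration (seed
#' streams split deterministically from the root seed), runs the requested
#' estimators and the heterogeneity test on each, and aggregates per-method
#' bias, root-mean-square error, 95% CI coverage of the true slope and
#' null-rejection rate, plus the Cochran-Q rejection rate and — when
#' outliers are planted — the sensitivity and specificity of
#' Bonferroni-threshold outlier flagging.
#'
#' @param cfg a [sim_config()].
#' @param replicates number of replicates (default 200; >= 100 advised for
#'   stable fractions).
#' @param methods subset of `r toString(RECOVERY_METHODS)`.
#' @param B bootstrap / SIMEX draws passed to the resampling estimators
#'   (kept modest by default: per-replicate cost is k x B).
#' @param alpha level for the Q test and outlier flagging.
#' @return list of class `recovery_report`: `per_method` data frame
#'   (`method`, `bias`, `rmse`, `ci_coverage`, `rejection_rate`),
#'   `q_rejection_rate`, and `outlier_sensitivity` / `outlier_specificity`
#'   (NA when none planted).
#' @export
recovery_experiment <- function(cfg, replicates = 200L,
                                methods = c("IVW-FE", "Egger"),
                                B = 200L, alpha = 0.05) {
  stopifnot(inherits(cfg, "sim_config"), replicates >= 1L)
  unknown <- setdiff(methods, RECOVERY_METHODS)
  if (length(unknown) > 0L) {
    stop("unknown method label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  est_beta <- est_se <- matrix(NA_real_, replicates, length(methods),
                               dimnames = list(NULL, methods))
  q_reject <- logical(replicates)
  sens <- spec <- rep(NA_real_, replicates)
  for (r in seq_len(replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- split_seed(cfg$seed, r)
    sim <- simulate_two_sample(cfg_r)
    hs <- harmonise(sim$exposure, sim$outcome)
    ratios <- wald_ratios(hs)
    fe <- ivw(ratios, mode = "FE")
    het <- cochran_q(ratios, fe)
    q_reject[r] <- het$p < alpha
    for (m in methods) {
      e <- switch(m,
        "IVW-FE" = fe,
        "IVW-RE" = ivw(ratios, mode = "RE"),
        "WMe" = weighted_median(ratios, B = max(B, 100L), seed = cfg_r$seed),
        "WMo" = weighted_mode(ratios, B = max(B, 100L), seed = cfg_r$seed),
        "Egger" = mr_egger(hs)$slope,
        "Egger-SIMEX" = egger_simex(hs, B = max(B, 200L),
                                    seed = cfg_r$seed)$slope
      )
      est_beta[r, m] <- e$beta
      est_se[r, m] <- e$se
    }
    if (cfg$n_outliers > 0L) {
      rep_out <- remove_outliers_refit(ratios, alpha = alpha)
      planted <- sim$truth$outlier_ids
      clean <- setdiff(ratios$variant_id, planted)
      sens[r] <- mean(planted %in% rep_out$flagged)
      spec[r] <- mean(!clean %in% rep_out$flagged)
    }
  }
  bt <- cfg$beta_true
  per_method <- do.call(rbind, lapply(methods, function(m) {
    bhat <- est_beta[, m]
    shat <- est_se[, m]
    data.frame(method = m,
               bias = mean(bhat) - bt,
               rmse = sqrt(mean((bhat - bt)^2)),
               ci_coverage = mean(bhat - 1.96 * shat <= bt &
                                    bt <= bhat + 1.96 * shat),
               rejection_rate = mean(2 * stats::pnorm(-abs(bhat / shat))
                                     < alpha),
               stringsAsFactors = FALSE)
  }))
  rownames(per_method) <- NULL
  structure(list(per_method = per_method,
                 q_rejection_rate = mean(q_reject),
                 outlier_sensitivity = if (cfg$n_outliers > 0L)
                   mean(sens) else NA_real_,
                 outlier_specificity = if (cfg$n_outliers > 0L)
                   mean(spec) else NA_real_,
                 replicates = replicates, config = cfg),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d replicate(s), beta_true=%.3f, scenario=%s\n",
              x$replicates, x$config$beta_true, x$config$pleiotropy))
  print.data.frame(x$per_method, digits = 3)
  cat(sprintf("  Q rejection rate: %.3f\n", x$q_rejection_rate))
  if (!is.na(x$outlier_sensitivity)) {
    cat(sprintf("  outlier sensitivity %.3f, specificity %.3f\n",
                x$outlier_sensitivity, x$outlier_specificity))
  }
  invisible(x)
}
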