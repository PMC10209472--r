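# Heterogeneity-based pleiotropy diagnostics on the Wald-ratio scale, with
# first-order inverse-variance weights matching the estimator module.

#' Cochran's Q heterogeneity test with I-squared
#'
#' `Q = sum w_j (ratio_j - pooled)^2` against the fixed-effect pooled
#' estimate, referred to a chi-squared distribution with `k - 1` df.
#' `I^2 = max(0, (Q - df)/Q)` measures the fraction of variability beyond
#' chance. Its confidence interval uses the Higgins-Thompson test-based
#' method on `ln H` (`H = sqrt(Q/df)`, clamped at 1), with the `Q > k` /
#' `Q <= k` standard-error branches, back-transformed and clamped to
#' `[0, 1)`. No CI is reported for `k = 2`.
#'
#' @param ratios a `ratio_estimates` data frame (k >= 2 rows).
#' @param pooled the IVW fixed-effect `mr_estimate` on the same ratios;
#'   computed internally if omitted.
#' @return list of class `heterogeneity_result`: `Q`, `df`, `p`, `i2`,
#'   `i2_ci_low`, `i2_ci_high` (NA for k = 2), `k`.
#' @export
cochran_q <- function(ratios, pooled = NULL) {
  stopifnot(is.data.frame(ratios))
  k <- nrow(ratios)
  if (k < 2L) stop("Cochran's Q requires at least 2 ratios", call. = FALSE)
  if (is.null(pooled)) pooled <- ivw(ratios, mode = "FE")
  w <- ratios$weight
  q <- sum(w * (ratios$ratio - pooled$beta)^2)
  df <- k - 1
  p <- stats::pchisq(q, df = df, lower.tail = FALSE)
  i2 <- if (q > 0) max(0, (q - df) / q) else 0

  ci <- c(NA_real_, NA_real_)
  if (k >= 3L) {
    # Higgins-Thompson (2002) test-based CI on ln H
    h <- sqrt(q / df)
    ln_h <- log(max(h, 1))
    se_ln_h <- if (q > k) {
      0.5 * (log(q) - log(df)) / (sqrt(2 * q) - sqrt(2 * k - 3))
    } else {
      sqrt(1 / (2 * (k - 2)) * (1 - 1 / (3 * (k - 2)^2)))
    }
    h_lo <- max(1, exp(ln_h - 1.96 * se_ln_h))
    h_hi <- max(1, exp(ln_h + 1.96 * se_ln_h))
    to_i2 <- function(h) max(0, min(1 - .Machine$double.eps,
                                    (h^2 - 1) / h^2))
    ci <- c(to_i2(h_lo), to_i2(h_hi))
  }
  structure(list(Q = q, df = df, p = p, i2 = i2,
                 i2_ci_low = ci[1], i2_ci_high = ci[2], k = k),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  ci_txt <- if (is.na(x$i2_ci_low)) "" else
    sprintf(" (95%% CI %.0f-%.0f%%)", 100 * x$i2_ci_low, 100 * x$i2_ci_high)
  cat(sprintf("<heterogeneity> Q=%.3f df=%d p=%.3g; I2=%.0f%%%s\n",
              x$Q, x$df, x$p, 100 * x$i2, ci_txt))
  invisible(x)
}

#' Per-variant contributions to Cochran's Q
#'
#' `q_j = w_j (ratio_j - pooled)^2`; the contributions sum to Q. Each is
#' flagged against the upper-`alpha` and Bonferroni upper-`alpha/k`
#' quantiles of chi-squared with 1 df, the two reference lines of the
#' outlier plot.
#'
#' @param ratios a `ratio_estimates` data frame.
#' @param pooled the IVW-FE `mr_estimate`; computed internally if omitted.
#' @param alpha nominal level (default 0.05).
#' @return data frame of class `q_contributions`: `variant_id`, `q_j`,
#'   `exceeds_nominal`, `exceeds_bonferroni`; attributes
#'   `nominal_threshold`, `bonferroni_threshold`, `alpha`.
#' @export
q_contributions <- function(ratios, pooled = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(ratios), nrow(ratios) >= 2L,
            alpha > 0, alpha < 1)
  if (is.null(pooled)) pooled <- ivw(ratios, mode = "FE")
  k <- nrow(ratios)
  q_j <- ratios$weight * (ratios$ratio - pooled$beta)^2
  thr_nom <- stats::qchisq(1 - alpha, df = 1)
  thr_bon <- stats::qchisq(1 - alpha / k, df = 1)
  out <- data.frame(variant_id = ratios$variant_id, q_j = q_j,
                    exceeds_nominal = q_j > thr_nom,
                    exceeds_bonferroni = q_j > thr_bon,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, nominal_threshold = thr_nom, bonferroni_threshold = thr_bon,
            alpha = alpha, class = c("q_contributions", "data.frame"))
}

#' Identify pleiotropic outliers by Q contribution and refit
#'
#' Flags every variant whose Q contribution exceeds the Bonferroni
#' chi-squared(1) threshold (upper `alpha/k` quantile) in a single pass,
#' then refits the IVW fixed-effect estimate and heterogeneity on the
#' remaining variants. With `iterate = TRUE` the flag-and-refit cycle
#' repeats until no contribution exceeds the (recomputed) threshold.
#'
#' @param set a `harmonised_set` or pairs data frame (k >= 3).
#' @param alpha nominal level (default 0.05); removal uses `alpha/k`.
#' @param iterate repeat removal until clean (default FALSE: single pass).
#' @return list of class `outlier_report`: `flagged` (variant ids),
#'   `thresholds` (nominal, bonferroni), `contributions` (the plot-ready
#'   table), `refit` (IVW-FE `mr_estimate` on the remainder), `refit_het`
#'   (its `heterogeneity_result`), and `ratios_kept`.
#' @export
remove_outliers_refit <- function(set, alpha = 0.05, iterate = FALSE) {
  ratios <- if (inherits(set, c("ratio_estimates")) ||
                (is.data.frame(set) && "ratio" %in% names(set))) set else
    wald_ratios(set)
  if (nrow(ratios) < 3L) stop("outlier screening requires k >= 3",
                              call. = FALSE)
  qc_full <- q_contributions(ratios, alpha = alpha)
  flagged <- character(0)
  kept <- ratios
  repeat {
    qc <- q_contributions(kept, alpha = alpha)
    new_flag <- qc$variant_id[qc$exceeds_bonferroni]
    if (length(new_flag) == 0L) break
    flagged <- c(flagged, new_flag)
    kept <- kept[!kept$variant_id %in% new_flag, , drop = FALSE]
    if (nrow(kept) < 2L) stop("all (or nearly all) variants flagged as outliers: degenerate set",
                              call. = FALSE)
    if (!iterate) break
  }
  refit <- ivw(kept, mode = "FE")
  refit_het <- cochran_q(kept, refit)
  structure(list(flagged = flagged,
                 thresholds = c(nominal = attr(qc_full, "nominal_threshold"),
                                bonferroni = attr(qc_full, "bonferroni_threshold")),
                 contributions = qc_full, refit = refit,
                 refit_het = refit_het, ratios_kept = kept, alpha = alpha),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> %d variant(s) flagged above Bonferroni chi2(1) threshold %.2f\n",
              length(x$flagged), x$thresholds["bonferroni"]))
  if (length(x$flagged)) cat("  flagged:", paste(x$flagged, collapse = ", "), "\n")
  cat("  refit: ")
  print(x$refit)
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the IVW fixed-effect estimate k times, omitting one variant
#' each, to check whether any single variant drives the pooled association.
#'
#' @param ratios a `ratio_estimates` data frame (k >= 3).
#' @return list of class `loo_result`: `table` (data frame `left_out_id`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `p`), `beta_full`,
#'   `max_influence_id` (variant whose omission moves the estimate most).
#' @export
leave_one_out <- function(ratios) {
  stopifnot(is.data.frame(ratios))
  k <- nrow(ratios)
  if (k < 3L) stop("leave-one-out requires k >= 3", call. = FALSE)
  full <- ivw(ratios, mode = "FE")
  rows <- lapply(seq_len(k), function(i) {
    e <- ivw(ratios[-i, , drop = FALSE], mode = "FE")
    data.frame(left_out_id = ratios$variant_id[i], beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, p = e$p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  shift <- abs(tab$beta - full$beta)
  structure(list(table = tab, beta_full = full$beta,
                 max_influence_id = tab$left_out_id[which.max(shift)]),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("<loo_result> %d refits; full beta=%.4f; max influence: %s\n",
              nrow(x$table), x$beta_full, x$max_influence_id))
  invisible(x)
}

#' Heterogeneity of the gene-exposure estimates (I-squared-GX)
#'
#' Quantifies violation of the no-measurement-error assumption of MR-Egger:
#' `Q_GX = sum gx_se_j^-2 (gx_beta_j - weighted mean)^2` after orienting all
#' gene-exposure estimates non-negative, and
#' `I2_GX = max(0, (Q_GX - (k-1))/Q_GX)`. Values below 0.9 indicate material
#' regression dilution of the Egger slope and recommend SIMEX correction.
#'
#' @param set a `harmonised_set` or pairs data frame (k >= 2).
#' @param simex_threshold recommend SIMEX when `i2_gx` is below this
#'   (default 0.9).
#' @return list of class `gx_heterogeneity`: `q_gx`, `i2_gx`,
#'   `simex_recommended`.
#' @export
i2_gx <- function(set, simex_threshold = 0.9) {
  p <- if (inherits(set, "harmonised_set")) set$pairs else set
  stopifnot(is.data.frame(p), nrow(p) >= 2L)
  x <- abs(p$gx_beta)   # orientation as in mr_egger
  # zero gx_se means no measurement error: floor avoids infinite weights
  # and yields i2_gx ~ 1 (SIMEX not needed)
  w <- pmax(p$gx_se, 1e-12)^-2
  xb <- sum(w * x) / sum(w)
  q_gx <- sum(w * (x - xb)^2)
  i2 <- if (q_gx > 0) max(0, (q_gx - (nrow(p) - 1)) / q_gx) else 0
  structure(list(q_gx = q_gx, i2_gx = i2,
                 simex_recommended = i2 < simex_threshold),
            class = "gx_heterogeneity")
}

#' @export
print.gx_heterogeneity <- function(x, ...) {
  cat(sprintf("<gx_heterogeneity> Q_GX=%.3f I2_GX=%.3f; SIMEX %srecommended\n",
              x$q_gx, x$i2_gx, if (x$simex_recommended) "" else "not "))
  invisible(x)
}
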