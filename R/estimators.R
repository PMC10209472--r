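# Pooled causal-effect estimators on the log-odds scale.
#
# All methods consume per-variant Wald ratios (gene-outcome over
# gene-exposure log odds ratios) or the harmonised pairs directly (Egger).
# Confidence intervals use the 1.96 normal multiplier throughout, matching
# the 95% convention; Egger uses a t reference with k - 2 df by default.

CI_Z <- 1.96

new_mr_estimate <- function(method, beta, se, n_snps, p = NULL,
                            df_note = "normal") {
  stopifnot(is.finite(beta), is.finite(se), se > 0)
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(beta / se))
  p <- max(min(p, 1), .Machine$double.xmin)
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - CI_Z * se, ci_high = beta + CI_Z * se,
                 p = p, n_snps = as.integer(n_snps), df_note = df_note),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  or <- to_odds_scale(x)
  cat(sprintf("<mr_estimate> %s (k=%d): beta=%.4f se=%.4f p=%.3g | OR %.3f (%.3f-%.3f)\n",
              x$method, x$n_snps, x$beta, x$se, x$p,
              or$odds_ratio, or$or_ci_low, or$or_ci_high))
  invisible(x)
}

#' Per-variant Wald ratio estimates
#'
#' The Wald (ratio) estimator divides the gene-outcome association by the
#' gene-exposure association per variant. The default standard error is
#' first order, `gy_se / |gx_beta|`, which ignores uncertainty in the
#' gene-exposure estimate and makes inverse-variance pooling equivalent to
#' weighted regression through the origin. The second-order delta-method
#' variance `gy_se^2/gx_beta^2 + gy_beta^2 gx_se^2 / gx_beta^4` is available
#' via `order = 2`.
#'
#' @param set a `harmonised_set` from [harmonise()], or a data frame with
#'   columns `variant_id`, `gx_beta`, `gx_se`, `gy_beta`, `gy_se`.
#' @param order 1 (default) or 2; order of the delta-method standard error.
#' @return data frame of class `ratio_estimates` with columns `variant_id`,
#'   `ratio`, `se`, `weight` (`= se^-2`); pairs with `gx_beta == 0` are
#'   excluded and recorded in the `exclusions` attribute with reason
#'   `zero_gx`.
#' @export
wald_ratios <- function(set, order = 1) {
  p <- if (inherits(set, "harmonised_set")) set$pairs else set
  stopifnot(is.data.frame(p),
            all(c("variant_id", "gx_beta", "gx_se", "gy_beta", "gy_se")
                %in% names(p)),
            order %in% c(1, 2))
  zero <- p$gx_beta == 0
  excl <- data.frame(variant_id = p$variant_id[zero],
                     stage = rep("wald_ratios", sum(zero)),
                     reason = rep("zero_gx", sum(zero)),
                     stringsAsFactors = FALSE)
  p <- p[!zero, , drop = FALSE]
  ratio <- p$gy_beta / p$gx_beta
  se <- if (order == 1) {
    p$gy_se / abs(p$gx_beta)
  } else {
    sqrt(p$gy_se^2 / p$gx_beta^2 + p$gy_beta^2 * p$gx_se^2 / p$gx_beta^4)
  }
  out <- data.frame(variant_id = p$variant_id, ratio = ratio, se = se,
                    weight = se^-2, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, exclusions = excl,
            class = c("ratio_estimates", "data.frame"))
}

#' Inverse-variance-weighted pooled estimate
#'
#' Pools Wald ratios by inverse-variance weighting. Under the fixed-effect
#' model the pooled standard error is `(sum w_j)^(-1/2)`. The random-effects
#' model is multiplicative overdispersion: the fixed-effect standard error is
#' inflated by `max(1, sqrt(Q/(k-1)))`, so homogeneous data reproduce the
#' fixed-effect interval exactly. An additive DerSimonian-Laird variant is
#' available via `mode = "RE-DL"`.
#'
#' @param ratios a `ratio_estimates` data frame from [wald_ratios()].
#' @param mode `"FE"` (default), `"RE"` (multiplicative) or `"RE-DL"`.
#' @return an `mr_estimate`.
#' @export
ivw <- function(ratios, mode = c("FE", "RE", "RE-DL")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(ratios), nrow(ratios) >= 2L)
  w <- ratios$weight
  b <- ratios$ratio
  k <- length(b)
  beta <- sum(w * b) / sum(w)
  se_fe <- 1 / sqrt(sum(w))
  q <- sum(w * (b - beta)^2)
  if (mode == "FE") {
    return(new_mr_estimate("IVW-FE", beta, se_fe, k))
  }
  if (mode == "RE") {
    scale <- max(1, sqrt(q / (k - 1)))
    return(new_mr_estimate("IVW-RE", beta, se_fe * scale, k,
                           df_note = "normal, multiplicative overdispersion"))
  }
  # additive DerSimonian-Laird
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  w_dl <- 1 / (1 / w + tau2)
  beta_dl <- sum(w_dl * b) / sum(w_dl)
  new_mr_estimate("IVW-RE", beta_dl, 1 / sqrt(sum(w_dl)), k,
                  df_note = "normal, DerSimonian-Laird")
}

# Weighted interpolated median of `b` with weights `w`: order statistics get
# positions p_j = cumsum(w') - w'/2 on (0,1); linear interpolation to 0.5.
weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  hit <- which(abs(p - 0.5) < 1e-12)
  if (length(hit) > 0L) return(b[hit[1]])   # exact tie: that order statistic
  if (0.5 <= p[1]) return(b[1])
  if (0.5 >= p[length(p)]) return(b[length(b)])
  stats::approx(p, b, xout = 0.5, ties = "ordered")$y
}

boot_se <- function(point_fun, b, se, w, B, seed) {
  if (!is.null(seed)) set.seed(seed)
  est <- vapply(seq_len(B), function(i) {
    point_fun(stats::rnorm(length(b), mean = b, sd = se), w)
  }, numeric(1))
  stats::sd(est)
}

#' Weighted median estimate
#'
#' The weighted median of the Wald ratios is consistent when variants
#' carrying at least half the weight are valid instruments. Order statistics
#' are placed at cumulative-weight positions `p_j = sum_{i<=j} w'_i - w'_j/2`
#' and the estimate interpolates linearly to position 0.5; a tie at exactly
#' 0.5 returns that order statistic. The standard error is a seeded
#' parametric bootstrap: ratios are redrawn as `Normal(ratio_j, se_j)` and
#' the weighted median recomputed `B` times.
#'
#' @param ratios a `ratio_estimates` data frame (at least 3 rows).
#' @param B number of bootstrap draws (default 1000, minimum 100).
#' @param seed integer seed for the bootstrap.
#' @return an `mr_estimate` with method `"WMe"`.
#' @export
weighted_median <- function(ratios, B = 1000L, seed = 1L) {
  stopifnot(is.data.frame(ratios), nrow(ratios) >= 3L, B >= 100L)
  b <- ratios$ratio
  w <- ratios$weight
  se <- ratios$se
  beta <- weighted_median_point(b, w)
  se_b <- boot_se(weighted_median_point, b, se, w, B, seed)
  if (!is.finite(se_b) || se_b <= 0) se_b <- .Machine$double.eps
  new_mr_estimate("WMe", beta, se_b, length(b),
                  df_note = sprintf("normal, parametric bootstrap B=%d", B))
}

# Modified Silverman bandwidth on the ratios; 0 when all ratios coincide.
mode_bandwidth <- function(b, phi) {
  s <- 0.9 * min(stats::sd(b), stats::IQR(b) / 1.34) * length(b)^(-1 / 5)
  phi * s
}

weighted_mode_point <- function(b, w, phi = 1, n_grid = 512L) {
  h <- mode_bandwidth(b, phi)
  if (!is.finite(h) || h <= 0) return(b[1])  # degenerate: all identical
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = n_grid)
  wn <- w / sum(w)
  dens <- vapply(grid, function(x) sum(wn * stats::dnorm((x - b) / h)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Weighted mode-based estimate
#'
#' Estimates the causal effect as the mode of the weight-weighted
#' normal-kernel density of the Wald ratios, consistent when the largest
#' group of variants sharing a causal estimate are valid (zero modal
#' pleiotropy). Bandwidth is `phi` times the modified Silverman rule
#' `0.9 min(sd, IQR/1.34) k^(-1/5)` on the ratios; the density is maximised
#' on a grid spanning `[min - 3h, max + 3h]`. If all ratios coincide the
#' common value is returned. Standard error by the same seeded parametric
#' bootstrap as [weighted_median()].
#'
#' @param ratios a `ratio_estimates` data frame (at least 3 rows).
#' @param phi bandwidth multiplier (> 0, default 1).
#' @param B bootstrap draws (default 1000).
#' @param seed integer seed.
#' @param n_grid grid resolution (minimum 512).
#' @return an `mr_estimate` with method `"WMo"`.
#' @export
weighted_mode <- function(ratios, phi = 1, B = 1000L, seed = 1L,
                          n_grid = 512L) {
  stopifnot(is.data.frame(ratios), nrow(ratios) >= 3L, phi > 0,
            n_grid >= 512L)
  b <- ratios$ratio
  w <- ratios$weight
  se <- ratios$se
  beta <- weighted_mode_point(b, w, phi, n_grid)
  se_b <- boot_se(function(bb, ww) weighted_mode_point(bb, ww, phi, n_grid),
                  b, se, w, B, seed)
  if (!is.finite(se_b) || se_b <= 0) se_b <- .Machine$double.eps
  new_mr_estimate("WMo", beta, se_b, length(b),
                  df_note = sprintf("normal, parametric bootstrap B=%d", B))
}

# Closed-form weighted least squares of y on x with intercept, weights w.
# Returns coefficients, their variances under multiplicative overdispersion
# phi = max(1, RSS_w/(k-2)), and the raw weighted RSS.
wls_egger_fit <- function(x, y, w) {
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  if (det <= 0) stop("degenerate design: gene-exposure estimates collinear",
                     call. = FALSE)
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  resid <- y - intercept - slope * x
  rss_w <- sum(w * resid^2)
  k <- length(x)
  phi <- max(1, rss_w / (k - 2))
  var_slope <- phi * sw / det
  var_intercept <- phi * swxx / det
  list(slope = slope, intercept = intercept,
       se_slope = sqrt(var_slope), se_intercept = sqrt(var_intercept),
       rss_w = rss_w, phi = phi, k = k)
}

#' MR-Egger regression
#'
#' Weighted least squares of the gene-outcome estimates on the gene-exposure
#' estimates with an unconstrained intercept, weights equal to the inverse
#' squared gene-outcome standard errors. Pairs are first oriented so every
#' gene-exposure estimate is non-negative (both members negated where
#' needed), which leaves Wald ratios unchanged. The slope estimates the
#' causal effect under the InSIDE assumption; the intercept estimates average
#' directional pleiotropy. Standard errors carry multiplicative
#' overdispersion `max(1, sqrt(RSS_w/(k-2)))` and p-values use a t reference
#' with `k - 2` df (`reference = "normal"` switches to the normal).
#'
#' The attenuation of the Egger slope from measurement error in the
#' gene-exposure estimates (violation of the no-measurement-error
#' assumption) is quantified by [i2_gx()]; see [egger_simex()] for the
#' correction.
#'
#' @param set a `harmonised_set` (or pairs data frame), at least 3 pairs.
#' @param reference `"t"` (default, k - 2 df) or `"normal"`.
#' @return list of class `egger_result`: `slope` (an `mr_estimate`, method
#'   `"Egger"`), `intercept_beta`, `intercept_se`, `intercept_p`, `i2_gx`,
#'   `simex_applied = FALSE`, and the fit internals.
#' @export
mr_egger <- function(set, reference = c("t", "normal")) {
  reference <- match.arg(reference)
  p <- if (inherits(set, "harmonised_set")) set$pairs else set
  stopifnot(is.data.frame(p), nrow(p) >= 3L)
  flip <- sign(p$gx_beta)
  flip[flip == 0] <- 1
  x <- p$gx_beta * flip
  y <- p$gy_beta * flip
  w <- p$gy_se^-2
  fit <- wls_egger_fit(x, y, w)
  k <- fit$k
  pfun <- if (reference == "t") {
    function(est, se) 2 * stats::pt(-abs(est / se), df = k - 2)
  } else {
    function(est, se) 2 * stats::pnorm(-abs(est / se))
  }
  slope <- new_mr_estimate("Egger", fit$slope, fit$se_slope, k,
                           p = pfun(fit$slope, fit$se_slope),
                           df_note = if (reference == "t")
                             sprintf("t with %d df", k - 2) else "normal")
  gx <- i2_gx(p)
  structure(list(slope = slope,
                 intercept_beta = fit$intercept,
                 intercept_se = fit$se_intercept,
                 intercept_p = pfun(fit$intercept, fit$se_intercept),
                 i2_gx = gx$i2_gx, simex_applied = FALSE,
                 simex_lambda_grid = NULL, simex_B = NULL,
                 fit = fit),
            class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  cat(sprintf("<egger_result>%s slope=%.4f (se %.4f, p=%.3g); intercept=%.4f (se %.4f, p=%.3g); I2_GX=%.2f\n",
              if (x$simex_applied) " [SIMEX]" else "",
              x$slope$beta, x$slope$se, x$slope$p,
              x$intercept_beta, x$intercept_se, x$intercept_p, x$i2_gx))
  invisible(x)
}

#' MR-Egger with SIMEX correction for regression dilution
#'
#' Measurement error in the gene-exposure estimates attenuates the MR-Egger
#' slope towards the null (regression dilution; violation of the
#' no-measurement-error assumption, flagged by low [i2_gx()]). SIMEX
#' (simulation extrapolation) re-estimates the Egger fit after adding known
#' extra noise `sqrt(lambda) * gx_se_j * z` to the gene-exposure estimates at
#' each multiplier `lambda` in `lambda_grid`, averages slope and intercept
#' over `B` draws per `lambda`, fits a quadratic trend in `lambda`, and
#' extrapolates to `lambda = -1` (the no-error limit).
#'
#' The extrapolated standard error applies the same quadratic extrapolation
#' to the mean model-based variance of the coefficient across draws; if the
#' extrapolated variance is non-positive the naive Egger standard error is
#' retained.
#'
#' @param set a `harmonised_set` (or pairs data frame), at least 3 pairs.
#' @param lambda_grid non-negative noise multipliers including 0; default
#'   `c(0, 0.5, 1, 1.5, 2)`.
#' @param B simulation draws per lambda (default 1000, minimum 200).
#' @param seed integer seed.
#' @param reference `"t"` or `"normal"`, as in [mr_egger()].
#' @return an `egger_result` with `simex_applied = TRUE` (unless all
#'   `gx_se` are zero, in which case the naive fit is returned unchanged).
#' @export
egger_simex <- function(set, lambda_grid = c(0, 0.5, 1, 1.5, 2), B = 1000L,
                        seed = 1L, reference = c("t", "normal")) {
  reference <- match.arg(reference)
  p <- if (inherits(set, "harmonised_set")) set$pairs else set
  stopifnot(is.data.frame(p), nrow(p) >= 3L, B >= 200L,
            length(lambda_grid) >= 3L, all(lambda_grid >= 0),
            0 %in% lambda_grid)
  naive <- mr_egger(p, reference = reference)
  if (all(p$gx_se == 0)) return(naive)

  flip <- sign(p$gx_beta)
  flip[flip == 0] <- 1
  x0 <- p$gx_beta * flip
  y <- p$gy_beta * flip
  w <- p$gy_se^-2
  sx <- p$gx_se
  k <- length(x0)

  if (!is.null(seed)) set.seed(seed)
  lambda_grid <- sort(lambda_grid)
  nl <- length(lambda_grid)
  m_slope <- m_int <- v_slope <- v_int <- numeric(nl)
  for (li in seq_len(nl)) {
    lam <- lambda_grid[li]
    if (lam == 0) {
      fit <- wls_egger_fit(x0, y, w)
      m_slope[li] <- fit$slope; m_int[li] <- fit$intercept
      v_slope[li] <- fit$se_slope^2; v_int[li] <- fit$se_intercept^2
      next
    }
    sl <- it <- vs <- vi <- numeric(B)
    for (b in seq_len(B)) {
      # orientation is fixed from the observed data: re-flipping inside the
      # simulation would make the lambda-trend non-smooth and spoil the
      # quadratic extrapolation
      xb <- x0 + sqrt(lam) * sx * stats::rnorm(k)
      fit <- wls_egger_fit(xb, y, w)
      sl[b] <- fit$slope; it[b] <- fit$intercept
      vs[b] <- fit$se_slope^2; vi[b] <- fit$se_intercept^2
    }
    m_slope[li] <- mean(sl); m_int[li] <- mean(it)
    v_slope[li] <- mean(vs); v_int[li] <- mean(vi)
  }

  extrap <- function(vals) {
    fit <- stats::lm(vals ~ lambda_grid + I(lambda_grid^2))
    unname(sum(stats::coef(fit) * c(1, -1, 1)))  # evaluate at lambda = -1
  }
  slope_sx <- extrap(m_slope)
  int_sx <- extrap(m_int)
  var_slope_sx <- extrap(v_slope)
  var_int_sx <- extrap(v_int)
  se_slope_sx <- if (is.finite(var_slope_sx) && var_slope_sx > 0)
    sqrt(var_slope_sx) else naive$slope$se
  se_int_sx <- if (is.finite(var_int_sx) && var_int_sx > 0)
    sqrt(var_int_sx) else naive$intercept_se

  pfun <- if (reference == "t") {
    function(est, se) 2 * stats::pt(-abs(est / se), df = k - 2)
  } else {
    function(est, se) 2 * stats::pnorm(-abs(est / se))
  }
  slope <- new_mr_estimate("Egger-SIMEX", slope_sx, se_slope_sx, k,
                           p = pfun(slope_sx, se_slope_sx),
                           df_note = if (reference == "t")
                             sprintf("t with %d df", k - 2) else "normal")
  structure(list(slope = slope, intercept_beta = int_sx,
                 intercept_se = se_int_sx,
                 intercept_p = pfun(int_sx, se_int_sx),
                 i2_gx = naive$i2_gx, simex_applied = TRUE,
                 simex_lambda_grid = lambda_grid, simex_B = as.integer(B),
                 fit = naive$fit),
            class = "egger_result")
}

#' Convert a log-odds estimate to the odds-ratio scale
#'
#' `OR = exp(beta)` with 95% CI `exp(beta +/- 1.96 se)`; the p-value is
#' carried over unchanged.
#'
#' @param est an `mr_estimate`.
#' @return list of class `odds_scale_result`: `odds_ratio`, `or_ci_low`,
#'   `or_ci_high`, `p`.
#' @export
to_odds_scale <- function(est) {
  stopifnot(inherits(est, "mr_estimate"))
  structure(list(odds_ratio = exp(est$beta),
                 or_ci_low = exp(est$beta - CI_Z * est$se),
                 or_ci_high = exp(est$beta + CI_Z * est$se),
                 p = est$p),
            class = "odds_scale_result")
}

#' @export
print.odds_scale_result <- function(x, ...) {
  cat(sprintf("OR %.3f (95%% CI %.3f-%.3f; p=%.3g)\n",
              x$odds_ratio, x$or_ci_low, x$or_ci_high, x$p))
  invisible(x)
}

#' Tabulate pooled estimates on both scales
#'
#' @param estimates list of `mr_estimate` objects.
#' @return data frame with columns `method`, `n_snps`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `p`, `or`, `or_ci_low`, `or_ci_high`.
#' @export
estimates_table <- function(estimates) {
  rows <- lapply(estimates, function(e) {
    or <- to_odds_scale(e)
    data.frame(method = e$method, n_snps = e$n_snps, beta = e$beta,
               se = e$se, ci_low = e$ci_low, ci_high = e$ci_high, p = e$p,
               or = or$odds_ratio, or_ci_low = or$or_ci_low,
               or_ci_high = or$or_ci_high, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
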