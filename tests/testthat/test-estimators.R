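test_that("wald_ratios divides, propagates first/second-order SEs, drops zero gx", {
  pairs <- make_pairs(gx_beta = c(0.1, -0.1, 0),
                      gy_beta = c(0.2, 0.2, 0.1),
                      gx_se = c(0.02, 0.02, 0.02),
                      gy_se = c(0.05, 0.05, 0.05))
  r <- wald_ratios(pairs)
  expect_equal(r$ratio, c(2, -2))
  expect_equal(r$se, c(0.5, 0.5))
  expect_equal(r$weight, 1 / r$se^2)
  excl <- attr(r, "exclusions")
  expect_equal(excl$variant_id, "rs003")
  expect_equal(excl$reason, "zero_gx")

  # second-order se against the delta-method expansion written out directly
  r2 <- wald_ratios(pairs[1, ], order = 2)
  oracle <- sqrt(0.05^2 / 0.1^2 + 0.2^2 * 0.02^2 / 0.1^4)
  expect_equal(r2$se, oracle, tolerance = 1e-12)
})

test_that("ivw pools with inverse-variance weights; RE clamps at FE", {
  r <- make_ratios(c(1, 3), c(1, 1))
  fe <- ivw(r)
  expect_equal(fe$beta, 2)
  expect_equal(fe$se, 1 / sqrt(2))

  r2 <- make_ratios(c(1, 2), c(0.5, 1))
  fe2 <- ivw(r2)
  expect_equal(fe2$beta, 1.2)
  expect_equal(fe2$se, 1 / sqrt(5))
  expect_equal(fe2$ci_low, 1.2 - 1.96 / sqrt(5))

  # identical ratios: Q = 0, multiplicative RE collapses to FE
  r3 <- make_ratios(c(1.5, 1.5, 1.5), c(0.2, 0.3, 0.4))
  expect_equal(ivw(r3, "RE")$se, ivw(r3, "FE")$se)
  expect_equal(ivw(r3, "RE")$beta, ivw(r3, "FE")$beta)

  # heterogeneous ratios: RE se strictly wider
  r4 <- make_ratios(c(0, 4, -3, 5), c(0.3, 0.3, 0.3, 0.3))
  expect_gt(ivw(r4, "RE")$se, ivw(r4, "FE")$se)

  expect_error(ivw(make_ratios(1, 1)), "nrow")
})

test_that("IVW-FE equals weighted regression through the origin (oracle)", {
  for (seed in c(21L, 22L, 23L)) {
    p <- random_pairs(15, seed)
    r <- wald_ratios(p)
    fe <- ivw(r)
    fit <- lm(gy_beta ~ 0 + gx_beta, data = p, weights = p$gy_se^-2)
    expect_equal(fe$beta, unname(coef(fit)), tolerance = 1e-10)
    # lm's se is scaled by the residual dispersion; undo it for the FE se
    lm_se <- summary(fit)$coefficients[1, 2] / summary(fit)$sigma
    expect_equal(fe$se, unname(lm_se), tolerance = 1e-10)
  }
})

test_that("weighted_median interpolates cumulative weight to 0.5", {
  # equal weights, symmetric: exact middle order statistic
  r <- make_ratios(c(1, 2, 3), rep(1, 3))
  expect_equal(weighted_median(r, B = 100, seed = 1)$beta, 2)

  # weights (0.5, 0.25, 0.25): positions (0.25, 0.625, 0.875) -> 5/3
  r2 <- make_ratios(c(1, 2, 3), c(sqrt(1 / 0.5), sqrt(1 / 0.25), sqrt(1 / 0.25)))
  expect_equal(weighted_median(r2, B = 100, seed = 1)$beta, 5 / 3,
               tolerance = 1e-12)

  # independent interpolation oracle on a random instance
  set.seed(31)
  b <- rnorm(9); se <- runif(9, 0.5, 2); w <- se^-2
  o <- order(b); wn <- w[o] / sum(w)
  pos <- cumsum(wn) - wn / 2
  oracle <- approx(pos, b[o], xout = 0.5)$y
  expect_equal(weighted_median(make_ratios(b, se), B = 100, seed = 1)$beta,
               oracle, tolerance = 1e-12)

  # degenerate: all ratios equal; bootstrap se consistent with the input SEs
  r3 <- make_ratios(rep(2, 5), rep(0.5, 5))
  wm <- weighted_median(r3, B = 1000, seed = 2)
  expect_equal(wm$beta, 2)
  # median of 5 iid N(2, 0.5) draws has sd ~ 0.5 * sqrt(pi/(2*5)) ~ 0.28
  expect_gt(wm$se, 0.15); expect_lt(wm$se, 0.45)

  expect_error(weighted_median(make_ratios(c(1, 2), c(1, 1))), "nrow")
})

test_that("weighted_mode finds the dominant cluster and matches a dense-grid oracle", {
  # robustness: one outlier does not pull the mode away from the cluster
  r <- make_ratios(c(1.0, 1.1, 0.9, 5.0), rep(1, 4))
  wmo <- weighted_mode(r, B = 100, seed = 1)
  expect_gte(wmo$beta, 0.9)
  expect_lte(wmo$beta, 1.1)

  # degenerate: identical ratios
  r2 <- make_ratios(rep(2, 3), rep(1, 3))
  expect_equal(weighted_mode(r2, B = 100, seed = 1)$beta, 2)

  # dense-grid oracle on a random seeded instance
  set.seed(41)
  b <- c(rnorm(7, 1, 0.2), rnorm(4, 3, 0.2))
  se <- runif(11, 0.5, 1.5)
  w <- se^-2
  h <- 0.9 * min(sd(b), IQR(b) / 1.34) * length(b)^(-1 / 5)
  dense <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = 1e5)
  dens <- vapply(dense, function(x) sum((w / sum(w)) * dnorm((x - b) / h)),
                 numeric(1))
  oracle <- dense[which.max(dens)]
  est <- weighted_mode(make_ratios(b, se), B = 100, seed = 1,
                       n_grid = 4096L)$beta
  grid_spacing <- (max(b) - min(b) + 6 * h) / 4095
  expect_lt(abs(est - oracle), 2 * grid_spacing)
})

test_that("mr_egger fits weighted LS with orientation; matches normal equations", {
  # exact fit: slope 2, intercept 0.05
  gx <- c(0.1, 0.2, 0.3)
  pairs <- make_pairs(gx, 0.05 + 2 * gx, rep(0.02, 3), rep(0.05, 3))
  eg <- mr_egger(pairs)
  expect_equal(eg$slope$beta, 2, tolerance = 1e-10)
  expect_equal(eg$intercept_beta, 0.05, tolerance = 1e-10)
  expect_equal(eg$fit$rss_w, 0, tolerance = 1e-16)

  # collinear after orientation flip
  pairs2 <- make_pairs(c(-0.1, 0.2, 0.3), c(-0.25, 0.45, 0.65),
                       rep(0.02, 3), rep(0.05, 3))
  eg2 <- mr_egger(pairs2)
  expect_equal(eg2$slope$beta, 2, tolerance = 1e-10)
  expect_equal(eg2$intercept_beta, 0.05, tolerance = 1e-10)

  # unequal weights vs closed-form normal-equations oracle
  for (seed in c(51L, 52L)) {
    p <- random_pairs(12, seed)
    flip <- ifelse(p$gx_beta < 0, -1, 1)
    x <- p$gx_beta * flip; y <- p$gy_beta * flip; w <- p$gy_se^-2
    X <- cbind(1, x)
    coefs <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
    eg3 <- mr_egger(p)
    expect_equal(eg3$intercept_beta, coefs[1], tolerance = 1e-10)
    expect_equal(eg3$slope$beta, coefs[2], tolerance = 1e-10)
    # SEs against lm with multiplicative dispersion (no clamp when phi > 1)
    fit <- lm(y ~ x, weights = w)
    disp <- summary(fit)$sigma
    if (disp > 1) {
      expect_equal(eg3$slope$se,
                   unname(summary(fit)$coefficients[2, 2]),
                   tolerance = 1e-10)
      expect_equal(eg3$intercept_se,
                   unname(summary(fit)$coefficients[1, 2]),
                   tolerance = 1e-10)
    }
    # p-values on t(k-2)
    expect_equal(eg3$slope$p,
                 2 * pt(-abs(eg3$slope$beta / eg3$slope$se), df = 10),
                 tolerance = 1e-12)
  }

  # dispersion clamp: exact-fit data keep phi at 1, not 0
  expect_equal(eg$fit$phi, 1)
  expect_error(mr_egger(make_pairs(c(0.1, 0.1, 0.1), c(0.2, 0.2, 0.2),
                                   rep(0.02, 3), rep(0.05, 3))),
               "collinear")
})

test_that("egger_simex extrapolates; degenerate cases fall through", {
  p <- random_pairs(15, 61)
  # all gx_se zero: identical to the naive fit, simex not applied
  p0 <- p; p0$gx_se <- 0
  sx <- egger_simex(p0, B = 200, seed = 1)
  naive <- mr_egger(p0)
  expect_false(sx$simex_applied)
  expect_equal(sx$slope$beta, naive$slope$beta)

  # with error simulated in, the flag and metadata are set
  sx2 <- egger_simex(p, B = 200, seed = 1)
  expect_true(sx2$simex_applied)
  expect_equal(sx2$simex_B, 200L)
  expect_equal(sx2$simex_lambda_grid, c(0, 0.5, 1, 1.5, 2))
  # reproducible under the same seed
  sx3 <- egger_simex(p, B = 200, seed = 1)
  expect_equal(sx2$slope$beta, sx3$slope$beta)

  # quadratic extrapolation is exact on exactly-quadratic means
  lam <- c(0, 0.5, 1, 1.5, 2)
  vals <- 1.3 - 0.4 * lam + 0.07 * lam^2
  fit <- lm(vals ~ lam + I(lam^2))
  expect_equal(unname(sum(coef(fit) * c(1, -1, 1))),
               1.3 - 0.4 * (-1) + 0.07 * 1, tolerance = 1e-10)
})

test_that("to_odds_scale exponentiates the estimate and its interval", {
  est <- bimr:::new_mr_estimate("IVW-FE", beta = 0.4762, se = 0.2227, n_snps = 59)
  or <- to_odds_scale(est)
  expect_equal(or$odds_ratio, 1.61, tolerance = 1e-3)
  expect_equal(or$or_ci_low, 1.04, tolerance = 1e-2)
  expect_equal(or$or_ci_high, 2.49, tolerance = 1e-2)
  expect_lt(abs(or$p - 0.032), 0.003)

  est0 <- bimr:::new_mr_estimate("IVW-FE", beta = 0, se = 1, n_snps = 3)
  or0 <- to_odds_scale(est0)
  expect_equal(or0$odds_ratio, 1)
  expect_equal(or0$or_ci_low * or0$or_ci_high, 1, tolerance = 1e-12)
  expect_equal(or0$p, 1)

  est2 <- bimr:::new_mr_estimate("IVW-FE", beta = log(2), se = log(2) / 1.96,
                                 n_snps = 3)
  or2 <- to_odds_scale(est2)
  expect_equal(or2$or_ci_low, 1, tolerance = 1e-12)
  expect_equal(or2$or_ci_high, 4, tolerance = 1e-12)
  expect_equal(or2$p, 0.05, tolerance = 1e-3)
})

test_that("estimators are equivariant under sign flips and outcome scaling", {
  p <- random_pairs(11, 71)
  r <- wald_ratios(p)

  # joint sign flip of a subset leaves every ratio unchanged
  flip <- c(1, 3, 5)
  p2 <- p
  p2$gx_beta[flip] <- -p2$gx_beta[flip]
  p2$gy_beta[flip] <- -p2$gy_beta[flip]
  r2 <- wald_ratios(p2)
  expect_equal(r2$ratio, r$ratio)
  expect_equal(ivw(r2)$beta, ivw(r)$beta)
  expect_equal(mr_egger(p2)$slope$beta, mr_egger(p)$slope$beta)
  expect_equal(weighted_median(r2, B = 100, seed = 3)$beta,
               weighted_median(r, B = 100, seed = 3)$beta)

  # scaling all gy and gy_se by c scales pooled beta and se by c
  cc <- 2.7
  p3 <- p
  p3$gy_beta <- cc * p3$gy_beta
  p3$gy_se <- cc * p3$gy_se
  r3 <- wald_ratios(p3)
  expect_equal(ivw(r3)$beta, cc * ivw(r)$beta, tolerance = 1e-12)
  expect_equal(ivw(r3)$se, cc * ivw(r)$se, tolerance = 1e-12)
  expect_equal(mr_egger(p3)$slope$beta, cc * mr_egger(p)$slope$beta,
               tolerance = 1e-12)

  # equal weights: weighted median reduces to the ordinary median
  req <- make_ratios(c(0.4, -1, 2, 0.9, 1.4), rep(1, 5))
  expect_equal(weighted_median(req, B = 100, seed = 1)$beta,
               median(req$ratio))
})

test_that("bootstrap SEs are seed-reproducible and stable across seeds", {
  set.seed(81)
  r <- make_ratios(rnorm(12, 1, 0.3), runif(12, 0.2, 0.6))
  a <- weighted_median(r, B = 1000, seed = 5)
  b <- weighted_median(r, B = 1000, seed = 5)
  expect_identical(a$se, b$se)
  c2 <- weighted_median(r, B = 1000, seed = 6)
  expect_lt(abs(a$se - c2$se) / a$se, 0.10)
})
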