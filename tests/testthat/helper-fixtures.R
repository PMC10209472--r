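# Fixtures are built in code; no stored data files.

# A small valid summary-statistics data frame (canonical columns).
make_sumstats_df <- function(n = 5L, seed = 101L, palindromic = FALSE) {
  set.seed(seed)
  ea <- if (palindromic) rep("A", n) else rep("A", n)
  oa <- if (palindromic) rep("T", n) else rep("G", n)
  beta <- rnorm(n, 0, 0.1)
  se <- runif(n, 0.01, 0.05)
  data.frame(
    variant_id = sprintf("rs%03d", seq_len(n)),
    effect_allele = ea, other_allele = oa,
    eaf = runif(n, 0.1, 0.4),
    beta = beta, se = se,
    pval = 2 * pnorm(-abs(beta / se)),
    stringsAsFactors = FALSE
  )
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Harmonised pairs straight from numbers, bypassing allele bookkeeping.
make_pairs <- function(gx_beta, gy_beta, gx_se, gy_se,
                       ids = sprintf("rs%03d", seq_along(gx_beta))) {
  data.frame(variant_id = ids, gx_beta = gx_beta, gx_se = gx_se,
             gy_beta = gy_beta, gy_se = gy_se,
             sign_flipped = FALSE, proxy_used = FALSE,
             palindromic_aligned = FALSE, stringsAsFactors = FALSE)
}

make_ratios <- function(ratio, se, ids = sprintf("rs%03d", seq_along(ratio))) {
  structure(data.frame(variant_id = ids, ratio = ratio, se = se,
                       weight = se^-2, stringsAsFactors = FALSE),
            class = c("ratio_estimates", "data.frame"))
}

# Random harmonised pairs for property-style loops.
random_pairs <- function(k, seed, beta = 0.3) {
  set.seed(seed)
  gamma <- abs(rnorm(k, 0, 0.15)) + 0.05
  gx_se <- runif(k, 0.01, 0.04)
  gy_se <- runif(k, 0.03, 0.12)
  make_pairs(gx_beta = gamma + rnorm(k, 0, gx_se),
             gy_beta = beta * gamma + rnorm(k, 0, gy_se),
             gx_se = gx_se, gy_se = gy_se)
}
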