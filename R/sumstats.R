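# Canonical column names for the summary-statistics dialect. `eaf` is optional
# on input; all others are required.
SUMSTAT_COLS <- c("variant_id", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval")
REQUIRED_COLS <- setdiff(SUMSTAT_COLS, "eaf")

DEFAULT_COLUMN_MAP <- c(
  variant_id = "SNP", effect_allele = "EA", other_allele = "OA",
  eaf = "EAF", beta = "BETA", se = "SE", pval = "P"
)

VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a GWAS summary-statistics table
#'
#' A `gwas_table` is a validated data frame of per-variant association summary
#' statistics for one trait: variant identifier, effect and other allele,
#' optional effect-allele frequency, log odds ratio per effect allele, its
#' standard error, and p-value. Rows violating the record invariants
#' (non-ACGT or identical alleles, `se <= 0`, `pval` outside (0, 1], `eaf`
#' outside (0, 1)) are dropped and logged in the `exclusions` attribute.
#'
#' @param df data frame with canonical columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval` and optionally `eaf`.
#' @param trait_label character scalar naming the trait.
#' @return A `gwas_table`: a data frame with attributes `trait_label` and
#'   `exclusions` (data frame of `variant_id`, `stage`, `reason`).
#' @export
gwas_table <- function(df, trait_label = "trait") {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(REQUIRED_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  df <- df[SUMSTAT_COLS]
  df$variant_id <- as.character(df$variant_id)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) df[[col]] <- as.numeric(df[[col]])

  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why
  flag(is.na(df$variant_id) | df$variant_id == "", "missing_variant_id")
  flag(duplicated(df$variant_id), "duplicate_variant_id")
  flag(!(df$effect_allele %in% VALID_ALLELES) |
         !(df$other_allele %in% VALID_ALLELES), "invalid_allele")
  flag(df$effect_allele == df$other_allele, "identical_alleles")
  flag(is.na(df$beta), "missing_beta")
  flag(is.na(df$se) | df$se <= 0, "nonpositive_se")
  flag(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "invalid_pval")
  flag(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "invalid_eaf")

  bad <- !is.na(reason)
  exclusions <- data.frame(
    variant_id = df$variant_id[bad],
    stage = rep("validate", sum(bad)),
    reason = reason[bad], stringsAsFactors = FALSE
  )
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, trait_label = trait_label, exclusions = exclusions,
            class = c("gwas_table", "data.frame"))
}

#' @export
print.gwas_table <- function(x, ...) {
  cat(sprintf("<gwas_table> %s: %d variant(s), %d excluded on validation\n",
              attr(x, "trait_label"), nrow(x), nrow(attr(x, "exclusions"))))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Reads a TSV with a header row, renames columns to the canonical dialect via
#' `column_map`, and validates each row. A missing required column is a
#' configuration error; rows violating record invariants are excluded and
#' logged, not fatal.
#'
#' @param path path to a tab-separated file with a header row.
#' @param column_map named character vector mapping canonical names
#'   (`variant_id`, `effect_allele`, ...) to the column names used in the
#'   file. Defaults cover the common SNP/EA/OA/EAF/BETA/SE/P convention;
#'   canonical names already present in the file are used as-is.
#' @param trait_label trait name attached to the table.
#' @return A [gwas_table()].
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("SNP\tEA\tOA\tEAF\tBETA\tSE\tP",
#'              "rs1\tA\tG\t0.30\t0.10\t0.02\t5e-9",
#'              "rs2\tC\tT\t0.55\t-0.08\t0.02\t1e-8"), tf)
#' gt <- read_sumstats(tf, trait_label = "example")
#' nrow(gt)
read_sumstats <- function(path, column_map = DEFAULT_COLUMN_MAP,
                          trait_label = "trait") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  # canonical names present in the file win; otherwise use the map
  for (canon in SUMSTAT_COLS) {
    if (canon %in% names(raw)) next
    alias <- unname(column_map[canon])
    if (!is.na(alias) && !is.null(alias) && alias %in% names(raw)) {
      names(raw)[names(raw) == alias] <- canon
    }
  }
  missing_cols <- setdiff(REQUIRED_COLS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("summary-statistics file lacks required column(s): ",
         paste(missing_cols, collapse = ", "),
         " (after applying column_map)", call. = FALSE)
  }
  gwas_table(raw, trait_label = trait_label)
}

#' Write a GWAS table in the canonical TSV dialect
#'
#' @param x a [gwas_table()] or compatible data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  utils::write.table(as.data.frame(x)[SUMSTAT_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns each exposure variant's outcome record to the exposure effect
#' allele. Swapped effect/other alleles negate the outcome beta (and reflect
#' its allele frequency). Palindromic variants (A/T, C/G), whose strand cannot
#' be read off the allele letters, are resolved by comparing effect-allele
#' frequencies on the two sides: if either frequency is missing or both fall
#' inside the ambiguity window the variant is dropped as
#' `palindromic_ambiguous`; if the aligned frequencies disagree about which
#' allele is minor, the outcome beta is negated (`palindromic_aligned`).
#' Variants with incompatible allele sets drop as `allele_mismatch`, and
#' exposure variants absent from the outcome drop as `missing_in_outcome`.
#' Every exposure variant lands in exactly one of `pairs` or `exclusions`.
#'
#' @param exposure,outcome [gwas_table()] objects (the outcome possibly
#'   augmented by [substitute_proxies()]).
#' @param ambiguity_window numeric length-2: effect-allele frequency band,
#'   symmetric about 0.5, within which a palindromic variant is considered
#'   unresolvable. Default `c(0.42, 0.58)`.
#' @return A `harmonised_set`: list with `pairs` (data frame of `variant_id`,
#'   `gx_beta`, `gx_se`, `gy_beta`, `gy_se`, logical flags `sign_flipped`,
#'   `proxy_used`, `palindromic_aligned`) and `exclusions`
#'   (`variant_id`, `stage`, `reason`).
#' @export
harmonise <- function(exposure, outcome, ambiguity_window = c(0.42, 0.58)) {
  stopifnot(inherits(exposure, "gwas_table"), inherits(outcome, "gwas_table"),
            length(ambiguity_window) == 2L,
            ambiguity_window[1] < ambiguity_window[2])
  proxy_map <- attr(outcome, "proxy_for")  # target_id -> TRUE, from proxies

  idx <- match(exposure$variant_id, outcome$variant_id)
  n <- nrow(exposure)
  pairs <- vector("list", n)
  excl <- vector("list", n)
  for (i in seq_len(n)) {
    ex <- exposure[i, ]
    drop <- function(why) {
      excl[[i]] <<- data.frame(variant_id = ex$variant_id,
                               stage = "harmonise", reason = why,
                               stringsAsFactors = FALSE)
    }
    if (is.na(idx[i])) { drop("missing_in_outcome"); next }
    oc <- outcome[idx[i], ]

    straight <- oc$effect_allele == ex$effect_allele &&
      oc$other_allele == ex$other_allele
    swapped <- oc$effect_allele == ex$other_allele &&
      oc$other_allele == ex$effect_allele
    if (!straight && !swapped) { drop("allele_mismatch"); next }

    gy_beta <- oc$beta
    gy_eaf <- oc$eaf
    sign_flipped <- FALSE
    if (swapped) {
      gy_beta <- -gy_beta
      if (!is.na(gy_eaf)) gy_eaf <- 1 - gy_eaf
      sign_flipped <- TRUE
    }

    pal <- is_palindromic(ex$effect_allele, ex$other_allele)
    pal_aligned <- FALSE
    if (pal) {
      # letters cannot resolve strand: fall back on allele frequency
      if (is.na(ex$eaf) || is.na(gy_eaf)) { drop("palindromic_ambiguous"); next }
      amb <- function(f) f >= ambiguity_window[1] & f <= ambiguity_window[2]
      if (amb(ex$eaf) && amb(gy_eaf)) { drop("palindromic_ambiguous"); next }
      if ((ex$eaf - 0.5) * (gy_eaf - 0.5) < 0) {
        # frequencies disagree about the minor allele: opposite strand coding
        gy_beta <- -gy_beta
        gy_eaf <- 1 - gy_eaf
        pal_aligned <- TRUE
      }
    }

    pairs[[i]] <- data.frame(
      variant_id = ex$variant_id,
      gx_beta = ex$beta, gx_se = ex$se,
      gy_beta = gy_beta, gy_se = oc$se,
      gx_eaf = ex$eaf, gy_eaf = gy_eaf,
      sign_flipped = sign_flipped,
      proxy_used = !is.null(proxy_map) && ex$variant_id %in% proxy_map,
      palindromic_aligned = pal_aligned,
      stringsAsFactors = FALSE
    )
  }

  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  excl <- do.call(rbind, excl[!vapply(excl, is.null, logical(1))])
  if (is.null(pairs)) pairs <- data.frame(
    variant_id = character(), gx_beta = numeric(), gx_se = numeric(),
    gy_beta = numeric(), gy_se = numeric(), gx_eaf = numeric(),
    gy_eaf = numeric(), sign_flipped = logical(), proxy_used = logical(),
    palindromic_aligned = logical(), stringsAsFactors = FALSE)
  if (is.null(excl)) excl <- data.frame(
    variant_id = character(), stage = character(), reason = character(),
    stringsAsFactors = FALSE)
  rownames(pairs) <- NULL

  structure(list(pairs = pairs, exclusions = excl),
            class = "harmonised_set")
}

#' @export
print.harmonised_set <- function(x, ...) {
  cat(sprintf("<harmonised_set> %d pair(s), %d exclusion(s)\n",
              nrow(x$pairs), nrow(x$exclusions)))
  if (nrow(x$exclusions) > 0L) {
    tab <- table(x$exclusions$reason)
    cat("  exclusions:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Substitute LD proxies for instruments missing from the outcome study
#'
#' For each exposure variant absent from the outcome table and covered by an
#' acceptable proxy (LD r-squared at or above `r2_threshold`), the proxy's
#' outcome record is relabelled to the target identifier with alleles
#' translated through the stated allele correspondence, so that downstream
#' harmonisation treats it as the target variant. Applied before
#' [harmonise()]; substituted targets carry the `proxy_used` flag there.
#'
#' @param exposure,outcome [gwas_table()] objects.
#' @param proxies data frame with columns `target_id`, `proxy_id`, `r2`,
#'   `proxy_effect_allele`, `target_effect_allele`.
#' @param r2_threshold minimum LD r-squared for acceptance (default 0.8).
#' @return The outcome `gwas_table` augmented with relabelled proxy records;
#'   attribute `proxy_for` lists substituted target ids and attribute
#'   `proxy_log` records the fate of every proxy offered.
#' @export
substitute_proxies <- function(exposure, outcome, proxies, r2_threshold = 0.8) {
  stopifnot(inherits(exposure, "gwas_table"), inherits(outcome, "gwas_table"))
  need <- c("target_id", "proxy_id", "r2",
            "proxy_effect_allele", "target_effect_allele")
  missing_cols <- setdiff(need, names(proxies))
  if (length(missing_cols) > 0L) {
    stop("proxy table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  log_rows <- list()
  add_log <- function(target, proxy, status, reason = "") {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      target_id = target, proxy_id = proxy, status = status, reason = reason,
      stringsAsFactors = FALSE)
  }
  out <- as.data.frame(outcome)
  used_targets <- character(0)
  for (i in seq_len(nrow(proxies))) {
    px <- proxies[i, ]
    if (px$target_id %in% out$variant_id) {
      add_log(px$target_id, px$proxy_id, "ignored", "target_present_in_outcome")
      next
    }
    if (is.na(px$r2) || px$r2 < r2_threshold) {
      add_log(px$target_id, px$proxy_id, "rejected", "r2_below_threshold")
      next
    }
    j <- match(px$proxy_id, out$variant_id)
    if (is.na(j)) {
      add_log(px$target_id, px$proxy_id, "rejected", "proxy_missing_in_outcome")
      next
    }
    t_idx <- match(px$target_id, exposure$variant_id)
    if (is.na(t_idx)) {
      add_log(px$target_id, px$proxy_id, "rejected", "target_not_in_exposure")
      next
    }
    target_ea <- toupper(px$target_effect_allele)
    proxy_ea <- toupper(px$proxy_effect_allele)
    target_oa <- if (target_ea == exposure$effect_allele[t_idx]) {
      exposure$other_allele[t_idx]
    } else if (target_ea == exposure$other_allele[t_idx]) {
      exposure$effect_allele[t_idx]
    } else {
      add_log(px$target_id, px$proxy_id, "rejected", "allele_map_inconsistent")
      next
    }
    rec <- out[j, ]
    if (rec$effect_allele == proxy_ea) {
      rec$effect_allele <- target_ea
      rec$other_allele <- target_oa
    } else if (rec$other_allele == proxy_ea) {
      # proxy's stated effect allele is the outcome's other allele
      rec$effect_allele <- target_oa
      rec$other_allele <- target_ea
    } else {
      add_log(px$target_id, px$proxy_id, "rejected", "allele_map_inconsistent")
      next
    }
    rec$variant_id <- px$target_id
    out <- rbind(out, rec)
    used_targets <- c(used_targets, px$target_id)
    add_log(px$target_id, px$proxy_id, "accepted")
  }
  rownames(out) <- NULL
  res <- structure(out, trait_label = attr(outcome, "trait_label"),
                   exclusions = attr(outcome, "exclusions"),
                   class = c("gwas_table", "data.frame"))
  attr(res, "proxy_for") <- unique(c(attr(outcome, "proxy_for"), used_targets))
  attr(res, "proxy_log") <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(target_id = character(), proxy_id = character(),
               status = character(), reason = character(),
               stringsAsFactors = FALSE)
  res
}

#' Read a proxy-map TSV
#'
#' Expects columns `target_id`, `proxy_id`, `r2`, `proxy_effect_allele`,
#' `target_effect_allele`.
#'
#' @param path path to a tab-separated proxy map with a header row.
#' @return data frame suitable for [substitute_proxies()].
#' @export
read_proxy_map <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Per-instrument F-statistics
#'
#' The instrument-strength F-statistic per variant is the squared ratio of the
#' gene-exposure estimate to its standard error. Variants with F at or below
#' `threshold` (conventionally 10) are reported as weak with a warning, not
#' removed.
#'
#' @param set a `harmonised_set` from [harmonise()].
#' @param threshold weak-instrument cut-off (default 10).
#' @return list of class `instrument_strength`: data frame `per_snp`
#'   (`variant_id`, `f`, `weak`), `f_min`, `f_max`, and `weak_ids`.
#' @export
instrument_f_stats <- function(set, threshold = 10) {
  stopifnot(inherits(set, "harmonised_set"))
  p <- set$pairs
  if (nrow(p) == 0L) stop("no harmonised pairs: cannot compute F-statistics",
                          call. = FALSE)
  f <- (p$gx_beta / p$gx_se)^2
  per <- data.frame(variant_id = p$variant_id, f = f, weak = f <= threshold,
                    stringsAsFactors = FALSE)
  weak_ids <- per$variant_id[per$weak]
  if (length(weak_ids) > 0L) {
    warning(sprintf("%d weak instrument(s) with F <= %g: %s",
                    length(weak_ids), threshold,
                    paste(weak_ids, collapse = ", ")), call. = FALSE)
  }
  structure(list(per_snp = per, f_min = min(f), f_max = max(f),
                 weak_ids = weak_ids, threshold = threshold),
            class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf("<instrument_strength> %d instrument(s); F in [%.3g, %.3g]; %d weak (F <= %g)\n",
              nrow(x$per_snp), x$f_min, x$f_max, length(x$weak_ids),
              x$threshold))
  invisible(x)
}

#' Write an exclusion log as TSV
#'
#' @param set a `harmonised_set` (or a data frame of `variant_id`, `stage`,
#'   `reason`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_exclusions <- function(set, path) {
  df <- if (inherits(set, "harmonised_set")) set$exclusions else set
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
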