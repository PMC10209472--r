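# Orchestration of a full two-sample MR direction and the bidirectional
# analysis, emitting plot-ready result tables.

#' Run configuration for one MR direction
#'
#' @param exposure path to the exposure summary-statistics TSV, or a
#'   [gwas_table()].
#' @param outcome path to the outcome summary-statistics TSV, or a
#'   [gwas_table()].
#' @param proxies optional proxy-map path or data frame (see
#'   [substitute_proxies()]).
#' @param r2_threshold LD r-squared acceptance threshold for proxies
#'   (default 0.8).
#' @param instrument_p_threshold genome-wide significance filter applied to
#'   the exposure p-values when selecting instruments (default 5e-8).
#' @param ambiguity_window palindromic allele-frequency ambiguity window.
#' @param methods robust methods to run in addition to IVW-FE; any of
#'   `"IVW-RE"`, `"WMe"`, `"WMo"`, `"Egger"`, `"Egger-SIMEX"`.
#' @param robust_when `"auto"` runs the robust methods only when the Q test
#'   is significant at `alpha` (mirroring reporting practice);
#'   `"always"`/`"never"` override.
#' @param alpha level for heterogeneity testing and outlier flagging.
#' @param B bootstrap/SIMEX draws.
#' @param seed integer seed for all stochastic steps.
#' @param exposure_map,outcome_map column maps for [read_sumstats()].
#' @param label direction label, e.g. `"GORD->IPF"`.
#' @return list of class `run_config`.
#' @export
run_config <- function(exposure, outcome, proxies = NULL,
                       r2_threshold = 0.8, instrument_p_threshold = 5e-8,
                       ambiguity_window = c(0.42, 0.58),
                       methods = c("IVW-RE", "WMe", "WMo", "Egger",
                                   "Egger-SIMEX"),
                       robust_when = c("auto", "always", "never"),
                       alpha = 0.05, B = 1000L, seed = 1L,
                       exposure_map = DEFAULT_COLUMN_MAP,
                       outcome_map = DEFAULT_COLUMN_MAP,
                       label = "X->Y") {
  robust_when <- match.arg(robust_when)
  stopifnot(r2_threshold > 0, r2_threshold <= 1,
            instrument_p_threshold > 0, instrument_p_threshold <= 1,
            alpha > 0, alpha < 1, B >= 100L)
  structure(list(exposure = exposure, outcome = outcome, proxies = proxies,
                 r2_threshold = r2_threshold,
                 instrument_p_threshold = instrument_p_threshold,
                 ambiguity_window = ambiguity_window, methods = methods,
                 robust_when = robust_when, alpha = alpha, B = as.integer(B),
                 seed = as.integer(seed), exposure_map = exposure_map,
                 outcome_map = outcome_map, label = label),
            class = "run_config")
}

resolve_table <- function(x, map, label) {
  if (inherits(x, "gwas_table")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(read_sumstats(x, column_map = map, trait_label = label))
  }
  if (is.data.frame(x)) return(gwas_table(x, trait_label = label))
  stop("expected a file path, data frame or gwas_table", call. = FALSE)
}

#' Run one MR direction
#'
#' Pipeline: filter the exposure to genome-wide-significant instruments,
#' substitute LD proxies into the outcome, harmonise, screen instrument
#' strength, form Wald ratios, pool by IVW-FE and test heterogeneity; when
#' heterogeneity is significant (or unconditionally with
#' `robust_when = "always"`), compute per-variant Q contributions, the
#' Bonferroni outlier removal refit, and the requested robust estimators
#' (Egger is SIMEX-corrected when `i2_gx < 0.9` and `"Egger-SIMEX"` is
#' requested). Leave-one-out always runs. Per-stage counts are logged to
#' stderr.
#'
#' @param cfg a [run_config()].
#' @return list of class `direction_report`: `label`,
#'   `n_instruments_initial`, `n_after_harmonisation`, `strength`,
#'   `estimates` (list of `mr_estimate`), `estimates_table`, `heterogeneity`,
#'   `q_contributions`, `outliers`, `loo`, `exclusions`, `harmonised`,
#'   `config` echo.
#' @export
run_direction <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  note <- function(...) message(sprintf("[%s] ", cfg$label), sprintf(...))
  exposure <- resolve_table(cfg$exposure, cfg$exposure_map, "exposure")
  outcome <- resolve_table(cfg$outcome, cfg$outcome_map, "outcome")

  keep <- exposure$pval < cfg$instrument_p_threshold
  dropped_p <- data.frame(
    variant_id = exposure$variant_id[!keep],
    stage = rep("instrument_selection", sum(!keep)),
    reason = rep("above_p_threshold", sum(!keep)), stringsAsFactors = FALSE)
  exposure_sel <- exposure[keep, , drop = FALSE]
  attr(exposure_sel, "class") <- class(exposure)
  attr(exposure_sel, "trait_label") <- attr(exposure, "trait_label")
  n0 <- nrow(exposure_sel)
  note("instrument selection: %d of %d exposure variant(s) at p < %g",
       n0, nrow(exposure), cfg$instrument_p_threshold)

  if (!is.null(cfg$proxies)) {
    proxies <- if (is.character(cfg$proxies)) read_proxy_map(cfg$proxies)
               else cfg$proxies
    outcome <- substitute_proxies(exposure_sel, outcome, proxies,
                                  r2_threshold = cfg$r2_threshold)
    plog <- attr(outcome, "proxy_log")
    note("proxy substitution: %d accepted, %d rejected/ignored",
         sum(plog$status == "accepted"), sum(plog$status != "accepted"))
  }

  hs <- harmonise(exposure_sel, outcome,
                  ambiguity_window = cfg$ambiguity_window)
  note("harmonisation: %d pair(s), %d exclusion(s)",
       nrow(hs$pairs), nrow(hs$exclusions))
  if (nrow(hs$pairs) < 2L) {
    stop(sprintf(
      "[%s] fewer than 2 usable instruments after harmonisation (%d); exclusions: %s",
      cfg$label, nrow(hs$pairs),
      paste(sprintf("%s(%s)", hs$exclusions$variant_id,
                    hs$exclusions$reason), collapse = ", ")), call. = FALSE)
  }

  strength <- withCallingHandlers(
    instrument_f_stats(hs),
    warning = function(w) { note("%s", conditionMessage(w))
                            invokeRestart("muffleWarning") })
  ratios <- wald_ratios(hs)
  fe <- ivw(ratios, mode = "FE")
  het <- cochran_q(ratios, fe)
  note("IVW-FE beta=%.4f se=%.4f p=%.3g; Q p=%.3g I2=%.0f%%",
       fe$beta, fe$se, fe$p, het$p, 100 * het$i2)

  estimates <- list(fe)
  qc <- NULL
  outliers <- NULL
  do_robust <- switch(cfg$robust_when,
                      auto = het$p < cfg$alpha,
                      always = TRUE, never = FALSE)
  if (do_robust && length(cfg$methods) > 0L) {
    qc <- q_contributions(ratios, fe, alpha = cfg$alpha)
    outliers <- tryCatch(remove_outliers_refit(ratios, alpha = cfg$alpha),
                         error = function(e) { note("outlier refit: %s",
                                                    conditionMessage(e))
                                               NULL })
    gx <- i2_gx(hs)
    for (m in cfg$methods) {
      e <- switch(m,
        "IVW-RE" = ivw(ratios, mode = "RE"),
        "WMe" = weighted_median(ratios, B = cfg$B, seed = cfg$seed),
        "WMo" = weighted_mode(ratios, B = cfg$B, seed = cfg$seed),
        "Egger" = mr_egger(hs)$slope,
        "Egger-SIMEX" = if (gx$simex_recommended) {
          egger_simex(hs, B = max(cfg$B, 200L), seed = cfg$seed)$slope
        } else NULL,
        stop("unknown method label: ", m, call. = FALSE))
      if (!is.null(e)) estimates <- c(estimates, list(e))
    }
  }
  loo <- if (nrow(ratios) >= 3L) leave_one_out(ratios) else NULL

  exclusions <- rbind(dropped_p, attr(exposure, "exclusions"),
                      hs$exclusions)
  structure(list(label = cfg$label,
                 n_instruments_initial = n0,
                 n_after_harmonisation = nrow(hs$pairs),
                 strength = strength, estimates = estimates,
                 estimates_table = estimates_table(estimates),
                 heterogeneity = het, q_contributions = qc,
                 outliers = outliers, loo = loo,
                 exclusions = exclusions, harmonised = hs,
                 config = cfg),
            class = "direction_report")
}

#' @export
print.direction_report <- function(x, ...) {
  cat(sprintf("<direction_report> %s: %d instrument(s) -> %d harmonised\n",
              x$label, x$n_instruments_initial, x$n_after_harmonisation))
  print.data.frame(x$estimates_table, digits = 4)
  print(x$heterogeneity)
  invisible(x)
}

#' Run the bidirectional analysis
#'
#' Two independent [run_direction()] calls with trait roles swapped. A
#' failure in one direction is recorded and does not block the other; the
#' report is flagged partial.
#'
#' @param forward_cfg,reverse_cfg [run_config()] objects for the two
#'   directions (instruments drawn from each direction's own exposure GWAS).
#' @return list of class `bidirectional_report`: `forward`, `reverse`
#'   (each a `direction_report` or a condition), `headline` (two-row data
#'   frame of direction, OR, CI, p), `partial`, `provenance`.
#' @export
run_bidirectional <- function(forward_cfg, reverse_cfg) {
  run_safe <- function(cfg) tryCatch(run_direction(cfg),
                                     error = function(e) e)
  fwd <- run_safe(forward_cfg)
  rev <- run_safe(reverse_cfg)
  headline_row <- function(dir) {
    if (inherits(dir, "error")) {
      return(data.frame(direction = NA_character_, or = NA_real_,
                        or_ci_low = NA_real_, or_ci_high = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    or <- to_odds_scale(dir$estimates[[1]])
    data.frame(direction = dir$label, or = or$odds_ratio,
               or_ci_low = or$or_ci_low, or_ci_high = or$or_ci_high,
               p = or$p, stringsAsFactors = FALSE)
  }
  headline <- rbind(headline_row(fwd), headline_row(rev))
  headline$direction[is.na(headline$direction)] <-
    c(forward_cfg$label, reverse_cfg$label)[is.na(headline$direction)]
  structure(list(forward = fwd, reverse = rev, headline = headline,
                 partial = inherits(fwd, "error") || inherits(rev, "error"),
                 provenance = list(
                   forward_config = forward_cfg,
                   reverse_config = reverse_cfg,
                   seeds = c(forward = forward_cfg$seed,
                             reverse = reverse_cfg$seed),
                   package_version = as.character(
                     utils::packageVersion("bimr")))),
            class = "bidirectional_report")
}

#' @export
print.bidirectional_report <- function(x, ...) {
  cat("<bidirectional_report>", if (x$partial) "(partial)" else "", "\n")
  print.data.frame(x$headline, digits = 4)
  invisible(x)
}

fmt_num <- function(x) formatC(x, digits = 10, format = "g")

direction_files <- function(dir_report, out_dir, prefix) {
  wt <- function(df, name) {
    path <- file.path(out_dir, paste0(prefix, "_", name, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  files <- character(0)
  files <- c(files, wt(dir_report$estimates_table, "estimates"))
  het <- dir_report$heterogeneity
  files <- c(files, wt(data.frame(
    Q = het$Q, df = het$df, p = het$p, i2 = het$i2,
    i2_ci_low = het$i2_ci_low, i2_ci_high = het$i2_ci_high), "heterogeneity"))
  if (!is.null(dir_report$q_contributions)) {
    qc <- dir_report$q_contributions
    files <- c(files, wt(cbind(as.data.frame(qc),
                               nominal_threshold = attr(qc, "nominal_threshold"),
                               bonferroni_threshold = attr(qc, "bonferroni_threshold")),
                         "q_contributions"))
  }
  if (!is.null(dir_report$loo)) {
    files <- c(files, wt(dir_report$loo$table, "leave_one_out"))
  }
  files <- c(files, wt(dir_report$exclusions, "exclusions"))
  files
}

direction_summary <- function(dir) {
  if (inherits(dir, "error")) {
    return(list(error = conditionMessage(dir)))
  }
  het <- dir$heterogeneity
  out <- list(
    label = dir$label,
    n_instruments_initial = dir$n_instruments_initial,
    n_after_harmonisation = dir$n_after_harmonisation,
    f_min = dir$strength$f_min, f_max = dir$strength$f_max,
    estimates = dir$estimates_table,
    heterogeneity = list(Q = het$Q, df = het$df, p = het$p, i2 = het$i2,
                         i2_ci_low = het$i2_ci_low,
                         i2_ci_high = het$i2_ci_high),
    exclusions = dir$exclusions
  )
  if (!is.null(dir$outliers)) {
    out$outliers <- list(
      flagged = dir$outliers$flagged,
      refit = list(beta = dir$outliers$refit$beta,
                   se = dir$outliers$refit$se,
                   p = dir$outliers$refit$p),
      refit_het_p = dir$outliers$refit_het$p)
  }
  if (!is.null(dir$loo)) {
    out$loo <- list(max_influence_id = dir$loo$max_influence_id)
  }
  out
}

#' Write a bidirectional report to disk
#'
#' Emits, per direction, the estimates table (the method-comparison figure
#' as data), heterogeneity, Q-contribution (the outlier figure as data),
#' leave-one-out and exclusion-log TSVs, plus one JSON summary for the whole
#' analysis. Output is bit-stable for identical inputs and seed.
#'
#' @param report a `bidirectional_report` (or a single `direction_report`).
#' @param out_dir output directory; created if absent.
#' @return character vector of files written, invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create output directory: ",
                                          out_dir, call. = FALSE)
  }
  if (inherits(report, "direction_report")) {
    files <- direction_files(report, out_dir, "direction")
    summary <- list(direction = direction_summary(report))
  } else {
    stopifnot(inherits(report, "bidirectional_report"))
    files <- character(0)
    if (!inherits(report$forward, "error")) {
      files <- c(files, direction_files(report$forward, out_dir, "forward"))
    }
    if (!inherits(report$reverse, "error")) {
      files <- c(files, direction_files(report$reverse, out_dir, "reverse"))
    }
    summary <- list(
      headline = report$headline,
      partial = report$partial,
      forward = direction_summary(report$forward),
      reverse = direction_summary(report$reverse),
      provenance = list(
        seeds = as.list(report$provenance$seeds),
        package_version = report$provenance$package_version,
        forward_label = report$provenance$forward_config$label,
        reverse_label = report$provenance$reverse_config$label,
        instrument_p_threshold =
          report$provenance$forward_config$instrument_p_threshold,
        r2_threshold = report$provenance$forward_config$r2_threshold,
        alpha = report$provenance$forward_config$alpha,
        B = report$provenance$forward_config$B))
  }
  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", na = "null",
                       pretty = TRUE)
  files <- c(files, json_path)
  invisible(files)
}
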