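#' Leave-one-out sensitivity analysis
#'
#' Drops each instrument in turn and recomputes the fixed- and
#' random-effects IVW estimates and Cochran's Q on the remaining
#' instruments.  The row whose exclusion moves the fixed-effects estimate
#' furthest from the full-set estimate is flagged as the most influential —
#' the usual way of spotting a single outlying variant driving
#' heterogeneity.
#'
#' @inheritParams mr_ivw
#' @return A data.frame of class `"mr_loo"` with one row per excluded
#'   variant: fixed and random estimates with ORs, `q`, `q_pval`,
#'   `delta_beta` (change from the full-set fixed estimate) and
#'   `most_influential`.
#' @export
leave_one_out <- function(instruments, scale_factor = 0.1, ci_level = 0.95) {
  J <- nrow(instruments)
  if (J < 3) {
    stop("leave-one-out requires at least 3 instruments", call. = FALSE)
  }
  full <- mr_ivw(instruments, "fixed", scale_factor, ci_level)
  rows <- lapply(seq_len(J), function(j) {
    sub <- instruments[-j, , drop = FALSE]
    fx <- mr_ivw(sub, "fixed", scale_factor, ci_level)
    rnd <- if (J - 1 >= 3) {
      mr_ivw(sub, "random", scale_factor, ci_level)
    } else {
      fx
    }
    het <- cochran_q(sub)
    data.frame(excluded_variant = instruments$variant_id[j],
               beta = fx$beta, se = fx$se,
               or = fx$or, or_ci_low = fx$or_ci_low, or_ci_high = fx$or_ci_high,
               pval = fx$pval,
               beta_random = rnd$beta, se_random = rnd$se,
               or_random_ci_low = rnd$or_ci_low,
               or_random_ci_high = rnd$or_ci_high,
               q = het$q, q_pval = het$pval,
               delta_beta = fx$beta - full$beta,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$most_influential <- abs(out$delta_beta) == max(abs(out$delta_beta))
  rownames(out) <- NULL
  structure(out, class = c("mr_loo", "data.frame"), full_beta = full$beta)
}

#' Screen one exposure against multiple outcomes
#'
#' Harmonises the exposure against each outcome table independently and
#' reports the fixed-effects IVW estimate per outcome — the layout used to
#' scan an exposure across a panel of risk factors for pleiotropic or
#' mediating pathways.  Outcomes sharing fewer than 2 variants with the
#' exposure are skipped with a warning.
#'
#' @param exposure An association table ([read_associations()] output).
#' @param outcomes Named list of association tables (or file paths).
#' @param proxies Optional proxy rules applied to every outcome.
#' @param scale_factor,ci_level As in [mr_ivw()].
#' @param r2_min Proxy linkage threshold.
#' @return A data.frame with one row per screened outcome: `outcome`,
#'   `n_instruments`, `beta`, `se`, `ci_low`, `ci_high`, `pval`, `or`,
#'   `or_ci_low`, `or_ci_high`.  Continuous outcomes are read off the beta
#'   columns, binary outcomes off the OR columns; both forms are reported.
#' @export
screen_outcomes <- function(exposure, outcomes, proxies = NULL,
                            scale_factor = 0.1, ci_level = 0.95,
                            r2_min = 0.8) {
  stopifnot(is.list(outcomes))
  if (length(outcomes) && is.null(names(outcomes))) {
    stop("outcomes must be a named list", call. = FALSE)
  }
  rows <- lapply(names(outcomes), function(label) {
    out_tab <- outcomes[[label]]
    if (is.character(out_tab)) {
      out_tab <- read_associations(out_tab, trait_label = label)
    }
    if (!is.null(proxies)) {
      out_tab <- substitute_proxies(out_tab, proxies, r2_min)
    }
    ins <- suppressMessages(harmonise(exposure, out_tab))
    if (nrow(ins) < 2) {
      warning("outcome '", label, "' shares fewer than 2 variants with the ",
              "exposure; skipped", call. = FALSE)
      return(NULL)
    }
    est <- mr_ivw(ins, "fixed", scale_factor, ci_level)
    cbind(data.frame(outcome = label, stringsAsFactors = FALSE),
          as.data.frame(est)[, c("beta", "se", "ci_low", "ci_high", "pval",
                                 "or", "or_ci_low", "or_ci_high",
                                 "n_instruments")])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(outcome = character(), beta = numeric(),
                      se = numeric(), ci_low = numeric(), ci_high = numeric(),
                      pval = numeric(), or = numeric(), or_ci_low = numeric(),
                      or_ci_high = numeric(), n_instruments = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Run the complete study pipeline
#'
#' End-to-end orchestration: read the exposure and outcome tables,
#' substitute proxies, harmonise, compute instrument diagnostics, fit every
#' enabled estimator, and run the leave-one-out analysis.  Optionally
#' screens additional outcomes.  Deterministic given `seed`.
#'
#' @param exposure,outcome Association tables or file paths.
#' @param proxies Optional proxy rules (data.frame or file path).
#' @param screening Optional named list of further outcome tables/paths for
#'   [screen_outcomes()].
#' @param trait_sd Exposure SD used if variance explained must be computed
#'   for the F-statistics (default 0.1).
#' @param r2_min Proxy linkage threshold (default 0.8).
#' @inheritParams mr_fit
#' @return An object of class `"mr_study"`: `fit` (the `"mr_fit"`), `loo`,
#'   `strength` (per-variant r2/F with `mean_f`, `total_r2`), `nome`,
#'   `screening`, `instruments`, plus the configuration used.
#' @examples
#' study <- mr_study(mriv_example("table2_magnesium.tsv"),
#'                   mriv_example("table2_cad.tsv"),
#'                   proxies = mriv_example("proxies.tsv"),
#'                   methods = c("ivw_fixed", "ivw_random"))
#' study
#' @export
mr_study <- function(exposure, outcome, proxies = NULL, screening = NULL,
                     methods = c("ivw_fixed", "ivw_random", "weighted_median",
                                 "egger", "egger_simex", "hpma"),
                     scale_factor = 0.1, ci_level = 0.95, n_boot = 10000,
                     simex_control = list(), hpma_control = list(),
                     trait_sd = 0.1, r2_min = 0.8, seed = NULL) {
  if (is.character(exposure)) {
    exposure <- read_associations(exposure, trait_label = "exposure")
  }
  if (is.character(outcome)) {
    outcome <- read_associations(outcome, trait_label = "outcome")
  }
  if (is.character(proxies)) proxies <- read_proxy_rules(proxies)
  if (!is.null(proxies)) {
    outcome <- substitute_proxies(outcome, proxies, r2_min)
  }
  instruments <- suppressMessages(harmonise(exposure, outcome))
  if (nrow(instruments) < 1) {
    stop("no instruments survived harmonisation", call. = FALSE)
  }
  fit <- mr_fit(instruments, methods = methods, scale_factor = scale_factor,
                ci_level = ci_level, n_boot = n_boot,
                simex_control = simex_control, hpma_control = hpma_control,
                seed = seed)
  loo <- if (nrow(instruments) >= 3) {
    leave_one_out(instruments, scale_factor, ci_level)
  } else {
    NULL
  }
  strength <- tryCatch(instrument_strength(instruments, trait_sd),
                       error = function(e) NULL)
  screening_tab <- if (!is.null(screening)) {
    screen_outcomes(exposure, screening, proxies, scale_factor, ci_level,
                    r2_min)
  } else {
    NULL
  }
  structure(list(fit = fit, loo = loo, strength = strength, nome = fit$nome,
                 screening = screening_tab, instruments = instruments,
                 scale_factor = scale_factor, ci_level = ci_level,
                 seed = seed),
            class = "mr_study")
}

#' @export
print.mr_study <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$strength)) {
    cat(sprintf("Mean instrument F = %.1f; total variance explained %.2f%%\n",
                attr(x$strength, "mean_f"), 100 * attr(x$strength, "total_r2")))
  }
  if (!is.null(x$loo)) {
    inf <- x$loo[x$loo$most_influential, ][1, ]
    cat(sprintf("Most influential instrument: %s (OR %.2f [%.2f, %.2f] after exclusion)\n",
                inf$excluded_variant, inf$or, inf$or_ci_low, inf$or_ci_high))
  }
  if (!is.null(x$screening) && nrow(x$screening)) {
    cat(sprintf("Screened %d additional outcome(s)\n", nrow(x$screening)))
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes `estimates.tsv`, `loo.tsv`, `screening.tsv` (when present) and a
#' `report.json` carrying the full-precision results; the TSV tables round
#' ORs and bounds to 2 decimals and p-values to 2 significant figures for
#' reading, while the JSON retains full precision.  Byte-identical across
#' runs with the same configuration and seed.
#'
#' @param study An `"mr_study"` object.
#' @param dir Output directory (created if needed).
#' @return The paths written, invisibly.
#' @export
write_mr_report <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  est <- estimates_table(study$fit)
  est_disp <- data.frame(method = est$method,
                         or = round(est$or, 2),
                         or_ci_low = round(est$or_ci_low, 2),
                         or_ci_high = round(est$or_ci_high, 2),
                         pval = signif(est$pval, 2),
                         n_instruments = est$n_instruments)
  p <- file.path(dir, "estimates.tsv")
  utils::write.table(est_disp, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(study$loo)) {
    p <- file.path(dir, "loo.tsv")
    loo_disp <- study$loo
    for (col in c("or", "or_ci_low", "or_ci_high")) {
      loo_disp[[col]] <- round(loo_disp[[col]], 2)
    }
    loo_disp$pval <- signif(loo_disp$pval, 2)
    utils::write.table(loo_disp, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(study$screening) && nrow(study$screening)) {
    p <- file.path(dir, "screening.tsv")
    utils::write.table(study$screening, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  report <- list(
    estimates = est,
    heterogeneity = unclass(study$fit$heterogeneity),
    nome = unclass(study$nome),
    strength = if (!is.null(study$strength)) {
      list(per_variant = study$strength,
           mean_f = attr(study$strength, "mean_f"),
           total_r2 = attr(study$strength, "total_r2"))
    },
    leave_one_out = study$loo,
    screening = study$screening,
    instruments = as.data.frame(study$instruments),
    scale_factor = study$scale_factor,
    ci_level = study$ci_level,
    seed = study$seed
  )
  p <- file.path(dir, "report.json")
  jsonlite::write_json(report[!vapply(report, is.null, logical(1))], p,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
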