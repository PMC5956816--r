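#' Fit the full set of Mendelian randomisation estimators
#'
#' One call running the requested causal estimators on a harmonised
#' instrument set — fixed- and random-effects IVW, the weighted median,
#' MR-Egger with and without SIMEX dilution correction, and
#' heterogeneity-penalised model averaging — together with Cochran's Q and
#' the I2GX instrument-error diagnostic.  This is the modelling entry point;
#' the returned object has `print`, `summary`, `coef`, `confint`, `plot`,
#' `residuals` and `simulate` methods.
#'
#' @param instruments An `"mr_instruments"` table from [harmonise()] or
#'   [mr_instruments()].
#' @param methods Estimators to run, any of `"ivw_fixed"`, `"ivw_random"`,
#'   `"weighted_median"`, `"egger"`, `"egger_simex"`, `"hpma"`.
#' @param scale_factor Exposure increment for the odds-ratio form of every
#'   estimate (default 0.1 exposure units).
#' @param ci_level Confidence level (default 0.95).
#' @param n_boot Bootstrap resamples for the weighted-median SE.
#' @param simex_control List of overrides for [mr_egger_simex()]
#'   (`lambda_grid`, `b_reps`, `extrapolant`).
#' @param hpma_control List of overrides for [mr_hpma()] (`grid_low`,
#'   `grid_high`, `grid_points`, `min_size`).
#' @param seed Integer seed; mandatory when a stochastic estimator
#'   (`weighted_median`, `egger_simex`) is requested.  Sub-seeds derived
#'   from it make the result independent of method order.
#' @return An object of class `"mr_fit"`: `estimates` (named list of
#'   `"mr_estimate"`s), `heterogeneity` (`"mr_het"`), `nome` (I2GX
#'   diagnostic, when at least 2 instruments), `egger` / `simex` / `hpma`
#'   (full method objects where run), `instruments`, `scale_factor`,
#'   `ci_level`, `seed`, `call`.
#' @examples
#' mg  <- read_associations(mriv_example("table2_magnesium.tsv"))
#' cad <- substitute_proxies(read_associations(mriv_example("table2_cad.tsv")),
#'                           read_proxy_rules(mriv_example("proxies.tsv")))
#' fit <- mr_fit(harmonise(mg, cad), seed = 42, n_boot = 2000,
#'               simex_control = list(b_reps = 200))
#' fit
#' @export
mr_fit <- function(instruments,
                   methods = c("ivw_fixed", "ivw_random", "weighted_median",
                               "egger", "egger_simex", "hpma"),
                   scale_factor = 0.1, ci_level = 0.95, n_boot = 10000,
                   simex_control = list(), hpma_control = list(),
                   seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  stochastic <- intersect(methods, c("weighted_median", "egger_simex"))
  if (length(stochastic) && is.null(seed)) {
    stop("a seed is mandatory when stochastic estimators are enabled (",
         paste(stochastic, collapse = ", "), ")", call. = FALSE)
  }
  estimates <- list()
  extras <- list()
  if ("ivw_fixed" %in% methods) {
    estimates$ivw_fixed <- mr_ivw(instruments, "fixed", scale_factor, ci_level)
  }
  if ("ivw_random" %in% methods) {
    estimates$ivw_random <- mr_ivw(instruments, "random", scale_factor,
                                   ci_level)
  }
  if ("weighted_median" %in% methods) {
    estimates$weighted_median <- mr_weighted_median(
      instruments, n_boot = n_boot, seed = seed + 1L,
      scale_factor = scale_factor, ci_level = ci_level)
  }
  if ("egger" %in% methods) {
    extras$egger <- mr_egger(instruments, scale_factor, ci_level)
    estimates$egger <- extras$egger$slope
  }
  if ("egger_simex" %in% methods) {
    args <- c(list(instruments = instruments, seed = seed + 2L,
                   scale_factor = scale_factor, ci_level = ci_level),
              simex_control)
    extras$simex <- do.call(mr_egger_simex, args)
    estimates$egger_simex <- extras$simex$slope
  }
  if ("hpma" %in% methods) {
    args <- c(list(instruments = instruments, scale_factor = scale_factor,
                   ci_level = ci_level), hpma_control)
    extras$hpma <- do.call(mr_hpma, args)
    estimates$hpma <- extras$hpma$estimate
  }
  het <- if (nrow(instruments) >= 2) cochran_q(instruments) else NULL
  nome <- if (nrow(instruments) >= 2) i2_gx(instruments) else NULL
  structure(c(list(estimates = estimates, heterogeneity = het, nome = nome,
                   instruments = instruments, scale_factor = scale_factor,
                   ci_level = ci_level, seed = seed,
                   call = match.call()),
              extras),
            class = "mr_fit")
}

# One row per estimate, OR form included
estimates_table <- function(fit) {
  do.call(rbind, lapply(fit$estimates, as.data.frame))
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("Two-sample MR fit: %d instruments, estimates per %g exposure units\n\n",
              nrow(x$instruments), x$scale_factor))
  tab <- estimates_table(x)
  disp <- data.frame(method = tab$method,
                     OR = sprintf("%.2f", tab$or),
                     CI = sprintf("[%.2f, %.2f]", tab$or_ci_low,
                                  tab$or_ci_high),
                     P = signif(tab$pval, 2))
  print(disp, row.names = FALSE)
  if (!is.null(x$heterogeneity)) {
    cat(sprintf("\nCochran's Q = %.2f on %d df (P = %.2g)\n",
                x$heterogeneity$q, x$heterogeneity$df, x$heterogeneity$pval))
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$estimates, `[[`, numeric(1), "beta")
}

#' @export
confint.mr_fit <- function(object, parm, level, ...) {
  tab <- estimates_table(object)
  out <- as.matrix(tab[, c("ci_low", "ci_high")])
  rownames(out) <- tab$method
  colnames(out) <- paste0(c((1 - object$ci_level) / 2,
                            1 - (1 - object$ci_level) / 2) * 100, " %")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
residuals.mr_fit <- function(object, ...) {
  # signed square-root contributions to Cochran's Q about the fixed IVW fit
  ivw <- mr_ivw(object$instruments, "fixed", object$scale_factor,
                object$ci_level)
  r <- sqrt(object$instruments$ivw_weight) *
    (object$instruments$ratio - ivw$beta)
  stats::setNames(r, object$instruments$variant_id)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object,
                 estimates = estimates_table(object),
                 ratios = ratio_estimates(object$instruments),
                 residuals = residuals(object)),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-variant Wald ratios:\n")
  print(cbind(x$ratios, q_contrib = round(x$residuals^2, 2)),
        row.names = FALSE)
  if (!is.null(x$fit$nome)) {
    cat(sprintf("\nI2GX = %.2f (relative Egger dilution %.0f%%)\n",
                x$fit$nome$i2_gx, 100 * x$fit$nome$relative_bias))
  }
  invisible(x)
}

#' Forest plot of per-variant and combined causal estimates
#'
#' Draws the per-variant Wald ratios (with normal confidence intervals) and
#' every fitted estimator on the exponentiated scale, the usual forest
#' display of a summary-data MR analysis.
#'
#' @param x An `"mr_fit"` object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mr_fit <- function(x, ...) {
  z <- ci_multiplier(x$ci_level)
  s <- x$scale_factor
  ins <- x$instruments
  tab <- estimates_table(x)
  labels <- c(ins$variant_id, toupper(tab$method))
  or <- c(exp(s * ins$ratio), tab$or)
  lo <- c(exp(s * (ins$ratio - z * ins$ratio_se)), tab$or_ci_low)
  hi <- c(exp(s * (ins$ratio + z * ins$ratio_se)), tab$or_ci_high)
  n <- length(or)
  y <- rev(seq_len(n))
  old <- graphics::par(mar = c(4, 9, 2, 2))
  on.exit(graphics::par(old))
  graphics::plot(or, y, xlim = range(lo, hi, 1, na.rm = TRUE),
                 ylim = c(0.5, n + 0.5), pch = 18,
                 cex = c(rep(1, nrow(ins)), rep(1.4, nrow(tab))),
                 yaxt = "n", ylab = "",
                 xlab = sprintf("OR per %g exposure units (log scale)", s),
                 log = "x", ...)
  graphics::segments(lo, y, hi, y)
  graphics::abline(v = 1, lty = 2, col = "grey50")
  graphics::abline(h = nrow(tab) + 0.5, lty = 3, col = "grey70")
  graphics::axis(2, at = y, labels = labels, las = 1, cex.axis = 0.8)
  invisible(x)
}

#' Simulate synthetic studies from a fitted model
#'
#' Parametric simulation conditioned on the fitted instrument set: the
#' observed exposure betas play the role of the true per-variant effects,
#' the fixed-effects IVW estimate (or `theta`) the true causal effect, and
#' new summary statistics are drawn with the observed standard errors.
#' Useful for checking estimator behaviour under a no-pleiotropy model that
#' matches the data's instrument strengths.
#'
#' @param object An `"mr_fit"`.
#' @param nsim Number of synthetic studies.
#' @param seed Integer seed.
#' @param theta True causal effect; defaults to the fixed-effects IVW
#'   estimate.
#' @param ... Unused.
#' @return A list of `nsim` synthetic studies (see [simulate_mr_study()]).
#' @export
simulate.mr_fit <- function(object, nsim = 1, seed = NULL, theta = NULL, ...) {
  ins <- object$instruments
  theta <- theta %||% mr_ivw(ins, "fixed")$beta
  base_seed <- seed %||% stats::runif(1, 1, 2^20)
  lapply(seq_len(nsim), function(i) {
    simulate_mr_study(n_variants = nrow(ins), theta = theta,
                      gamma = ins$beta_exposure, sigma_x = ins$se_exposure,
                      sigma_y = ins$se_outcome,
                      seed = as.integer(base_seed) + i)
  })
}
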