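# Container for a single causal-effect estimate.  `beta` is on the
# per-1-exposure-unit scale; the odds-ratio fields are reported per
# `scale_factor` exposure units, so `or = exp(scale_factor * beta)`.
new_mr_estimate <- function(method, beta, se, n_instruments,
                            scale_factor = 0.1, ci_level = 0.95,
                            pval = NULL, ci = NULL, extra = list()) {
  z <- ci_multiplier(ci_level)
  if (is.null(ci)) ci <- c(beta - z * se, beta + z * se)
  if (is.null(pval)) pval <- 2 * stats::pnorm(-abs(beta / se))
  est <- list(method = method, beta = beta, se = se,
              ci_low = ci[1], ci_high = ci[2], pval = pval,
              n_instruments = n_instruments,
              scale_factor = scale_factor, ci_level = ci_level,
              or = exp(scale_factor * beta),
              or_ci_low = exp(scale_factor * ci[1]),
              or_ci_high = exp(scale_factor * ci[2]))
  est[names(extra)] <- extra
  structure(est, class = "mr_estimate")
}

#' Rescale a causal estimate to a different exposure increment
#'
#' Multiplies the estimate, its standard error and confidence bounds by
#' `factor` (e.g. 0.1 to report per 0.1 mmol/L rather than per 1 mmol/L) and
#' recomputes the exponentiated (odds-ratio) form from the rescaled values.
#' The p-value is unchanged: rescaling is a units change, not a new test.
#'
#' @param estimate An `"mr_estimate"` object.
#' @param factor Positive exposure-unit multiplier.
#' @return The rescaled `"mr_estimate"`, with `scale_factor` reset to 1 so
#'   that the exponentiated fields continue to satisfy
#'   `or = exp(scale_factor * beta)`.
#' @export
rescale_estimate <- function(estimate, factor) {
  stopifnot(inherits(estimate, "mr_estimate"), factor > 0)
  out <- estimate
  out$beta <- estimate$beta * factor
  out$se <- estimate$se * factor
  out$ci_low <- estimate$ci_low * factor
  out$ci_high <- estimate$ci_high * factor
  out$scale_factor <- 1
  out$or <- exp(out$beta)
  out$or_ci_low <- exp(out$ci_low)
  out$or_ci_high <- exp(out$ci_high)
  out
}

#' @export
print.mr_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%s estimate (%d instruments)\n", x$method, x$n_instruments))
  cat(sprintf("  beta = %.*f (SE %.*f), %d%% CI [%.*f, %.*f], p = %.3g\n",
              digits, x$beta, digits, x$se,
              round(100 * x$ci_level), digits, x$ci_low, digits, x$ci_high,
              x$pval))
  cat(sprintf("  OR per %g exposure units: %.2f [%.2f, %.2f]\n",
              x$scale_factor, x$or, x$or_ci_low, x$or_ci_high))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             or = x$or, or_ci_low = x$or_ci_low, or_ci_high = x$or_ci_high,
             scale_factor = x$scale_factor,
             n_instruments = x$n_instruments,
             stringsAsFactors = FALSE)
}
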