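# Closed-form weighted least squares of y on x with an intercept and
# weights w.  Returns coefficients, their covariance scaled by the
# multiplicative overdispersion factor max(1, sqrt(Q_E / (n - 2))) (floored
# at 1 to mirror the IVW random-effects convention), and the weighted
# residual sum of squares Q_E.
wls_line <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  if (det <= 0) stop("degenerate regression: no variation in x", call. = FALSE)
  slope <- (sw * sxy - sx * sy) / det
  intercept <- (sy - slope * sx) / sw
  res <- y - intercept - slope * x
  q_e <- sum(w * res^2)
  n <- length(x)
  disp <- if (n > 2) max(1, sqrt(q_e / (n - 2))) else 1
  # (X' W X)^{-1}, scaled
  var_slope <- sw / det * disp^2
  var_intercept <- sxx / det * disp^2
  list(slope = slope, intercept = intercept,
       se_slope = sqrt(var_slope), se_intercept = sqrt(var_intercept),
       q_e = q_e, dispersion = disp, residuals = res)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of the outcome betas on the exposure
#' betas with an intercept, weights `1 / se_outcome^2`, all instruments
#' oriented to their exposure-raising allele.  The slope is a causal
#' estimate that remains consistent under directional pleiotropy provided
#' instrument strength is independent of the direct effects (InSIDE); the
#' intercept estimates the average per-allele pleiotropic effect, and an
#' intercept distinguishable from zero is evidence of directional
#' pleiotropy.  Standard errors come from the WLS covariance with a
#' multiplicative overdispersion factor `max(1, sqrt(Q_E / (J - 2)))`;
#' p-values are two-sided normal.
#'
#' @inheritParams mr_ivw
#' @return A list of class `"mr_egger"`: `slope` (an `"mr_estimate"`,
#'   method `"egger"`) and `intercept` (estimate, se, ci, pval on the
#'   per-allele log-odds scale).
#' @examples
#' mg  <- read_associations(mriv_example("table2_magnesium.tsv"))
#' cad <- substitute_proxies(read_associations(mriv_example("table2_cad.tsv")),
#'                           read_proxy_rules(mriv_example("proxies.tsv")))
#' mr_egger(harmonise(mg, cad))$intercept$estimate  # ~ -0.023
#' @export
mr_egger <- function(instruments, scale_factor = 0.1, ci_level = 0.95) {
  J <- nrow(instruments)
  if (J < 3) {
    stop("MR-Egger requires at least 3 instruments ",
         "(slope and intercept are not jointly identified with df otherwise)",
         call. = FALSE)
  }
  if (any(instruments$beta_exposure <= 0)) {
    stop("instruments must be oriented to the exposure-raising allele ",
         "before MR-Egger (run harmonise())", call. = FALSE)
  }
  fit <- wls_line(instruments$beta_exposure, instruments$beta_outcome,
                  1 / instruments$se_outcome^2)
  z <- ci_multiplier(ci_level)
  slope <- new_mr_estimate("egger", fit$slope, fit$se_slope, J,
                           scale_factor, ci_level,
                           extra = list(q_e = fit$q_e,
                                        dispersion = fit$dispersion))
  intercept <- list(
    estimate = fit$intercept, se = fit$se_intercept,
    ci_low = fit$intercept - z * fit$se_intercept,
    ci_high = fit$intercept + z * fit$se_intercept,
    pval = 2 * stats::pnorm(-abs(fit$intercept / fit$se_intercept))
  )
  structure(list(slope = slope, intercept = intercept,
                 residuals = fit$residuals),
            class = "mr_egger")
}

#' @export
print.mr_egger <- function(x, digits = 3, ...) {
  cat("MR-Egger regression\n")
  cat(sprintf("  slope:     %.*f (SE %.*f), p = %.3g; OR per %g units %.2f [%.2f, %.2f]\n",
              digits, x$slope$beta, digits, x$slope$se, x$slope$pval,
              x$slope$scale_factor, x$slope$or, x$slope$or_ci_low,
              x$slope$or_ci_high))
  cat(sprintf("  intercept: %.*f (SE %.*f), p = %.3g\n",
              digits, x$intercept$estimate, digits, x$intercept$se,
              x$intercept$pval))
  invisible(x)
}

#' SIMEX dilution correction for the MR-Egger slope
#'
#' Exposure-side measurement error dilutes the MR-Egger slope towards the
#' null (violation of the NO-Measurement-Error assumption; see [i2_gx()]).
#' Simulation extrapolation (SIMEX) corrects the dilution empirically: for
#' each error-inflation multiplier lambda in `lambda_grid`, every exposure
#' beta is perturbed by `sqrt(lambda) * se_exposure` normal noise `b_reps`
#' times and the Egger regression refit; the mean slope (and intercept) per
#' lambda, together with the unperturbed fit at lambda = 0, is extrapolated
#' by a polynomial in lambda back to lambda = -1, the error-free limit.
#' The standard error of the extrapolated slope is a jackknife over the
#' pseudo-replicates.
#'
#' @inheritParams mr_ivw
#' @param lambda_grid Distinct non-negative error-inflation multipliers
#'   (default `c(0.5, 1, 1.5, 2)`; lambda = 0 is always included via the
#'   naive fit).
#' @param b_reps Pseudo-replicates per lambda (default 1000, minimum 2).
#' @param extrapolant Polynomial degree of the extrapolation (default 2,
#'   quadratic).
#' @param seed Integer seed for the perturbations.
#' @return A list of class `"mr_egger_simex"`: `slope` (an `"mr_estimate"`,
#'   method `"egger_simex"`), `intercept` (point extrapolation), `naive`
#'   (the lambda = 0 [mr_egger()] fit) and the per-lambda mean slopes.
#' @export
mr_egger_simex <- function(instruments, lambda_grid = c(0.5, 1, 1.5, 2),
                           b_reps = 1000, extrapolant = 2, seed = NULL,
                           scale_factor = 0.1, ci_level = 0.95) {
  if (anyDuplicated(lambda_grid) || any(lambda_grid < 0)) {
    stop("lambda_grid must be distinct and non-negative", call. = FALSE)
  }
  if (b_reps < 2) stop("b_reps must be at least 2", call. = FALSE)
  n_lambda <- length(lambda_grid) + 1  # including lambda = 0
  if (n_lambda < extrapolant + 1) {
    stop("extrapolant degree ", extrapolant, " needs at least ",
         extrapolant + 1, " lambda points (including lambda = 0)",
         call. = FALSE)
  }
  naive <- mr_egger(instruments, scale_factor, ci_level)
  J <- nrow(instruments)
  w <- 1 / instruments$se_outcome^2
  by <- instruments$beta_outcome
  bx <- instruments$beta_exposure
  sx <- instruments$se_exposure

  fits <- with_seed(seed, {
    lapply(lambda_grid, function(lam) {
      slopes <- numeric(b_reps)
      ints <- numeric(b_reps)
      for (b in seq_len(b_reps)) {
        bx_b <- bx + sqrt(lam) * sx * stats::rnorm(J)
        f <- wls_line(bx_b, by, w)
        slopes[b] <- f$slope
        ints[b] <- f$intercept
      }
      list(slopes = slopes, ints = ints)
    })
  })
  slope_mat <- vapply(fits, `[[`, numeric(b_reps), "slopes")  # b_reps x L
  int_mat <- vapply(fits, `[[`, numeric(b_reps), "ints")

  lambdas <- c(0, lambda_grid)
  # Extrapolation at lambda = -1 is a fixed linear functional of the
  # per-lambda means: h = x0' (X'X)^{-1} X' with X the polynomial design.
  X <- outer(lambdas, 0:extrapolant, `^`)
  x0 <- (-1)^(0:extrapolant)
  h <- drop(x0 %*% solve(crossprod(X), t(X)))

  mean_slopes <- c(naive$slope$beta, colMeans(slope_mat))
  mean_ints <- c(naive$intercept$estimate, colMeans(int_mat))
  slope_simex <- sum(h * mean_slopes)
  int_simex <- sum(h * mean_ints)

  # Jackknife over pseudo-replicates: drop replicate b jointly across all
  # lambdas (the naive term is replicate-free and stays fixed).
  col_sums <- colSums(slope_mat)
  loo_means <- sweep(-slope_mat, 2, col_sums, `+`) / (b_reps - 1)  # b x L
  theta_loo <- h[1] * naive$slope$beta +
    drop(loo_means %*% h[-1])
  theta_bar <- mean(theta_loo)
  se_simex <- sqrt((b_reps - 1) / b_reps * sum((theta_loo - theta_bar)^2))

  slope <- new_mr_estimate("egger_simex", slope_simex, se_simex, J,
                           scale_factor, ci_level,
                           extra = list(lambda_grid = lambda_grid,
                                        b_reps = b_reps, seed = seed))
  structure(list(slope = slope, intercept = int_simex, naive = naive,
                 lambdas = lambdas, mean_slopes = mean_slopes),
            class = "mr_egger_simex")
}

#' @export
print.mr_egger_simex <- function(x, digits = 3, ...) {
  cat("SIMEX-corrected MR-Egger\n")
  cat(sprintf("  naive slope: %.*f; SIMEX slope: %.*f (SE %.*f), p = %.3g\n",
              digits, x$naive$slope$beta, digits, x$slope$beta,
              digits, x$slope$se, x$slope$pval))
  cat(sprintf("  SIMEX intercept: %.*f\n", digits, x$intercept))
  invisible(x)
}
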