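# Weighted median of x with positive weights w: sort x ascending, form
# standardised mid-cumulative weights p_j = (S_j - w_j/2) / S_total, and
# linearly interpolate x at p = 0.5.  Reduces to the ordinary median for
# equal weights; invariant to duplicating a point while halving its weight.
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0))
  if (sum(w) <= 0) stop("total weight must be positive", call. = FALSE)
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(x[1])
  if (0.5 >= p[length(p)]) return(x[length(x)])
  stats::approx(p, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted median causal estimate
#'
#' The weighted median of the per-variant Wald ratios, with the normalised
#' IVW weights: consistent as long as instruments carrying at least half of
#' the total weight are valid, so it tolerates up to 50% invalid instruments
#' where IVW tolerates none.  The standard error is estimated by parametric
#' bootstrap: each resample perturbs every exposure and outcome beta by a
#' normal draw with its reported standard error, recomputes ratios and
#' weights, and re-takes the weighted median; the SE is the standard
#' deviation of the resampled estimates and the confidence interval is
#' normal-based around the point estimate.
#'
#' @inheritParams mr_ivw
#' @param n_boot Number of bootstrap resamples (default 10000; at least
#'   1000 is recommended for a stable SE).
#' @param seed Integer seed for the bootstrap.  `NULL` uses the current RNG
#'   stream; supply a seed for reproducible intervals.
#' @return An `"mr_estimate"` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(instruments, n_boot = 10000, seed = NULL,
                               scale_factor = 0.1, ci_level = 0.95) {
  J <- nrow(instruments)
  if (J < 3) {
    stop("the weighted median requires at least 3 instruments", call. = FALSE)
  }
  beta <- weighted_median(instruments$ratio, instruments$ivw_weight)
  boots <- with_seed(seed, {
    bx <- matrix(stats::rnorm(J * n_boot, instruments$beta_exposure,
                              instruments$se_exposure), nrow = J)
    by <- matrix(stats::rnorm(J * n_boot, instruments$beta_outcome,
                              instruments$se_outcome), nrow = J)
    sy2 <- instruments$se_outcome^2
    vapply(seq_len(n_boot), function(b) {
      weighted_median(by[, b] / bx[, b], bx[, b]^2 / sy2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  new_mr_estimate("weighted_median", beta, se, J, scale_factor, ci_level,
                  extra = list(n_boot = n_boot, seed = seed))
}
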