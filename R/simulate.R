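#' Simulate a two-sample summary-statistics study with known truth
#'
#' Generates exposure and outcome association tables under the standard
#' two-sample generative model: each variant j has a true exposure effect
#' `gamma_j` and a direct (pleiotropic) outcome effect `alpha_j`; the true
#' outcome effect is `Gamma_j = theta * gamma_j + alpha_j`; the observed
#' betas are normal draws around the truth with the supplied standard
#' errors, and outcome effects live directly on the log-odds scale (no
#' individual-level case-control simulation — the estimators consume only
#' summary statistics).  Allele frequencies are Uniform(0.1, 0.9);
#' every variant is written as an unambiguous A/G variant so harmonisation
#' is exercised without strand ambiguity.
#'
#' Pleiotropy regimes (`pleiotropy$type`):
#' \describe{
#'   \item{`"none"`}{all instruments valid, `alpha_j = 0`.}
#'   \item{`"balanced_inside"`}{a fraction `frac_invalid` of instruments
#'     (the last ones, in variant order) draw `alpha ~ N(0, alpha_sd)`,
#'     independent of gamma (InSIDE holds).}
#'   \item{`"directional"`}{invalid instruments draw
#'     `alpha ~ N(alpha_mean, alpha_sd)` with `alpha_mean != 0`,
#'     independent of gamma.}
#'   \item{`"plurality"`}{invalid instruments split as evenly as possible
#'     into two clusters with pleiotropic means `+alpha_mean` and
#'     `-alpha_mean` (SD `alpha_sd`); the valid class must remain the
#'     largest, matching the assumption under which model averaging is
#'     consistent.}
#' }
#' Setting `inside_violation` to a non-zero value adds
#' `inside_violation * (gamma_j - mean(gamma))` to every invalid
#' instrument's alpha, correlating direct effects with instrument strength —
#' a deliberate InSIDE violation for negative tests of MR-Egger.
#'
#' Defaults emulate the magnesium instrument set: six variants, exposure
#' effects spanning 0.004-0.011 trait units with SE 0.001 (exposure GWAS of
#' ~24k individuals), outcome SEs of 0.011 log-odds (a case-control GWAS of
#' ~180k).
#'
#' @param n_variants Number of instruments J (>= 2).
#' @param theta True causal effect, log-odds per exposure unit.
#' @param gamma Per-variant true exposure effects: a length-J vector, or a
#'   length-2 range to draw from uniformly.
#' @param sigma_x,sigma_y Exposure/outcome standard errors (scalar or
#'   length J).
#' @param eaf_range Range of simulated effect-allele frequencies.
#' @param pleiotropy List with `type` and, as needed, `frac_invalid`,
#'   `alpha_mean`, `alpha_sd`, `inside_violation`.
#' @param n_exposure,n_outcome Nominal sample sizes written to the tables.
#' @param seed Integer seed; the study is fully reproducible from it.
#' @return A list of class `"mr_sim"`: `exposure` and `outcome` association
#'   tables (ready for [harmonise()]) and `truth` (`theta`, `gamma`,
#'   `alpha`, `valid`).
#' @examples
#' sim <- simulate_mr_study(theta = -1.25, seed = 7)
#' mr_ivw(harmonise(sim$exposure, sim$outcome))$beta
#' @export
simulate_mr_study <- function(n_variants = 6, theta = 0,
                              gamma = c(0.004, 0.011),
                              sigma_x = 0.001, sigma_y = 0.011,
                              eaf_range = c(0.1, 0.9),
                              pleiotropy = list(type = "none"),
                              n_exposure = 23829, n_outcome = 184305,
                              seed = NULL) {
  if (n_variants < 2) stop("need at least 2 variants", call. = FALSE)
  type <- match.arg(pleiotropy$type %||% "none",
                    c("none", "balanced_inside", "directional", "plurality"))
  frac_invalid <- pleiotropy$frac_invalid %||%
    (if (type == "none") 0 else 0.3)
  if (frac_invalid < 0 || frac_invalid >= 1) {
    stop("frac_invalid must lie in [0,1)", call. = FALSE)
  }
  alpha_mean <- pleiotropy$alpha_mean %||% 0.02
  alpha_sd <- pleiotropy$alpha_sd %||% 0.005
  kappa <- pleiotropy$inside_violation %||% 0
  sigma_x <- rep_len(sigma_x, n_variants)
  sigma_y <- rep_len(sigma_y, n_variants)
  if (any(sigma_x < 0) || any(sigma_y < 0)) {
    stop("standard errors must be non-negative", call. = FALSE)
  }

  with_seed(seed, {
    gam <- if (length(gamma) == n_variants) {
      gamma
    } else if (length(gamma) == 2) {
      stats::runif(n_variants, min(gamma), max(gamma))
    } else {
      stop("gamma must be length n_variants or a length-2 range",
           call. = FALSE)
    }
    n_invalid <- round(frac_invalid * n_variants)
    valid <- rep(TRUE, n_variants)
    if (type != "none" && n_invalid > 0) {
      valid[(n_variants - n_invalid + 1):n_variants] <- FALSE
    }
    alpha <- numeric(n_variants)
    inv <- which(!valid)
    if (length(inv)) {
      alpha[inv] <- switch(
        type,
        balanced_inside = stats::rnorm(length(inv), 0, alpha_sd),
        directional = stats::rnorm(length(inv), alpha_mean, alpha_sd),
        plurality = {
          half <- ceiling(length(inv) / 2)
          cluster <- ifelse(seq_along(inv) <= half, alpha_mean, -alpha_mean)
          n_valid <- n_variants - length(inv)
          if (max(half, length(inv) - half) >= n_valid) {
            stop("plurality regime requires the valid class to be the ",
                 "largest; reduce frac_invalid", call. = FALSE)
          }
          stats::rnorm(length(inv), cluster, alpha_sd)
        },
        stop("pleiotropy regime '", type, "' requires frac_invalid > 0",
             call. = FALSE)
      )
      if (kappa != 0) alpha[inv] <- alpha[inv] + kappa * (gam[inv] - mean(gam))
    }
    Gamma <- theta * gam + alpha
    bx <- stats::rnorm(n_variants, gam, sigma_x)
    by <- stats::rnorm(n_variants, Gamma, sigma_y)
    eaf <- stats::runif(n_variants, eaf_range[1], eaf_range[2])
    ids <- sprintf("sim%03d", seq_len(n_variants))

    make_tab <- function(beta, se, n) {
      pv <- ifelse(se > 0, 2 * stats::pnorm(-abs(beta / se)), NA_real_)
      structure(data.frame(variant_id = ids, effect_allele = "A",
                           other_allele = "G", eaf = eaf, beta = beta,
                           se = se, pval = pv, n = n,
                           variance_explained = NA_real_,
                           proxy_used = FALSE, stringsAsFactors = FALSE),
                class = c("mr_assoc", "data.frame"))
    }
    structure(list(exposure = make_tab(bx, sigma_x, n_exposure),
                   outcome = make_tab(by, sigma_y, n_outcome),
                   truth = list(theta = theta, gamma = gam, alpha = alpha,
                                valid = valid, regime = type)),
              class = "mr_sim")
  })
}

#' Write a simulated study to disk
#'
#' Writes `exposure.tsv` and `outcome.tsv` in the dialect
#' [read_associations()] consumes, and `truth.json` with the generating
#' parameters.
#'
#' @param sim An `"mr_sim"` object.
#' @param dir Output directory (created if needed).
#' @return The paths written, invisibly.
#' @export
write_simulated_study <- function(sim, dir) {
  stopifnot(inherits(sim, "mr_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rename <- function(tab) {
    names(tab)[names(tab) == "variant_id"] <- "snp"
    tab$proxy_used <- NULL
    tab
  }
  p_exp <- file.path(dir, "exposure.tsv")
  p_out <- file.path(dir, "outcome.tsv")
  p_truth <- file.path(dir, "truth.json")
  utils::write.table(rename(as.data.frame(sim$exposure)), p_exp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rename(as.data.frame(sim$outcome)), p_out, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, p_truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(p_exp, p_out, p_truth))
}

#' Estimator recovery experiment on simulated studies
#'
#' Repeatedly simulates a study, applies each requested estimator, and
#' aggregates bias, spread and interval coverage against the known truth.
#' Replicates on which an estimator fails are counted and reported, not
#' silently dropped.
#'
#' @param n_reps Number of simulated studies (>= 2; >= 100 recommended).
#' @param estimators Any of `"ivw_fixed"`, `"ivw_random"`,
#'   `"weighted_median"`, `"egger"`.
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @param n_boot Bootstrap resamples for the weighted-median SE within each
#'   replicate (kept small by default — the SE enters only coverage).
#' @param ci_level Interval level used for coverage.
#' @param ... Passed to [simulate_mr_study()] (`theta`, `gamma`,
#'   `pleiotropy`, ...).
#' @return A data.frame with one row per estimator: `mean_bias`,
#'   `empirical_se`, `rmse`, `coverage`, `n_ok`, `n_failed`.
#' @export
recovery_experiment <- function(n_reps = 100,
                                estimators = c("ivw_fixed", "ivw_random",
                                               "weighted_median", "egger"),
                                seed = 1, n_boot = 200, ci_level = 0.95,
                                ...) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  if (n_reps < 2) stop("n_reps must be at least 2", call. = FALSE)
  sim_args <- list(...)
  theta <- sim_args$theta %||% 0
  res <- lapply(seq_len(n_reps), function(r) {
    sim <- do.call(simulate_mr_study, c(sim_args, list(seed = seed + r)))
    ins <- suppressMessages(suppressWarnings(
      harmonise(sim$exposure, sim$outcome)))
    vapply(estimators, function(est) {
      tryCatch({
        e <- switch(est,
                    ivw_fixed = mr_ivw(ins, "fixed", ci_level = ci_level),
                    ivw_random = mr_ivw(ins, "random", ci_level = ci_level),
                    weighted_median = mr_weighted_median(
                      ins, n_boot = n_boot, seed = seed + r,
                      ci_level = ci_level),
                    egger = mr_egger(ins, ci_level = ci_level)$slope)
        c(beta = e$beta, covered = as.numeric(e$ci_low <= theta &
                                                theta <= e$ci_high))
      }, error = function(err) c(beta = NA_real_, covered = NA_real_))
    }, numeric(2))
  })
  betas <- t(vapply(res, function(m) m["beta", ], numeric(length(estimators))))
  covered <- t(vapply(res, function(m) m["covered", ],
                      numeric(length(estimators))))
  if (length(estimators) == 1) {
    betas <- matrix(betas, ncol = 1)
    covered <- matrix(covered, ncol = 1)
  }
  data.frame(
    estimator = estimators,
    mean_bias = colMeans(betas - theta, na.rm = TRUE),
    empirical_se = apply(betas, 2, stats::sd, na.rm = TRUE),
    rmse = sqrt(colMeans((betas - theta)^2, na.rm = TRUE)),
    coverage = colMeans(covered, na.rm = TRUE),
    n_ok = colSums(!is.na(betas)),
    n_failed = colSums(is.na(betas)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
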