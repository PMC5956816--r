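#' Variance in the exposure explained by one variant
#'
#' Standard biallelic additive-model definition:
#' `2 * eaf * (1 - eaf) * beta^2 / trait_sd^2`, the fraction of exposure
#' variance attributable to the variant under Hardy-Weinberg proportions.
#'
#' @param beta Per-allele effect on the exposure, in trait units.
#' @param eaf Effect-allele frequency in (0,1); a frequency of exactly 0 or
#'   1 carries no variance and returns 0.
#' @param trait_sd Standard deviation of the exposure in the same trait
#'   units.  Default 0.1, the approximate population SD of serum magnesium
#'   in mmol/L.
#' @return Fraction of variance explained.
#' @examples
#' variance_explained(0.010, 0.54, trait_sd = 0.0934)  # ~0.0057
#' @export
variance_explained <- function(beta, eaf, trait_sd = 0.1) {
  if (any(trait_sd <= 0)) stop("trait_sd must be positive", call. = FALSE)
  if (any(is.na(eaf)) || any(eaf < 0 | eaf > 1)) {
    stop("eaf must lie in [0,1]", call. = FALSE)
  }
  2 * eaf * (1 - eaf) * beta^2 / trait_sd^2
}

#' Instrument F-statistic
#'
#' Single-instrument, one-parameter form `r2 * (n - 2) / (1 - r2)`: the
#' F-statistic of the exposure-on-variant regression given the fraction of
#' variance explained and the GWAS sample size.  Values above ~10 are
#' conventionally taken to indicate that weak-instrument bias is limited.
#'
#' @param r2 Fraction of exposure variance explained, in `[0, 1)`.
#' @param n Exposure GWAS sample size (> 2).
#' @return The F value (vectorised over `r2` and `n`).
#' @examples
#' f_statistic(0.0057, 23829)  # ~136
#' @export
f_statistic <- function(r2, n) {
  if (any(is.na(r2)) || any(r2 < 0 | r2 >= 1)) {
    stop("r2 must lie in [0,1)", call. = FALSE)
  }
  if (any(n <= 2)) stop("n must exceed 2", call. = FALSE)
  r2 * (n - 2) / (1 - r2)
}

#' Per-variant instrument strength diagnostics
#'
#' Tabulates, for each instrument, the fraction of exposure variance it
#' explains and its F-statistic.  Variance explained is taken from the
#' instrument table's `variance_explained` column when present (e.g. as
#' published), and otherwise computed from the effect size and allele
#' frequency via [variance_explained()].
#'
#' @param instruments An `"mr_instruments"` table.
#' @param trait_sd Exposure SD used when variance explained must be computed.
#' @param n Exposure GWAS sample size; defaults to the table's `n_exposure`.
#' @return A data.frame with `variant_id`, `r2`, `f_stat`, plus attributes
#'   `mean_f` and `total_r2`.
#' @export
instrument_strength <- function(instruments, trait_sd = 0.1, n = NULL) {
  stopifnot(nrow(instruments) >= 1)
  r2 <- instruments$variance_explained
  if (is.null(r2) || all(is.na(r2))) {
    r2 <- variance_explained(instruments$beta_exposure,
                             instruments$eaf_exposure, trait_sd)
  }
  n <- n %||% instruments$n_exposure
  if (is.null(n) || all(is.na(n))) {
    stop("exposure sample size required to compute F-statistics",
         call. = FALSE)
  }
  out <- data.frame(variant_id = instruments$variant_id,
                    r2 = r2,
                    f_stat = f_statistic(r2, n),
                    stringsAsFactors = FALSE)
  structure(out, mean_f = mean(out$f_stat), total_r2 = sum(out$r2))
}

#' NO-Measurement-Error (NOME) diagnostic I2GX
#'
#' MR-Egger regression assumes the exposure-side betas are measured without
#' error; violation dilutes the Egger slope towards the null.  The I2GX
#' statistic quantifies the violation: with `Q_GX` the inverse-variance
#' weighted heterogeneity of the exposure betas about their weighted mean,
#' `I2GX = max(0, (Q_GX - (J - 1)) / Q_GX)`.  An I2GX near 1 means
#' exposure-side measurement error is negligible relative to the spread of
#' the true effects; `1 - I2GX` approximates the relative dilution of the
#' Egger slope, which [mr_egger_simex()] corrects.
#'
#' @param instruments An `"mr_instruments"` table with at least 2 rows.
#' @return A list of class `"nome_diag"`: `q_gx`, `df`, `i2_gx`,
#'   `relative_bias` (= 1 - i2_gx).
#' @examples
#' mg  <- read_associations(mriv_example("table2_magnesium.tsv"))
#' cad <- substitute_proxies(read_associations(mriv_example("table2_cad.tsv")),
#'                           read_proxy_rules(mriv_example("proxies.tsv")))
#' i2_gx(harmonise(mg, cad))  # ~0.87
#' @export
i2_gx <- function(instruments) {
  J <- nrow(instruments)
  if (J < 2) stop("I2GX requires at least 2 instruments", call. = FALSE)
  bx <- instruments$beta_exposure
  sx <- instruments$se_exposure
  stopifnot(all(sx > 0))
  w <- 1 / sx^2
  bw <- sum(w * bx) / sum(w)
  q_gx <- sum(w * (bx - bw)^2)
  i2 <- if (q_gx > 0) max(0, (q_gx - (J - 1)) / q_gx) else 0
  structure(list(q_gx = q_gx, df = J - 1, i2_gx = i2,
                 relative_bias = 1 - i2),
            class = "nome_diag")
}

#' @export
print.nome_diag <- function(x, ...) {
  cat(sprintf("NOME diagnostic: I2GX = %.3f (Q_GX = %.2f on %d df)\n",
              x$i2_gx, x$q_gx, x$df))
  cat(sprintf("Relative dilution of the MR-Egger slope: %.0f%%\n",
              100 * x$relative_bias))
  invisible(x)
}
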