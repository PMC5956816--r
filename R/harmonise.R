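#' Harmonise exposure and outcome associations into an instrument set
#'
#' Joins exposure and outcome summary statistics on variant id, resolves the
#' allele orientation of each pair, orients every instrument to its
#' exposure-raising allele, and computes the per-variant Wald ratio and
#' inverse-variance weight.
#'
#' Orientation proceeds in two steps.  First the outcome record is aligned
#' to the exposure's effect allele: if the outcome's effect allele matches it
#' the record is kept as-is; if the outcome is reported on the opposite
#' allele its beta is negated and its allele frequency complemented; a pair
#' whose alleles cannot be reconciled is dropped with a warning.  Palindromic
#' pairs (A/T or C/G) are resolved by comparing allele frequencies when both
#' are available and both lie outside `palindromic_window`, and dropped
#' otherwise.  When the non-effect allele is unrecorded (as in published
#' per-instrument tables that print only the trait-raising allele), matching
#' effect alleles are accepted with an "unverified strand" note.  Second,
#' any instrument whose exposure beta is negative has both betas negated so
#' that `beta_exposure > 0`; the Wald ratio `beta_outcome / beta_exposure`
#' is invariant to this, and the convention makes the sign of the MR-Egger
#' intercept interpretable.
#'
#' @param exposure,outcome Association tables ([read_associations()] output,
#'   or any data.frame with the same columns).
#' @param palindromic_window Frequency window around 0.5 within which
#'   palindromic variants are considered unresolvable (default
#'   `c(0.42, 0.58)`).
#' @return A `data.frame` of class `"mr_instruments"`, sorted by variant id,
#'   with columns `variant_id`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`, `eaf_exposure`, `n_exposure`,
#'   `variance_explained`, `ratio`, `ratio_se`, `ivw_weight`, `proxy_used`.
#'   An attribute `dropped` records variants excluded and why.
#' @examples
#' mg  <- read_associations(mriv_example("table2_magnesium.tsv"))
#' cad <- substitute_proxies(read_associations(mriv_example("table2_cad.tsv")),
#'                           read_proxy_rules(mriv_example("proxies.tsv")))
#' instruments <- harmonise(mg, cad)
#' instruments[, c("variant_id", "ratio", "ivw_weight")]
#' @export
harmonise <- function(exposure, outcome, palindromic_window = c(0.42, 0.58)) {
  stopifnot(is.data.frame(exposure), is.data.frame(outcome))
  for (col in c("other_allele", "eaf", "n", "variance_explained", "pval")) {
    if (!col %in% names(exposure)) exposure[[col]] <- NA
    if (!col %in% names(outcome)) outcome[[col]] <- NA
  }
  if (!"proxy_used" %in% names(outcome)) outcome$proxy_used <- FALSE

  shared <- intersect(exposure$variant_id, outcome$variant_id)
  dropped <- data.frame(variant_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  drop <- function(id, why) {
    dropped <<- rbind(dropped, data.frame(variant_id = id, reason = why,
                                          stringsAsFactors = FALSE))
    warning("variant ", id, " dropped during harmonisation: ", why,
            call. = FALSE)
  }
  complement <- c(A = "T", T = "A", C = "G", G = "C")
  is_palindromic <- function(ea, oa) {
    !is.na(ea) && !is.na(oa) && identical(unname(complement[ea]), oa)
  }

  rows <- vector("list", length(shared))
  for (k in seq_along(shared)) {
    id <- shared[k]
    ex <- exposure[match(id, exposure$variant_id), ]
    ou <- outcome[match(id, outcome$variant_id), ]
    ea_x <- ex$effect_allele; oa_x <- ex$other_allele
    ea_y <- ou$effect_allele; oa_y <- ou$other_allele
    beta_y <- ou$beta; eaf_y <- ou$eaf

    if (identical(ea_y, ea_x)) {
      flip <- FALSE
    } else if ((!is.na(oa_x) && identical(ea_y, oa_x)) ||
               (!is.na(oa_y) && identical(oa_y, ea_x))) {
      flip <- TRUE
    } else {
      drop(id, paste0("alleles irreconcilable (exposure ", ea_x, "/",
                      oa_x %||% "?", ", outcome ", ea_y, "/",
                      oa_y %||% "?", ")"))
      next
    }
    if (flip) {
      beta_y <- -beta_y
      eaf_y <- if (is.na(eaf_y)) NA_real_ else 1 - eaf_y
    }
    if (is_palindromic(ea_x, oa_x)) {
      f_x <- ex$eaf; f_y <- eaf_y
      resolvable <- !is.na(f_x) && !is.na(f_y) &&
        (f_x < palindromic_window[1] || f_x > palindromic_window[2]) &&
        (f_y < palindromic_window[1] || f_y > palindromic_window[2])
      if (!resolvable) {
        drop(id, "palindromic with unresolvable allele frequencies")
        next
      }
      if ((f_x > 0.5) != (f_y > 0.5)) {
        # outcome reported on the opposite strand: same letter names the
        # complementary allele, so the aligned record must be flipped
        beta_y <- -beta_y
        eaf_y <- 1 - eaf_y
      }
    }
    if (is.na(oa_x) || (is.na(oa_y) && !flip)) {
      message("variant ", id,
              ": non-effect allele unrecorded; strand match unverified")
    }
    if (is.na(ex$beta) || ex$beta == 0) {
      drop(id, "zero exposure beta (undefined Wald ratio)")
      next
    }
    beta_x <- ex$beta
    if (beta_x < 0) {  # orient to the exposure-raising allele
      beta_x <- -beta_x
      beta_y <- -beta_y
    }
    rows[[k]] <- data.frame(
      variant_id = id,
      beta_exposure = beta_x,
      se_exposure = ex$se,
      beta_outcome = beta_y,
      se_outcome = ou$se,
      eaf_exposure = ex$eaf,
      n_exposure = ex$n,
      variance_explained = ex$variance_explained,
      ratio = beta_y / beta_x,
      ratio_se = ou$se / beta_x,
      ivw_weight = beta_x^2 / ou$se^2,
      proxy_used = isTRUE(ou$proxy_used),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(variant_id = character(), beta_exposure = numeric(),
                      se_exposure = numeric(), beta_outcome = numeric(),
                      se_outcome = numeric(), eaf_exposure = numeric(),
                      n_exposure = numeric(), variance_explained = numeric(),
                      ratio = numeric(), ratio_se = numeric(),
                      ivw_weight = numeric(), proxy_used = logical(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("mr_instruments", "data.frame"), dropped = dropped)
}

#' Construct an instrument table directly
#'
#' Builds an `"mr_instruments"` table from already-oriented summary
#' statistics, computing the Wald ratio and inverse-variance weight.  Useful
#' for simulated data and for re-analysing a published instrument table that
#' is already on the exposure-raising orientation.
#'
#' @param variant_id Character vector of variant identifiers.
#' @param beta_exposure,se_exposure Exposure effects (must be positive after
#'   orientation) and standard errors.
#' @param beta_outcome,se_outcome Outcome effects and standard errors.
#' @param ... Further per-variant columns carried through (e.g.
#'   `eaf_exposure`, `n_exposure`, `variance_explained`).
#' @return An `"mr_instruments"` data.frame sorted by variant id.
#' @export
mr_instruments <- function(variant_id, beta_exposure, se_exposure,
                           beta_outcome, se_outcome, ...) {
  stopifnot(all(se_exposure > 0), all(se_outcome > 0),
            all(beta_exposure != 0))
  sgn <- sign(beta_exposure)
  out <- data.frame(variant_id = as.character(variant_id),
                    beta_exposure = beta_exposure * sgn,
                    se_exposure = se_exposure,
                    beta_outcome = beta_outcome * sgn,
                    se_outcome = se_outcome,
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  if (!"proxy_used" %in% names(out)) out$proxy_used <- FALSE
  out$ratio <- out$beta_outcome / out$beta_exposure
  out$ratio_se <- out$se_outcome / out$beta_exposure
  out$ivw_weight <- out$beta_exposure^2 / out$se_outcome^2
  out <- out[order(out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("mr_instruments", "data.frame"),
            dropped = data.frame(variant_id = character(),
                                 reason = character(),
                                 stringsAsFactors = FALSE))
}
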