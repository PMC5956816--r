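#' Enumerate instrument subsets with their IVW summaries
#'
#' Every subset of the instruments of at least `min_size` members, each with
#' its fixed-effects IVW estimate, standard error and Cochran's Q.  This is
#' the support of the heterogeneity-penalised model average: subsets that
#' mix instruments with conflicting causal signals acquire a large Q and are
#' down-weighted by [mr_hpma()].
#'
#' @param instruments An `"mr_instruments"` table with at most `max_j` rows.
#' @param min_size Smallest subset size retained (default 2, the smallest
#'   size on which Q is defined).
#' @param max_j Enumeration guard: exhaustive enumeration is refused above
#'   this many instruments (default 20, i.e. ~1e6 subsets).
#' @return A data.frame with one row per subset: `mask` (membership string
#'   in instrument order), `variants`, `size`, `beta_s`, `se_s`, `q_s`.
#' @export
enumerate_subsets <- function(instruments, min_size = 2, max_j = 20) {
  J <- nrow(instruments)
  if (min_size < 2) stop("min_size must be at least 2", call. = FALSE)
  if (J < min_size) {
    stop("need at least ", min_size, " instruments", call. = FALSE)
  }
  if (J > max_j) {
    stop("exhaustive enumeration refused for ", J, " > ", max_j,
         " instruments (2^J subsets); no sampling fallback is implemented",
         call. = FALSE)
  }
  w <- instruments$ivw_weight
  r <- instruments$ratio
  ids <- instruments$variant_id
  rows <- vector("list", 2^J)
  for (m in seq_len(2^J - 1)) {
    members <- which(bitwAnd(m, bitwShiftL(1L, 0:(J - 1))) != 0L)
    if (length(members) < min_size) next
    ws <- w[members]
    beta_s <- sum(ws * r[members]) / sum(ws)
    rows[[m]] <- data.frame(
      mask = paste(as.integer(seq_len(J) %in% members), collapse = ""),
      variants = paste(ids[members], collapse = ","),
      size = length(members),
      beta_s = beta_s,
      se_s = 1 / sqrt(sum(ws)),
      q_s = sum(ws * (r[members] - beta_s)^2),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Heterogeneity-penalised model-averaging causal estimate
#'
#' A plurality-valid estimator: it remains consistent when the largest group
#' of instruments sharing one causal ratio is the valid group, even if that
#' group is a minority overall.  Each subset S of at least `min_size`
#' instruments receives weight proportional to
#' `(prod of members' normalised IVW weights) * exp(-Q_S / 2)`,
#' so subsets whose members disagree (large Q_S) are exponentially
#' penalised.  The composite function
#' `L(theta) = sum_S w_S * dnorm(theta; beta_S, se_S)`
#' is evaluated on a grid; the estimate is its mode, and the 95% region is
#' the highest-density superlevel set containing 95% of the total grid mass
#' — which may be a union of disjoint intervals when instrument clusters
#' disagree, in which case all intervals are reported along with their
#' enclosing hull and a non-contiguity flag.
#'
#' The reported p-value is twice the smaller of the composite mass on
#' either side of zero — a tail-mass analogue of a two-sided test under the
#' composite function.
#'
#' @inheritParams enumerate_subsets
#' @param grid_low,grid_high Grid limits on the per-unit causal scale;
#'   default `min(beta_s) - 4 * max(se_s)` to `max(beta_s) + 4 * max(se_s)`.
#' @param grid_points Number of grid points (default 2001).
#' @param scale_factor,ci_level As in [mr_ivw()]; `ci_level` sets the region
#'   mass.
#' @return A list of class `"mr_hpma"`: `estimate` (an `"mr_estimate"` whose
#'   CI is the enclosing hull of the region, method `"hpma"`), `mode`,
#'   `region` (matrix of interval bounds and masses), `non_contiguous`,
#'   `subsets` (the weighted subset table), `grid`, `density`.
#' @examples
#' mg  <- read_associations(mriv_example("table2_magnesium.tsv"))
#' cad <- substitute_proxies(read_associations(mriv_example("table2_cad.tsv")),
#'                           read_proxy_rules(mriv_example("proxies.tsv")))
#' fit <- mr_hpma(harmonise(mg, cad))
#' fit$estimate$or  # ~0.84 per 0.1 mmol/L
#' @export
mr_hpma <- function(instruments, grid_low = NULL, grid_high = NULL,
                    grid_points = 2001, min_size = 2, max_j = 20,
                    scale_factor = 0.1, ci_level = 0.95) {
  subsets <- enumerate_subsets(instruments, min_size, max_j)
  p_j <- instruments$ivw_weight / sum(instruments$ivw_weight)
  log_p <- log(p_j)
  mask_mat <- vapply(strsplit(subsets$mask, ""),
                     function(ch) as.integer(ch), integer(nrow(instruments)))
  log_w <- drop(crossprod(mask_mat, log_p)) - subsets$q_s / 2
  w_s <- exp(log_w - max(log_w))
  subsets$weight <- w_s / sum(w_s)

  grid_low <- grid_low %||% (min(subsets$beta_s) - 4 * max(subsets$se_s))
  grid_high <- grid_high %||% (max(subsets$beta_s) + 4 * max(subsets$se_s))
  if (grid_high <= grid_low) stop("empty grid", call. = FALSE)
  grid <- seq(grid_low, grid_high, length.out = grid_points)
  # mixture of normals, vectorised over the grid
  dens <- rowSums(vapply(seq_len(nrow(subsets)), function(s) {
    subsets$weight[s] * stats::dnorm(grid, subsets$beta_s[s], subsets$se_s[s])
  }, numeric(grid_points)))

  i_mode <- which.max(dens)
  if (i_mode == 1L || i_mode == grid_points) {
    stop("composite-function mode at the grid boundary; widen the grid ",
         "(grid_low/grid_high)", call. = FALSE)
  }
  mode <- grid[i_mode]

  mass <- dens / sum(dens)
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  thr <- dens[ord][which(cum >= ci_level)[1]]
  in_region <- dens >= thr
  runs <- rle(in_region)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  region <- cbind(low = grid[starts[keep]], high = grid[ends[keep]],
                  mass = vapply(keep, function(k) {
                    sum(mass[starts[k]:ends[k]])
                  }, numeric(1)))
  non_contiguous <- nrow(region) > 1

  p_below <- sum(mass[grid < 0])
  pval <- min(1, 2 * min(p_below, 1 - p_below))
  hull <- c(min(region[, "low"]), max(region[, "high"]))
  estimate <- new_mr_estimate("hpma", mode, NA_real_,
                              nrow(instruments), scale_factor, ci_level,
                              pval = pval, ci = hull,
                              extra = list(non_contiguous = non_contiguous))
  structure(list(estimate = estimate, mode = mode, region = region,
                 non_contiguous = non_contiguous, subsets = subsets,
                 grid = grid, density = dens),
            class = "mr_hpma")
}

#' @export
print.mr_hpma <- function(x, digits = 3, ...) {
  cat(sprintf("Heterogeneity-penalised model average over %d subsets\n",
              nrow(x$subsets)))
  cat(sprintf("  mode = %.*f; OR per %g units %.2f\n", digits, x$mode,
              x$estimate$scale_factor, x$estimate$or))
  cat(sprintf("  %d%% region%s:\n", round(100 * x$estimate$ci_level),
              if (x$non_contiguous) " (non-contiguous)" else ""))
  for (i in seq_len(nrow(x$region))) {
    cat(sprintf("    [%.*f, %.*f] (mass %.3f)\n", digits, x$region[i, "low"],
                digits, x$region[i, "high"], x$region[i, "mass"]))
  }
  cat(sprintf("  tail-mass p = %.3g\n", x$estimate$pval))
  invisible(x)
}
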