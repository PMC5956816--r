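#' Read a table of variant-trait associations
#'
#' Reads delimited GWAS summary statistics into a validated association
#' table: one row per variant with alleles, effect-allele frequency, the
#' per-allele effect estimate and its standard error.  Rows that cannot
#' support downstream estimation (missing or non-positive standard error,
#' missing beta, malformed alleles or frequencies) are rejected with a
#' recorded reason rather than silently kept.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping the canonical field names
#'   (`variant_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pval`, `n`, `variance_explained`) to the column names used in the file.
#'   Only the names you want to override need be given; defaults follow the
#'   common `snp`/`effect_allele`/`beta`/`se` dialect.
#' @param trait_label Optional label describing the trait (used in messages
#'   and kept as an attribute).
#' @param sep Field separator, tab by default.
#' @return A `data.frame` of class `"mr_assoc"` with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`,
#'   `variance_explained`, `proxy_used`.  Attributes `trait_label`,
#'   `n_accepted`, `n_rejected` and `rejected` (a data.frame of dropped rows
#'   with reasons) record the validation outcome.
#' @examples
#' mg <- read_associations(mriv_example("table2_magnesium.tsv"),
#'                         trait_label = "serum magnesium")
#' nrow(mg)
#' @export
read_associations <- function(path, column_map = NULL, trait_label = NULL,
                              sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  map <- c(variant_id = "snp", effect_allele = "effect_allele",
           other_allele = "other_allele", eaf = "eaf", beta = "beta",
           se = "se", pval = "pval", n = "n",
           variance_explained = "variance_explained")
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(map))
    if (length(bad)) {
      stop("unknown column_map field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    map[names(column_map)] <- column_map
  }
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = "character",
                           check.names = FALSE)
  mandatory <- c("variant_id", "effect_allele", "beta", "se")
  missing_cols <- mandatory[!map[mandatory] %in% names(raw)]
  if (length(missing_cols)) {
    stop("mandatory column(s) not found in ", path, ": ",
         paste(map[missing_cols], collapse = ", "), call. = FALSE)
  }
  get_col <- function(field, n_row) {
    col <- map[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(NA_character_, n_row)
  }
  n_row <- nrow(raw)
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- data.frame(
    variant_id = trimws(get_col("variant_id", n_row)),
    effect_allele = toupper(trimws(get_col("effect_allele", n_row))),
    other_allele = toupper(trimws(get_col("other_allele", n_row))),
    eaf = num(get_col("eaf", n_row)),
    beta = num(get_col("beta", n_row)),
    se = num(get_col("se", n_row)),
    pval = num(get_col("pval", n_row)),
    n = num(get_col("n", n_row)),
    variance_explained = num(get_col("variance_explained", n_row)),
    stringsAsFactors = FALSE
  )
  out$other_allele[!out$other_allele %in% c("A", "C", "G", "T")] <- NA_character_
  out$proxy_used <- rep(FALSE, n_row)

  reason <- rep(NA_character_, n_row)
  flag <- function(cond, why) reason[is.na(reason) & cond] <<- why
  flag(is.na(out$variant_id) | !nzchar(out$variant_id), "missing variant id")
  flag(!out$effect_allele %in% c("A", "C", "G", "T"), "invalid effect allele")
  flag(is.na(out$beta), "missing beta")
  flag(is.na(out$se), "missing SE")
  flag(!is.na(out$se) & out$se <= 0, "non-positive SE")
  flag(!is.na(out$eaf) & (out$eaf < 0 | out$eaf > 1), "EAF outside [0,1]")
  flag(!is.na(out$pval) & (out$pval <= 0 | out$pval > 1), "p-value outside (0,1]")
  flag(!is.na(out$other_allele) & out$other_allele == out$effect_allele,
       "identical alleles")

  keep <- is.na(reason)
  rejected <- data.frame(variant_id = out$variant_id[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    message(sum(!keep), " row(s) rejected reading ",
            trait_label %||% basename(path), ": ",
            paste(unique(rejected$reason), collapse = "; "))
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("mr_assoc", "data.frame"),
            trait_label = trait_label,
            n_accepted = nrow(out),
            n_rejected = nrow(rejected),
            rejected = rejected)
}

#' Read proxy-substitution rules
#'
#' A proxy rule states that a missing target variant may be represented by a
#' linked variant, with the linkage r-squared (computed on an external
#' reference panel; supplied here as metadata) and a mapping between the
#' proxy's alleles and the target's alleles.
#'
#' @param path Tab-separated file with columns `target_id`, `proxy_id`, `r2`
#'   and optionally `target_effect_allele`, `proxy_effect_allele`,
#'   `target_other_allele`, `proxy_other_allele`.
#' @return A data.frame of rules.
#' @export
read_proxy_rules <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rules <- utils::read.delim(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  needed <- c("target_id", "proxy_id", "r2")
  missing_cols <- setdiff(needed, names(rules))
  if (length(missing_cols)) {
    stop("proxy rule file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("target_effect_allele", "proxy_effect_allele",
                "target_other_allele", "proxy_other_allele")) {
    if (!col %in% names(rules)) rules[[col]] <- NA_character_
  }
  rules
}

#' Substitute proxy variants for missing instruments
#'
#' For each rule whose target variant is absent from `assocs` (typically an
#' outcome dataset genotyped on a different platform than the exposure GWAS),
#' the proxy variant's association is relabelled as the target, with alleles
#' re-mapped through the rule's allele map and the row flagged `proxy_used`.
#' Rules below the linkage threshold are ignored with a warning, as are
#' rules whose proxy is itself absent.
#'
#' @param assocs An `mr_assoc` table (usually the outcome associations).
#' @param rules A data.frame of rules as returned by [read_proxy_rules()].
#' @param r2_min Minimum linkage r-squared for a rule to be honoured
#'   (default 0.8).
#' @return `assocs` with qualifying proxies relabelled and flagged.
#' @examples
#' cad <- read_associations(mriv_example("table2_cad.tsv"))
#' rules <- read_proxy_rules(mriv_example("proxies.tsv"))
#' cad <- substitute_proxies(cad, rules)
#' cad$variant_id[cad$proxy_used]
#' @export
substitute_proxies <- function(assocs, rules, r2_min = 0.8) {
  stopifnot(is.data.frame(assocs), is.data.frame(rules))
  if (!"proxy_used" %in% names(assocs)) assocs$proxy_used <- FALSE
  for (i in seq_len(nrow(rules))) {
    rule <- rules[i, ]
    if (is.na(rule$r2) || rule$r2 < r2_min) {
      warning("proxy rule ", rule$target_id, " -> ", rule$proxy_id,
              " ignored: r2 = ", rule$r2, " below threshold ", r2_min,
              call. = FALSE)
      next
    }
    if (rule$target_id %in% assocs$variant_id) next
    j <- which(assocs$variant_id == rule$proxy_id)
    if (!length(j)) {
      warning("variant ", rule$target_id, " absent and its proxy ",
              rule$proxy_id, " is also absent; variant dropped",
              call. = FALSE)
      next
    }
    j <- j[1L]
    assocs$variant_id[j] <- rule$target_id
    pe <- rule$proxy_effect_allele
    if (!is.na(pe) && !is.na(assocs$effect_allele[j])) {
      if (identical(assocs$effect_allele[j], pe)) {
        assocs$effect_allele[j] <- rule$target_effect_allele
        if (!is.na(rule$target_other_allele)) {
          assocs$other_allele[j] <- rule$target_other_allele
        }
      } else if (!is.na(rule$proxy_other_allele) &&
                 identical(assocs$effect_allele[j], rule$proxy_other_allele)) {
        # proxy reported on the opposite orientation: map to the target's
        # other allele so harmonisation flips it downstream
        assocs$effect_allele[j] <- rule$target_other_allele
        assocs$other_allele[j] <- rule$target_effect_allele
      }
    }
    assocs$proxy_used[j] <- TRUE
  }
  assocs
}
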