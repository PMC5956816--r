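# Hand-typed copy of the published six-variant instrument table (exposure:
# serum magnesium, mmol/L per allele; outcome: CAD log-odds per allele),
# kept independent of the package readers so it can serve as an oracle.
table2_hand <- function() {
  data.frame(
    variant_id = c("rs4072037", "rs7965584", "rs3925584", "rs11144134",
                   "rs13146355", "rs448378"),
    beta_exposure = c(0.010, 0.007, 0.006, 0.011, 0.005, 0.004),
    se_exposure = rep(0.001, 6),
    beta_outcome = c(-0.015, -0.016, -0.016, 0.039, -0.003, -0.017),
    se_outcome = c(0.010, 0.011, 0.010, 0.019, 0.010, 0.009),
    eaf = c(0.54, 0.71, 0.55, 0.08, 0.44, 0.53),
    r2 = c(0.0057, 0.0025, 0.0025, 0.0023, 0.0019, 0.0013),
    stringsAsFactors = FALSE
  )
}

# Instrument set built through the packaged fixture pipeline
table2_instruments <- function() {
  mg <- read_associations(mriv_example("table2_magnesium.tsv"),
                          trait_label = "magnesium")
  cad <- read_associations(mriv_example("table2_cad.tsv"),
                           trait_label = "CAD")
  cad <- substitute_proxies(cad, read_proxy_rules(mriv_example("proxies.tsv")))
  suppressMessages(harmonise(mg, cad))
}

# Random positive-exposure instrument sets for property tests
random_instruments <- function(J, seed) {
  set.seed(seed)
  mr_instruments(sprintf("v%02d", seq_len(J)),
                 beta_exposure = runif(J, 0.002, 0.02),
                 se_exposure = runif(J, 5e-4, 2e-3),
                 beta_outcome = rnorm(J, 0, 0.03),
                 se_outcome = runif(J, 0.005, 0.02))
}

# Write an association table in the default reader dialect
write_assoc_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}
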