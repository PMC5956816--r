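test_that("the packaged exposure table reads into validated associations", {
  mg <- read_associations(mriv_example("table2_magnesium.tsv"),
                          trait_label = "magnesium")
  expect_s3_class(mg, "mr_assoc")
  expect_equal(nrow(mg), 6)
  expect_equal(attr(mg, "n_rejected"), 0)
  row <- mg[mg$variant_id == "rs4072037", ]
  expect_equal(row$beta, 0.010)
  expect_equal(row$se, 0.001)
  expect_equal(row$eaf, 0.54)
  expect_equal(row$effect_allele, "T")
})

test_that("an empty file with only a header yields an empty table", {
  path <- write_assoc_tsv(data.frame(snp = character(),
                                     effect_allele = character(),
                                     beta = numeric(), se = numeric()))
  out <- read_associations(path)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "n_rejected"), 0)
})

test_that("rows failing validation are rejected with a reason, not kept", {
  df <- data.frame(snp = sprintf("rs%d", 1:6),
                   effect_allele = c("A", "C", "G", "T", "A", "Z"),
                   beta = c(0.01, NA, 0.02, 0.01, 0.03, 0.01),
                   se = c(0.001, 0.001, 0, -1, 0.002, 0.001),
                   eaf = c(0.5, 0.5, 0.5, 0.5, 1.5, 0.5))
  expect_message(out <- read_associations(write_assoc_tsv(df)), "rejected")
  expect_equal(nrow(out), 1)
  expect_equal(out$variant_id, "rs1")
  rej <- attr(out, "rejected")
  expect_setequal(rej$reason,
                  c("missing beta", "non-positive SE",
                    "EAF outside [0,1]", "invalid effect allele"))
  expect_equal(rej$reason[rej$variant_id == "rs3"], "non-positive SE")
})

test_that("a single row with se = 0 is the only rejection", {
  df <- data.frame(snp = sprintf("rs%d", 1:6), effect_allele = "A",
                   beta = 0.01, se = c(rep(0.001, 5), 0))
  suppressMessages(out <- read_associations(write_assoc_tsv(df)))
  expect_equal(attr(out, "n_accepted"), 5)
  expect_equal(attr(out, "rejected")$reason, "non-positive SE")
})

test_that("missing mandatory columns raise a configuration error", {
  df <- data.frame(snp = "rs1", effect_allele = "A", beta = 0.01)
  expect_error(read_associations(write_assoc_tsv(df)), "mandatory column")
  expect_error(read_associations(write_assoc_tsv(df),
                                 column_map = c(nonsense = "x")),
               "unknown column_map")
})

test_that("column_map renames dialects onto the canonical fields", {
  df <- data.frame(SNP_ID = "rs1", EA = "A", b = 0.01, stderr = 0.001)
  out <- read_associations(write_assoc_tsv(df),
                           column_map = c(variant_id = "SNP_ID",
                                          effect_allele = "EA",
                                          beta = "b", se = "stderr"))
  expect_equal(out$variant_id, "rs1")
  expect_equal(out$se, 0.001)
})

test_that("proxy substitution attaches the proxy's association to the target", {
  cad <- read_associations(mriv_example("table2_cad.tsv"))
  rules <- read_proxy_rules(mriv_example("proxies.tsv"))
  expect_false("rs7965584" %in% cad$variant_id)
  out <- substitute_proxies(cad, rules)
  row <- out[out$variant_id == "rs7965584", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$beta, -0.016)
  expect_equal(row$se, 0.011)
  expect_true(row$proxy_used)
  expect_false("rs10858938" %in% out$variant_id)
})

test_that("proxy substitution is the identity when nothing is missing", {
  mg <- read_associations(mriv_example("table2_magnesium.tsv"))
  rules <- data.frame(target_id = "rs4072037", proxy_id = "rsX", r2 = 0.99,
                      target_effect_allele = "T", proxy_effect_allele = "T")
  out <- substitute_proxies(mg, rules)
  expect_equal(as.data.frame(out), as.data.frame(mg))
  expect_false(any(out$proxy_used))
})

test_that("weak or unusable proxy rules warn and leave the variant missing", {
  cad <- read_associations(mriv_example("table2_cad.tsv"))
  weak <- data.frame(target_id = "rs7965584", proxy_id = "rs10858938",
                     r2 = 0.5, target_effect_allele = "A",
                     proxy_effect_allele = "A")
  expect_warning(out <- substitute_proxies(cad, weak), "below threshold")
  expect_false("rs7965584" %in% out$variant_id)
  absent <- data.frame(target_id = "rs999", proxy_id = "rs998", r2 = 0.95,
                       target_effect_allele = "A", proxy_effect_allele = "A")
  expect_warning(substitute_proxies(cad, absent), "also absent")
})

test_that("harmonisation reproduces the published instrument set", {
  ins <- table2_instruments()
  expect_s3_class(ins, "mr_instruments")
  expect_equal(nrow(ins), 6)
  expect_true(all(ins$beta_exposure > 0))
  row <- ins[ins$variant_id == "rs448378", ]
  expect_equal(row$ratio, -0.017 / 0.004)
  expect_equal(row$ivw_weight, 0.004^2 / 0.009^2)
  expect_true(ins$proxy_used[ins$variant_id == "rs7965584"])
  expect_equal(ins$variant_id, sort(ins$variant_id))
})

test_that("an outcome reported on the opposite allele harmonises identically", {
  exposure <- data.frame(variant_id = "rs1", effect_allele = "A",
                         other_allele = "G", eaf = 0.3, beta = 0.01,
                         se = 0.001, pval = 1e-10, n = 1000,
                         variance_explained = NA)
  outcome <- data.frame(variant_id = "rs1", effect_allele = "A",
                        other_allele = "G", eaf = 0.3, beta = -0.02,
                        se = 0.005, pval = 0.1, n = 5000,
                        variance_explained = NA)
  swapped <- outcome
  swapped$effect_allele <- "G"
  swapped$other_allele <- "A"
  swapped$beta <- -outcome$beta
  swapped$eaf <- 1 - outcome$eaf
  a <- suppressMessages(harmonise(exposure, outcome))
  b <- suppressMessages(harmonise(exposure, swapped))
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("orientation to the exposure-raising allele leaves the ratio fixed", {
  exposure <- data.frame(variant_id = "rs1", effect_allele = "A",
                         other_allele = "G", eaf = 0.4, beta = -0.005,
                         se = 0.001)
  outcome <- data.frame(variant_id = "rs1", effect_allele = "A",
                        other_allele = "G", eaf = 0.4, beta = 0.003,
                        se = 0.002)
  ins <- suppressMessages(harmonise(exposure, outcome))
  expect_equal(ins$beta_exposure, 0.005)
  expect_equal(ins$beta_outcome, -0.003)
  expect_equal(ins$ratio, -0.6)
})

test_that("harmonisation is idempotent", {
  ins <- table2_instruments()
  as_assoc <- function(beta, se) {
    data.frame(variant_id = ins$variant_id, effect_allele = "A",
               other_allele = "G", eaf = ins$eaf_exposure, beta = beta,
               se = se, pval = NA, n = ins$n_exposure,
               variance_explained = ins$variance_explained)
  }
  again <- suppressMessages(harmonise(
    as_assoc(ins$beta_exposure, ins$se_exposure),
    as_assoc(ins$beta_outcome, ins$se_outcome)))
  expect_equal(again$beta_exposure, ins$beta_exposure)
  expect_equal(again$beta_outcome, ins$beta_outcome)
  expect_equal(again$ratio, ins$ratio)
  expect_equal(again$ivw_weight, ins$ivw_weight)
})

test_that("irreconcilable alleles, zero betas and bad palindromes are dropped", {
  exposure <- data.frame(variant_id = c("rs1", "rs2", "rs3", "rs4"),
                         effect_allele = c("A", "A", "A", "C"),
                         other_allele = c("G", "G", "T", "G"),
                         eaf = c(0.3, 0.3, 0.5, 0.2),
                         beta = c(0.01, 0, 0.01, 0.01), se = 0.001)
  outcome <- data.frame(variant_id = c("rs1", "rs2", "rs3", "rs4"),
                        effect_allele = c("C", "A", "A", "C"),
                        other_allele = c("T", "G", "T", "G"),
                        eaf = c(0.3, 0.3, 0.5, 0.2),
                        beta = c(0.02, 0.02, 0.02, 0.02), se = 0.005)
  ins <- suppressMessages(suppressWarnings(harmonise(exposure, outcome)))
  # rs1 irreconcilable, rs2 zero exposure beta, rs3 palindromic at EAF 0.5;
  # rs4 palindromic but resolvable (both EAFs far from 0.5, same side)
  expect_equal(ins$variant_id, "rs4")
  expect_warning(suppressMessages(harmonise(exposure[1, ], outcome[1, ])),
                 "irreconcilable")
})

test_that("the join never yields more instruments than either table", {
  for (seed in 1:5) {
    set.seed(seed)
    n_e <- sample(3:8, 1)
    n_o <- sample(3:8, 1)
    exposure <- data.frame(variant_id = sprintf("rs%d", sample(1:10, n_e)),
                           effect_allele = "A", other_allele = "G",
                           eaf = 0.3, beta = runif(n_e, 0.001, 0.01),
                           se = 0.001)
    outcome <- data.frame(variant_id = sprintf("rs%d", sample(1:10, n_o)),
                          effect_allele = "A", other_allele = "G",
                          eaf = 0.3, beta = rnorm(n_o, 0, 0.01), se = 0.005)
    ins <- suppressMessages(harmonise(exposure, outcome))
    expect_lte(nrow(ins), min(n_e, n_o))
    expect_setequal(ins$variant_id,
                    intersect(exposure$variant_id, outcome$variant_id))
  }
})
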