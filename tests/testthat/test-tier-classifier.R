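panel <- c("ATM", "CHEK2", "FANCM", "POLG", "RAD18", "TP53", "BRCA1")

test_that("prefilter excludes off-panel, intergenic and common variants", {
  v <- rbind(
    make_variants("ATM", "stopgain", clinvar = "5", cadd = 35, maf = 2.5e-5,
                  key = "k1"),
    make_variants("GREM1", "missense", cadd = 30, revel = 0.9, maf = 1e-4,
                  key = "k2"),
    make_variants("ATM", "missense", cadd = 30, revel = 0.9, maf = 0.0107,
                  key = "k3"),
    make_variants("ATM", "missense", cadd = 30, revel = 0.9,
                  region = "intergenic", key = "k4"),
    make_variants("ATM", "missense", cadd = 30, revel = 0.9, key = "k5"))
  reasons <- prefilter_variants(v, panel)
  expect_equal(reasons, c(NA, "OFF_PANEL", "COMMON", "INTERGENIC", NA))
  # absent MAF is rare, not common (k5 retained and classified)
  asg <- classify_variants(v, panel)
  expect_equal(asg$tier, c("TIER1", "EXCLUDED", "EXCLUDED", "EXCLUDED",
                           "TIER2"))
  # MAF exactly at the threshold is not excluded (strict >)
  v$maf[3] <- 0.01
  expect_true(is.na(prefilter_variants(v, panel)[3]))
})

test_that("tier rules reproduce the published exemplar variants", {
  cases <- list(
    # stopgain, ClinVar pathogenic, CADD 35 -> Tier 1 via P/LP
    list(make_variants("ATM", "stopgain", clinvar = "5", cadd = 35,
                       maf = 2.5e-5), "TIER1", "TRUNCATING_PLP"),
    # truncating rule ignores a low REVEL
    list(make_variants("FANCM", "stopgain", clinvar = "4", cadd = 35,
                       revel = 0.12, maf = 1.3e-3), "TIER1",
         "TRUNCATING_PLP"),
    # frameshift with absent CADD still passes the CADD condition
    list(make_variants("CHEK2", "frameshift_deletion", clinvar = "5",
                       maf = 1.8e-3), "TIER1", "TRUNCATING_PLP"),
    # stopgain without ClinVar but disrupting a domain
    list(make_variants("RAD18", "stopgain", cadd = 36, maf = 1e-4,
                       domain = TRUE), "TIER1", "TRUNCATING_DOMAIN"),
    # missense P/LP qualifies despite REVEL below threshold
    list(make_variants("POLG", "missense", clinvar = "5,3", cadd = 26,
                       revel = 0.71, maf = 2e-4), "TIER2", "MISSENSE_PLP"),
    # mixed assertions with any P/LP code count as P/LP
    list(make_variants("BRCA1", "missense", clinvar = "5,4,3", cadd = 35,
                       revel = 0.79, maf = 2.5e-5), "TIER2", "MISSENSE_PLP"),
    # score-qualified missense
    list(make_variants("ATM", "missense", clinvar = "3", cadd = 29,
                       revel = 0.88, maf = 3e-4), "TIER2",
         "MISSENSE_SCORES"),
    # CADD below threshold stays neutral whatever the REVEL
    list(make_variants("ATM", "missense", cadd = 19.9, revel = 0.99),
         "NEUTRAL", "NO_RULE_MET"),
    # truncating, no ClinVar, no domain disruption -> neutral
    list(make_variants("ATM", "stopgain", cadd = 36), "NEUTRAL",
         "NO_RULE_MET"),
    # benign precedence
    list(make_variants("ATM", "missense", clinvar = "2", cadd = 35,
                       revel = 0.99), "NEUTRAL", "CLINVAR_BENIGN"))
  for (case in cases) {
    asg <- classify_variants(case[[1]], panel)
    expect_equal(asg$tier, case[[2]], info = case[[1]]$clinvar)
    expect_equal(asg$reason, case[[3]])
  }
})

test_that("ClinVar benign precedence holds over random score grids", {
  set.seed(5)
  for (i in 1:50) {
    v <- make_variants(
      "ATM", sample(c("missense", "stopgain", "frameshift_insertion",
                      "splicing"), 1),
      clinvar = sample(c("1", "2", "2,3", "1,3"), 1),
      cadd = sample(c(NA, runif(1, 0, 50)), 1),
      revel = sample(c(NA, runif(1)), 1),
      maf = sample(c(NA, runif(1, 0, 0.01)), 1),
      domain = sample(c(NA, TRUE, FALSE), 1))
    asg <- classify_variants(v, panel)
    expect_equal(asg$tier, "NEUTRAL")
    expect_equal(asg$reason, "CLINVAR_BENIGN")
  }
})

test_that("tiers are total, deterministic, and class-disjoint", {
  set.seed(9)
  classes <- c("stopgain", "frameshift_insertion", "frameshift_deletion",
               "splicing", "missense", "other")
  n <- 300
  v <- make_variants(
    sample(c(panel, "OFFX"), n, TRUE), sample(classes, n, TRUE),
    clinvar = sample(c(NA, "5", "4", "3", "2", "1", "5,4,3", "5,3", "2,3"),
                     n, TRUE),
    cadd = ifelse(runif(n) < 0.3, NA, runif(n, 0, 50)),
    revel = ifelse(runif(n) < 0.3, NA, runif(n)),
    maf = ifelse(runif(n) < 0.3, NA, 10^runif(n, -6, log10(0.5))),
    domain = sample(c(NA, TRUE, FALSE), n, TRUE),
    region = sample(c("exonic_or_splicing", "intergenic"), n, TRUE,
                    prob = c(0.9, 0.1)))
  a1 <- classify_variants(v, panel)
  a2 <- classify_variants(v, panel)
  expect_identical(a1, a2)
  expect_equal(nrow(a1), n)
  expect_true(all(a1$tier %in% c("TIER1", "TIER2", "NEUTRAL", "EXCLUDED")))
  trunc <- v$func_class %in% c("stopgain", "frameshift_insertion",
                               "frameshift_deletion", "splicing")
  expect_false(any(a1$tier == "TIER2" & trunc))
  expect_false(any(a1$tier == "TIER1" & v$func_class == "missense"))
  expect_false(any(a1$tier == "TIER1" & !trunc))
  # reason/tier pairing invariants
  expect_true(all(a1$reason[a1$tier == "TIER1"] %in%
                    c("TRUNCATING_PLP", "TRUNCATING_DOMAIN")))
  expect_true(all(a1$reason[a1$tier == "TIER2"] %in%
                    c("MISSENSE_PLP", "MISSENSE_SCORES")))
  expect_true(all(a1$reason[a1$tier == "EXCLUDED"] %in%
                    c("OFF_PANEL", "INTERGENIC", "COMMON")))
})

test_that("the packaged variant fixture is re-tiered without mismatch", {
  vt <- lethal_case_variants()
  asg <- classify_variants(vt, panel = default_repair_panel())
  expect_equal(asg$tier, vt$printed_tier)
  expect_equal(sum(asg$tier == "TIER1"), 11L)
  expect_equal(sum(asg$tier == "TIER2"), 20L)

  # degenerate inputs
  expect_equal(nrow(classify_variants(vt[0, ], default_repair_panel())), 0L)
  common <- vt
  common$maf <- 0.02
  expect_true(all(classify_variants(common,
                                    default_repair_panel())$tier == "EXCLUDED"))
})

test_that("classify_cohorts unifies variants across cohorts", {
  cfg <- simulation_config(seed = 3)
  coh <- simulate_case_cohort(cfg)
  ctl <- simulate_control_counts(cfg)
  asg <- classify_cohorts(coh, ctl, panel = default_repair_panel())
  expect_false(anyDuplicated(asg$variant_key) > 0)
  expect_true(all(coh$calls$variant_key %in% asg$variant_key))
  expect_true(all(ctl$rows$variant_key %in% asg$variant_key))
})
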