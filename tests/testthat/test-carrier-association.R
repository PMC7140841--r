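test_that("fisher_two_sided reproduces published single-gene comparisons", {
  expect_equal(round(fisher_two_sided(1, 121, 0, 6192), 3), 0.019)
  expect_equal(round(fisher_two_sided(1, 121, 0, 3307), 3), 0.036)
  expect_equal(round(fisher_two_sided(2, 120, 7, 6185), 3), 0.012)
  expect_equal(fisher_two_sided(0, 122, 0, 60), 1)
  expect_error(fisher_two_sided(-1, 5, 2, 3), "non-negative")
  expect_error(fisher_two_sided(0, 0, 2, 3), "margin")
})

test_that("fisher_two_sided is symmetric and bounded below by the point probability", {
  set.seed(8)
  for (i in 1:200) {
    cells <- rpois(4, sample(c(2, 8, 40), 1))
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    if (a + b == 0 || c + d == 0) next
    p <- fisher_two_sided(a, b, c, d)
    expect_equal(fisher_two_sided(c, d, a, b), p)   # row swap
    expect_equal(fisher_two_sided(b, a, d, c), p)   # column swap
    point <- dhyper(a, a + b, c + d, a + c)
    expect_gte(p, point * (1 - 1e-12))
    expect_lte(p, 1)
    # independent implementations agree
    expect_equal(p, oracle_fisher(a, b, c, d), tolerance = 1e-12)
    expect_equal(p,
                 fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("expected carriers scale linearly in rate and cohort size", {
  expect_equal(round(expected_carriers(0.0093, 122), 1), 1.1)
  expect_equal(expected_carriers(0, 50), 0)
  expect_equal(expected_carriers(1, 7), 7)
  expect_equal(expected_carriers(0.02, 300),
               2 * expected_carriers(0.01, 300))
  expect_equal(expected_carriers(0.02, 300),
               3 * expected_carriers(0.02, 100))
})

test_that("case carriers count distinct individuals once", {
  v <- rbind(
    make_variants("ATM", "stopgain", clinvar = "5", cadd = 35, key = "v1"),
    make_variants("ATM", "frameshift_deletion", clinvar = "5", key = "v2"),
    make_variants("CHEK2", "stopgain", clinvar = "5", cadd = 35, key = "v3"),
    make_variants("TP53", "missense", clinvar = "5", cadd = 28, revel = 0.89,
                  key = "v4"))
  asg <- classify_variants(v)
  cohort <- make_cohort(
    sprintf("M%02d", 1:10), v,
    data.frame(sample_id = c("M01", "M01", "M02", "M03"),
               variant_key = c("v1", "v2", "v3", "v4")))
  one_man <- case_carriers(cohort, asg, "TIER1", gene = "ATM")
  expect_equal(one_man$n_carriers, 1L)  # two ATM Tier 1 variants, one man
  all_t1 <- case_carriers(cohort, asg, "TIER1")
  expect_equal(all_t1$n_carriers, 2L)
  expect_equal(all_t1$rate, 0.2)
  expect_equal(case_carriers(cohort, asg, "TIER2")$n_carriers, 1L)
  expect_equal(case_carriers(cohort, asg, "TIER1", gene = "BRCA2")$n_carriers,
               0L)
  expect_error(case_carriers(cohort, asg, "NEUTRAL"), "burden")
  expect_error(case_carriers(cohort, asg[asg$variant_key != "v1", ], "TIER1"),
               "cover")
})

test_that("control carrier estimation sums allele counts per gene", {
  # published Tier 1 per-gene counts: Finnish sum 177, Swedish sum 101
  fin <- make_controls(c("ERCC3", "RAD18", "ATM", "FANCM", "NTHL1", "CHEK2"),
                       c(0, 0, 4, 89, 24, 60), 3307)
  swe <- make_controls(c("ERCC3", "RAD18", "ATM", "FANCM", "NTHL1", "CHEK2"),
                       c(3, 0, 10, 44, 39, 5), 6192)
  asg <- classify_variants(fin$rows[, !(names(fin$rows) %in%
                                          c("allele_count",
                                            "covered_persons"))])
  expect_equal(control_carriers(fin, asg, "TIER1")$n_carriers, 177L)
  expect_equal(control_carriers(swe, asg, "TIER1")$n_carriers, 101L)
  expect_equal(round(100 * control_carriers(fin, asg, "TIER1")$rate, 2), 5.35)
  expect_equal(round(100 * control_carriers(swe, asg, "TIER1")$rate, 2), 1.63)
  expect_equal(control_carriers(swe, asg, "TIER1", gene = "FANCM")$n_carriers,
               44L)

  # two qualifying variants in one gene: counts add
  two <- make_controls(c("ATM", "ATM"), c(3, 2), 1000)
  two$rows$variant_key <- c("x1", "x2")
  asg2 <- classify_variants(two$rows[, !(names(two$rows) %in%
                                           c("allele_count",
                                             "covered_persons"))])
  expect_equal(control_carriers(two, asg2, "TIER1", gene = "ATM")$n_carriers,
               5L)
})

test_that("control denominators: minimum within gene, error when ambiguous for ALL", {
  ctl <- make_controls(c("ATM", "ATM"), c(3, 2), 1000)
  ctl$rows$variant_key <- c("x1", "x2")
  ctl$rows$covered_persons <- c(900L, 1000L)
  ctl$covered_persons <- NULL
  asg <- classify_variants(ctl$rows[, !(names(ctl$rows) %in%
                                          c("allele_count",
                                            "covered_persons"))])
  atm <- control_carriers(ctl, asg, "TIER1", gene = "ATM")
  expect_equal(atm$n_total, 900L)
  expect_error(control_carriers(ctl, asg, "TIER1"), "covered_persons")
  ctl$covered_persons <- 1000L
  expect_equal(control_carriers(ctl, asg, "TIER1")$n_total, 1000L)
})

test_that("p-value rendering matches report conventions", {
  expect_equal(format_p_value(c(0.0004999, 0.0005, 0.0007, 0.1234, 1)),
               c("<0.001", "0.001", "0.001", "0.123", "1.000"))
})

test_that("association tables reproduce the aggregate cohort contrasts", {
  # 15/122 Tier 1 and 16/122 Tier 2 lethal carriers vs 0 and 3 of 60
  genes <- sprintf("G%02d", 1:16)
  v <- rbind(
    make_variants(genes[1:15], rep("stopgain", 15), clinvar = "5", cadd = 35,
                  key = sprintf("t1_%02d", 1:15)),
    make_variants(genes[1:16], rep("missense", 16), clinvar = "5", cadd = 30,
                  revel = 0.9, key = sprintf("t2_%02d", 1:16)))
  asg <- classify_variants(v)
  lethal <- make_cohort(
    sprintf("L%03d", 1:122), v,
    data.frame(sample_id = c(sprintf("L%03d", 1:15), sprintf("L%03d", 31:46)),
               variant_key = c(sprintf("t1_%02d", 1:15),
                               sprintf("t2_%02d", 1:16))),
    label = "lethal")
  unsel <- make_cohort(
    sprintf("U%03d", 1:60), v,
    data.frame(sample_id = sprintf("U%03d", 1:3),
               variant_key = sprintf("t2_%02d", 1:3)),
    label = "unselected")
  tab <- build_association_table(lethal, list(unselected = unsel), asg)
  all_t1 <- tab[tab$gene == "ALL" & tab$tier == "TIER1", ]
  expect_equal(c(all_t1$a, all_t1$b, all_t1$c, all_t1$d), c(15, 107, 0, 60))
  expect_equal(all_t1$p_display, "0.003")
  expect_equal(all_t1$rate_case_pct, 12.30)
  all_t2 <- tab[tab$gene == "ALL" & tab$tier == "TIER2", ]
  expect_equal(all_t2$p_display, "0.123")
  expect_equal(c(all_t2$rate_case_pct, all_t2$rate_comp_pct), c(13.11, 5.00))

  # identical cohorts give p = 1 everywhere
  mirror <- make_cohort(
    sprintf("V%03d", 1:122), v,
    data.frame(sample_id = c(sprintf("V%03d", 1:15), sprintf("V%03d", 31:46)),
               variant_key = c(sprintf("t1_%02d", 1:15),
                               sprintf("t2_%02d", 1:16))),
    label = "mirror")
  tab2 <- build_association_table(lethal, list(mirror = mirror), asg)
  expect_equal(tab2$p_value, rep(1, nrow(tab2)), tolerance = 1e-9)

  # overlapping sample ids between case and comparison cohorts are an error
  expect_error(build_association_table(lethal, list(bad = lethal), asg),
               "share sample id")
})
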