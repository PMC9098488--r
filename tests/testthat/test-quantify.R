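cts <- function(III, II, I, wt) {
  c(class_III = III, class_II = II, class_I = I, wt = wt)
}

test_that("phenotype fractions are proportions that conserve mass", {
  expect_equal(unname(phenotype_fractions(cts(10, 10, 0, 0))),
               c(0.5, 0.5, 0, 0))
  expect_equal(unname(phenotype_fractions(cts(0, 0, 7, 0))), c(0, 0, 1, 0))
  expect_error(phenotype_fractions(cts(0, 0, 0, 0)), "zero")
  expect_error(phenotype_fractions(c(1, 2, 3)), "4 values")
  set.seed(5)
  for (i in 1:1000) {
    x <- cts(rpois(1, 20), rpois(1, 20), rpois(1, 20), rpois(1, 20) + 1)
    expect_lt(abs(sum(phenotype_fractions(x)) - 1), 1e-12)
  }
})

test_that("the highly-efficient rule needs >=50% severe and <10% wild type", {
  expect_false(classify_highly_efficient(cts(40, 20, 20, 20)))  # WT 20%
  expect_true(classify_highly_efficient(cts(50, 0, 45, 5)))     # boundary >=
  expect_false(classify_highly_efficient(cts(0, 0, 0, 100)))
  expect_false(classify_highly_efficient(cts(49, 0, 46, 5)))    # severe 49%
  expect_false(classify_highly_efficient(cts(60, 30, 0, 10)))   # WT exactly 10%
  # both cutoffs are parameters
  expect_true(classify_highly_efficient(cts(40, 20, 20, 20),
                                        severe_min = 0.5, wt_max = 0.25))
})

test_that("mosaic fraction is the non-wild-type share", {
  expect_equal(mosaic_mutant_fraction(cts(0, 5, 5, 90)), 0.10)
  expect_equal(mosaic_mutant_fraction(cts(0, 0, 0, 50)), 0)
  set.seed(6)
  for (i in 1:100) {
    x <- cts(rpois(1, 5), rpois(1, 5), rpois(1, 5), rpois(1, 5) + 1)
    f <- phenotype_fractions(x)
    expect_equal(mosaic_mutant_fraction(x), unname(1 - f[["wt"]]))
  }
})

test_that("per-P0 efficiency divides positives by F1s and excludes small broods", {
  expect_equal(p0_efficiency(12, 60, min_f1 = 10), 0.2)
  expect_true(is.na(p0_efficiency(3, 8, min_f1 = 10)))  # excluded, not 0
  expect_true(is.na(p0_efficiency(0, 0, min_f1 = 0)))
  expect_error(p0_efficiency(5, 3), "exceed")
  e <- p0_efficiency(c(10, 50, 3), c(100, 100, 8), min_f1 = 10)
  expect_equal(e, c(0.1, 0.5, NA))
  expect_true(all(e[!is.na(e)] >= 0 & e[!is.na(e)] <= 1))
})

test_that("edited-allele percentage matches the closed formula exhaustively", {
  for (n in 1:10) {
    for (h in 0:n) {
      for (het in 0:(n - h)) {
        expect_equal(edited_allele_percent(h, het, n),
                     100 * (2 * h + het) / (2 * n))
      }
    }
  }
  expect_equal(edited_allele_percent(5, 0, 10), 50)
  expect_equal(edited_allele_percent(10, 0, 10), 100)
  expect_equal(edited_allele_percent(0, 0, 10), 0)
  expect_error(edited_allele_percent(6, 5, 10), "exceed")
  expect_error(edited_allele_percent(0, 0, 0), "positive")
})

test_that("edited-allele percentage is monotone in hom/het and dilution", {
  expect_lt(edited_allele_percent(2, 3, 10), edited_allele_percent(3, 3, 10))
  expect_lt(edited_allele_percent(2, 3, 10), edited_allele_percent(2, 4, 10))
  expect_lt(edited_allele_percent(2, 3, 11), edited_allele_percent(2, 3, 10))
})

test_that("HDR efficiency is correct insertions over genotyped F1s", {
  expect_equal(report_percent(hdr_efficiency(12, 61)), 19.7)
  expect_equal(hdr_efficiency(0, 20), 0)
  expect_equal(hdr_efficiency(7, 7), 100)
  expect_error(hdr_efficiency(8, 7), "exceed")
})

test_that("Fisher exact matches hypergeometric enumeration", {
  expect_equal(fisher_enrichment(matrix(c(1, 1, 1, 1), 2)), 1.0)
  t2 <- matrix(c(5, 0, 0, 5), 2)
  expect_equal(fisher_enrichment(t2), oracle_fisher2x2(t2), tolerance = 1e-10)
  set.seed(77)
  for (i in 1:40) {
    tab <- matrix(rbinom(4, 12, 0.4), 2)
    if (sum(tab) == 0) next
    p <- fisher_enrichment(tab)
    expect_gt(p, 0)
    expect_lte(p, 1)
    expect_equal(p, oracle_fisher2x2(tab), tolerance = 1e-8)
  }
  expect_error(fisher_enrichment(matrix(0, 2, 2)), "all-zero")
  expect_error(fisher_enrichment(matrix(1, 3, 3)), "2x2")
})

test_that("chi-squared with Yates matches the direct formula and is conservative", {
  balanced <- matrix(c(10, 10, 10, 10), 2)
  res <- chisq_yates(balanced)
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 1)

  tab <- matrix(c(10, 20, 20, 10), 2)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat_yates <- sum((pmax(abs(tab - e) - 0.5, 0))^2 / e)
  stat_plain <- sum((tab - e)^2 / e)
  expect_equal(unname(chisq_yates(tab)$statistic), stat_yates)
  expect_equal(unname(chisq_yates(tab, correct = FALSE)$statistic), stat_plain)
  expect_lte(stat_yates, stat_plain)
  expect_equal(chisq_yates(tab)$p.value,
               stats::pchisq(stat_yates, df = 1, lower.tail = FALSE))
  expect_error(chisq_yates(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), "margin")
})

test_that("the enrichment table cross-tabulates prediction against outcome", {
  tab <- enrichment_table(c(TRUE, TRUE, FALSE, FALSE, NA),
                          c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(as.vector(tab), c(1, 1, 1, 1))
  expect_equal(rownames(tab), c("score_gt_threshold", "score_le_threshold"))
})

test_that("experiment tables are validated on read", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("condition\tclass_III\tclass_II\tclass_I\twt",
               "g1\t30\t25\t20\t25"), f)
  df <- read_phenotype_table(f)
  expect_equal(df$n_total, 100)
  writeLines(c("condition\tclass_III", "g1\t30"), f)
  expect_error(read_phenotype_table(f), "missing column")

  writeLines(c("p0_id\tn_f1_total\tn_positive", "P1\t50\t60"), f)
  expect_error(read_p0_table(f), "exceed")
})
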