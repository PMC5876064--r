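test_that("proband counting applies the phenotype-ambiguity filters", {
  expect_identical(count_eligible_probands(list(), "HCM")$count, 0L)

  obs <- list(proband_observation("P1", phenotype = "HCM"),
              proband_observation("P2", phenotype = "LVNC-isolated"),
              proband_observation("P3", phenotype = "DCM"),
              proband_observation("P4", phenotype = "DCM-with-prior-HCM"))
  hcm <- count_eligible_probands(obs, "HCM")
  # isolated LVNC and plain DCM are excluded in an HCM context;
  # DCM with earlier HCM evidence counts
  expect_identical(hcm$count, 2L)
  expect_identical(hcm$trace$eligible, c(TRUE, FALSE, FALSE, TRUE))

  dcm <- count_eligible_probands(obs, "DCM")
  expect_identical(dcm$count, 2L)  # DCM + DCM-with-prior-HCM; LVNC still out

  rcm <- count_eligible_probands(obs, "RCM")
  expect_identical(rcm$count, 0L)
  expect_identical(count_eligible_probands(
    list(proband_observation("P9", phenotype = "RCM")), "RCM")$count, 1L)
})

test_that("suspected duplicates collapse to one proband", {
  obs <- list(proband_observation("A", "cohort1", "HCM"),
              proband_observation("B", "cohort2", "HCM", duplicate_of = "A"),
              proband_observation("C", "cohort1", "HCM"),
              proband_observation("C", "cohort3", "HCM"))  # same id twice
  res <- count_eligible_probands(obs, "HCM")
  expect_identical(res$count, 2L)
  expect_identical(sum(res$trace$counted), 2L)
  # transitive links: B dup-of A, D dup-of B
  obs2 <- list(proband_observation("A", phenotype = "HCM"),
               proband_observation("B", phenotype = "HCM", duplicate_of = "A"),
               proband_observation("D", phenotype = "HCM", duplicate_of = "B"))
  expect_identical(count_eligible_probands(obs2, "HCM")$count, 1L)
})

test_that("proband eligibility filtering is idempotent", {
  obs <- c(make_probands(4, "HCM"), make_probands(3, "LVNC-isolated", "L"),
           list(proband_observation("X", phenotype = "DCM")))
  first <- count_eligible_probands(obs, "HCM")
  kept <- obs[first$trace$counted]
  second <- count_eligible_probands(kept, "HCM")
  expect_identical(second$count, first$count)
  expect_true(all(second$trace$counted))
})

test_that("quasi case-control matches Fisher's exact test", {
  res <- quasi_case_control(2, cohort_model(cases = c(AFR = 500),
                                            controls = c(AFR = 5203),
                                            control_carriers = 2), "AFR")
  ft <- fisher.test(res$table)
  expect_equal(res$p_value, ft$p.value, tolerance = 1e-12)
  # sample odds ratio, not the conditional MLE
  expect_equal(res$odds_ratio, (2 * 5201) / (2 * 498), tolerance = 1e-12)

  # strong enrichment: 15 carriers in 2500 cases vs 2 in 33370 controls
  res2 <- quasi_case_control(15, cohort_model(cases = c(NFE = 2500),
                                              controls = c(NFE = 33370),
                                              control_carriers = 2), "NFE")
  expect_lt(res2$p_value, 1e-6)
  expect_gt(res2$odds_ratio, 10)
  expect_equal(res2$p_value, fisher.test(res2$table)$p.value,
               tolerance = 1e-12)
})

test_that("quasi case-control conventions for empty and degenerate tables", {
  empty <- quasi_case_control(0, cohort_model(control_carriers = 0), "NFE")
  expect_identical(empty$odds_ratio, 1)
  expect_identical(empty$p_value, 1)
  noctrl <- quasi_case_control(3, cohort_model(control_carriers = 0), "NFE")
  expect_identical(noctrl$odds_ratio, Inf)
  expect_error(quasi_case_control(2, cohort_model(), "MARS"),
               "unknown ancestry")
  expect_error(quasi_case_control(1e6, cohort_model(), "NFE"),
               "case cohort size")
})

test_that("quasi case-control matches enumeration exhaustively on small cohorts", {
  for (c1 in c(3, 7, 12)) {
    for (c2 in c(4, 9, 15)) {
      for (m in 0:(c1 + c2)) {
        oracle <- fisher_enum_oracle_margin(c1, c2, m)
        for (a in as.integer(names(oracle))) {
          b <- m - a
          got <- quasi_case_control(a, cohort_model(
            cases = c(X = c1), controls = c(X = c2),
            control_carriers = b), "X")$p_value
          expect_equal(got, unname(oracle[as.character(a)]),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("PS4 tiers activate at 2/6/15 probands and only under PM2", {
  expect_identical(tier_ps4(1, TRUE), "none")
  expect_identical(tier_ps4(2, TRUE), "PS4_Supporting")
  expect_identical(tier_ps4(5, TRUE), "PS4_Supporting")
  expect_identical(tier_ps4(6, TRUE), "PS4_Moderate")
  expect_identical(tier_ps4(14, TRUE), "PS4_Moderate")
  expect_identical(tier_ps4(15, TRUE), "PS4")
  expect_identical(tier_ps4(15, FALSE), "none")
  # monotone: increasing the count never lowers the tier
  rank <- c(none = 0, PS4_Supporting = 1, PS4_Moderate = 2, PS4 = 3)
  tiers <- rank[vapply(0:30, tier_ps4, character(1), pm2_met = TRUE)]
  expect_true(all(diff(tiers) >= 0))
})

test_that("LOD score is n*log10(2) and linear in n", {
  expect_equal(lod_score(3), 0.903, tolerance = 1e-3)
  expect_equal(lod_score(5), 1.505, tolerance = 1e-3)
  expect_equal(lod_score(7), 2.107, tolerance = 1e-3)
  expect_identical(lod_score(0), 0)
  expect_identical(lod_score(4) + lod_score(9), lod_score(13))
  expect_error(lod_score(-1), "non-negative")
})

test_that("meiosis counting sums direct counts and honors nonsegregation", {
  recs <- list(segregation_record("F1", 3), segregation_record("F2", 4))
  ev <- count_informative_meioses(recs)
  expect_identical(ev$n, 7)
  expect_equal(ev$lod, 7 * log10(2))
  expect_false(ev$nonsegregation)

  # a nonsegregating family contributes zero meioses
  recs2 <- list(segregation_record("F1", 3),
                segregation_record("F2", 4, nonsegregation = TRUE))
  ev2 <- count_informative_meioses(recs2)
  expect_identical(ev2$n, 3)
  expect_true(ev2$nonsegregation)
})

test_that("PP1 tiers activate at 3/5/7 meioses under PM2, even single-family", {
  ev <- function(n, nonseg = FALSE) list(n = n, nonsegregation = nonseg)
  expect_identical(tier_pp1(ev(2), TRUE)$pp1, "none")
  expect_identical(tier_pp1(ev(3), TRUE)$pp1, "PP1")
  expect_identical(tier_pp1(ev(5), TRUE)$pp1, "PP1_Moderate")
  expect_identical(tier_pp1(ev(7), TRUE)$pp1, "PP1_Strong")
  expect_identical(tier_pp1(ev(7), FALSE)$pp1, "none")
  res <- tier_pp1(ev(6, nonseg = TRUE), TRUE)
  expect_identical(res$pp1, "none")
  expect_true(res$bs4)
  # monotone in n
  rank <- c(none = 0, PP1 = 1, PP1_Moderate = 2, PP1_Strong = 3)
  tiers <- rank[vapply(0:12, function(n) tier_pp1(ev(n), TRUE)$pp1,
                       character(1))]
  expect_true(all(diff(tiers) >= 0))
})

test_that("de novo logic distinguishes PS2 and PM6 and never returns both", {
  expect_identical(evaluate_de_novo(list()), "none")
  expect_identical(evaluate_de_novo(list(qualifying_de_novo(TRUE))), "PS2")
  expect_identical(evaluate_de_novo(list(qualifying_de_novo(FALSE))), "PM6")
  expect_identical(evaluate_de_novo(rep(list(qualifying_de_novo(FALSE)), 2)),
                   "PM6")
  # three documented occurrences upgrade to strong without paternity proof
  expect_identical(evaluate_de_novo(rep(list(qualifying_de_novo(FALSE)), 3)),
                   "PS2")
  # parents must be genotype-, phenotype- and history-negative to qualify
  incomplete <- de_novo_observation(TRUE, TRUE, TRUE, TRUE, FALSE)
  expect_identical(evaluate_de_novo(list(incomplete)), "none")
})
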