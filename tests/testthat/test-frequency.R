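test_that("filtering allele frequency inverts the Poisson survival function", {
  # zero observations give no credible lower bound
  expect_identical(filtering_allele_frequency(0, 10000), 0)
  # closed-form inversion agrees with a bisection oracle
  faf <- filtering_allele_frequency(1, 66740)
  expect_equal(faf, faf_bisection_oracle(1, 66740), tolerance = 1e-9)
  expect_lt(faf, 1 / 66740)
  # at the returned frequency, seeing >= AC alleles has probability 5%
  expect_equal(ppois(0, faf * 66740, lower.tail = FALSE), 0.05,
               tolerance = 1e-9)
})

test_that("filtering AF matches the bisection oracle over a grid of counts", {
  for (an in c(1e3, 1e4, 1e5)) {
    ac <- 1:20
    ac <- ac[ac <= an]
    got <- filtering_allele_frequency(ac, rep(an, length(ac)))
    want <- vapply(ac, faf_bisection_oracle, numeric(1), an = an)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("filtering AF is monotone and bounded by the point estimate", {
  an <- 66740
  faf <- filtering_allele_frequency(0:30, rep(an, 31))
  expect_true(all(diff(faf) > 0))              # non-decreasing in AC
  expect_true(all(faf <= (0:30) / an))         # never above AC/AN
  expect_true(all(faf[-1] > 0) && faf[1] == 0) # zero iff AC = 0
  # non-increasing in AN at fixed AC
  faf_an <- vapply(c(1e3, 1e4, 1e5, 1e6), function(an)
    filtering_allele_frequency(5, an), numeric(1))
  expect_true(all(diff(faf_an) < 0))
})

test_that("binomial mode agrees closely with the Poisson default at low AF", {
  pois <- filtering_allele_frequency(5, 120000)
  bin <- filtering_allele_frequency(5, 120000, method = "binomial")
  expect_equal(pois, bin, tolerance = 1e-3)
})

test_that("filtering AF rejects impossible counts", {
  expect_error(filtering_allele_frequency(5, 0), "an > 0")
  expect_error(filtering_allele_frequency(11, 10), "ac <= an")
  expect_error(filtering_allele_frequency(1, 100, confidence = 1.2),
               "confidence")
})

test_that("maximum credible AF follows allele-level prevalence arithmetic", {
  # realistic parameter set: prevalence 1/500, variant share 2%, penetrance 50%
  expect_identical(max_credible_af(1/500, 0.02, 0.5), 4e-5)
  # conservative parameter set used for the benign-strong bound
  expect_equal(max_credible_af(1/200, 0.02, 0.3), 1.667e-4, tolerance = 1e-3)
  # full contribution and penetrance reduce to half the individual prevalence
  p <- 0.012
  expect_identical(max_credible_af(p, 1, 1), p / 2)
  expect_error(max_credible_af(1/500, 0.02, 0), "penetrance")
})

test_that("frequency rule outcomes follow the threshold ladder", {
  cfg <- frequency_rule_config()
  expect_identical(
    evaluate_frequency_rules(list(make_pop(0, 120000)), cfg)$outcome, "PM2")
  # FAF ~1.5e-3 >= 0.1%
  expect_identical(
    evaluate_frequency_rules(list(make_pop(200, 120000)), cfg)$outcome, "BA1")
  # FAF ~2.5e-4 >= 0.02% in a deeply characterized population
  expect_identical(
    evaluate_frequency_rules(list(make_pop(40, 120000)), cfg)$outcome, "BS1")
  # same counts in a population not deeply characterized: BS1 ineligible
  expect_identical(
    evaluate_frequency_rules(list(make_pop(40, 120000, label = "OTH",
                                           deeply = FALSE)), cfg)$outcome,
    "none")
  # FAF between the PM2 and BS1 thresholds
  expect_identical(
    evaluate_frequency_rules(list(make_pop(20, 120000)), cfg)$outcome, "none")
  expect_error(evaluate_frequency_rules(list(), cfg), "at least one")
})

test_that("BA1 and BS1 activate inclusively at their thresholds", {
  faf <- filtering_allele_frequency(40, 120000)
  cfg_at <- frequency_rule_config(bs1 = faf)
  expect_identical(
    evaluate_frequency_rules(list(make_pop(40, 120000)), cfg_at)$outcome,
    "BS1")
  cfg_ba1 <- frequency_rule_config(ba1 = faf)
  expect_identical(
    evaluate_frequency_rules(list(make_pop(40, 120000)), cfg_ba1)$outcome,
    "BA1")
})

test_that("rules are evaluated popmax-style over populations passing the AN gate", {
  recs <- list(make_pop(0, 120000),
               make_pop(3, 800, label = "TINY", deeply = FALSE))
  out <- evaluate_frequency_rules(recs, frequency_rule_config())
  # the undersampled population is ignored; the variant is absent elsewhere
  expect_identical(out$outcome, "PM2")
  expect_identical(out$per_population$eligible, c(TRUE, FALSE))
  # a common variant in any eligible population drives BA1
  recs2 <- list(make_pop(0, 120000), make_pop(200, 100000))
  expect_identical(evaluate_frequency_rules(recs2)$outcome, "BA1")
  # nothing passes the gate: no outcome, warning flag raised
  out3 <- evaluate_frequency_rules(list(make_pop(1, 500)))
  expect_identical(out3$outcome, "none")
  expect_true(out3$warning)
})

test_that("frequency outcomes are mutually exclusive by construction", {
  for (ac in c(0, 5, 20, 40, 200, 500)) {
    out <- evaluate_frequency_rules(list(make_pop(ac, 120000)))
    expect_length(out$outcome, 1)
    expect_true(out$outcome %in% c("BA1", "BS1", "PM2", "none"))
  }
})

test_that("threshold derivation table pairs derived maxima with encoded constants", {
  tab <- threshold_derivation_table(myh7_config())
  expect_setequal(tab$rule, c("BA1", "BS1", "PM2"))
  pm2 <- tab[tab$rule == "PM2", ]
  expect_identical(pm2$derived_max_credible_af, pm2$encoded_threshold)
  ba1 <- tab[tab$rule == "BA1", ]
  expect_lt(ba1$encoded_threshold / ba1$derived_max_credible_af, 1.2)
})
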