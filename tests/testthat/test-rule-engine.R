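test_that("registry audit matches the adapted framework's structure", {
  reg <- build_registry()
  audit <- registry_audit(reg)
  expect_identical(audit$n_base, 28L)
  expect_identical(audit$removed, 9L)
  expect_identical(audit$disease_gene, 12L)
  expect_identical(audit$modified_strength, 5L)
  expect_identical(audit$no_change, 7L)
  expect_setequal(reg$code[reg$spec_type == "removed"],
                  c("PVS1", "PM3", "PP2", "PP4", "PP5", "BS2", "BP1", "BP3",
                    "BP6"))
  expect_setequal(reg$code[reg$spec_type == "modified-strength"],
                  c("PVS1_Moderate", "PS4_Moderate", "PS4_Supporting",
                    "PP1_Moderate", "PP1_Strong"))
  # gating is declared in data: proband and segregation tiers require PM2
  gated <- reg$code[reg$gating == "PM2"]
  expect_setequal(gated, c("PS4", "PS4_Moderate", "PS4_Supporting",
                           "PP1", "PP1_Moderate", "PP1_Strong"))
})

test_that("registry overrides apply and unknown codes are rejected", {
  reg <- build_registry(list(PM1 = list(spec_type = "no-change")))
  expect_identical(reg$spec_type[reg$code == "PM1"], "no-change")
  expect_error(build_registry(list(PXX = list(strength = "strong"))),
               "unknown rule code")
})

test_that("registry round-trips through YAML", {
  reg <- build_registry()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_registry_yaml(reg, path)
  back <- read_registry_yaml(path)
  expect_identical(as.data.frame(back), as.data.frame(reg))
})

test_that("PM1 covers missense in the head domain, boundaries inclusive", {
  miss_at <- function(pos) variant_identity(consequence = "missense",
                                            aa_position = pos)
  expect_true(evaluate_pm1(miss_at(500))$met)
  expect_true(evaluate_pm1(miss_at(181))$met)
  expect_true(evaluate_pm1(miss_at(937))$met)
  expect_false(evaluate_pm1(miss_at(180))$met)
  expect_false(evaluate_pm1(miss_at(938))$met)
  expect_false(evaluate_pm1(variant_identity(consequence = "missense"))$met)
  # restricted to missense: other consequence classes never activate PM1
  for (cons in setdiff(c("nonsense", "frameshift", "canonical-splice",
                         "synonymous", "in-frame indel", "stop-loss",
                         "other"), "missense")) {
    expect_false(evaluate_pm1(variant_identity(consequence = cons,
                                               aa_position = 500L))$met)
  }
})

test_that("loss-of-function variants earn moderate weight only", {
  for (cons in c("nonsense", "frameshift", "canonical-splice")) {
    r <- evaluate_pvs1_moderate(variant_identity(consequence = cons))
    expect_true(r$met)
    expect_identical(r$strength, "moderate")
  }
  expect_false(evaluate_pvs1_moderate(
    variant_identity(consequence = "missense"))$met)
  # a LOF variant alone yields uncertain significance downstream
  b <- evidence_bundle(variant_identity(consequence = "frameshift"), "HCM",
                       list(make_pop(20, 120000)))
  expect_identical(classify_bundle(b)$tier, "uncertain significance")
})

test_that("only mammalian knock-in assays drive PS3/BS3", {
  ki_damaging <- functional_evidence("mammalian-variant-specific-knock-in",
                                     "damaging")
  ki_benign <- functional_evidence("mammalian-variant-specific-knock-in",
                                   "benign")
  r <- evaluate_functional(list(ki_damaging))
  expect_true(r$PS3$met); expect_false(r$BS3$met)
  r2 <- evaluate_functional(list(ki_benign))
  expect_false(r2$PS3$met); expect_true(r2$BS3$met)
  for (cls in c("transgenic-dosage-model", "knockout", "in-vitro", "other")) {
    r3 <- evaluate_functional(list(functional_evidence(cls, "damaging"),
                                   functional_evidence(cls, "benign")))
    expect_false(r3$PS3$met); expect_false(r3$BS3$met)
  }
  r4 <- evaluate_functional(list())
  expect_false(r4$PS3$met); expect_false(r4$BS3$met)
})

test_that("annotation rules map curated assertions with consequence guards", {
  miss <- variant_identity(consequence = "missense", aa_position = 500L)
  rules <- evaluate_annotation_rules(
    annotation_evidence("pathogenic-supporting",
                        same_aa_known_pathogenic = TRUE,
                        other_change_at_pathogenic_residue = TRUE), miss)
  expect_true(rules$PS1$met)
  expect_true(rules$PM5$met)
  expect_true(rules$PP3$met)
  expect_false(rules$BP4$met)

  # PM4: in-frame length change outside repeats, or stop-loss
  indel <- variant_identity(consequence = "in-frame indel", aa_position = 10L)
  expect_true(evaluate_annotation_rules(annotation_evidence(), indel)$PM4$met)
  indel_rep <- variant_identity(consequence = "in-frame indel",
                                aa_position = 10L, in_repeat_region = TRUE)
  expect_false(evaluate_annotation_rules(annotation_evidence(),
                                         indel_rep)$PM4$met)
  stoploss <- variant_identity(consequence = "stop-loss")
  expect_true(evaluate_annotation_rules(annotation_evidence(),
                                        stoploss)$PM4$met)

  # BP7 needs a synonymous change plus the splice/conservation assertion
  syn <- variant_identity(consequence = "synonymous", aa_position = 500L)
  a_bp7 <- annotation_evidence(splice_no_impact_not_conserved = TRUE)
  expect_true(evaluate_annotation_rules(a_bp7, syn)$BP7$met)
  expect_false(evaluate_annotation_rules(a_bp7, miss)$BP7$met)

  # benign-direction assertions
  rules_b <- evaluate_annotation_rules(
    annotation_evidence("benign-supporting", in_trans_no_severity = TRUE,
                        alternate_molecular_basis = TRUE), miss)
  expect_true(rules_b$BP4$met)
  expect_true(rules_b$BP2$met)
  expect_true(rules_b$BP5$met)
  expect_false(rules_b$PP3$met)
})

test_that("evaluate_all reproduces the published worked-example rule sets", {
  path <- system.file("extdata", "worked_examples.json",
                      package = "myh7rules")
  bundles <- read_evidence(path)
  expect_length(bundles, 2)
  # p.Arg1420Trp: rare, 11 probands, computational support
  r1 <- evaluate_all(bundles[[1]])
  expect_setequal(met_rules(r1), c("PM2", "PS4_Moderate", "PP3"))
  # p.Arg1909Pro: rare, de novo without paternity proof, computational support
  r2 <- evaluate_all(bundles[[2]])
  expect_setequal(met_rules(r2), c("PM2", "PM6", "PP3"))
})

test_that("an empty evidence bundle activates no rules", {
  b <- evidence_bundle(variant_identity(consequence = "other"), "HCM",
                       list(make_pop(20, 120000)))
  expect_identical(met_rules(evaluate_all(b)), character(0))
})

test_that("removed rules are never evaluated as met", {
  fx <- generate_fixtures(seed = 11)
  removed <- c("PVS1", "PM3", "PP2", "PP4", "PP5", "BS2", "BP1", "BP3", "BP6")
  for (b in fx$bundles) {
    expect_length(intersect(met_rules(evaluate_all(b)), removed), 0)
  }
})

test_that("gating soundness: proband and segregation tiers imply PM2", {
  fx <- generate_fixtures(seed = 23, n_per_scenario = 2)
  for (b in fx$bundles) {
    met <- met_rules(evaluate_all(b))
    gated <- grepl("^PS4|^PP1", met)
    if (any(gated)) expect_true("PM2" %in% met)
    # never two strengths of the same base rule
    bases <- sub("_.*$", "", met)
    expect_false(anyDuplicated(bases) > 0)
  }
})

test_that("evaluation is deterministic: identical traces on repeat runs", {
  path <- system.file("extdata", "worked_examples.json",
                      package = "myh7rules")
  b <- read_evidence(path)[[1]]
  r1 <- evaluate_all(b)
  r2 <- evaluate_all(b)
  expect_identical(r1, r2)
})

test_that("invalid bundles are rejected with context", {
  b <- evidence_bundle(variant_identity(consequence = "missense"), "HCM",
                       list(population_frequency_record("NFE", 5, 3)))
  expect_error(evaluate_all(b), "invalid evidence bundle")
})
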