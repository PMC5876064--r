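# Deterministic synthetic fixture generator. Each scenario constructs an
# evidence bundle whose intended rule activations and intended five-tier
# classification are known by construction (the tier is hand-assigned from
# the parent combining table, independently of the package's combiner), so
# engine output can be checked against the manifest end to end. Scenarios
# cover every non-removed rule's activation and non-activation, the
# published count boundaries, the phenotype-ambiguity filters, and
# conflicting-evidence cases.

fx_pop <- function(rng_an, ac, deeply = TRUE, label = if (deeply) "NFE" else "OTH") {
  population_frequency_record(label, ac, rng_an, deeply_characterized = deeply)
}

# frequency presets chosen so the intended outcome is stable across the
# jittered allele-number range (AN ~ U[110000, 130000]):
#   absent  AC = 0   -> FAF 0            (< 0.004%, PM2)
#   between AC = 20  -> FAF ~ 1.1e-4     (between PM2 and BS1 thresholds)
#   bs1     AC = 40  -> FAF ~ 2.5e-4     (>= 0.02%)
#   ba1     AC = 200 -> FAF ~ 1.5e-3     (>= 0.1%)
fx_freq <- function(kind, an, deeply = TRUE) {
  ac <- switch(kind, absent = 0, between = 20, bs1 = 40, ba1 = 200)
  list(fx_pop(an, ac, deeply = deeply))
}

fx_probands <- function(n, prefix, phenotype = "HCM") {
  lapply(seq_len(n), function(i)
    proband_observation(sprintf("%s-P%02d", prefix, i),
                        cohort = sprintf("cohort-%d", 1 + i %% 3),
                        phenotype = phenotype))
}

fx_dn <- function(paternity) {
  de_novo_observation(paternity_confirmed = paternity,
                      maternity_confirmed = FALSE,
                      parents_genotype_negative = TRUE,
                      parents_phenotype_negative = TRUE,
                      family_history_negative = TRUE)
}

fixture_scenarios <- function() {
  miss <- function(pos = 500) variant_identity(
    hgvs_c = sprintf("c.%dG>A", pos * 3), hgvs_p = sprintf("p.Xaa%dYaa", pos),
    consequence = "missense", aa_position = pos)

  sc <- list()
  add <- function(name, rules, tier, build) {
    sc[[name]] <<- list(name = name, intended_rules = rules,
                        intended_tier = tier, build = build)
  }

  # frequency spectrum -------------------------------------------------------
  add("ba1_common", "BA1", "benign", function(an, id)
    evidence_bundle(miss(1000), "HCM", fx_freq("ba1", an)))
  add("bs1_high", "BS1", "likely benign", function(an, id)
    evidence_bundle(miss(1000), "HCM", fx_freq("bs1", an)))
  add("bs1_boundary", "BS1", "likely benign", function(an, id)
    evidence_bundle(miss(1000), "HCM", list(fx_pop(150900, 40))))
  add("bs1_not_deeply_characterized", character(0), "uncertain significance",
      function(an, id)
        evidence_bundle(miss(1000), "HCM", fx_freq("bs1", an, deeply = FALSE)))
  add("pm2_absent", "PM2", "uncertain significance", function(an, id)
    evidence_bundle(miss(1000), "HCM", fx_freq("absent", an)))
  add("freq_between_thresholds", character(0), "uncertain significance",
      function(an, id)
        evidence_bundle(miss(1000), "HCM", fx_freq("between", an)))

  # proband-count boundaries (PS4 tiers, PM2 met) ----------------------------
  ps4 <- list(`1` = c("PM2"), `2` = c("PM2", "PS4_Supporting"),
              `5` = c("PM2", "PS4_Supporting"), `6` = c("PM2", "PS4_Moderate"),
              `14` = c("PM2", "PS4_Moderate"), `15` = c("PM2", "PS4"))
  for (k in names(ps4)) {
    n <- as.integer(k)
    tier <- if (n >= 15) "likely pathogenic" else "uncertain significance"
    local({
      n <- n
      add(sprintf("ps4_probands_%02d", n), ps4[[k]], tier, function(an, id)
        evidence_bundle(miss(1000), "HCM", fx_freq("absent", an),
                        probands = fx_probands(n, id)))
    })
  }
  add("ps4_without_pm2", character(0), "uncertain significance",
      function(an, id)
        evidence_bundle(miss(1000), "HCM", fx_freq("between", an),
                        probands = fx_probands(15, id)))

  # phenotype-ambiguity filters ----------------------------------------------
  add("lvnc_excluded_hcm", c("PM2", "PS4_Supporting"), "uncertain significance",
      function(an, id)
        evidence_bundle(miss(1000), "HCM", fx_freq("absent", an),
          probands = c(fx_probands(2, id, "HCM"),
                       fx_probands(3, paste0(id, "L"), "LVNC-isolated"))))
  add("dcm_excluded_hcm", c("PM2", "PS4_Supporting"), "uncertain significance",
      function(an, id)
        evidence_bundle(miss(1000), "HCM", fx_freq("absent", an),
          probands = c(fx_probands(1, id, "HCM"),
                       fx_probands(3, paste0(id, "D"), "DCM"),
                       fx_probands(1, paste0(id, "E"), "DCM-with-prior-HCM"))))
  add("duplicate_probands_collapsed", c("PM2", "PS4_Supporting"),
      "uncertain significance", function(an, id)
        evidence_bundle(miss(1000), "HCM", fx_freq("absent", an),
          probands = list(
            proband_observation(paste0(id, "-A"), "c1", "HCM"),
            proband_observation(paste0(id, "-B"), "c2", "HCM",
                                duplicate_of = paste0(id, "-A")),
            proband_observation(paste0(id, "-C"), "c1", "HCM"))))

  # segregation boundaries (PP1 tiers, PM2 met) ------------------------------
  pp1 <- list(`2` = c("PM2"), `3` = c("PM2", "PP1"), `4` = c("PM2", "PP1"),
              `5` = c("PM2", "PP1_Moderate"), `6` = c("PM2", "PP1_Moderate"),
              `7` = c("PM2", "PP1_Strong"))
  for (k in names(pp1)) {
    n <- as.integer(k)
    tier <- if (n >= 7) "likely pathogenic" else "uncertain significance"
    local({
      n <- n
      add(sprintf("pp1_meioses_%d", n), pp1[[k]], tier, function(an, id)
        evidence_bundle(miss(1000), "HCM", fx_freq("absent", an),
                        segregations = list(segregation_record("F1", n))))
    })
  }
  add("pp1_without_pm2", character(0), "uncertain significance",
      function(an, id)
        evidence_bundle(miss(1000), "HCM", fx_freq("between", an),
                        segregations = list(segregation_record("F1", 7))))
  add("nonsegregation_bs4", "BS4", "uncertain significance", function(an, id)
    evidence_bundle(miss(1000), "HCM", fx_freq("between", an),
                    segregations = list(
                      segregation_record("F1", 4, nonsegregation = TRUE))))

  # de novo -------------------------------------------------------------------
  add("de_novo_confirmed", c("PM2", "PS2"), "likely pathogenic",
      function(an, id)
        evidence_bundle(miss(1000), "HCM", fx_freq("absent", an),
                        de_novo = list(fx_dn(TRUE))))
  add("de_novo_unconfirmed_1", c("PM2", "PM6"), "uncertain significance",
      function(an, id)
        evidence_bundle(miss(1000), "HCM", fx_freq("absent", an),
                        de_novo = list(fx_dn(FALSE))))
  add("de_novo_unconfirmed_2", c("PM2", "PM6"), "uncertain significance",
      function(an, id)
        evidence_bundle(miss(1000), "HCM", fx_freq("absent", an),
                        de_novo = list(fx_dn(FALSE), fx_dn(FALSE))))
  add("de_novo_unconfirmed_3", c("PM2", "PS2"), "likely pathogenic",
      function(an, id)
        evidence_bundle(miss(1000), "HCM", fx_freq("absent", an),
                        de_novo = list(fx_dn(FALSE), fx_dn(FALSE), fx_dn(FALSE))))

  # domain / LOF / functional -------------------------------------------------
  add("pm1_head_domain", c("PM2", "PM1"), "uncertain significance",
      function(an, id)
        evidence_bundle(miss(500), "HCM", fx_freq("absent", an)))
  add("pm1_below_domain", "PM2", "uncertain significance", function(an, id)
    evidence_bundle(miss(180), "HCM", fx_freq("absent", an)))
  add("pm1_above_domain", "PM2", "uncertain significance", function(an, id)
    evidence_bundle(miss(938), "HCM", fx_freq("absent", an)))
  add("pvs1_moderate_alone", "PVS1_Moderate", "uncertain significance",
      function(an, id)
        evidence_bundle(variant_identity(hgvs_c = "c.100del",
                                         consequence = "frameshift"),
                        "HCM", fx_freq("between", an)))
  add("ps3_knock_in", c("PM2", "PS3"), "likely pathogenic", function(an, id)
    evidence_bundle(miss(1000), "HCM", fx_freq("absent", an),
      functional = list(
        functional_evidence("mammalian-variant-specific-knock-in", "damaging"))))
  add("in_vitro_not_counted", "PM2", "uncertain significance", function(an, id)
    evidence_bundle(miss(1000), "HCM", fx_freq("absent", an),
      functional = list(functional_evidence("in-vitro", "damaging"),
                        functional_evidence("knockout", "damaging"))))
  add("bs3_knock_in", "BS3", "uncertain significance", function(an, id)
    evidence_bundle(miss(1000), "HCM", fx_freq("between", an),
      functional = list(
        functional_evidence("mammalian-variant-specific-knock-in", "benign"))))

  # annotation rules ----------------------------------------------------------
  add("pp3_computational", c("PM2", "PP3"), "uncertain significance",
      function(an, id)
        evidence_bundle(miss(1000), "HCM", fx_freq("absent", an),
          annotation = annotation_evidence("pathogenic-supporting")))
  add("pm4_inframe_nonrepeat", "PM4", "uncertain significance",
      function(an, id)
        evidence_bundle(variant_identity(hgvs_c = "c.300_302del",
                                         consequence = "in-frame indel",
                                         aa_position = 100),
                        "HCM", fx_freq("between", an)))
  add("pm4_repeat_region_blocked", character(0), "uncertain significance",
      function(an, id)
        evidence_bundle(variant_identity(hgvs_c = "c.300_302del",
                                         consequence = "in-frame indel",
                                         aa_position = 100,
                                         in_repeat_region = TRUE),
                        "HCM", fx_freq("between", an)))
  add("ps1_same_aa", c("PM2", "PS1"), "likely pathogenic",
      function(an, id)
        evidence_bundle(miss(1000), "HCM", fx_freq("absent", an),
          annotation = annotation_evidence(same_aa_known_pathogenic = TRUE)))
  add("pm5_same_residue", c("PM2", "PM5"), "uncertain significance",
      function(an, id)
        evidence_bundle(miss(1000), "HCM", fx_freq("absent", an),
          annotation = annotation_evidence(
            other_change_at_pathogenic_residue = TRUE)))
  add("bp4_bp7_silent", c("BP4", "BP7"), "likely benign", function(an, id)
    evidence_bundle(variant_identity(hgvs_c = "c.1500C>T",
                                     consequence = "synonymous",
                                     aa_position = 500),
                    "HCM", fx_freq("between", an),
      annotation = annotation_evidence(
        "benign-supporting", splice_no_impact_not_conserved = TRUE)))
  add("bp2_bp5_pair", c("BP2", "BP5"), "likely benign", function(an, id)
    evidence_bundle(miss(1000), "HCM", fx_freq("between", an),
      annotation = annotation_evidence(in_trans_no_severity = TRUE,
                                       alternate_molecular_basis = TRUE)))

  # strong combinations --------------------------------------------------------
  add("pathogenic_stack", c("PM2", "PS4", "PM1", "PP1_Moderate"), "pathogenic",
      function(an, id)
        evidence_bundle(miss(500), "HCM", fx_freq("absent", an),
                        probands = fx_probands(16, id),
                        segregations = list(segregation_record("F1", 5))))
  add("likely_pathogenic_stack", c("PM2", "PS2", "PP1_Moderate"),
      "likely pathogenic", function(an, id)
        evidence_bundle(miss(1000), "HCM", fx_freq("absent", an),
                        segregations = list(segregation_record("F1", 5)),
                        de_novo = list(fx_dn(TRUE))))

  # conflicting evidence -------------------------------------------------------
  add("conflict_pm2_bs4", c("PM2", "BS4"), "uncertain significance",
      function(an, id)
        evidence_bundle(miss(1000), "HCM", fx_freq("absent", an),
                        segregations = list(
                          segregation_record("F1", 3, nonsegregation = TRUE))))
  add("conflict_bs1_pp3", c("BS1", "PP3"), "uncertain significance",
      function(an, id)
        evidence_bundle(miss(1000), "HCM", fx_freq("bs1", an),
          annotation = annotation_evidence("pathogenic-supporting")))

  sc
}

#' Generate deterministic synthetic evidence fixtures
#'
#' Builds evidence bundles for every scenario in the generator's catalog,
#' together with a manifest stating each bundle's intended rule activations
#' and intended five-tier classification (assigned by construction from the
#' parent combining table, independently of this package's combiner).
#' Generation is deterministic: the same seed yields byte-identical files.
#'
#' @param seed Integer seed controlling the jittered nuisance parameters
#'   (allele numbers, identifiers); the seed is recorded in the manifest.
#' @param n_per_scenario Number of replicate bundles per scenario.
#' @param dir Optional output directory; when given, one JSON file per
#'   bundle plus `manifest.tsv` are written there.
#' @return List with `bundles` (named list of [evidence_bundle()]s) and
#'   `manifest` (data frame: `id`, `scenario`, `intended_rules`,
#'   `intended_tier`, `seed`).
#' @export
generate_fixtures <- function(seed = 17L, n_per_scenario = 1L, dir = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  scenarios <- fixture_scenarios()
  bundles <- list()
  rows <- list()
  for (sc in scenarios) {
    for (rep in seq_len(n_per_scenario)) {
      id <- sprintf("%s_r%d", sc$name, rep)
      an <- sample(110000:130000, 1)
      bundles[[id]] <- sc$build(an, id)
      rows[[id]] <- data.frame(
        id = id, scenario = sc$name,
        intended_rules = paste(sort(sc$intended_rules), collapse = "|"),
        intended_tier = sc$intended_tier, seed = as.integer(seed),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, unname(rows))

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(bundles)) {
      write_evidence(bundles[id], file.path(dir, paste0(id, ".json")))
    }
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(bundles = bundles, manifest = manifest)
}
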