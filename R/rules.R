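# Per-criterion evaluators and the orchestrator that runs every applicable
# rule on an evidence bundle. Each evaluation produces an applied_rule
# carrying a human-readable evidence trace for auditability.

#' Construct an applied-rule record
#'
#' @param code Rule code (possibly strength-modified, e.g. `PS4_Moderate`).
#' @param met Did the criterion activate?
#' @param strength Strength as applied (governs combining arithmetic).
#' @param direction `"pathogenic"` or `"benign"`.
#' @param summary Human-readable evidence trace.
#' @param inputs Named list of the inputs consumed (for the audit trail).
#' @return An `applied_rule` object.
#' @export
applied_rule <- function(code, met, strength, direction, summary = "",
                         inputs = list()) {
  structure(list(code = code, base = sub("_.*$", "", code), met = isTRUE(met),
                 strength = strength, direction = direction,
                 summary = summary, inputs = inputs),
            class = "applied_rule")
}

#' @export
print.applied_rule <- function(x, ...) {
  cat(sprintf("%-15s %-7s %-11s %s\n", x$code,
              if (x$met) "MET" else "not met", x$strength, x$summary))
  invisible(x)
}

#' Evaluate the critical-domain rule PM1
#'
#' Missense variants in the myosin head functional domain (amino acids
#' 181-937, on the canonical transcript) earn moderate pathogenic weight;
#' pathogenic variants cluster significantly in this region. Restricted to
#' missense: truncating variants route through `PVS1_Moderate` instead, to
#' avoid counting the same evidence twice.
#'
#' @param variant A [variant_identity()].
#' @param domain Inclusive amino-acid bounds of the critical domain.
#' @return An [applied_rule()] for PM1.
#' @export
evaluate_pm1 <- function(variant, domain = c(181L, 937L)) {
  pos <- variant$aa_position
  met <- identical(variant$consequence, "missense") &&
    !is.null(pos) && !is.na(pos) && pos >= domain[1] && pos <= domain[2]
  applied_rule("PM1", met, "moderate", "pathogenic",
               sprintf("consequence=%s aa=%s domain=[%d,%d]",
                       variant$consequence,
                       if (is.null(pos) || is.na(pos)) "NA" else pos,
                       domain[1], domain[2]),
               list(consequence = variant$consequence, aa_position = pos))
}

#' Evaluate the loss-of-function rule at moderate strength (PVS1_Moderate)
#'
#' Loss-of-function variants in this gene are rare and their heterozygous
#' disease contribution is incompletely understood, so null variants earn
#' moderate (not very strong) weight; alone this yields a classification of
#' uncertain significance in the absence of case-level data.
#'
#' @param variant A [variant_identity()].
#' @return An [applied_rule()] for PVS1_Moderate.
#' @export
evaluate_pvs1_moderate <- function(variant) {
  lof <- c("nonsense", "frameshift", "canonical-splice")
  met <- variant$consequence %in% lof
  applied_rule("PVS1_Moderate", met, "moderate", "pathogenic",
               sprintf("consequence=%s (LOF classes: %s)",
                       variant$consequence, paste(lof, collapse = "/")),
               list(consequence = variant$consequence))
}

#' Evaluate the functional-assay rules PS3 / BS3
#'
#' Only a mammalian variant-specific knock-in model qualifies: dosage models
#' (transgenics, knockouts, knock-downs) say nothing about the particular
#' variant, and the typical in-vitro assays have low positive predictive
#' value. A qualifying assay supporting damage activates PS3; one supporting
#' no damaging effect activates BS3.
#'
#' @param functional List of [functional_evidence()]s.
#' @return List of two [applied_rule()]s, `PS3` and `BS3`.
#' @export
evaluate_functional <- function(functional) {
  classes <- vapply(functional, function(f) f$assay_class %||% "other",
                    character(1))
  dirs <- vapply(functional, function(f) f$direction %||% "inconclusive",
                 character(1))
  ki <- classes == "mammalian-variant-specific-knock-in"
  ps3 <- any(ki & dirs == "damaging")
  bs3 <- any(ki & dirs == "benign")
  trace <- if (length(classes)) {
    paste(sprintf("%s:%s", classes, dirs), collapse = "; ")
  } else "no functional evidence"
  list(
    PS3 = applied_rule("PS3", ps3, "strong", "pathogenic", trace,
                       list(assays = classes, directions = dirs)),
    BS3 = applied_rule("BS3", bs3, "strong", "benign", trace,
                       list(assays = classes, directions = dirs))
  )
}

#' Evaluate the annotation-driven rules
#'
#' PS1, PM4, PM5, PP3, BP2, BP4, BP5 and BP7 each consume a single
#' curator-asserted boolean or enumeration from the annotation evidence,
#' combined with the variant's consequence class where the criterion
#' requires it (PM4: in-frame indel outside a repeat region or stop-loss;
#' PM5: missense; BP7: synonymous).
#'
#' @param annotation An [annotation_evidence()].
#' @param variant A [variant_identity()].
#' @return Named list of [applied_rule()]s.
#' @export
evaluate_annotation_rules <- function(annotation, variant) {
  cons <- variant$consequence
  consensus <- annotation$computational_consensus %||% "absent"
  pm4 <- (identical(cons, "in-frame indel") && !isTRUE(variant$in_repeat_region)) ||
    identical(cons, "stop-loss")
  list(
    PS1 = applied_rule("PS1", isTRUE(annotation$same_aa_known_pathogenic),
                       "strong", "pathogenic",
                       "different nucleotide change, same amino acid as established pathogenic"),
    PM4 = applied_rule("PM4", pm4, "moderate", "pathogenic",
                       sprintf("consequence=%s in_repeat_region=%s", cons,
                               isTRUE(variant$in_repeat_region))),
    PM5 = applied_rule("PM5",
                       identical(cons, "missense") &&
                         isTRUE(annotation$other_change_at_pathogenic_residue),
                       "moderate", "pathogenic",
                       "novel missense change at residue with established pathogenic missense"),
    PP3 = applied_rule("PP3", identical(consensus, "pathogenic-supporting"),
                       "supporting", "pathogenic",
                       sprintf("computational consensus = %s", consensus)),
    BP4 = applied_rule("BP4", identical(consensus, "benign-supporting"),
                       "supporting", "benign",
                       sprintf("computational consensus = %s", consensus)),
    BP2 = applied_rule("BP2",
                       isTRUE(annotation$in_trans_no_severity) ||
                         isTRUE(annotation$in_cis_with_pathogenic),
                       "supporting", "benign",
                       sprintf("in_trans_no_severity=%s in_cis_with_pathogenic=%s",
                               isTRUE(annotation$in_trans_no_severity),
                               isTRUE(annotation$in_cis_with_pathogenic))),
    BP5 = applied_rule("BP5", isTRUE(annotation$alternate_molecular_basis),
                       "supporting", "benign",
                       "alternate molecular basis for disease in carrier case"),
    BP7 = applied_rule("BP7",
                       identical(cons, "synonymous") &&
                         isTRUE(annotation$splice_no_impact_not_conserved),
                       "supporting", "benign",
                       sprintf("consequence=%s splice_no_impact_not_conserved=%s",
                               cons,
                               isTRUE(annotation$splice_no_impact_not_conserved)))
  )
}

#' Evaluate every applicable rule on an evidence bundle
#'
#' Runs the allele-frequency rules first (PM2 gates the proband and
#' segregation tiers), then case-level, functional, domain, and annotation
#' rules. Removed rules are never evaluated and never appear as met. The
#' result is deterministic for identical input and every rule carries an
#' evidence trace.
#'
#' @param bundle An [evidence_bundle()].
#' @param config A [myh7_config()].
#' @param pedigrees Named list of pedigrees (see [read_ped()]) for
#'   segregation records carrying pedigree references.
#' @return Named list of [applied_rule()]s, one per evaluated rule code
#'   (base codes carry the tier actually applied; e.g. the `PS4` entry may
#'   hold code `PS4_Moderate`).
#' @export
evaluate_all <- function(bundle, config = myh7_config(), pedigrees = list()) {
  issues <- validate_bundle(bundle)
  if (length(issues)) {
    stop(sprintf("invalid evidence bundle: %s", paste(issues, collapse = "; ")))
  }
  rules <- list()

  # frequency rules ----------------------------------------------------------
  if (length(bundle$population_frequencies)) {
    freq <- evaluate_frequency_rules(bundle$population_frequencies,
                                     config$frequency)
    faf_txt <- sprintf("max filtering AF = %s over %d population(s)",
                       format(freq$max_faf, digits = 4),
                       sum(freq$per_population$eligible))
    if (freq$warning) faf_txt <- "no population passed the minimum-AN gate"
  } else {
    freq <- list(outcome = "none", max_faf = NA_real_, warning = TRUE)
    faf_txt <- "no population frequency data"
  }
  rules$BA1 <- applied_rule("BA1", freq$outcome == "BA1", "standalone",
                            "benign", faf_txt)
  rules$BS1 <- applied_rule("BS1", freq$outcome == "BS1", "strong",
                            "benign", faf_txt)
  rules$PM2 <- applied_rule("PM2", freq$outcome == "PM2", "moderate",
                            "pathogenic", faf_txt)
  pm2_met <- rules$PM2$met

  # multiple probands (PS4 tiers, PM2-gated) ---------------------------------
  pro <- count_eligible_probands(bundle$probands, bundle$disease_context)
  ps4_code <- tier_ps4(pro$count, pm2_met)
  ps4_trace <- sprintf("%d eligible proband(s) (of %d observed), PM2 %s",
                       pro$count, length(bundle$probands),
                       if (pm2_met) "met" else "not met")
  rules$PS4 <- if (ps4_code == "none") {
    applied_rule("PS4", FALSE, "strong", "pathogenic", ps4_trace,
                 list(count = pro$count, trace = pro$trace))
  } else {
    reg <- build_registry()
    applied_rule(ps4_code, TRUE, reg$strength[reg$code == ps4_code],
                 "pathogenic", ps4_trace,
                 list(count = pro$count, trace = pro$trace))
  }

  # segregation (PP1 tiers, PM2-gated; BS4) ----------------------------------
  seg <- count_informative_meioses(bundle$segregations, pedigrees)
  pp1 <- tier_pp1(seg, pm2_met)
  seg_trace <- sprintf("n = %d informative meioses (LOD %.3f), nonsegregation = %s, PM2 %s",
                       seg$n, seg$lod, seg$nonsegregation,
                       if (pm2_met) "met" else "not met")
  rules$PP1 <- if (pp1$pp1 == "none") {
    applied_rule("PP1", FALSE, "supporting", "pathogenic", seg_trace,
                 list(n = seg$n, lod = seg$lod))
  } else {
    reg <- build_registry()
    applied_rule(pp1$pp1, TRUE, reg$strength[reg$code == pp1$pp1],
                 "pathogenic", seg_trace, list(n = seg$n, lod = seg$lod))
  }
  rules$BS4 <- applied_rule("BS4", pp1$bs4, "strong", "benign", seg_trace)

  # de novo -------------------------------------------------------------------
  dn <- evaluate_de_novo(bundle$de_novo)
  dn_trace <- sprintf("%d de novo observation(s), outcome %s",
                      length(bundle$de_novo), dn)
  rules$PS2 <- applied_rule("PS2", dn == "PS2", "strong", "pathogenic", dn_trace)
  rules$PM6 <- applied_rule("PM6", dn == "PM6", "moderate", "pathogenic", dn_trace)

  # domain / LOF / functional / annotation ------------------------------------
  rules$PM1 <- evaluate_pm1(bundle$variant)
  rules$PVS1_Moderate <- evaluate_pvs1_moderate(bundle$variant)
  rules <- c(rules, evaluate_functional(bundle$functional))
  rules <- c(rules, evaluate_annotation_rules(bundle$annotation, bundle$variant))

  rules
}

#' Rules that were met, as a character vector of applied codes
#'
#' @param rules Result of [evaluate_all()].
#' @return Character vector of the codes of met rules.
#' @export
met_rules <- function(rules) {
  unname(vapply(Filter(function(r) r$met, rules), `[[`, character(1), "code"))
}
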