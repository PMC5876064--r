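# Structured evidence model: one EvidenceBundle holds everything the rules
# engine may consume for a single variant in a single disease context.
# Evidence is declarative -- curator-asserted booleans and enumerations are
# taken at face value, never inferred from free text.

#' Enumerations used by the evidence model
#'
#' Controlled vocabularies for variant consequence classes, proband phenotype
#' tags, disease contexts, functional assay classes and directions,
#' computational consensus verdicts, and classification tiers.
#'
#' @name myh7-enums
#' @keywords internal
NULL

consequence_classes <- c(
  "missense", "nonsense", "frameshift", "canonical-splice",
  "synonymous", "in-frame indel", "stop-loss", "other"
)

phenotype_tags <- c(
  "HCM", "DCM", "RCM", "LVNC-isolated", "DCM-with-prior-HCM", "other"
)

disease_contexts <- c("HCM", "DCM", "RCM")

assay_classes <- c(
  "mammalian-variant-specific-knock-in", "transgenic-dosage-model",
  "knockout", "in-vitro", "other"
)

functional_directions <- c("damaging", "benign", "inconclusive")

computational_consensus_levels <- c(
  "pathogenic-supporting", "benign-supporting", "conflicting", "absent"
)

#' Five-tier classification vocabulary, ordered benign to pathogenic
#' @return Character vector of the five tiers.
#' @export
classification_tiers <- function() {
  c("benign", "likely benign", "uncertain significance",
    "likely pathogenic", "pathogenic")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scalar_or_na <- function(x) {
  if (is.null(x) || length(x) == 0) NA else x[[1]]
}

# preferred human-readable descriptor: protein-level, then coding-level
variant_label <- function(variant) {
  for (f in c("hgvs_p", "hgvs_c")) {
    v <- scalar_or_na(variant[[f]])
    if (!is.null(v) && !is.na(v)) return(v)
  }
  NA_character_
}

#' Describe the variant under classification
#'
#' @param gene Gene symbol; the shipped rule set is specified for `"MYH7"`.
#' @param transcript Reference transcript, default `"NM_000257.3"`.
#' @param hgvs_c,hgvs_p Free-text coding- and protein-level descriptors.
#' @param consequence One of the consequence classes (`missense`, `nonsense`,
#'   `frameshift`, `canonical-splice`, `synonymous`, `in-frame indel`,
#'   `stop-loss`, `other`).
#' @param aa_position 1-based affected amino-acid position on the protein;
#'   `NA` for non-coding effects.
#' @param in_repeat_region Is the variant in a repetitive region (gates PM4)?
#' @return A `variant_identity` object.
#' @export
variant_identity <- function(gene = "MYH7", transcript = "NM_000257.3",
                             hgvs_c = NA_character_, hgvs_p = NA_character_,
                             consequence = "other", aa_position = NA_integer_,
                             in_repeat_region = FALSE) {
  structure(list(
    gene = as.character(scalar_or_na(gene)),
    transcript = as.character(scalar_or_na(transcript)),
    hgvs_c = as.character(scalar_or_na(hgvs_c)),
    hgvs_p = as.character(scalar_or_na(hgvs_p)),
    consequence = as.character(scalar_or_na(consequence)),
    aa_position = suppressWarnings(as.integer(scalar_or_na(aa_position))),
    in_repeat_region = isTRUE(scalar_or_na(in_repeat_region))
  ), class = "variant_identity")
}

#' Allele counts for one population cohort
#'
#' @param population Cohort/ancestry label (e.g. `"NFE"`, `"AFR"`).
#' @param ac Allele count (non-negative integer).
#' @param an Allele number (positive integer).
#' @param deeply_characterized Is this a population where sufficient probands
#'   have been deeply analyzed, making it eligible for BS1? Defaults to `TRUE`
#'   for European-ancestry-style cohort labels, the only populations the
#'   shipped configuration treats as deeply characterized.
#' @return A `population_frequency_record` object.
#' @export
population_frequency_record <- function(population, ac, an,
                                        deeply_characterized = NULL) {
  population <- as.character(scalar_or_na(population))
  if (is.null(deeply_characterized)) {
    deeply_characterized <- !is.na(population) &&
      toupper(population) %in% c("NFE", "EUR", "EUROPEAN",
                                 "NON-FINNISH EUROPEAN", "FIN")
  }
  structure(list(
    population = population,
    ac = suppressWarnings(as.numeric(scalar_or_na(ac))),
    an = suppressWarnings(as.numeric(scalar_or_na(an))),
    deeply_characterized = isTRUE(scalar_or_na(deeply_characterized))
  ), class = "population_frequency_record")
}

#' One independently ascertained index case carrying the variant
#'
#' Unrecognized phenotype tags are conservatively mapped to `"other"`, which
#' is never counted toward proband evidence.
#'
#' @param id Proband identifier.
#' @param cohort Cohort/study identifier the proband was ascertained in.
#' @param phenotype One of `HCM`, `DCM`, `RCM`, `LVNC-isolated`,
#'   `DCM-with-prior-HCM`, `other`.
#' @param duplicate_of Optional identifier of a proband record this
#'   observation is known or suspected to duplicate.
#' @return A `proband_observation` object.
#' @export
proband_observation <- function(id, cohort = NA_character_,
                                phenotype = "other",
                                duplicate_of = NA_character_) {
  phenotype <- as.character(scalar_or_na(phenotype))
  if (is.na(phenotype) || !phenotype %in% phenotype_tags) phenotype <- "other"
  structure(list(
    id = as.character(scalar_or_na(id)),
    cohort = as.character(scalar_or_na(cohort)),
    phenotype = phenotype,
    duplicate_of = as.character(scalar_or_na(duplicate_of))
  ), class = "proband_observation")
}

#' Segregation evidence for one family
#'
#' Supply either a direct count of informative meioses or a pedigree
#' reference (resolved against parsed PED data), never both.
#'
#' @param family Family identifier.
#' @param meioses Direct count of informative meioses separating affected
#'   variant carriers in this family (non-negative integer), or `NA` when a
#'   pedigree reference is given.
#' @param pedigree Family identifier within a parsed PED file, or `NA`.
#' @param nonsegregation Has at least one affected noncarrier been observed?
#' @return A `segregation_record` object.
#' @export
segregation_record <- function(family, meioses = NA_integer_,
                               pedigree = NA_character_,
                               nonsegregation = FALSE) {
  structure(list(
    family = as.character(scalar_or_na(family)),
    meioses = suppressWarnings(as.numeric(scalar_or_na(meioses))),
    pedigree = as.character(scalar_or_na(pedigree)),
    nonsegregation = isTRUE(scalar_or_na(nonsegregation))
  ), class = "segregation_record")
}

#' One documented de novo occurrence
#'
#' All fields must be explicitly asserted by the curator; there are no
#' implicit defaults for evidence.
#'
#' @param paternity_confirmed Biological paternity established.
#' @param maternity_confirmed Biological maternity established (recorded for
#'   the audit trail only; the adapted rules do not require it).
#' @param parents_genotype_negative Both parents genotype-negative.
#' @param parents_phenotype_negative Both parents phenotype-negative after a
#'   thorough clinical evaluation.
#' @param family_history_negative No diagnosed disease or suspicious findings
#'   in a three-generation pedigree.
#' @return A `de_novo_observation` object.
#' @export
de_novo_observation <- function(paternity_confirmed,
                                maternity_confirmed,
                                parents_genotype_negative,
                                parents_phenotype_negative,
                                family_history_negative) {
  as_flag <- function(x) {
    x <- scalar_or_na(x)
    if (is.null(x) || is.na(x)) NA else isTRUE(as.logical(x))
  }
  structure(list(
    paternity_confirmed = as_flag(paternity_confirmed),
    maternity_confirmed = as_flag(maternity_confirmed),
    parents_genotype_negative = as_flag(parents_genotype_negative),
    parents_phenotype_negative = as_flag(parents_phenotype_negative),
    family_history_negative = as_flag(family_history_negative)
  ), class = "de_novo_observation")
}

#' One functional assay result
#'
#' @param assay_class One of `mammalian-variant-specific-knock-in`,
#'   `transgenic-dosage-model`, `knockout`, `in-vitro`, `other`. Only the
#'   knock-in class can activate PS3/BS3.
#' @param direction `damaging`, `benign`, or `inconclusive`.
#' @return A `functional_evidence` object.
#' @export
functional_evidence <- function(assay_class, direction = "inconclusive") {
  structure(list(
    assay_class = as.character(scalar_or_na(assay_class)),
    direction = as.character(scalar_or_na(direction))
  ), class = "functional_evidence")
}

#' Curator-asserted annotation evidence
#'
#' These fields back the rules that consume a single curated judgment:
#' PS1, PM5, PP3/BP4, BP2, BP5 and BP7.
#'
#' @param computational_consensus `pathogenic-supporting`, `benign-supporting`,
#'   `conflicting`, or `absent`.
#' @param same_aa_known_pathogenic Different nucleotide change producing the
#'   same amino-acid change as an established pathogenic variant (PS1).
#' @param other_change_at_pathogenic_residue Different missense change at a
#'   residue with an established pathogenic missense change (PM5).
#' @param in_trans_no_severity Observed in trans / double het without
#'   increased disease severity (BP2).
#' @param in_cis_with_pathogenic Observed in cis with a pathogenic variant
#'   (BP2).
#' @param alternate_molecular_basis Found in a case with an alternate
#'   molecular basis for disease (BP5).
#' @param splice_no_impact_not_conserved Splicing algorithms predict no impact
#'   and the nucleotide is not highly conserved (BP7, silent variants).
#' @return An `annotation_evidence` object.
#' @export
annotation_evidence <- function(computational_consensus = "absent",
                                same_aa_known_pathogenic = FALSE,
                                other_change_at_pathogenic_residue = FALSE,
                                in_trans_no_severity = FALSE,
                                in_cis_with_pathogenic = FALSE,
                                alternate_molecular_basis = FALSE,
                                splice_no_impact_not_conserved = FALSE) {
  structure(list(
    computational_consensus = as.character(scalar_or_na(computational_consensus)),
    same_aa_known_pathogenic = isTRUE(scalar_or_na(same_aa_known_pathogenic)),
    other_change_at_pathogenic_residue =
      isTRUE(scalar_or_na(other_change_at_pathogenic_residue)),
    in_trans_no_severity = isTRUE(scalar_or_na(in_trans_no_severity)),
    in_cis_with_pathogenic = isTRUE(scalar_or_na(in_cis_with_pathogenic)),
    alternate_molecular_basis = isTRUE(scalar_or_na(alternate_molecular_basis)),
    splice_no_impact_not_conserved =
      isTRUE(scalar_or_na(splice_no_impact_not_conserved))
  ), class = "annotation_evidence")
}

#' Assemble all evidence for one variant in one disease context
#'
#' The bundle is the engine's sole input: every rule evaluator consumes a
#' slice of it and nothing else.
#'
#' @param variant A [variant_identity()].
#' @param disease_context `"HCM"`, `"DCM"`, or `"RCM"`.
#' @param population_frequencies List of [population_frequency_record()]s.
#' @param probands List of [proband_observation()]s.
#' @param segregations List of [segregation_record()]s.
#' @param de_novo List of [de_novo_observation()]s.
#' @param functional List of [functional_evidence()]s.
#' @param annotation An [annotation_evidence()].
#' @param expert_override Optional list with elements `classification` (one of
#'   the five tiers) and `justification`; records an expert-panel judgment
#'   without altering the rule-based classification.
#' @return An `evidence_bundle` object.
#' @export
evidence_bundle <- function(variant = variant_identity(),
                            disease_context = "HCM",
                            population_frequencies = list(),
                            probands = list(),
                            segregations = list(),
                            de_novo = list(),
                            functional = list(),
                            annotation = annotation_evidence(),
                            expert_override = NULL) {
  structure(list(
    schema_version = "1.0",
    variant = variant,
    disease_context = as.character(scalar_or_na(disease_context)),
    population_frequencies = unname(population_frequencies),
    probands = unname(probands),
    segregations = unname(segregations),
    de_novo = unname(de_novo),
    functional = unname(functional),
    annotation = annotation,
    expert_override = expert_override
  ), class = "evidence_bundle")
}

violation <- function(where, what) sprintf("%s: %s", where, what)

#' Validate an evidence bundle against the data-model invariants
#'
#' Total over arbitrary input: violations are returned, never raised. Each
#' violation names the offending field and, for list entries, the record
#' index.
#'
#' @param bundle An [evidence_bundle()] (or anything claiming to be one).
#' @return Character vector of violations; empty when the bundle is valid.
#' @export
validate_bundle <- function(bundle) {
  out <- character()
  add <- function(...) out <<- c(out, violation(...))
  if (!is.list(bundle)) {
    return(violation("bundle", "not a list/evidence_bundle"))
  }

  ctx <- scalar_or_na(bundle$disease_context)
  if (is.null(ctx) || is.na(ctx) || !ctx %in% disease_contexts) {
    add("disease_context", sprintf("must be one of %s",
                                   paste(disease_contexts, collapse = "/")))
  }

  v <- bundle$variant
  if (!is.list(v)) {
    add("variant", "missing or not a variant_identity")
  } else {
    if (is.null(v$consequence) || is.na(v$consequence) ||
        !v$consequence %in% consequence_classes) {
      add("variant$consequence", sprintf("must be one of %s",
                                         paste(consequence_classes, collapse = "/")))
    }
    if (!is.null(v$aa_position) && !is.na(v$aa_position) &&
        (!is.numeric(v$aa_position) || v$aa_position < 1)) {
      add("variant$aa_position", "must be >= 1 when present")
    }
  }

  for (i in seq_along(bundle$population_frequencies)) {
    r <- bundle$population_frequencies[[i]]
    where <- sprintf("population_frequencies[%d]", i)
    if (!is.list(r)) { add(where, "not a population_frequency_record"); next }
    ac <- scalar_or_na(r$ac); an <- scalar_or_na(r$an)
    if (is.null(an) || is.na(an) || !is.numeric(an) || an <= 0) {
      add(paste0(where, "$an"), "AN must be > 0")
    }
    if (is.null(ac) || is.na(ac) || !is.numeric(ac) || ac < 0) {
      add(paste0(where, "$ac"), "AC must be >= 0")
    } else if (is.numeric(an) && !is.na(an) && ac > an) {
      add(paste0(where, "$ac"), sprintf("AC (%s) must not exceed AN (%s)", ac, an))
    }
  }

  for (i in seq_along(bundle$probands)) {
    r <- bundle$probands[[i]]
    where <- sprintf("probands[%d]", i)
    if (!is.list(r)) { add(where, "not a proband_observation"); next }
    ph <- scalar_or_na(r$phenotype)
    if (is.null(ph) || is.na(ph) || !ph %in% phenotype_tags) {
      add(paste0(where, "$phenotype"), "unrecognized phenotype tag")
    }
  }

  for (i in seq_along(bundle$segregations)) {
    r <- bundle$segregations[[i]]
    where <- sprintf("segregations[%d]", i)
    if (!is.list(r)) { add(where, "not a segregation_record"); next }
    has_n <- !is.null(r$meioses) && !is.na(scalar_or_na(r$meioses))
    has_ped <- !is.null(r$pedigree) && !is.na(scalar_or_na(r$pedigree))
    if (has_n == has_ped) {
      add(where, "exactly one of {meioses count, pedigree reference} must be supplied")
    }
    if (has_n && (!is.numeric(r$meioses) || r$meioses < 0)) {
      add(paste0(where, "$meioses"), "must be >= 0")
    }
  }

  for (i in seq_along(bundle$de_novo)) {
    r <- bundle$de_novo[[i]]
    where <- sprintf("de_novo[%d]", i)
    if (!is.list(r)) { add(where, "not a de_novo_observation"); next }
    for (f in c("paternity_confirmed", "maternity_confirmed",
                "parents_genotype_negative", "parents_phenotype_negative",
                "family_history_negative")) {
      x <- scalar_or_na(r[[f]])
      if (is.null(x) || is.na(x) || !is.logical(x)) {
        add(paste0(where, "$", f), "must be explicitly TRUE or FALSE")
      }
    }
  }

  for (i in seq_along(bundle$functional)) {
    r <- bundle$functional[[i]]
    where <- sprintf("functional[%d]", i)
    if (!is.list(r)) { add(where, "not a functional_evidence"); next }
    if (is.null(r$assay_class) || is.na(scalar_or_na(r$assay_class)) ||
        !r$assay_class %in% assay_classes) {
      add(paste0(where, "$assay_class"), "unrecognized assay class")
    }
    if (is.null(r$direction) || is.na(scalar_or_na(r$direction)) ||
        !r$direction %in% functional_directions) {
      add(paste0(where, "$direction"), "must be damaging/benign/inconclusive")
    }
  }

  a <- bundle$annotation
  if (!is.list(a)) {
    add("annotation", "missing or not an annotation_evidence")
  } else if (is.null(a$computational_consensus) ||
             is.na(scalar_or_na(a$computational_consensus)) ||
             !a$computational_consensus %in% computational_consensus_levels) {
    add("annotation$computational_consensus",
        sprintf("must be one of %s",
                paste(computational_consensus_levels, collapse = "/")))
  }

  ov <- bundle$expert_override
  if (!is.null(ov)) {
    cl <- scalar_or_na(ov$classification)
    if (is.null(cl) || is.na(cl) || !cl %in% classification_tiers()) {
      add("expert_override$classification", "must be one of the five tiers")
    }
  }

  out
}

#' @export
print.evidence_bundle <- function(x, ...) {
  cat(sprintf("<evidence_bundle> %s %s (%s)\n",
              x$variant$gene %||% "?",
              x$variant$hgvs_p %||% x$variant$hgvs_c %||% "?",
              x$disease_context))
  cat(sprintf("  populations: %d | probands: %d | families: %d | de novo: %d | assays: %d\n",
              length(x$population_frequencies), length(x$probands),
              length(x$segregations), length(x$de_novo), length(x$functional)))
  if (!is.null(x$expert_override)) {
    cat(sprintf("  expert override -> %s\n", x$expert_override$classification))
  }
  invisible(x)
}
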