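# The adapted rule registry: all 28 base ACMG/AMP criteria with their
# MYH7-specific specification types (removed, disease/gene-specified,
# unchanged), the five strength-modified derivative codes, and the gating
# relations (PS4 and PP1 tiers require PM2). The registry is data, not
# logic, so future gene adaptations can reuse the engine.

rule_strengths <- c("standalone", "very-strong", "strong", "moderate",
                    "supporting")

registry_row <- function(code, base, direction, strength, spec_type,
                         gating = "", description = "") {
  data.frame(code = code, base = base, direction = direction,
             strength = strength, spec_type = spec_type, gating = gating,
             description = description, stringsAsFactors = FALSE)
}

default_registry_table <- function() {
  rbind(
    # pathogenic framework ---------------------------------------------------
    registry_row("PVS1", "PVS1", "pathogenic", "very-strong", "removed", "",
      "Null variant in gene with established LOF as disease mechanism"),
    registry_row("PS1", "PS1", "pathogenic", "strong", "no-change", "",
      "Different nucleotide change (same amino acid) as an established pathogenic variant"),
    registry_row("PS2", "PS2", "pathogenic", "strong", "disease-gene", "",
      "De novo (paternity confirmed) in a patient with disease and no family history; maternity proof not required"),
    registry_row("PS3", "PS3", "pathogenic", "strong", "disease-gene", "",
      "Functional studies of mammalian knock-in models supportive of a damaging effect"),
    registry_row("PS4", "PS4", "pathogenic", "strong", "disease-gene", "PM2",
      "Variant identified in >= 15 probands with consistent phenotypes"),
    registry_row("PM1", "PM1", "pathogenic", "moderate", "disease-gene", "",
      "Missense variant in the myosin head functional domain (amino acids 181-937)"),
    registry_row("PM2", "PM2", "pathogenic", "moderate", "disease-gene", "",
      "Absent/extremely rare (filtering allele frequency < 0.004%) from large population studies"),
    registry_row("PM3", "PM3", "pathogenic", "moderate", "removed", "",
      "Detected in trans with a pathogenic variant (recessive)"),
    registry_row("PM4", "PM4", "pathogenic", "moderate", "no-change", "",
      "Protein length change: in-frame indel in a nonrepeat region, or stop-loss"),
    registry_row("PM5", "PM5", "pathogenic", "moderate", "no-change", "",
      "Different missense change at a residue with an established pathogenic missense change"),
    registry_row("PM6", "PM6", "pathogenic", "moderate", "disease-gene", "",
      "Assumed de novo without confirmation of paternity"),
    registry_row("PP1", "PP1", "pathogenic", "supporting", "disease-gene", "PM2",
      "Cosegregation: >= 3 informative meioses (LOD 0.9)"),
    registry_row("PP2", "PP2", "pathogenic", "supporting", "removed", "",
      "Missense variant in a missense-constrained gene"),
    registry_row("PP3", "PP3", "pathogenic", "supporting", "no-change", "",
      "Multiple lines of computational evidence support a deleterious effect"),
    registry_row("PP4", "PP4", "pathogenic", "supporting", "removed", "",
      "Phenotype specific for disease with single genetic etiology"),
    registry_row("PP5", "PP5", "pathogenic", "supporting", "removed", "",
      "Reputable source reports as pathogenic without accessible evidence"),
    # strength-modified derivative codes -------------------------------------
    registry_row("PVS1_Moderate", "PVS1", "pathogenic", "moderate",
                 "modified-strength", "",
      "Null variant in gene with evidence supporting LOF as disease mechanism"),
    registry_row("PS4_Moderate", "PS4", "pathogenic", "moderate",
                 "modified-strength", "PM2",
      "Variant identified in >= 6 probands with consistent phenotypes"),
    registry_row("PS4_Supporting", "PS4", "pathogenic", "supporting",
                 "modified-strength", "PM2",
      "Variant identified in >= 2 probands with consistent phenotypes"),
    registry_row("PP1_Moderate", "PP1", "pathogenic", "moderate",
                 "modified-strength", "PM2",
      "Cosegregation: >= 5 informative meioses (LOD 1.5)"),
    registry_row("PP1_Strong", "PP1", "pathogenic", "strong",
                 "modified-strength", "PM2",
      "Cosegregation: >= 7 informative meioses (LOD 2.1)"),
    # benign framework --------------------------------------------------------
    registry_row("BA1", "BA1", "benign", "standalone", "disease-gene", "",
      "Filtering allele frequency >= 0.1% in a well-sampled population"),
    registry_row("BS1", "BS1", "benign", "strong", "disease-gene", "",
      "Filtering allele frequency >= 0.02% in a deeply characterized population, no conflicting information"),
    registry_row("BS2", "BS2", "benign", "strong", "removed", "",
      "Observed in healthy adult with full penetrance expected at an early age"),
    registry_row("BS3", "BS3", "benign", "strong", "no-change", "",
      "Functional studies of mammalian knock-in models supportive of no damaging effect"),
    registry_row("BS4", "BS4", "benign", "strong", "disease-gene", "",
      "Nonsegregation in affected members of a family"),
    registry_row("BP1", "BP1", "benign", "supporting", "removed", "",
      "Missense variant in gene where only LOF causes disease"),
    registry_row("BP2", "BP2", "benign", "supporting", "disease-gene", "",
      "In trans / double het without increased severity, or in cis with a pathogenic variant"),
    registry_row("BP3", "BP3", "benign", "supporting", "removed", "",
      "In-frame indels in a repetitive region without known function"),
    registry_row("BP4", "BP4", "benign", "supporting", "no-change", "",
      "Multiple lines of computational evidence suggest no impact"),
    registry_row("BP5", "BP5", "benign", "supporting", "disease-gene", "",
      "Variant found in a case with an alternate molecular basis for disease"),
    registry_row("BP6", "BP6", "benign", "supporting", "removed", "",
      "Reputable source reports as benign without accessible evidence"),
    registry_row("BP7", "BP7", "benign", "supporting", "no-change", "",
      "Silent variant, no predicted splicing impact, nucleotide not conserved")
  )
}

#' Build the adapted rule registry
#'
#' Returns the full registry of ACMG/AMP criteria as adapted for MYH7:
#' every base rule with its specification type (`removed`, `disease-gene`,
#' `no-change`) plus the strength-modified derivative codes
#' (`PVS1_Moderate`, `PS4_Moderate`, `PS4_Supporting`, `PP1_Moderate`,
#' `PP1_Strong`). Removed rules are retained as rows for the audit trail but
#' are never evaluated.
#'
#' @param config Optional list of per-code overrides, each a named list of
#'   registry columns to replace (e.g.
#'   `list(PM1 = list(spec_type = "no-change"))`). Naming an unknown rule
#'   code is an error.
#' @return Data frame with columns `code`, `base`, `direction`, `strength`,
#'   `spec_type`, `gating`, `description`, of class `myh7_registry`.
#' @export
build_registry <- function(config = NULL) {
  reg <- default_registry_table()
  if (!is.null(config)) {
    for (code in names(config)) {
      i <- match(code, reg$code)
      if (is.na(i)) stop(sprintf("unknown rule code in config: '%s'", code))
      for (field in names(config[[code]])) {
        if (!field %in% names(reg)) {
          stop(sprintf("unknown registry field '%s'", field))
        }
        reg[i, field] <- config[[code]][[field]]
      }
    }
  }
  bad_gate <- setdiff(unlist(strsplit(reg$gating[reg$gating != ""], ",")),
                      reg$code)
  if (length(bad_gate)) {
    stop(sprintf("gating references unknown rule(s): %s",
                 paste(bad_gate, collapse = ", ")))
  }
  class(reg) <- c("myh7_registry", "data.frame")
  reg
}

#' Audit the registry against the published specification counts
#'
#' @param registry A registry from [build_registry()].
#' @return List with `n_base` (distinct base rules), `removed`,
#'   `disease_gene` (base rules requiring disease/gene adjustment, counting
#'   a base rule once even when it carries strength-modified derivatives),
#'   `modified_strength` (derivative codes), and `no_change`.
#' @export
registry_audit <- function(registry) {
  base_rows <- registry[registry$spec_type != "modified-strength", ]
  list(
    n_base = length(unique(registry$base)),
    removed = sum(base_rows$spec_type == "removed"),
    disease_gene = sum(base_rows$spec_type == "disease-gene"),
    modified_strength = sum(registry$spec_type == "modified-strength"),
    no_change = sum(base_rows$spec_type == "no-change")
  )
}

#' Write / read a registry as YAML
#'
#' @param registry A registry from [build_registry()].
#' @param path File path.
#' @return `write_registry_yaml` returns `path` invisibly;
#'   `read_registry_yaml` returns a registry data frame.
#' @export
write_registry_yaml <- function(registry, path) {
  rows <- lapply(seq_len(nrow(registry)), function(i) as.list(registry[i, ]))
  yaml::write_yaml(list(rules = rows), path)
  invisible(path)
}

#' @rdname write_registry_yaml
#' @export
read_registry_yaml <- function(path) {
  rows <- yaml::read_yaml(path)$rules
  reg <- do.call(rbind, lapply(rows, function(r) {
    do.call(registry_row, r[c("code", "base", "direction", "strength",
                              "spec_type", "gating", "description")])
  }))
  class(reg) <- c("myh7_registry", "data.frame")
  reg
}
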