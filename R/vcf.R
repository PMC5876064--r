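# Optional VCF annotation of classification results. Goes through
# Bioconductor's VariantAnnotation, loaded on demand so the core engine
# stays light.

#' Annotate a template VCF with classification results
#'
#' Matches template records to bundles by the VCF `ID` column against the
#' bundle's protein-level (or, failing that, coding-level) descriptor, and
#' writes three INFO keys: `MYH7_TIER` (five-tier classification),
#' `MYH7_RULES` (met rule codes, `|`-separated), and `MYH7_CONFLICT`
#' (0/1). Header lines declaring the keys are added; unmatched records pass
#' through with the keys unset.
#'
#' @param bundles List of [evidence_bundle()]s.
#' @param classifications Parallel list from [classify_bundle()].
#' @param template_vcf Path to the template VCF.
#' @param out Output VCF path.
#' @return List with `path`, `n_annotated`, `n_unmatched`, invisibly.
#' @export
write_vcf_annotations <- function(bundles, classifications, template_vcf, out) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("VCF annotation requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(template_vcf, genome = "unknown")
  ids <- rownames(vcf)

  keys <- vapply(bundles, function(b) variant_label(b$variant), character(1))

  tier <- rep(NA_character_, length(ids))
  rulestr <- rep(NA_character_, length(ids))
  conflict <- rep(NA_integer_, length(ids))
  hit <- match(ids, keys)
  matched <- !is.na(hit)
  tier[matched] <- vapply(classifications[hit[matched]], `[[`, character(1),
                          "tier")
  rulestr[matched] <- vapply(classifications[hit[matched]], function(cls) {
    if (length(cls$met)) paste(cls$met, collapse = "|") else "none"
  }, character(1))
  conflict[matched] <- vapply(classifications[hit[matched]], function(cls)
    as.integer(cls$conflict), integer(1))

  hdr <- VariantAnnotation::header(vcf)
  new_info <- S4Vectors::DataFrame(
    Number = c("1", "1", "1"),
    Type = c("String", "String", "Integer"),
    Description = c(
      "Five-tier rule-based classification (MYH7-adapted ACMG/AMP)",
      "Met rule codes, pipe-separated",
      "1 when pathogenic- and benign-direction evidence conflict"),
    row.names = c("MYH7_TIER", "MYH7_RULES", "MYH7_CONFLICT"))
  VariantAnnotation::info(hdr) <- rbind(VariantAnnotation::info(hdr), new_info)
  VariantAnnotation::header(vcf) <- hdr
  VariantAnnotation::info(vcf)$MYH7_TIER <- gsub(" ", "_", tier)
  VariantAnnotation::info(vcf)$MYH7_RULES <- rulestr
  VariantAnnotation::info(vcf)$MYH7_CONFLICT <- conflict

  VariantAnnotation::writeVcf(vcf, out)
  invisible(list(path = out, n_annotated = sum(matched),
                 n_unmatched = sum(!matched)))
}
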