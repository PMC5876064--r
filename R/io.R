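# Evidence-bundle JSON I/O and classification reports (JSON + flat TSV).
# Frequencies are proportions everywhere internally; percent appears only in
# presentation-layer output.

bundle_to_list <- function(bundle) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  strip(unclass(bundle))
}

bundle_from_list <- function(x) {
  v <- x$variant %||% list()
  evidence_bundle(
    variant = do.call(variant_identity, v[intersect(names(v),
      names(formals(variant_identity)))]),
    disease_context = x$disease_context %||% NA_character_,
    population_frequencies = lapply(x$population_frequencies %||% list(),
      function(r) population_frequency_record(
        r$population %||% NA_character_, r$ac, r$an,
        deeply_characterized = r$deeply_characterized)),
    probands = lapply(x$probands %||% list(), function(r)
      proband_observation(r$id %||% NA_character_,
                          r$cohort %||% NA_character_,
                          r$phenotype %||% "other",
                          r$duplicate_of %||% NA_character_)),
    segregations = lapply(x$segregations %||% list(), function(r)
      segregation_record(r$family %||% NA_character_,
                         meioses = r$meioses %||% NA_integer_,
                         pedigree = r$pedigree %||% NA_character_,
                         nonsegregation = r$nonsegregation %||% FALSE)),
    de_novo = lapply(x$de_novo %||% list(), function(r)
      de_novo_observation(r$paternity_confirmed %||% NA,
                          r$maternity_confirmed %||% NA,
                          r$parents_genotype_negative %||% NA,
                          r$parents_phenotype_negative %||% NA,
                          r$family_history_negative %||% NA)),
    functional = lapply(x$functional %||% list(), function(r)
      functional_evidence(r$assay_class %||% "other",
                          r$direction %||% "inconclusive")),
    annotation = do.call(annotation_evidence,
      (x$annotation %||% list())[intersect(names(x$annotation %||% list()),
        names(formals(annotation_evidence)))]),
    expert_override = x$expert_override
  )
}

#' Write evidence bundles as JSON
#'
#' One JSON array, one object per bundle, each carrying a `schema_version`
#' field.
#'
#' @param bundles List of [evidence_bundle()]s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(bundles, path) {
  jsonlite::write_json(lapply(bundles, bundle_to_list), path,
                       auto_unbox = TRUE, null = "null", na = "null",
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read evidence bundles from JSON
#'
#' Parses the documented JSON dialect, validates every record, and returns
#' the valid bundles. Malformed records are rejected and collected into an
#' error report (attribute `"errors"`, one entry per rejected record naming
#' the record index and its violations). An empty file yields an empty list
#' with a warning.
#'
#' @param path Path to a JSON file (array of bundles).
#' @return List of validated [evidence_bundle()]s with attribute `"errors"`.
#' @export
read_evidence <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!nzchar(trimws(txt))) {
    warning(sprintf("empty evidence file: %s", path))
    return(structure(list(), errors = character()))
  }
  raw <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (!is.null(raw$bundles)) raw <- raw$bundles
  bundles <- list()
  errors <- character()
  for (i in seq_along(raw)) {
    sv <- raw[[i]]$schema_version %||% "1.0"
    if (!identical(as.character(sv), "1.0")) {
      errors <- c(errors, sprintf("record %d: unsupported schema_version '%s'",
                                  i, sv))
      next
    }
    b <- bundle_from_list(raw[[i]])
    issues <- validate_bundle(b)
    if (length(issues)) {
      errors <- c(errors, sprintf("record %d: %s", i,
                                  paste(issues, collapse = "; ")))
    } else {
      bundles[[length(bundles) + 1]] <- b
    }
  }
  structure(bundles, errors = errors)
}

classification_row <- function(bundle, cls) {
  data.frame(
    gene = bundle$variant$gene,
    variant = variant_label(bundle$variant),
    disease_context = bundle$disease_context,
    tier = cls$tier,
    criterion = cls$criterion,
    conflict = cls$conflict,
    rules_met = paste(cls$met, collapse = "|"),
    override = if (!is.null(cls$override)) cls$override$classification
               else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Write classification reports
#'
#' `write_report_tsv` emits one line per variant (tier, matched criterion,
#' conflict flag, met rules, any expert override). `write_report_json`
#' emits the same assignments plus the full applied-rule traces.
#'
#' @param bundles List of [evidence_bundle()]s.
#' @param classifications List of classifications from [classify_bundle()],
#'   parallel to `bundles`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(bundles, classifications, path) {
  rows <- do.call(rbind, Map(classification_row, bundles, classifications))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
write_report_json <- function(bundles, classifications, path) {
  entries <- Map(function(b, cls) {
    list(
      gene = b$variant$gene,
      variant = variant_label(b$variant),
      disease_context = b$disease_context,
      tier = cls$tier,
      criterion = cls$criterion,
      conflict = cls$conflict,
      rules_met = as.list(cls$met),
      override = cls$override,
      applied_rules = lapply(unname(cls$rules), function(r)
        list(code = r$code, met = r$met, strength = r$strength,
             direction = r$direction, summary = r$summary))
    )
  }, bundles, classifications)
  jsonlite::write_json(unname(entries), path, auto_unbox = TRUE,
                       null = "null", na = "null", pretty = TRUE, digits = NA)
  invisible(path)
}
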