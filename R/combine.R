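# Evidence combination: maps a set of applied rules to one of the five
# tiers using the parent ACMG/AMP combining table plus the expert-panel
# modification allowing likely benign on BS1 alone. The table is data
# (config-expressible); the shipped default is the parent framework.

#' The parent evidence-combination table
#'
#' Each entry is a minimum-count requirement over strength tallies
#' (`vs` very strong, `s` strong, `m` moderate, `p` supporting for the
#' pathogenic direction; `sa` standalone, `bs` strong, `bp` supporting for
#' the benign direction). A tier is reached when any of its requirements is
#' satisfied; pathogenic is checked before likely pathogenic, benign before
#' likely benign. `bs1_alone_likely_benign` encodes the expert-panel
#' modification: BS1 alone yields likely benign when no pathogenic-direction
#' rule is met.
#'
#' @return A `combining_table` list.
#' @export
default_combining_table <- function() {
  structure(list(
    pathogenic = list(
      c(vs = 1, s = 1), c(vs = 1, m = 2), c(vs = 1, m = 1, p = 1),
      c(vs = 1, p = 2), c(s = 2), c(s = 1, m = 3), c(s = 1, m = 2, p = 2),
      c(s = 1, m = 1, p = 4)
    ),
    likely_pathogenic = list(
      c(vs = 1, m = 1), c(s = 1, m = 1), c(s = 1, p = 2), c(m = 3),
      c(m = 2, p = 2), c(m = 1, p = 4)
    ),
    benign = list(c(sa = 1), c(bs = 2)),
    likely_benign = list(c(bs = 1, bp = 1), c(bp = 2)),
    bs1_alone_likely_benign = TRUE
  ), class = "combining_table")
}

requirement_label <- function(req) {
  nm <- c(vs = "VS", s = "S", m = "M", p = "P", sa = "SA", bs = "BS", bp = "BP")
  paste(sprintf("%d%s", unname(req), nm[names(req)]), collapse = "+")
}

match_requirements <- function(tally, reqs) {
  for (req in reqs) {
    if (all(tally[names(req)] >= req)) return(requirement_label(req))
  }
  NULL
}

#' Combine applied rules into a five-tier classification
#'
#' Tallies met rules by evidence direction and strength as applied, then
#' walks the combining table. BA1 is standalone and overrides everything
#' else; otherwise mixed-direction evidence resolves to uncertain
#' significance with the conflict flag raised, so curators see the tension
#' rather than a silent tie-break. BS1 alone (no pathogenic-direction rule
#' met) yields likely benign.
#'
#' @param rules List of [applied_rule()]s (met and unmet; unmet are kept in
#'   the trace only).
#' @param combining A [default_combining_table()]-shaped list.
#' @return A `myh7_classification` list: `tier`, `criterion` (matched
#'   combining-table label), `conflict`, `met` (codes), and `rules` (the
#'   full applied-rule trace).
#' @export
combine_rules <- function(rules, combining = default_combining_table()) {
  met <- Filter(function(r) isTRUE(r$met), rules)
  bases <- vapply(met, `[[`, character(1), "base")
  if (anyDuplicated(bases)) {
    stop(sprintf("duplicate base rule code(s) among met rules: %s",
                 paste(unique(bases[duplicated(bases)]), collapse = ", ")))
  }
  dirs <- vapply(met, `[[`, character(1), "direction")
  strengths <- vapply(met, `[[`, character(1), "strength")
  codes <- vapply(met, `[[`, character(1), "code")

  tally <- c(vs = sum(dirs == "pathogenic" & strengths == "very-strong"),
             s = sum(dirs == "pathogenic" & strengths == "strong"),
             m = sum(dirs == "pathogenic" & strengths == "moderate"),
             p = sum(dirs == "pathogenic" & strengths == "supporting"),
             sa = sum(dirs == "benign" & strengths == "standalone"),
             bs = sum(dirs == "benign" & strengths == "strong"),
             bp = sum(dirs == "benign" & strengths == "supporting"))

  has_path <- any(dirs == "pathogenic")
  has_ben <- any(dirs == "benign")
  tier <- "uncertain significance"
  criterion <- NA_character_
  conflict <- FALSE

  if (tally[["sa"]] >= 1) {
    # standalone benign evidence is absolute in the parent framework
    tier <- "benign"
    criterion <- "SA"
  } else if (has_path && has_ben) {
    conflict <- TRUE
  } else if (has_path) {
    lab <- match_requirements(tally, combining$pathogenic)
    if (!is.null(lab)) {
      tier <- "pathogenic"; criterion <- lab
    } else {
      lab <- match_requirements(tally, combining$likely_pathogenic)
      if (!is.null(lab)) { tier <- "likely pathogenic"; criterion <- lab }
    }
  } else if (has_ben) {
    lab <- match_requirements(tally, combining$benign)
    if (!is.null(lab)) {
      tier <- "benign"; criterion <- lab
    } else {
      lab <- match_requirements(tally, combining$likely_benign)
      if (!is.null(lab)) {
        tier <- "likely benign"; criterion <- lab
      } else if (isTRUE(combining$bs1_alone_likely_benign) &&
                 "BS1" %in% codes) {
        tier <- "likely benign"; criterion <- "BS1 alone"
      }
    }
  }

  structure(list(tier = tier, criterion = criterion, conflict = conflict,
                 met = codes, tally = tally, rules = rules),
            class = "myh7_classification")
}

#' @export
print.myh7_classification <- function(x, ...) {
  cat(sprintf("<classification> %s%s\n", x$tier,
              if (x$conflict) " (conflicting evidence)" else ""))
  if (!is.na(x$criterion)) cat(sprintf("  matched criterion: %s\n", x$criterion))
  cat(sprintf("  met rules: %s\n",
              if (length(x$met)) paste(x$met, collapse = ", ") else "none"))
  if (!is.null(x$override)) {
    cat(sprintf("  expert override -> %s (%s)\n",
                x$override$classification, x$override$justification %||% ""))
  }
  invisible(x)
}

#' Classify one evidence bundle end to end
#'
#' Convenience wrapper: [evaluate_all()] then [combine_rules()]. When the
#' bundle carries an expert override, the report records both the rule-based
#' tier and the overridden tier with its justification; the override never
#' alters the rule-based result.
#'
#' @inheritParams evaluate_all
#' @return A `myh7_classification` with an `override` element when present.
#' @export
classify_bundle <- function(bundle, config = myh7_config(),
                            pedigrees = list()) {
  rules <- evaluate_all(bundle, config, pedigrees)
  cls <- combine_rules(rules, config$combining)
  if (!is.null(bundle$expert_override)) {
    cls$override <- bundle$expert_override
  }
  cls
}
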