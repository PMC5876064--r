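# Case-level evidence: proband counting with phenotype filters and duplicate
# collapsing (PS4 tiers), quasi case-control enrichment statistics,
# segregation LOD from informative meioses (PP1 tiers, BS4), and de novo
# logic (PS2/PM6).

#' Count probands eligible for PS4-style evidence
#'
#' Deduplicates observations (same proband identifier, or records linked by
#' `duplicate_of`, count once per identity cluster) and applies the
#' phenotype-ambiguity filters: isolated left ventricular noncompaction is
#' never counted in HCM or DCM contexts, and plain DCM cases are excluded
#' from HCM counts unless earlier clinical evidence supported HCM
#' (`DCM-with-prior-HCM`). Phenotypes matching the disease context always
#' count; `other` never does.
#'
#' @param observations List of [proband_observation()]s.
#' @param disease_context `"HCM"`, `"DCM"`, or `"RCM"`.
#' @return List with `count` (integer) and `trace` (data frame with one row
#'   per observation: phenotype, eligibility, identity cluster, and whether
#'   the observation was the one counted for its cluster).
#' @export
count_eligible_probands <- function(observations, disease_context) {
  disease_context <- match.arg(disease_context, disease_contexts)
  n <- length(observations)
  if (n == 0) {
    return(list(count = 0L,
                trace = data.frame(id = character(), phenotype = character(),
                                   eligible = logical(), cluster = integer(),
                                   counted = logical(),
                                   stringsAsFactors = FALSE)))
  }

  ids <- vapply(observations, function(o) o$id %||% NA_character_, character(1))
  dups <- vapply(observations, function(o) o$duplicate_of %||% NA_character_,
                 character(1))
  phen <- vapply(observations, function(o) o$phenotype %||% "other", character(1))

  eligible <- vapply(phen, function(p) {
    if (p %in% c("other", "LVNC-isolated")) return(FALSE)
    if (p == disease_context) return(TRUE)
    if (p == "DCM-with-prior-HCM") return(disease_context %in% c("HCM", "DCM"))
    FALSE
  }, logical(1))

  # identity clusters: union over shared ids and duplicate links
  nodes <- unique(stats::na.omit(c(ids, dups)))
  cluster <- seq_len(n)
  if (length(nodes)) {
    key <- function(x) match(x, nodes)
    parent <- seq_along(nodes)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    union2 <- function(i, j) parent[find(i)] <<- find(j)
    for (k in seq_len(n)) {
      if (!is.na(ids[k]) && !is.na(dups[k])) union2(key(ids[k]), key(dups[k]))
    }
    roots <- vapply(seq_along(nodes), find, integer(1))
    cluster <- ifelse(is.na(ids), seq_len(n) + length(nodes),
                      roots[match(ids, nodes)])
  }
  cluster <- match(cluster, unique(cluster))

  counted <- logical(n)
  for (cl in unique(cluster[eligible])) {
    members <- which(cluster == cl & eligible)
    counted[members[1]] <- TRUE
  }

  list(count = sum(counted),
       trace = data.frame(id = ids, phenotype = phen, eligible = eligible,
                          cluster = cluster, counted = counted,
                          stringsAsFactors = FALSE))
}

#' Case and control cohort sizes for quasi case-control analysis
#'
#' Large reference cohorts (ExAC-style) stand in for healthy controls;
#' disease cohorts are pooled across studies. The shipped sizes are
#' illustrative defaults; supply your own when cohort composition is known.
#' Under the PM2 gate the variant is assumed absent or extremely rare in
#' controls, encoded as a small fixed control carrier count.
#'
#' @param cases Named numeric vector of case cohort sizes (individuals) per
#'   ancestry label.
#' @param controls Named numeric vector of control cohort sizes per ancestry.
#' @param control_carriers Assumed control carrier count (non-negative).
#' @return A `cohort_model` object.
#' @export
cohort_model <- function(cases = c(AFR = 500, NFE = 2500),
                         controls = c(AFR = 5203, NFE = 33370),
                         control_carriers = 2) {
  if (any(cases <= 0) || any(controls <= 0)) stop("cohort sizes must be positive")
  if (control_carriers < 0) stop("control_carriers must be >= 0")
  structure(list(cases = cases, controls = controls,
                 control_carriers = control_carriers),
            class = "cohort_model")
}

fisher_two_sided_p <- function(a, b, c, d) {
  # two-sided p = sum of probabilities of all tables (fixed margins) no more
  # likely than the observed one; ties included with a small relative slack
  m <- a + b; k <- a + c; N <- a + b + c + d
  lo <- max(0L, k - (c + d)); hi <- min(m, k)
  x <- lo:hi
  p <- stats::dhyper(x, m, N - m, k)
  min(1, sum(p[p <= p[x == a] * (1 + 1e-7)]))
}

#' Quasi case-control enrichment test
#'
#' Builds the 2x2 carrier/non-carrier by case/control table for one ancestry
#' by pooling proband carriers against a large reference cohort standing in
#' for controls, and tests conditional independence with the two-sided
#' Fisher's exact test (sum of all table probabilities no larger than the
#' observed table's). The odds ratio is the sample odds ratio, `Inf` when no
#' control carriers are assumed, and reported as 1 by convention when there
#' are no carriers at all.
#'
#' @param case_carriers Number of probands carrying the variant.
#' @param cohorts A [cohort_model()].
#' @param ancestry Ancestry label present in both cohort vectors.
#' @return List with `odds_ratio`, `p_value`, and `table` (2x2 matrix:
#'   rows carrier/non-carrier, columns case/control).
#' @export
quasi_case_control <- function(case_carriers, cohorts = cohort_model(),
                               ancestry = "NFE") {
  if (!ancestry %in% names(cohorts$cases) ||
      !ancestry %in% names(cohorts$controls)) {
    stop(sprintf("unknown ancestry label '%s'", ancestry))
  }
  n_case <- cohorts$cases[[ancestry]]
  n_ctrl <- cohorts$controls[[ancestry]]
  if (case_carriers < 0 || case_carriers > n_case) {
    stop("case_carriers must be between 0 and the case cohort size")
  }
  a <- case_carriers                      # case carriers
  b <- cohorts$control_carriers           # control carriers
  c <- n_case - a                         # case non-carriers
  d <- n_ctrl - b                         # control non-carriers
  tab <- matrix(c(a, c, b, d), nrow = 2,
                dimnames = list(c("carrier", "non-carrier"),
                                c("case", "control")))
  or <- if (a == 0 && b == 0) 1
        else if (b == 0 || c == 0) Inf
        else (a * d) / (b * c)
  p <- if (a == 0 && b == 0) 1 else fisher_two_sided_p(a, b, c, d)
  list(odds_ratio = or, p_value = p, table = tab)
}

#' Tier the multiple-probands rule PS4
#'
#' Universal proband-count thresholds of at least 2 (supporting), 6
#' (moderate), and 15 (strong), applicable only when the variant is absent
#' or extremely rare in population databases (PM2 met).
#'
#' @param proband_count Deduplicated eligible proband count.
#' @param pm2_met Is PM2 met for this variant?
#' @return `"PS4"`, `"PS4_Moderate"`, `"PS4_Supporting"`, or `"none"`.
#' @export
tier_ps4 <- function(proband_count, pm2_met) {
  if (proband_count < 0) stop("proband_count must be >= 0")
  if (!isTRUE(pm2_met)) return("none")
  if (proband_count >= 15) "PS4"
  else if (proband_count >= 6) "PS4_Moderate"
  else if (proband_count >= 2) "PS4_Supporting"
  else "none"
}

#' Segregation LOD score from informative meioses
#'
#' Affected-only cosegregation in an autosomal dominant setting: each
#' informative meiosis halves the probability of the observed transmission
#' pattern under no linkage, so the LOD score simplifies to
#' `log10(2^n) = n * log10(2)`.
#'
#' @param n Number of informative meioses (non-negative).
#' @return LOD score.
#' @examples
#' lod_score(3)  # 0.903
#' lod_score(7)  # 2.107
#' @export
lod_score <- function(n) {
  if (any(!is.numeric(n)) || any(is.na(n)) || any(n < 0)) {
    stop("n must be a non-negative number of meioses")
  }
  n * log10(2)
}

#' Count informative meioses across families
#'
#' Direct counts are summed as given. Pedigree-referenced records are
#' resolved against parsed PED data: within a family, informative meioses
#' are the transmission links among affected genotyped carriers, with
#' unaffected or ungenotyped connectors traversed but not credited — each
#' pedigree connected component containing k affected carriers contributes
#' k - 1 meioses. Any affected noncarrier marks the family as
#' nonsegregating; a nonsegregating family contributes zero meioses.
#'
#' @param records List of [segregation_record()]s.
#' @param pedigrees Named list of pedigree data frames (see [read_ped()]),
#'   indexed by family identifier, for records carrying a pedigree
#'   reference.
#' @return List with `n` (total informative meioses), `lod`,
#'   `nonsegregation` (any family nonsegregating), and `families` (per-family
#'   breakdown data frame).
#' @export
count_informative_meioses <- function(records, pedigrees = list()) {
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    nonseg <- isTRUE(r$nonsegregation)
    if (!is.null(r$pedigree) && !is.na(scalar_or_na(r$pedigree))) {
      ped <- pedigrees[[r$pedigree]]
      if (is.null(ped)) {
        stop(sprintf("segregation record %d references unknown pedigree '%s'",
                     i, r$pedigree))
      }
      res <- pedigree_meioses(ped)
      nonseg <- nonseg || res$nonsegregation
      n <- if (nonseg) 0 else res$n
    } else {
      n <- if (nonseg) 0 else r$meioses
    }
    data.frame(family = r$family %||% NA_character_, meioses = n,
               nonsegregation = nonseg, stringsAsFactors = FALSE)
  })
  fam <- if (length(rows)) do.call(rbind, rows)
         else data.frame(family = character(), meioses = numeric(),
                         nonsegregation = logical(), stringsAsFactors = FALSE)
  n <- sum(fam$meioses)
  list(n = n, lod = lod_score(n), nonsegregation = any(fam$nonsegregation),
       families = fam)
}

#' Tier the cosegregation rule PP1 and flag nonsegregation (BS4)
#'
#' Evidence levels follow autosomal dominant likelihood ratios of 10, 30 and
#' 100: supporting at 3 or more informative meioses (LOD 0.9), moderate at 5
#' (LOD 1.5), strong at 7 (LOD 2.1), provided PM2 is met and no
#' nonsegregation has been observed. Meioses may come from a single family;
#' the parent framework's multi-family requirement is waived for this
#' well-established disease gene.
#'
#' @param evidence Result of [count_informative_meioses()].
#' @param pm2_met Is PM2 met?
#' @return List with `pp1` (`"PP1_Strong"`, `"PP1_Moderate"`, `"PP1"`, or
#'   `"none"`) and `bs4` (logical nonsegregation flag).
#' @export
tier_pp1 <- function(evidence, pm2_met) {
  bs4 <- isTRUE(evidence$nonsegregation)
  pp1 <- "none"
  if (isTRUE(pm2_met) && !bs4) {
    n <- evidence$n
    pp1 <- if (n >= 7) "PP1_Strong"
           else if (n >= 5) "PP1_Moderate"
           else if (n >= 3) "PP1"
           else "none"
  }
  list(pp1 = pp1, bs4 = bs4)
}

#' Evaluate de novo evidence (PS2 / PM6)
#'
#' An observation qualifies only when both parents are genotype- and
#' phenotype-negative and the three-generation family history is negative.
#' Strong weight (PS2) applies with a single paternity-confirmed qualifying
#' occurrence, or with three or more qualifying occurrences regardless of
#' paternity confirmation; otherwise a qualifying occurrence earns moderate
#' weight (PM6). Proof of maternity is not required.
#'
#' @param observations List of [de_novo_observation()]s.
#' @return `"PS2"`, `"PM6"`, or `"none"` (never both PS2 and PM6).
#' @export
evaluate_de_novo <- function(observations) {
  if (length(observations) == 0) return("none")
  qual <- vapply(observations, function(o) {
    isTRUE(o$parents_genotype_negative) &&
      isTRUE(o$parents_phenotype_negative) &&
      isTRUE(o$family_history_negative)
  }, logical(1))
  if (!any(qual)) return("none")
  confirmed <- vapply(observations, function(o) isTRUE(o$paternity_confirmed),
                      logical(1))
  if (any(qual & confirmed) || sum(qual) >= 3) "PS2" else "PM6"
}
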