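# Independent oracles used across the suite. Each is implemented from first
# principles, on a different code path from the functions it checks.

# One-sided lower confidence bound on the allele frequency by bisection on
# the Poisson survival function (oracle for filtering_allele_frequency).
faf_bisection_oracle <- function(ac, an, confidence = 0.95) {
  if (ac == 0) return(0)
  f <- function(p) stats::ppois(ac - 1, p * an, lower.tail = FALSE) -
    (1 - confidence)
  stats::uniroot(f, c(0, 1), tol = 1e-14)$root
}

# Two-sided Fisher p for one table by explicit enumeration over the
# hypergeometric support, summing probabilities no larger than the observed
# table's (with fisher.test's relative tie slack).
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b
  k <- a + c
  N <- a + b + c + d
  x <- max(0, k - (N - m)):min(m, k)
  pr <- stats::dhyper(x, m, N - m, k)
  min(1, sum(pr[pr <= pr[x == a] * (1 + 1e-7)]))
}

# Vectorized form: for fixed margins (case total c1, control total c2,
# carrier total m), returns the two-sided p for every possible case-carrier
# count a at once, via sorted cumulative probabilities.
fisher_enum_oracle_margin <- function(c1, c2, m) {
  a <- max(0, m - c2):min(c1, m)
  pr <- stats::dhyper(a, m, c1 + c2 - m, c1)
  ord <- order(pr)
  cs <- cumsum(pr[ord])
  idx <- findInterval(pr * (1 + 1e-7), pr[ord])
  stats::setNames(pmin(1, cs[idx]), a)
}

# Brute-force reimplementation of the parent evidence-combination table,
# written as literal nested conditions (oracle for combine_rules). Takes
# met-rule descriptors, returns a tier string.
combine_oracle <- function(codes, directions, strengths) {
  vs <- sum(directions == "pathogenic" & strengths == "very-strong")
  s  <- sum(directions == "pathogenic" & strengths == "strong")
  m  <- sum(directions == "pathogenic" & strengths == "moderate")
  p  <- sum(directions == "pathogenic" & strengths == "supporting")
  sa <- sum(directions == "benign" & strengths == "standalone")
  bs <- sum(directions == "benign" & strengths == "strong")
  bp <- sum(directions == "benign" & strengths == "supporting")
  if (sa >= 1) return("benign")
  path <- (vs + s + m + p) > 0
  ben <- (bs + bp) > 0
  if (path && ben) return("uncertain significance")
  if (path) {
    if (vs >= 1) {
      if (s >= 1 || m >= 2 || (m == 1 && p >= 1) || p >= 2) return("pathogenic")
    }
    if (s >= 2) return("pathogenic")
    if (s >= 1) {
      if (m >= 3 || (m == 2 && p >= 2) || (m == 1 && p >= 4)) return("pathogenic")
    }
    if (vs == 1 && m == 1) return("likely pathogenic")
    if (s == 1 && m >= 1 && m <= 2) return("likely pathogenic")
    if (s == 1 && p >= 2) return("likely pathogenic")
    if (m >= 3) return("likely pathogenic")
    if (m == 2 && p >= 2) return("likely pathogenic")
    if (m == 1 && p >= 4) return("likely pathogenic")
    return("uncertain significance")
  }
  if (ben) {
    if (bs >= 2) return("benign")
    if (bs >= 1 && bp >= 1) return("likely benign")
    if (bp >= 2) return("likely benign")
    if ("BS1" %in% codes && bs == 1 && bp == 0) return("likely benign")
    return("uncertain significance")
  }
  "uncertain significance"
}

# Build an applied-rule list for arbitrary met codes, looking direction and
# strength up in the registry.
rules_from_codes <- function(codes, registry = build_registry()) {
  lapply(codes, function(code) {
    i <- match(code, registry$code)
    applied_rule(code, TRUE, registry$strength[i], registry$direction[i])
  })
}

# Random met-rule sets with no duplicated base code and no removed rules.
random_rule_sets <- function(n, registry = build_registry()) {
  live <- registry[registry$spec_type != "removed", ]
  replicate(n, {
    k <- sample(0:6, 1)
    picked <- character(0)
    bases <- character(0)
    pool <- sample(seq_len(nrow(live)))
    for (i in pool) {
      if (length(picked) >= k) break
      if (!live$base[i] %in% bases) {
        picked <- c(picked, live$code[i])
        bases <- c(bases, live$base[i])
      }
    }
    picked
  }, simplify = FALSE)
}

tier_rank <- function(tier) match(tier, classification_tiers())

make_pop <- function(ac, an, label = "NFE", deeply = TRUE) {
  population_frequency_record(label, ac, an, deeply_characterized = deeply)
}

make_probands <- function(n, phenotype = "HCM", prefix = "P") {
  lapply(seq_len(n), function(i)
    proband_observation(sprintf("%s%03d", prefix, i), "cohort", phenotype))
}

qualifying_de_novo <- function(paternity = TRUE) {
  de_novo_observation(paternity_confirmed = paternity,
                      maternity_confirmed = FALSE,
                      parents_genotype_negative = TRUE,
                      parents_phenotype_negative = TRUE,
                      family_history_negative = TRUE)
}
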