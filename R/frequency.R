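# Allele-frequency-driven rules: filtering allele frequency (the one-sided
# 95% lower confidence bound on the true allele frequency), the maximum
# credible population allele frequency for a dominant pathogenic allele, and
# the BA1 / BS1 / PM2 threshold logic evaluated popmax-style.

#' Filtering allele frequency
#'
#' The lower bound of a one-sided confidence interval on the true allele
#' frequency given an observed allele count: the largest underlying frequency
#' p at which seeing `ac` or more alleles among `an` would still be as rare
#' as `1 - confidence`. Using this statistically corrected estimate instead
#' of the raw AC/AN protects rare-variant threshold comparisons against
#' sampling noise in smaller cohorts.
#'
#' Under the default Poisson model the bound inverts the Poisson survival
#' function in closed form (`qgamma(1 - confidence, shape = ac) / an`); an
#' exact-binomial mode (`qbeta`) is available for cross-checking.
#'
#' @param ac Observed allele count, `0 <= ac <= an`.
#' @param an Allele number, `> 0`.
#' @param confidence One-sided confidence level, default 0.95.
#' @param method `"poisson"` (default) or `"binomial"`.
#' @return The filtering allele frequency as a proportion; 0 when `ac = 0`.
#' @examples
#' filtering_allele_frequency(1, 66740)
#' filtering_allele_frequency(0, 120000)
#' @export
filtering_allele_frequency <- function(ac, an, confidence = 0.95,
                                       method = c("poisson", "binomial")) {
  method <- match.arg(method)
  if (!is.numeric(ac) || !is.numeric(an) || length(ac) != length(an)) {
    stop("ac and an must be numeric vectors of equal length")
  }
  if (any(is.na(ac)) || any(is.na(an)) || any(an <= 0) || any(ac < 0) ||
      any(ac > an)) {
    stop("require 0 <= ac <= an and an > 0")
  }
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1) {
    stop("confidence must be in (0, 1)")
  }
  faf <- numeric(length(ac))
  pos <- ac > 0
  if (any(pos)) {
    faf[pos] <- switch(method,
      # P(Pois(p*an) >= ac) = 1 - confidence  <=>  p*an = qgamma(1 - conf, ac)
      poisson = stats::qgamma(1 - confidence, shape = ac[pos]) / an[pos],
      # P(Bin(an, p) >= ac) = 1 - confidence  <=>  p = qbeta(1 - conf, ac, an - ac + 1)
      binomial = stats::qbeta(1 - confidence, ac[pos], an[pos] - ac[pos] + 1)
    )
  }
  faf
}

#' Maximum credible population allele frequency
#'
#' The highest frequency a pathogenic allele could plausibly reach in the
#' general population, given the disease prevalence (per individual; halved
#' to an allele-level prevalence for an autosomal dominant disorder), the
#' allelic contribution (the gene's share of disease for BA1-style bounds,
#' or the maximum single-variant share for BS1/PM2-style bounds), and the
#' penetrance (incomplete penetrance inflates the credible frequency).
#'
#' @param prevalence Disease prevalence as a proportion of individuals
#'   (e.g. `1/200`).
#' @param contribution Allelic contribution in (0, 1].
#' @param penetrance Penetrance in (0, 1].
#' @return Maximum credible allele frequency as a proportion.
#' @examples
#' max_credible_af(1/500, 0.02, 0.5)   # 4e-5, i.e. 0.004%
#' max_credible_af(1/200, 0.106, 0.3)  # ~8.8e-4, rounded up to 0.1% for BA1
#' @export
max_credible_af <- function(prevalence, contribution, penetrance) {
  for (x in list(prevalence = prevalence, contribution = contribution,
                 penetrance = penetrance)) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
      stop("prevalence, contribution and penetrance must be numeric scalars")
    }
  }
  if (penetrance <= 0) stop("penetrance must be > 0")
  if (prevalence <= 0 || prevalence > 1) stop("prevalence must be in (0, 1]")
  if (contribution <= 0 || contribution > 1) stop("contribution must be in (0, 1]")
  if (penetrance > 1) stop("penetrance must be <= 1")
  (prevalence / 2) * contribution / penetrance
}

#' Configuration for the allele-frequency rules
#'
#' Thresholds are encoded constants (the expert-panel values), not quantities
#' recomputed at run time: the panel's rounding from derived maxima to the
#' published thresholds is a judgment, not an algorithm.
#'
#' @param ba1 BA1 threshold (proportion), default 1e-3 (0.1%).
#' @param bs1 BS1 threshold, default 2e-4 (0.02%).
#' @param pm2 PM2 threshold, default 4e-5 (0.004%).
#' @param confidence One-sided confidence for the filtering allele frequency.
#' @param min_an Minimum allele number for a population to be considered
#'   (default 2000 alleles).
#' @param method Filtering-AF model, `"poisson"` or `"binomial"`.
#' @return A `frequency_rule_config` object.
#' @export
frequency_rule_config <- function(ba1 = 1e-3, bs1 = 2e-4, pm2 = 4e-5,
                                  confidence = 0.95, min_an = 2000,
                                  method = "poisson") {
  if (!(pm2 < bs1 && bs1 < ba1)) {
    stop("thresholds must satisfy pm2 < bs1 < ba1")
  }
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  structure(list(ba1 = ba1, bs1 = bs1, pm2 = pm2, confidence = confidence,
                 min_an = min_an, method = method),
            class = "frequency_rule_config")
}

#' Evaluate the allele-frequency rules BA1 / BS1 / PM2
#'
#' Computes the filtering allele frequency per population, drops populations
#' below the minimum allele number, and evaluates the thresholds on the
#' maximum filtering AF across the remaining populations (popmax-style: a
#' variant common in any well-sampled ancestry cannot be a dominant
#' pathogenic allele). BA1 and BS1 activate at `>=` their thresholds (BS1
#' only in deeply characterized populations); PM2 activates when the maximum
#' filtering AF over all eligible populations is `<` its threshold. The
#' outcomes are mutually exclusive; BS1's "no conflicting information"
#' proviso is enforced downstream by the combiner.
#'
#' @param records List of [population_frequency_record()]s (at least one).
#' @param config A [frequency_rule_config()].
#' @return List with `outcome` (`"BA1"`, `"BS1"`, `"PM2"`, or `"none"`),
#'   `per_population` (data frame of AC, AN, filtering AF, eligibility),
#'   `max_faf`, and `warning` (`TRUE` when no population passed the
#'   minimum-AN gate, in which case the outcome is `"none"`).
#' @export
evaluate_frequency_rules <- function(records, config = frequency_rule_config()) {
  if (length(records) == 0) stop("at least one population record is required")
  per <- do.call(rbind, lapply(records, function(r) {
    data.frame(population = r$population, ac = r$ac, an = r$an,
               deeply_characterized = isTRUE(r$deeply_characterized),
               stringsAsFactors = FALSE)
  }))
  per$faf <- filtering_allele_frequency(per$ac, per$an,
                                        confidence = config$confidence,
                                        method = config$method)
  per$eligible <- per$an >= config$min_an

  if (!any(per$eligible)) {
    return(list(outcome = "none", per_population = per, max_faf = NA_real_,
                warning = TRUE))
  }

  elig <- per[per$eligible, , drop = FALSE]
  max_faf <- max(elig$faf)
  bs1_pops <- elig[elig$deeply_characterized, , drop = FALSE]
  outcome <-
    if (max_faf >= config$ba1) "BA1"
    else if (nrow(bs1_pops) > 0 && max(bs1_pops$faf) >= config$bs1) "BS1"
    else if (max_faf < config$pm2) "PM2"
    else "none"

  list(outcome = outcome, per_population = per, max_faf = max_faf,
       warning = FALSE)
}
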