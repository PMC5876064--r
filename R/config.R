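# Run configuration: frequency thresholds, threshold-derivation parameters,
# cohort model, registry overrides and combining table, with YAML round-trip
# for the shipped MYH7 defaults.

#' Assemble the full engine configuration
#'
#' The shipped defaults are the MYH7 adaptation: BA1/BS1/PM2 filtering-AF
#' thresholds of 0.1% / 0.02% / 0.004%, the published threshold-derivation
#' parameter sets, an illustrative quasi case-control cohort model, and the
#' parent combining table with the BS1-alone likely-benign modification.
#'
#' @param frequency A [frequency_rule_config()].
#' @param cohorts A [cohort_model()].
#' @param derivation Named list of threshold-derivation parameter sets, each
#'   with `prevalence`, `contribution`, `penetrance` (proportions).
#' @param registry_overrides Optional overrides passed to [build_registry()].
#' @param combining A combining table, see [default_combining_table()].
#' @return A `myh7_config` list.
#' @export
myh7_config <- function(frequency = frequency_rule_config(),
                        cohorts = cohort_model(),
                        derivation = default_derivation_params(),
                        registry_overrides = NULL,
                        combining = default_combining_table()) {
  structure(list(frequency = frequency, cohorts = cohorts,
                 derivation = derivation,
                 registry_overrides = registry_overrides,
                 combining = combining),
            class = "myh7_config")
}

#' Published threshold-derivation parameter sets
#'
#' BA1 uses the most conservative disease prevalence across the associated
#' cardiomyopathies (1/200 individuals), the gene's contribution to disease
#' (10.6%), and a deliberately low penetrance (30%). BS1 replaces the gene
#' contribution with the maximum credible single-variant contribution (2%).
#' PM2 uses more realistic prevalence and penetrance (1/500, 50%) with the
#' same maximum variant contribution.
#'
#' @return Named list of parameter sets (`ba1`, `bs1`, `pm2`).
#' @export
default_derivation_params <- function() {
  list(
    ba1 = list(prevalence = 1/200, contribution = 0.106, penetrance = 0.30),
    bs1 = list(prevalence = 1/200, contribution = 0.02, penetrance = 0.30),
    pm2 = list(prevalence = 1/500, contribution = 0.02, penetrance = 0.50)
  )
}

#' Threshold-derivation table
#'
#' One row per frequency rule: the derivation parameters, the derived
#' maximum credible allele frequency, and the encoded threshold actually
#' applied (the panel's rounded constant).
#'
#' @param config A [myh7_config()].
#' @return Data frame with columns `rule`, `prevalence`, `contribution`,
#'   `penetrance`, `derived_max_credible_af`, `encoded_threshold`.
#' @export
threshold_derivation_table <- function(config = myh7_config()) {
  rules <- names(config$derivation)
  do.call(rbind, lapply(rules, function(r) {
    p <- config$derivation[[r]]
    data.frame(
      rule = toupper(r),
      prevalence = p$prevalence,
      contribution = p$contribution,
      penetrance = p$penetrance,
      derived_max_credible_af =
        max_credible_af(p$prevalence, p$contribution, p$penetrance),
      encoded_threshold = config$frequency[[r]],
      stringsAsFactors = FALSE
    )
  }))
}

#' Read / write engine configuration as YAML
#'
#' @param path File path. `read_myh7_config(NULL)` loads the YAML shipped
#'   with the package (`inst/extdata/myh7_config.yaml`), whose values equal
#'   the in-code defaults.
#' @param config A [myh7_config()].
#' @return `read_myh7_config` returns a `myh7_config`; `write_myh7_config`
#'   returns `path` invisibly.
#' @export
read_myh7_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "myh7_config.yaml", package = "myh7rules")
  }
  y <- yaml::read_yaml(path)
  freq <- do.call(frequency_rule_config, y$frequency)
  coh <- cohort_model(cases = unlist(y$cohorts$cases),
                      controls = unlist(y$cohorts$controls),
                      control_carriers = y$cohorts$control_carriers)
  comb <- default_combining_table()
  if (!is.null(y$combining)) {
    for (tier in c("pathogenic", "likely_pathogenic", "benign",
                   "likely_benign")) {
      if (!is.null(y$combining[[tier]])) {
        comb[[tier]] <- lapply(y$combining[[tier]], function(r) unlist(r))
      }
    }
    if (!is.null(y$combining$bs1_alone_likely_benign)) {
      comb$bs1_alone_likely_benign <- isTRUE(y$combining$bs1_alone_likely_benign)
    }
  }
  myh7_config(frequency = freq, cohorts = coh, derivation = y$derivation,
              registry_overrides = y$registry_overrides, combining = comb)
}

#' @rdname read_myh7_config
#' @export
write_myh7_config <- function(config, path) {
  y <- list(
    frequency = unclass(config$frequency),
    cohorts = list(cases = as.list(config$cohorts$cases),
                   controls = as.list(config$cohorts$controls),
                   control_carriers = config$cohorts$control_carriers),
    derivation = config$derivation,
    registry_overrides = config$registry_overrides,
    combining = c(
      lapply(unclass(config$combining)[c("pathogenic", "likely_pathogenic",
                                         "benign", "likely_benign")],
             function(reqs) lapply(reqs, as.list)),
      list(bs1_alone_likely_benign = config$combining$bs1_alone_likely_benign)
    )
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
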