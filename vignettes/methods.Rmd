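---
title: "Methods: the MYH7-adapted classification rules and their implementation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the MYH7-adapted classification rules and their implementation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myh7rules)
```

## The classification model

`myh7rules` implements a gene-specific adaptation of the ACMG/AMP
variant-classification framework for MYH7-associated cardiomyopathies
(HCM, DCM, RCM). The framework is a weighted-evidence system: criteria on
the pathogenic side (very strong / strong / moderate / supporting) and the
benign side (standalone / strong / supporting) activate independently, and
a fixed combining table maps the tally to one of five tiers. The adaptation
has three structural parts:

1. a **registry** of all 28 base criteria annotated with their
   gene-specific status — 9 removed, 12 disease/gene-specified, 7
   unchanged — plus 5 strength-modified derivative codes
   (`PVS1_Moderate`, `PS4_Moderate`, `PS4_Supporting`, `PP1_Moderate`,
   `PP1_Strong`);
2. **quantitative evaluators** for the criteria the parent framework
   leaves vague: allele-frequency thresholds, segregation LOD tiers,
   proband-count tiers, de novo logic; and
3. the parent **combining table**, modified so that BS1 alone yields
   likely benign when nothing argues for pathogenicity.

The engine's input is a declarative *evidence bundle*: curator-asserted
counts, enumerations and booleans. The engine never infers evidence from
free text — the rules consume curated judgments, and the package's job is
to apply them identically every time, with a per-rule trace.

Key modeling assumptions inherited from the framework: autosomal dominant
inheritance, a single-variant disease paradigm, and evidence independence
across criteria (the registry avoids double counting structurally, e.g.
PP2 is removed because PM1 already rewards head-domain missense variants).

## Allele-frequency rules

A dominant pathogenic allele cannot be common. The *maximum credible
population allele frequency* is

$$\mathrm{AF}_{\max} = \frac{\text{prevalence}/2 \times \text{allelic contribution}}{\text{penetrance}}$$

with prevalence per individual (halved to chromosomes), allelic
contribution the variant's maximum share of disease, and penetrance in
(0, 1]. The shipped derivation parameter sets are: BA1 — prevalence 1/200,
gene contribution 10.6%, penetrance 30% (derived 8.83e-4, encoded 1e-3);
BS1 — 1/200, maximum variant contribution 2%, 30% (derived 1.67e-4,
encoded 2e-4); PM2 — 1/500, 2%, 50% (derived and encoded 4e-5). The
encoded thresholds are constants, not values recomputed at run time: the
panel's rounding from derived maxima to published thresholds is a
judgment, and re-deriving it would silently change classifications.

Observed cohort frequencies are noisy for rare variants, so comparisons
use the **filtering allele frequency**: the lower bound of a one-sided 95%
confidence interval on the true frequency. Under the default Poisson model
this is the exact inversion `qgamma(1 - conf, shape = AC) / AN`; an
exact-binomial mode (`qbeta(1 - conf, AC, AN - AC + 1)`) is provided as a
numerical cross-check. The two agree to ~0.1% at the allele frequencies
that matter here. `AC = 0` maps to frequency 0.

Numerical and boundary choices:

- BA1 and BS1 activate **inclusively** (`>=` threshold); PM2 activates
  strictly below its threshold, matching how the thresholds are printed.
- Evaluation is **popmax-style**: the maximum filtering AF across
  populations with at least `min_an` alleles (default 2000 — roughly 1000
  genotyped individuals, below which the 95% bound is so far under the
  point estimate that the comparison is uninformative). If no population
  passes the gate the outcome is "none" with a warning flag, not an error.
- BS1 applies only to populations flagged *deeply characterized* (default:
  European-ancestry-style labels), because knowledge of the benign
  spectrum in under-sampled ancestries is too thin to call a variant
  "too common for disease" there.
- The three outcomes are mutually exclusive by the evaluation order
  BA1 → BS1 → PM2.

## Segregation

Cardiomyopathies show variable onset and reduced penetrance, so the
implementation uses affected-only counting: `n` informative meioses
separating affected variant carriers gives `LOD = n·log10(2)` (each
transmission halves the no-linkage likelihood). Tiers: supporting at
n ≥ 3 (LOD 0.9), moderate at n ≥ 5 (LOD 1.5), strong at n ≥ 7 (LOD 2.1),
gated on PM2, single families allowed.

From a pedigree, meioses are counted as transmission links among affected
genotyped carriers: each connected component containing *k* affected
carriers contributes *k − 1*. Unaffected or ungenotyped individuals
connect carriers but are never credited — an affected-carrier grandparent
and grandchild joined through an unaffected carrier parent yield one
meiosis, not two. This is the most conservative reading of affected-only
counting; for complex (e.g. consanguineous) families a direct curator
count is the authoritative escape hatch, supplied per family in the
segregation record. Any affected noncarrier marks the family as
nonsegregating (BS4; one observation suffices, overridable in the
registry) and zeroes that family's meioses.

## Multiple probands

PS4 tiers are driven by universal deduplicated proband-count thresholds
(≥ 2 supporting, ≥ 6 moderate, ≥ 15 strong, PM2 required). Counting
applies the panel's ambiguity filters: isolated left ventricular
noncompaction never counts in HCM or DCM contexts (its disease status is
debated); DCM cases do not count toward HCM variants unless earlier
clinical evidence supported HCM; records linked as known or suspected
duplicates collapse into one identity cluster (transitively), and the
trace records which observation carried the count.

The underlying statistic — a quasi case-control comparison pooling
probands against a large reference cohort as proxy controls — is exposed
as `quasi_case_control()`: a two-sided Fisher's exact test (p = sum of all
table probabilities no larger than the observed table's, with a 1e-7
relative tie slack, the same convention as `stats::fisher.test`) plus the
sample odds ratio (`Inf` when no control carriers are assumed; OR 1 and
p 1 for the empty table by convention). Tiering is deliberately driven by
the count thresholds, not the statistic, mirroring the framework's
simplification for routine diagnostic use; the statistic is reporting
context. The default cohort model (cases 500 AFR / 2500 NFE against
reference cohorts of 5203 / 33370 with 2 assumed control carriers) is
illustrative and config-replaceable; cohort sizes behind the published
odds ratios are not public, so none are hard-coded as truth.

## De novo, functional, domain and annotation rules

A de novo observation qualifies only when both parents are genotype- and
phenotype-negative and a three-generation history is negative (each a
single curator-asserted boolean — the framework does not define a minimal
evaluation dataset more precisely). PS2 requires confirmed paternity or
≥ 3 qualifying occurrences; otherwise PM6. Maternity confirmation is
recorded but not required. PS2 and PM6 are mutually exclusive.

PS3/BS3 activate only for mammalian variant-specific knock-in models;
dosage models and the historically weak in-vitro assays never do. PM1
covers missense variants in the myosin head domain, amino acids 181–937
inclusive. The registry restricts PM1 to missense even though the
published rule table does not literally say so: pathogenic clustering in
the head domain is a missense phenomenon there, and truncating variants
already route through `PVS1_Moderate`; the restriction is a registry
field, so an override (`build_registry(list(PM1 = ...))`) can relax it.
PS1/PM5 lookups, computational consensus (PP3/BP4), BP2, BP5 and BP7 are
curator-supplied assertions — no databases are bundled.

## Combining

`combine_rules()` tallies met rules by direction and *strength as applied*
(so `PP1_Strong` counts as strong, `PS4_Supporting` as supporting,
`PVS1_Moderate` as moderate) and walks the combining table, which is data:
minimum-count requirements per tier, pathogenic checked before likely
pathogenic. The full parent table is implemented, including very-strong
rows the default registry cannot produce, for reuse in other gene
adaptations. BA1 is absolute. Mixed-direction evidence yields uncertain
significance with a raised conflict flag rather than a silent tie-break —
this also suppresses BS1-alone likely benign whenever any
pathogenic-direction rule is met. Whether a lone BS4 should reach likely
benign is not specified anywhere; the default follows the parent table
(it does not), and the combining table is configurable.

## The synthetic fixture generator

`generate_fixtures()` produces ~46 scenario bundles whose intended rule
activations *and* intended tier are assigned by construction (the tier
from the parent combining table by hand, independently of the package's
combiner), covering: the frequency ladder including a just-above-threshold
BS1 case; proband counts 1/2/5/6/14/15; meioses 2–7; de novo counts 1–3
with and without paternity; the LVNC and DCM-context filters; duplicate
collapsing; domain boundaries 180/181/937/938; functional assay classes;
every annotation rule; and conflict cases. Nuisance quantities (allele
numbers, identifiers) are jittered deterministically from the seed inside
ranges chosen so the intended outcome is invariant; allele counts are
fixed per scenario. A filtering AF *exactly equal* to a shipped threshold
is not constructible from integer counts, so inclusive boundary semantics
are tested separately by setting a config threshold equal to a computed
filtering AF.

What the generator emulates is the *evidence shapes* the rules consume —
not real cohort data. Passing the recovery check therefore demonstrates
that the engine applies the stated rules faithfully to stated evidence; it
says nothing about upstream curation quality, phenotype misclassification
rates, or the true population genetics of any cohort.

## Verification strategy and problem sizes

Every quantitative component is checked against an independent oracle on a
different code path: the filtering AF against bisection on the Poisson
survival function (counts 1–20, cohort sizes 1e3–1e5, relative tolerance
1e-6); the Fisher p-value exhaustively against a vectorized hypergeometric
enumeration for all 2×2 tables with case and control cohort sizes up to 50
(~1.8 million tables, agreement to 1e-9), with the enumeration itself
validated against `stats::fisher.test` on a random subsample; the combiner
against a brute-force nested-conditional transcription of the parent table
on 10,000 random rule sets plus all 4,096 subsets of a 12-rule core; and
the end-to-end engine against the generator manifest. These sizes were
chosen to keep the default suite around three minutes on one core while
still being exhaustive where exhaustiveness is cheap.

## Known limitations

- The engine classifies *evidence bundles*; it does not model expert
  clinical judgment. The override field records a panel judgment alongside
  the rule-based tier without blending the two.
- Thresholds assume autosomal dominant inheritance; no sex-chromosome or
  founder-population corrections are applied.
- Pedigree meiosis counting is deliberately simple; direct counts are
  authoritative for structures it does not model well.
- HGVS strings are carried as opaque descriptors — no parsing, transcript
  mapping, or liftover.
- The quasi case-control model treats reference cohorts as unphenotyped
  controls; cryptic cases in the reference bias the odds ratio downward.
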