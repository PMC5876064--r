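# myh7rules

An R rules engine for classifying sequence variants in **MYH7** (beta-myosin
heavy chain), the gene behind a large share of inherited hypertrophic,
dilated, and restrictive cardiomyopathy (HCM/DCM/RCM), under the ClinGen
Inherited Cardiomyopathy Expert Panel's gene-specific adaptation of the
ACMG/AMP variant-classification framework.

It is written for variant curators, clinical laboratory scientists, and
methodologists who want the adapted criteria applied reproducibly and
audibly: every classification carries a per-rule evidence trace, and every
quantitative rule is an explicit, testable function rather than a judgment
buried in prose.

## What it computes

Evidence for one variant in one disease context is assembled into a
structured *evidence bundle* (JSON), and the engine evaluates every
applicable criterion:

- **Allele-frequency rules (BA1 / BS1 / PM2).** Comparisons use the
  *filtering allele frequency*: the lower bound of a one-sided 95%
  confidence interval on the true allele frequency given the observed
  allele count — under a Poisson model, the largest `p` with
  `P(X ≥ AC | λ = p·AN) = 0.05`, i.e. `qgamma(0.05, AC)/AN`. Thresholds are
  derived from the maximum credible population frequency of a dominant
  pathogenic allele,

  `AF_max = (prevalence / 2) × allelic contribution / penetrance`,

  and encoded as the panel's constants: BA1 ≥ 0.1%, BS1 ≥ 0.02% (deeply
  characterized populations only), PM2 < 0.004%. Rules are evaluated
  popmax-style across populations passing a minimum-AN gate.
- **Segregation (PP1 tiers, BS4).** Affected-only cosegregation with
  `LOD = log10(2^n) = n·log10 2` over `n` informative meioses, counted
  directly or from 7-column PED pedigrees (carrier status in column 7);
  supporting / moderate / strong at n ≥ 3 / 5 / 7 (LOD 0.9 / 1.5 / 2.1),
  gated on PM2. Affected noncarriers flag nonsegregation (BS4).
- **Multiple probands (PS4 tiers).** Deduplicated proband counts with
  phenotype-ambiguity filters (isolated LVNC never counts in HCM/DCM
  contexts; plain DCM does not count toward HCM variants); supporting /
  moderate / strong at ≥ 2 / 6 / 15 probands, gated on PM2. A quasi
  case-control Fisher's exact test against a reference cohort standing in
  for controls (two-sided p and sample odds ratio) is available alongside.
- **De novo (PS2/PM6).** Maternity proof is not required; PS2 with
  confirmed paternity or with ≥ 3 documented qualifying occurrences.
- **Domain, LOF, functional and annotation rules.** PM1 for missense in
  the myosin head domain (aa 181–937); PVS1 demoted to `PVS1_Moderate`;
  PS3/BS3 restricted to mammalian variant-specific knock-in models; PS1,
  PM4, PM5, PP3, BP2, BP4, BP5, BP7 from curated assertions.
- **Combining.** The parent ACMG/AMP combining table (as data, not code),
  with the panel's modification that BS1 alone yields likely benign absent
  conflicting evidence; mixed-direction evidence resolves to uncertain
  significance with a conflict flag. Removed rules (PVS1, PM3, PP2, PP4,
  PP5, BS2, BP1, BP3, BP6) are never evaluated.

## Worked example

The two variants whose full applied-rule sets are public ship as fixtures.
From R:

```r
library(myh7rules)
bundles <- read_evidence(system.file("extdata", "worked_examples.json",
                                     package = "myh7rules"))
classify_bundle(bundles[[1]])
```

or from the shell via the bundled CLI:

```
$ Rscript exec/myh7rules classify \
    --input inst/extdata/worked_examples.json --out /tmp/demo
myh7rules 0.1.0 | subcommand: classify
config: package defaults
p.Arg1420Trp: uncertain significance (PM2, PS4_Moderate, PP3) [expert override -> likely pathogenic]
p.Arg1909Pro: uncertain significance (PM2, PM6, PP3) [expert override -> likely pathogenic]
wrote /tmp/demo/report.tsv and /tmp/demo/report.json
```

Reading: for p.Arg1420Trp the variant is effectively absent from population
cohorts (PM2), seen in 11 independent probands (PS4_Moderate, ≥ 6 but
< 15), and computationally predicted deleterious (PP3). One strong-or-better
or one more supporting criterion short of likely pathogenic, the rule-based
tier is *uncertain significance*; the expert panel's recorded judgment
(likely pathogenic) is reported alongside without altering the rule-based
result.

The threshold-derivation table behind the frequency rules:

```
$ Rscript exec/myh7rules thresholds
 rule prevalence contribution penetrance derived_max_credible_af encoded_threshold derived_pct encoded_pct
  BA1      0.005        0.106        0.3            0.0008833333             1e-03    0.08833%        0.1%
  BS1      0.005        0.020        0.3            0.0001666667             2e-04    0.01667%       0.02%
  PM2      0.002        0.020        0.5            0.0000400000             4e-05      0.004%      0.004%
```

Other subcommands: `registry --audit` (prints the adapted rule table and
its audit counts), `simulate` (deterministic synthetic evidence fixtures
with a ground-truth manifest), `validate` (schema check, nonzero exit on
violations).

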