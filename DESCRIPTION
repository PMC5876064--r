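Package: myh7rules
Title: MYH7-Adapted ACMG/AMP Variant Classification Rules Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rules engine for classifying variants in the MYH7 gene under the
    ClinGen Inherited Cardiomyopathy Expert Panel adaptation of the ACMG/AMP
    framework. Provides a structured evidence data model, quantitative allele
    frequency rules based on the filtering allele frequency (BA1/BS1/PM2),
    segregation LOD scoring from informative meioses (PP1 tiers, BS4),
    semiquantitative proband counting with quasi case-control statistics (PS4
    tiers), de novo logic (PS2/PM6), the adapted rule registry with removed and
    strength-modified criteria, and the modified evidence-combination table
    producing five-tier classifications with full evidence traces. Includes
    JSON/TSV/PED/VCF/YAML interfaces, a command-line front end, and a
    deterministic synthetic fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    S4Vectors,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
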