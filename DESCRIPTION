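Package: sexnest
Title: Sex-Partitioned Nestedness Analysis of Flower-Visitor Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds plant x visitor interaction count matrices from flower-visiting
    insect specimen records and splits each network into female and male
    subnetworks. Computes weighted NODF nestedness, connectance, Chao
    abundance-based niche overlap and abundance-weighted Shannon partner
    diversity, standardizes every index against fixed-marginal (Patefield)
    null networks as z scores, and compares network types with mixed models
    and Bonferroni-corrected pairwise contrasts. Ships a synthetic
    specimen-record generator encoding sex-specific visitation (preference-
    concentrated females, encounter-driven males) over heavy-tailed species
    abundances, so the full pipeline runs end-to-end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
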