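Package: pedpower
Title: Power and Type 1 Error Evaluation for Association and Linkage in Large Complex Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Gene-dropping SNP simulation on large, deep, consanguineous template
    pedigrees of the kind found in population isolates, together with the analyses
    needed to calibrate them: a kinship-corrected quasi-likelihood score (MQLS-style)
    association test that can use phenotypes of ungenotyped relatives, bit-size-limited
    pedigree splitting covering affected individuals and their unaffected siblings,
    exact two-point parametric linkage (LOD and heterogeneity HLOD) on the resulting
    subpedigrees via variable-elimination peeling with loop handling, and replicate
    tallying of empirical type 1 error and power against p-value and HLOD thresholds.
    Includes a synthetic template generator emulating a 13-generation, ~5,000-member
    Amish-like pedigree profile, LINKAGE pre-makeped pedigree file I/O, and exact
    recursive kinship/inbreeding computation on looped pedigrees.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
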