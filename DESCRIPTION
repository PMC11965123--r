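Package: ponlef
Title: Pharmaco-Epigenetic Analysis of Leflunomide Response in Rheumatoid
    Arthritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the joint effect of the PON1 promoter
    polymorphism rs705379 and allele-specific DNA methylation at the
    cg17330251 CpG island on six-month response to leflunomide in
    rheumatoid arthritis cohorts. Implements DAS28 scoring and EULAR
    response classification, blood-count inflammation indices
    (NLR/PLR/SII/SIRI), Hardy-Weinberg testing, genetic-model association
    (codominant, dominant, recessive, allele) with crude and age/sex
    adjusted odds ratios, quartile-based CpG methylation categorisation,
    a composite genetic protective score with multifactor logistic
    models, and a synthetic cohort generator that reproduces the
    allele-specific methylation structure the analysis assumes, so the
    full pipeline can be exercised and verified without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
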