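Package: specdis
Title: Diversity Responses to Disturbance in Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests the specialization-disturbance hypothesis on microbial
    feature-count tables: coverage-based rarefaction of OTU tables to a common
    sample coverage with Hill-number diversity of order q = 2 (inverse
    Simpson), Chao-Shen-estimated Shannon entropy of Gene Ontology term
    abundances converted to effective numbers of functions (1D), and
    disturbed-versus-control group comparison with Welch's t-test and
    Anderson-Darling normality screening. Includes a synthetic community
    generator that emulates specialist/generalist structure (many
    narrow-repertoire specialists, few broad-repertoire generalists,
    disturbance as selection on repertoire size) so the full analysis can be
    exercised without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nortest,
    vegan,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
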