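Package: segviab
Title: Genotype Survival Modeling for Segregation-Distorted Mouse Crosses
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing offspring genotype distributions from mouse
    breeding studies in which some genotype classes die before observation.
    Enumerates exact Mendelian fractions for crosses segregating one X-linked
    and one autosomal null allele (the Naa10/Naa12 design), renormalizes them
    under genotype- and age-specific cumulative survival rates to predict
    observed genotype frequencies at cross-sectional embryonic harvests and a
    postnatal census, fits constrained survival schedules to observed counts
    by a staged grid search minimizing the relative standard deviation of
    observed-minus-expected deltas, computes implied conception litter sizes,
    and performs the within-litter smallest-pup Fisher exact analysis. A
    seeded litter simulator with multinomial genotype draws and binomial
    survival thinning makes the whole pipeline testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
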