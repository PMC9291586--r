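Package: sdturnover
Title: Deterministic Modelling of Sex-Determination Turnover under
    Sexually Antagonistic Selection and Epistasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A deterministic, infinite-population, two-sex recursion model
    for evolutionary transitions between genetic sex-determination systems.
    The genome comprises three linkage groups that each carry a
    sex-determination locus (Y, A or W) linked to a sexually antagonistic
    locus, plus an autosomal locus that interacts epistatically with one of
    the sexually antagonistic loci to modify male fitness. The package
    tracks egg- and sperm-pool haplotype frequencies through gametogenesis
    with recombination, random mating, sex assignment and within-sex
    viability selection; it runs transition scenarios in which a novel
    sex-determining allele invades an ancestral XY system, classifies
    turnover versus maintenance outcomes, performs seeded parameter sweeps,
    and estimates turnover boundaries in parameter space with a smoothed
    binary classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    grDevices,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
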