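Package: sfskit
Title: Joint Site-Frequency-Spectrum Demographic Inference and
    f-Statistic Admixture Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing multi-population demographic history
    from diploid genotype panels: SNP filtering for unfolded site frequency
    spectra (missingness, Hardy-Weinberg, CpG/coding masks, ancestral
    state), multidimensional joint SFS construction with low-count masking
    and 1 Mb block bootstrap, a declarative demographic-model language with
    a built-in single-locus structured coalescent simulator, composite
    likelihood parameter estimation by expectation conditional maximization
    with replicate-run management, likelihood re-estimation, decisive model
    selection and bootstrap confidence intervals, plus f3/f4 statistics,
    Hudson FST, block-jackknife errors, qpWave rank tests and qpAdm
    admixture-weight estimation.  Includes a synthetic-data module that
    generates genotype and allele-frequency panels with known truth for
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    jsonlite,
    yaml,
    vcfR,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
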