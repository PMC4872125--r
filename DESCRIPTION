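Package: ebprtools
Title: Stoichiometric, Community and Probe-Based Analysis of Enhanced
    Biological Phosphorus Removal Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for enhanced biological phosphorus removal
    (EBPR) studies combining batch-test chemistry, 16S community surveys
    and shotgun metagenome reads.  Computes anaerobic and aerobic
    transformation ratios (P/HAc, Gly/HAc, PHB/HAc, PHV/HAc, P/PHA,
    Gly/PHA) from batch-reactor time series and summarises them by
    operating epoch; compares them against canonical polyphosphate- and
    glycogen-accumulating organism (PAO/GAO) stoichiometric models and
    fits a glycolysis-plus-full-TCA flux-balance model with jackknife
    standard errors, estimating the fraction of acetyl-CoA oxidised
    anaerobically and the TCA share of reducing power; detects step-like
    abundance changes in OTU time series between operating epochs with
    Storey-Tibshirani false discovery rate control and simulation-based
    error-rate characterisation; and quantifies FISH probe and primer
    target sites in shotgun reads by exact IUPAC-aware matching
    normalised to a universal probe (in-silico FISH).  Includes
    generators for synthetic batch, OTU and read data with known planted
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    vegan
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
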