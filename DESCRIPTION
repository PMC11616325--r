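Package: bcsfbasl
Title: Quantification of Blood-CSF-Barrier Function from Multi-TI FAIR-ASL MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic-model quantification of multi-inversion-time FAIR arterial
    spin labelling (ASL) MRI in the mouse brain: inversion-recovery T1/M0
    estimation, single-compartment Buxton modelling of tissue cerebral blood
    flow, and a two-compartment model of total blood-CSF-barrier (BCSFB)
    mediated water delivery into ventricular CSF at ultra-long echo time.
    Includes ventricular volumetry and M0 volume normalisation, Y-maze
    spontaneous-alternation scoring, Rayleigh-noise-based choroid-plexus
    volumetry of ex-vivo micro-MRI, the group-comparison statistical layer
    (Mann-Whitney and Welch tests with Benjamini-Hochberg FDR control,
    unbalanced Type III two-way ANOVA with Sidak post-hoc tests), and a fully
    seeded synthetic-data generator for end-to-end parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    emmeans,
    knitr,
    rmarkdown
Config/testthat/edition: 3
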