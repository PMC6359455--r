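Package: psptherm
Title: Partial Solvation Parameters for Drug Thermodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Thermodynamic toolkit built on partial solvation parameters
    (PSP) for pharmaceutical compounds. Converts Abraham LSER descriptors
    (Vx, E, S, A, B) and molar volumes to dispersion, polarity, acidity and
    basicity solvation parameters; solves hydrogen-bonding association
    equilibria by Veytsman statistics; computes combinatorial and residual
    activity-coefficient contributions and the Flory-Huggins chi parameter;
    predicts drug solubility in solvents from fusion data; decomposes
    surface energy into dispersive and acid/base components and predicts
    contact angles; reduces inverse gas chromatography (IGC) retention data
    to infinite-dilution activity coefficients; and estimates a compound's
    LSER descriptors from IGC probe data by staged nonlinear least squares.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
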