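# psptherm

Partial solvation parameters (PSP) for drug thermodynamics in R.

Poorly water-soluble drugs dominate modern pipelines, and formulation work
needs quantitative handles on how a drug interacts with solvents,
excipients and interfaces. Hansen-style solubility parameters are the
traditional tool but lump all hydrogen bonding into one number; Abraham
LSER descriptors distinguish acidity from basicity but sit outside a
thermodynamic model. The PSP framework bridges the two: it maps the five
LSER descriptors of a compound — McGowan volume `Vx`, excess refraction
`E`, polarity `S`, hydrogen-bond acidity `A` and basicity `B` — onto
free-energy-level solvation parameters

    sigma_d  = 100 * sqrt((3.1 Vx + E) / Vm)     (dispersion)
    sigma_p  = 100 * sqrt(S / Vm)                (polarity)
    sigma_Ga = 100 * sqrt(A / Vm)                (acidity)
    sigma_Gb = 100 * sqrt(B / Vm)                (basicity)

in MPa^0.5 (with `Vm` in cm^3/mol), and embeds them in a full mixture
model: hydrogen-bond association equilibria by Veytsman statistics with

    E_HB = -30450 sqrt(AB) J/mol,   S_HB = -35.1 sqrt(AB) J/(K mol),

activity coefficients split into Flory-Huggins combinatorial plus
dispersion, polarity and hydrogen-bonding residual contributions (and the
Flory-Huggins interaction parameter `chi12`), solid–liquid-equilibrium
solubility from fusion data, acid/base surface-energy components, and the
reduction of inverse gas chromatography (IGC) retention data to
infinite-dilution activity coefficients from which a drug's own LSER
descriptors are fitted.

The package is aimed at pharmaceutical scientists doing solvent and
excipient screening, IGC practitioners characterising solid surfaces, and
thermodynamicists who want an auditable, tested implementation of the
whole chain from raw retention times to predicted solubilities.

## Worked example

Six model drugs (carvedilol, cyclosporine A, ketoconazole, loratadine,
simvastatin, zafirlukast) ship with their IGC-derived descriptors,
measured dispersive surface energies and fusion data:

```r
library(psptherm)
library(dplyr)

surface_components(psp_drugs()) |>
  select(name, gamma_a, gamma_b, gamma_hb, gamma_tot)
#> 1 Carvedilol       1.51     4.37     5.13      53.0
#> 2 Cyclosporine A   0.215    1.38     1.09      14.3
#> 3 Ketoconazole     0        1.84     0         45.9
#> 4 Loratadine       0        1.78     0         41.6
#> 5 Simvastatin      0.705    2.47     2.64      60.0
#> 6 Zafirlukast      1.64     4.85     5.64      55.1
```

Reading: carvedilol's measured dispersive surface energy (47.8 mJ/m^2) is
split by its descriptors into a small acidic (1.51) and a larger basic
(4.37) component, giving a hydrogen-bonding term of 5.13 and a total
surface energy of 53.0 mJ/m^2 — ketoconazole and loratadine, with `A = 0`,
have no hydrogen-bonding surface term at all.

Cohesive-energy (solubility-parameter) components come from the same
descriptors, with each drug's molar volume recovered from its dispersion
parameter:

```r
add_psp(psp_drugs()) |>
  select(name, Vm, sigma_p, sigma_Ga, sigma_Gb, sigma_hb)
#> 1 Carvedilol      325.    9.90     3.92     6.68     8.39
#> 2 Cyclosporine A 1084.    8.44     2.54     6.44     7.04
#> ...
```

Solubility prediction couples the activity model to fusion data: for
loratadine in ethanol at 298.15 K,

```r
drug <- left_join(psp_drugs(), psp_fusion(), by = "name")
solve_solubility(compound_row(drug, "Loratadine"),
                 compound_row(psp_solvents(), "Ethanol"))
#>      y1 ideal_y1 gamma_C gamma_res chi12 iterations converged
#>  0.0662   0.0486   0.115      6.37 0.290         26 TRUE
```

the ideal (fusion-only) solubility of 0.0486 mole fraction is corrected by
the combinatorial (0.115, size mismatch favours dissolution) and residual
(6.37, unfavourable interactions) activity coefficients to a predicted
saturation of 0.066 mole fraction.

Descriptor fitting runs the model in reverse — from measured (here
simulated) infinite-dilution activity coefficients back to the drug's
descriptors, broom-style accessors included:

```r
truth <- tibble::tibble(Vx = 3.10, E = 3.08, S = 3.19, A = 0.50, B = 1.45)
dat <- generate_synthetic_igc(truth, psp_solvents()[c(2:5, 11, 13, 18:20, 29), ],
                              noise_sd = 0.05, seed = 42)
fit <- fit_descriptors(dat, Vx = 3.10)
tidy(fit)
#>   term  estimate std_error
#> 1 E        1.16     1.01
#> 2 S        3.37     0.0577
#> 3 A        0.578    0.0178
#> 4 B        1.82     0.101
autoplot(fit)
```

Note the honest standard errors: with 0.05 noise on ln gamma, `E` is
weakly identified (SE about 1) while `S`, `A`, `B` are tight — the methods
vignette discusses why.

## Package layout

- `R/` — descriptors and PSP conversions, hydrogen-bond equilibria,
  activity model, solubility, surface energy, IGC reduction, descriptor
  fitting, plotting.
- `inst/extdata/` — solvent/probe descriptor table, drug records, fusion
  data, reference probe physical properties (editable).
- `vignettes/psp-framework.Rmd` — the model, its assumptions, numerical
  choices and limitations.
- `tests/testthat/` — unit, property and end-to-end suites, including an
  independent brute-force oracle for the association solver.
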