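Package: yedomaflux
Title: Nitrogen Cycling and Nitrous Oxide Flux Analysis for Thawing Permafrost
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for nitrogen cycling and greenhouse-gas flux studies on
    thawing ice-rich (Yedoma) permafrost exposures: static-chamber N2O/CH4/CO2 flux
    calculation with RMSE-based quality control, soil-physical derivations
    (water-filled pore space, dry-weight mineral nitrogen, C/N ratio), net and gross
    (15N pool dilution) nitrogen transformation rates, flask-incubation N2O
    production rates with acetylene-block denitrification partitioning,
    DEM-differencing and transect-based thermal-erosion budgeting up to a
    nitrogen-mobilization and N2O emission-factor chain, functional N-cycling gene
    abundance summaries, and nonparametric group statistics with compact letter
    displays. Includes synthetic-data generators that emulate the statistical
    structure of each field and laboratory measurement, so the whole pipeline is
    testable without field data.
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
    jsonlite,
    withr
Config/testthat/edition: 3
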