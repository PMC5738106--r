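Package: midasim
Title: Digital Twin of the M.I.D.A. Infant In Vitro Digestion Protocol
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Plans simulated digestive fluids and enzyme doses for the
    M.I.D.A. (Model of an Infant Digestive Apparatus) dynamic in vitro
    digestion protocol, generates the 15-second pyloric pulse schedule from
    the power-exponential gastric-emptying model, simulates oral, gastric and
    intestinal starch digestion as a discrete-event compartmental mass
    balance, and computes digestion metrics (degree of starch conversion,
    D-glucose released, percentage of starch hydrolysis) with replicate
    comparisons on simulated, synthetic or measured time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
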