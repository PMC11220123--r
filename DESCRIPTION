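Package: tridea
Title: Three-Stage DEA-Malmquist Efficiency Analysis with Spatial
    Autocorrelation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Input-oriented radial data envelopment analysis (CCR and BCC
    envelopment models with two-phase slack maximisation and returns-to-scale
    classification), stochastic-frontier adjustment of input slacks for
    environmental conditions and statistical noise (the three-stage DEA
    procedure), Malmquist total-factor-productivity decomposition between
    adjacent periods, and global and local Moran's I spatial autocorrelation
    with permutation inference. Includes a synthetic panel generator with
    full ground truth for method validation, a 31-unit provincial fixture
    with contiguity structure, and a pipeline that orchestrates all stages
    over balanced panels of decision-making units.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
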