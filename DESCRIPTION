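Package: herdsample
Title: Sampling Validity of Herd-Level Welfare Indicator Prevalences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for judging how well sample-based surveys
    recover the true herd-level prevalence of binary animal welfare
    indicators in fattening-pig herds. Generates synthetic herds with a
    rooms-pens-animals hierarchy, exact indicator counts and a tunable
    within-pen clustering mechanism; draws samples under five designs
    (simple random, stratified, clustered, stratified clustered, and the
    KTBL guide's pen-based scheme); and evaluates estimator validity by
    Monte-Carlo bias, relative bias, RMSE, range-normalized RMSE and
    deviation-threshold proportions, with exact finite-population
    (hypergeometric) reference computations for the simple random design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
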