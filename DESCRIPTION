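Package: eprsim
Title: Discrete-Event Simulation of External Price Referencing for Medicines
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A deterministic monthly-stepped simulator of external price
    referencing (EPR), the pharmaceutical pricing policy in which a country
    benchmarks the price of a medicine against its prices in a basket of
    reference countries. Models per-country rulebooks (reference basket,
    minimum-availability requirement, benchmark formula, revision schedule)
    for the 28 European EPR-applying countries as of 2015, price adjustments
    by statutory and commercial discounts and by purchasing power parities,
    batch execution of policy scenarios that modify one parameter of the EPR
    methodology at a time, and end-of-horizon comparison statistics against
    the unchanged-policy base case. Includes a seeded generator of random
    EPR country networks for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
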