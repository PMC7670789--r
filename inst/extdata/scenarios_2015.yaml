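# The eight bundled simulation scenarios: the base case (every country
# keeps its 2015 EPR methodology) plus seven one-parameter changes applied
# to all simulated countries. These names are built into the package
# (builtin_scenarios()); this file documents them and the parameter each
# one changes, for use with the command-line batch runner.
scenarios:
  - name: base_case
    parameter: none
    change: "2015 EPR methodology of every country, unchanged"
  - name: strategic_basket
    parameter: reference countries
    change: "every country references Germany, Italy, Finland and Portugal (minus itself)"
  - name: large_basket
    parameter: reference countries
    change: "every country references the 30 other countries of the universe"
  - name: lowest_price
    parameter: calculation method
    change: "every country references the lowest price in its basket"
  - name: statutory_discounts
    parameter: discounts
    change: "statutory manufacturer rebates in Germany, Greece and Ireland are considered"
  - name: statutory_and_commercial_discounts
    parameter: discounts
    change: "additionally an assumed 20% confidential discount on quotes from the configured large economies"
  - name: ppp
    parameter: income adjustment
    change: "reference prices weighted by purchasing power parities"
  - name: biannual_revisions
    parameter: revision frequency
    change: "every country reviews reference prices every 6 months"
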