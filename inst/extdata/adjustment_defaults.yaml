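# Default adjustment parameters for the bundled 2015 base case.
#
# All flags ship FALSE: no country (except a German legal mandate unused in
# practice) considered discounts or weighting in its 2015 EPR methodology,
# so the base case applies none. Scenario transforms flip the flags.
#
# Magnitudes:
#  * statutory rebate rates are the published 2015 values (Germany §130a
#    SGB V manufacturer rebate 7%; Greece EOPYY rebate 9%; Ireland IPHA
#    framework-agreement rebate 5.25%) — configuration inputs, replaceable;
#  * the commercial (confidential) discount is an assumed flat 20% on quotes
#    from the named large economies;
#  * the PPP index is an APPROXIMATE, RECONSTRUCTED set of 2015 comparative
#    price-level indices (actual individual consumption, EU28 = 100); only
#    ratios enter the adjustment. Replace with authoritative values for any
#    serious calibration.
statutory:
  active: false
  rates:
    DE: 0.07
    GR: 0.09
    IE: 0.0525
commercial:
  active: false
  rate: 0.20
  countries: [DE, FR, IT, NL, ES, UK]
ppp:
  active: false
  index:
    AT: 105
    BE: 107
    BG: 46
    HR: 64
    CY: 88
    CZ: 61
    DE: 101
    DK: 137
    EE: 73
    ES: 90
    FI: 119
    FR: 107
    GR: 82
    HU: 57
    IE: 120
    IS: 119
    IT: 99
    LT: 61
    LU: 122
    LV: 69
    MT: 80
    NL: 109
    NO: 141
    PL: 54
    PT: 79
    RO: 50
    SE: 126
    SI: 82
    SK: 66
    CH: 159
    UK: 118
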