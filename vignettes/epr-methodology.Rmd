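---
title: "Simulating external price referencing: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating external price referencing: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eprsim)
```

## The policy being modelled

Under external price referencing (EPR) a pricing authority derives a
benchmark for a medicine from its prices in a basket of other countries.
National methodologies differ in five parameters: which countries are in
the basket, how many reference prices must be available before a price can
be set at all, the formula that turns reference prices into a benchmark,
whether quotes are adjusted (discounts, purchasing power), and how often
the benchmark is re-derived. `eprsim` simulates the joint dynamics of 28
European countries' 2015 methodologies as a deterministic monthly-stepped
cascade, and quantifies how changing one parameter at a time moves prices
relative to leaving all methodologies unchanged.

## State, events and the monthly step

The state at month $t$ is a price vector $p(t)$ over the country universe,
with an explicit *unpriced* value (`NA`) for countries whose benchmark
cannot yet be computed, plus the month each country first priced. Three
country roles exist:

* **kick-off** countries seed the cascade with launch prices (Germany 100,
  Italy 70 in the bundled base case; fictitious euro values at ex-factory
  level, unitless in the model since no currency conversion is simulated);
* **exogenous** countries are referenced at a constant price and never
  simulated (Denmark, Sweden, UK at 100);
* **simulated** countries derive prices by EPR. Kick-off countries may
  also carry a rulebook: they are never re-derived at launch, but revise
  on their own schedule (Italy, every 24 months, in the base case).

Each month every simulated country is examined:

1. *Initial setting.* An unpriced country collects the first
   `active_count` pool members (in priority order) that have a price. If
   at least `min_required` are available, the benchmark formula is applied
   to the adjusted quotes and the price is set; the month is recorded as
   the country's `set_month`.
2. *Revision.* A priced country with revision interval $R$ re-derives the
   same benchmark at `set_month` $+ R, +2R, \dots$. If fewer than
   `min_required` references were available the revision would keep the
   old price (with monotone availability this cannot occur in a
   trajectory started from the initial state, but the contract is defined
   and unit-tested). Countries with no legislated revision never change
   after first setting.

All month-$t{+}1$ prices are computed from the month-$t$ state
(synchronous update). The model's published description does not fix a
within-month ordering; synchrony was chosen because it makes the result
independent of how the countries are enumerated, which is asserted by a
permutation test. Anchoring revision clocks at each country's own first
setting (rather than a global calendar) was likewise an open choice; it
matches the reading that prices are held constant until *that country's*
revision is due.

There is no inflation, deflation or exchange-rate movement, and no
stochastic element anywhere in the engine.

## Benchmark formulas

Five formulas cover the surveyed 2015 methodologies: the arithmetic
average; the minimum; the average of the $m$ lowest (Czech Republic,
Greece, Norway, Slovakia with $m = 3$); the $k$-th lowest; and the $k$-th
lowest capped by named countries — Latvia's benchmark is the third-lowest
basket price but may not exceed the price in Lithuania or Estonia, encoded
as `min(3rd lowest, p_LT, p_EE)` with an unavailable cap simply omitted.

Two degenerate situations are resolved explicitly (the published rules are
silent): with fewer than $m$ (or $k$) available quotes the formula uses
all available quotes (respectively the highest available rank), provided
`min_required` was met; and ties in the sorted quotes need no tie-break
because selection is by value. No rounding is applied anywhere in the
computation; reporting rounds to 0.1 percentage points at display time
only.

Croatia (3 of 5) and Cyprus (4 of 10) keep a priority-ordered pool of
alternates: per evaluation the first `active_count` available pool members
are used, so lower-priority countries substitute exactly when
higher-priority data are missing.

## Quote adjustments

Adjusted quotes are multiplicative and order-independent:

$$\tilde p_r = p_r \,(1 - s_r)\,(1 - c \cdot [r \in C])\,
  \frac{\pi_{own}}{\pi_r}$$

with $s_r$ the statutory rebate of the referenced country (0 where none),
$c$ the flat commercial discount applied to the set $C$ of large
economies, and $\pi$ a comparative price-level index. Each factor is
present only while its activation flag is on; the base case runs with all
flags off, matching the surveyed 2015 practice.

The PPP direction — reference prices converted *to the referencing
country's* price level — is a deliberate choice: it raises benchmarks in
high-price-level countries (Switzerland, Norway) and lowers them in
lower-income ones (Bulgaria, Romania, Hungary), the behaviour the
adjustment is meant to produce.

Defaults, all replaceable configuration inputs
(`inst/extdata/adjustment_defaults.yaml`):

| parameter | default | provenance |
|---|---|---|
| statutory rebate DE | 0.07 | §130a SGB V manufacturer rebate, 2015 |
| statutory rebate GR | 0.09 | EOPYY rebate, 2015 |
| statutory rebate IE | 0.0525 | IPHA framework agreement, 2015 |
| commercial discount | 0.20 on DE, FR, IT, NL, ES, UK | assumed flat confidential discount |
| PPP index | approximate 2015 comparative price levels, EU28 = 100 | reconstructed; only ratios matter |

The commercial set is described in the underlying survey material as
"five large economies" yet six countries are named; the default includes
all six named countries.

## The bundled base case and its reconstructed parts

The verifiable survey scalars — basket size, minimum-availability count
(Austria 14, Iceland/Hungary/Malta/Czech Republic/Greece 3, the
Netherlands/Croatia 2, most others 1), formula and revision interval —
are shipped in `epr_parameters_2015.csv` and asserted value-by-value in
the test suite. Basket *membership* was never published at this level;
`basket_membership_2015_reconstructed.yaml` is a documented approximation
(exact sizes, plausible members: e.g. Germany's statutory 15-country
basket, France referencing DE/ES/IT/UK, Spain the 18 other eurozone
members, Italy the Euripid group) and is overridable via
`builtin_base_case(membership = ...)`. Two sizes need a note: Hungary's
and Poland's published basket size of 31 counts the whole 28 EU + 3 EFTA
group *including the country itself*; since a country never references
itself, the effective pool holds the 30 other countries. Luxembourg's
single reference country is not named in the survey; the reconstruction
uses Germany (the typical first-launch market, guaranteeing Luxembourg a
price at month 1).

## Scenarios

`apply_scenario()` transforms the base case without mutating it;
`base_case` is the identity. The seven policy scenarios each change one
parameter for *all* simulated countries: `strategic_basket` (basket
becomes DE/IT/FI/PT minus the country itself — the four named countries
therefore keep 3-member baskets; `min_required` is clipped to the new pool
size, otherwise small baskets could never price), `large_basket` (all 30
other countries), `lowest_price` (every formula becomes the minimum),
`statutory_discounts`, `statutory_and_commercial_discounts`, `ppp`, and
`biannual_revisions` (interval 6 for every country, including former
no-revision countries such as Germany, Austria, Belgium and Hungary).

End-of-horizon comparison: for each simulated country priced at month 120
in both runs, the relative change (scenario − base)/base; negative means
cheaper than the base case. Cross-country summaries are unweighted
arithmetic means and five-number summaries (quartiles by linear
interpolation between closest ranks, R's default type 7); exogenous
countries are excluded, as are countries unpriced in either run (none, in
the bundled scenarios).

## The synthetic-system generator

`generate_system()` draws random EPR networks from a `system_recipe()`:
the seed is the only source of randomness in the package, and identical
recipes yield identical systems. Defaults bracket the observed 2015
regime: basket sizes 1–4 by default (configurable up to the full network),
revision mix over none/6/12/24/36/60 months, a rule mix dominated by
average and minimum, kick-off fraction 0.25 with launch prices in
50–150. Two deliberate simplifications keep generated systems inside the
regime where the engine's provable properties hold: generated kick-off
countries are constant sources (no revision clocks), and `active_count`
always equals the pool size (the k-out-of-pool fallback structure is
specific to Croatia and Cyprus; under priority truncation the all-minimum
monotonicity argument below fails, so it is exercised through the bundled
base case and targeted unit tests instead).

The generator emulates network *mechanics* — baskets, rules, revision
clocks, availability gating — not realistic price levels or country
economics. Passing property tests on generated systems therefore
demonstrates the engine's correctness and invariances, not policy
conclusions about real countries.

Properties asserted over generated systems (fixed seeds, acceptance
suite): benchmark ordering (minimum ≤ average-of-m-lowest ≤ average;
k-th lowest non-decreasing in k) over 1000 random multisets; on
all-minimum systems every price series is non-increasing once set (with
constant kick-off prices, a price revision takes a minimum over a superset
of earlier, element-wise-lower prices — an induction the tests check on
200 systems); activating discounts can only lower every priced entry
month-wise (30 systems); country-order invariance; equality with an
independently written naive simulator that re-derives every due event from
scratch each month (100 systems); and positive homogeneity — scaling all
launch prices by λ scales whole trajectories by λ to machine precision.
Problem sizes (systems of 4–10 countries over 36–48 months; the full
31-country batch over 120 months elsewhere) were chosen as the smallest
scales at which every mechanism — availability gating, revisions, k-out-of-
pool, caps — is actually exercised; the whole suite runs in well under a
minute.

## Numerical behaviour and limitations

Without discounts or PPP, every derived price is a minimum or average of
existing prices, so no price can ever fall below the lowest launch price
(70): trajectories of the undiscounted scenarios live in [70, 100], and
the `lowest_price` scenario is bounded below by (70 − base)/base per
country. Discount scenarios have no such floor: a referencing loop that
passes a discounted country contracts geometrically at each revision
cycle, which is why the discount scenarios produce by far the deepest
reductions and why countries inside such loops (minimum-rule countries
referencing Greece, with its 3-month revisions) fall furthest.

Results for the real 2015 network depend on the reconstructed inputs —
basket membership above all, statutory rates and PPP indices next. The
direction of each scenario's effect is robust to those choices; the
magnitudes, and the relative depth of the statutory-only versus
lowest-price scenarios, are not. Anyone with authoritative 2015 baskets
should substitute them via `builtin_base_case(membership = ...)` and
re-run `scripts/acceptance.R`.

Out of scope by design: volume weighting of reference prices (no
consumption data), expenditure and budget-impact modelling, launch-delay
spill-overs, currency handling, and ingestion of real price databases.
Medicine prices are the sole outcome indicator.
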