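test_that("benchmark formulas match hand-computed values", {
  expect_equal(compute_benchmark(benchmark_rule("average"), c(100, 70)), 85)
  expect_equal(compute_benchmark(benchmark_rule("minimum"), 70), 70)
  expect_equal(
    compute_benchmark(benchmark_rule("avg_lowest", m = 3),
                      c(100, 90, 80, 70)),
    80)  # mean of 70, 80, 90

  # Latvia-style rule: 3rd lowest of the basket is 30, capped by LT at 25
  expect_equal(
    compute_benchmark(benchmark_rule("kth_lowest_capped", k = 3,
                                     caps = c("LT", "EE")),
                      c(10, 20, 30, 40, 50, 60, 70),
                      cap_prices = c(LT = 25, EE = 40)),
    25)
  # cap whose price is unavailable is omitted
  expect_equal(
    compute_benchmark(benchmark_rule("kth_lowest_capped", k = 3,
                                     caps = c("LT", "EE")),
                      c(10, 20, 30), cap_prices = c(EE = 40)),
    30)
})

test_that("rank-based rules degrade gracefully with few quotes", {
  expect_equal(compute_benchmark(benchmark_rule("avg_lowest", m = 3),
                                 c(90, 70)), 80)
  expect_equal(compute_benchmark(benchmark_rule("kth_lowest", k = 3),
                                 c(90, 70)), 90)
  expect_error(compute_benchmark(benchmark_rule("average"), numeric(0)),
               "at least one")
})

test_that("rule constructors reject malformed parameters", {
  expect_error(benchmark_rule("avg_lowest"), "m >= 1")
  expect_error(benchmark_rule("kth_lowest", k = 0), "k >= 1")
  expect_error(benchmark_rule("kth_lowest_capped", k = 2), "caps")
})

test_that("adjustments are multiplicative and order-independent", {
  none <- adjustment_policy()
  expect_equal(adjust_reference_price(100, "DE", "AT", none), 100)

  comm <- adjustment_policy(commercial_rate = 0.20,
                            commercial_countries = c("DE", "FR"),
                            active = c(commercial = TRUE))
  expect_equal(adjust_reference_price(100, "DE", "AT", comm), 80)
  expect_equal(adjust_reference_price(100, "BG", "AT", comm), 100)

  ppp <- adjustment_policy(ppp_index = c(AT = 0.8, DE = 1.0),
                           active = c(ppp = TRUE))
  expect_equal(adjust_reference_price(100, "DE", "AT", ppp), 80)
  expect_error(adjust_reference_price(100, "FR", "AT", ppp), "no index")

  all3 <- adjustment_policy(statutory_rates = c(DE = 0.07),
                            commercial_rate = 0.20,
                            commercial_countries = "DE",
                            ppp_index = c(AT = 0.8, DE = 1.0),
                            active = c(statutory = TRUE, commercial = TRUE,
                                       ppp = TRUE))
  expect_equal(adjust_reference_price(100, "DE", "AT", all3),
               100 * 0.93 * 0.80 * 0.8)
  # a country with no statutory rate simply carries none
  stat <- adjustment_policy(statutory_rates = c(DE = 0.07),
                            active = c(statutory = TRUE))
  expect_equal(adjust_reference_price(100, "FR", "AT", stat), 100)
})

test_that("rule ordering, bounds, homogeneity and discount dominance hold", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(1:10, 1)
    q <- runif(n, 10, 200)
    mn <- compute_benchmark(benchmark_rule("minimum"), q)
    av <- compute_benchmark(benchmark_rule("average"), q)
    m <- sample(1:5, 1)
    am <- compute_benchmark(benchmark_rule("avg_lowest", m = m), q)
    expect_true(mn <= am + 1e-12 && am <= av + 1e-12)

    kth <- vapply(1:6, function(k)
      compute_benchmark(benchmark_rule("kth_lowest", k = k), q), numeric(1))
    expect_true(all(diff(kth) >= -1e-12))  # non-decreasing in k

    # all rules inside [min, max] of the quotes
    expect_true(all(c(mn, av, am, kth) >= min(q) - 1e-12))
    expect_true(all(c(mn, av, am, kth) <= max(q) + 1e-12))

    # positive homogeneity
    lam <- runif(1, 0.1, 5)
    expect_equal(compute_benchmark(benchmark_rule("avg_lowest", m = m),
                                   lam * q), lam * am, tolerance = 1e-12)

    # capping can only lower the result
    caps <- c(X = runif(1, 10, 200))
    capped <- compute_benchmark(
      benchmark_rule("kth_lowest_capped", k = 2, caps = "X"), q, caps)
    uncapped <- compute_benchmark(benchmark_rule("kth_lowest", k = 2), q)
    expect_true(capped <= uncapped + 1e-12)
  }

  # all quotes equal p and caps >= p: every rule returns p
  p <- 83.5
  q <- rep(p, 5)
  for (rule in list(benchmark_rule("average"), benchmark_rule("minimum"),
                    benchmark_rule("avg_lowest", m = 3),
                    benchmark_rule("kth_lowest", k = 2),
                    benchmark_rule("kth_lowest_capped", k = 2, caps = "X")))
    expect_equal(compute_benchmark(rule, q, c(X = p + 1)), p)

  # with only discounts active, adjusted <= raw for every quote
  pol <- adjustment_policy(statutory_rates = c(DE = 0.07, GR = 0.09),
                           commercial_rate = 0.2,
                           commercial_countries = c("DE", "FR"),
                           active = c(statutory = TRUE, commercial = TRUE))
  for (ref in c("DE", "GR", "FR", "BG"))
    expect_lte(adjust_reference_price(100, ref, "AT", pol), 100)
})
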