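test_that("initialization seeds kick-off and exogenous prices only", {
  base <- builtin_base_case()
  st <- initialize_state(base)
  expect_equal(st$month, 0L)
  expect_equal(st$prices[["DE"]], 100)
  expect_equal(st$prices[["IT"]], 70)
  expect_equal(unname(st$prices[c("DK", "SE", "UK")]), c(100, 100, 100))
  expect_equal(sum(is.na(st$prices)), 26)  # 28 simulated minus DE, IT
  expect_equal(st$set_month[["DE"]], 0L)
  expect_true(is.na(st$set_month[["AT"]]))

  only_exo <- simulation_config(
    countries = list(country_epr_config("XX", pool = "DK",
                                        rule = benchmark_rule("average"))),
    exogenous = c(DK = 100))
  st2 <- initialize_state(only_exo)
  expect_equal(st2$prices[!is.na(st2$prices)], c(DK = 100))

  no_exo <- two_kickoff_config(
    country_epr_config("XX", pool = c("DE", "IT"),
                       rule = benchmark_rule("average")))
  st3 <- initialize_state(no_exo)
  expect_equal(sort(names(st3$prices[!is.na(st3$prices)])), c("DE", "IT"))
})

test_that("initial price setting is gated by minimum availability", {
  cfg <- two_kickoff_config(
    country_epr_config("XX", pool = c("DE", "IT"),
                       rule = benchmark_rule("average"), min_required = 2),
    country_epr_config("YY", pool = c("DE", "IT", "XX"),
                       rule = benchmark_rule("average"), min_required = 3))
  st1 <- step_month(initialize_state(cfg), cfg)
  expect_equal(st1$prices[["XX"]], 85)  # mean(100, 70)
  expect_true(is.na(st1$prices[["YY"]]))  # XX not yet priced at month 0
  expect_equal(st1$set_month[["XX"]], 1L)
  st2 <- step_month(st1, cfg)
  expect_equal(st2$prices[["YY"]], mean(c(100, 70, 85)))
  expect_equal(st2$set_month[["YY"]], 2L)
})

test_that("the hand-traced three-country cascade is reproduced exactly", {
  fix <- fixture_cascade()
  traj <- run_simulation(fix$config)
  expect_equal(traj_matrix(traj, rownames(fix$trajectory)), fix$trajectory)

  # singleton reference: switching B to an average rule changes nothing
  alt <- fix$config
  alt$countries$B$rule <- benchmark_rule("average")
  expect_equal(traj_matrix(run_simulation(alt),
                           rownames(fix$trajectory)), fix$trajectory)

  # horizon 0: only the kick-off country is priced
  t0 <- run_simulation(fix$config, horizon = 0)
  expect_equal(ncol(t0), 1)
  col0 <- t0[, 1]
  expect_equal(col0[!is.na(col0)], c(A = 100))
})

test_that("revisions fire on the country's own clock and only then", {
  # B launches at 60 and revises to the average of A (=100) at month 12
  cfg <- simulation_config(
    countries = list(
      country_epr_config("B", pool = "A", rule = benchmark_rule("average"),
                         revision_interval = 12L)),
    kickoff = c(A = 100, B = 60), horizon = 30L)
  traj <- run_simulation(cfg)
  expect_equal(unname(traj["B", as.character(0:11)]), rep(60, 12))
  expect_equal(unname(traj["B", as.character(12:30)]), rep(100, 19))

  # no-revision country never changes after first setting
  cfg2 <- simulation_config(
    countries = list(
      country_epr_config("B", pool = "A", rule = benchmark_rule("average")),
      country_epr_config("A", pool = "B", rule = benchmark_rule("average"),
                         revision_interval = 6L)),
    kickoff = c(A = 100, B = 60), horizon = 20L)
  traj2 <- run_simulation(cfg2)
  expect_equal(unname(traj2["B", ]), rep(60, 21))
  # A revises to B's price at months 6, 12, 18
  expect_equal(unname(traj2["A", as.character(0:5)]), rep(100, 6))
  expect_equal(unname(traj2["A", as.character(6:20)]), rep(60, 15))
})

test_that("a revision with insufficient references keeps the old price", {
  cfg <- simulation_config(
    countries = list(
      country_epr_config("X", pool = "Y", rule = benchmark_rule("average"),
                         revision_interval = 3L)),
    kickoff = c(A = 100, Y = 50), horizon = 6L)
  # hand-built state: X priced at 80 since month 0, Y's price missing
  st <- structure(list(
    month = 2L,
    prices = c(X = 80, Y = NA_real_, A = 100),
    set_month = c(X = 0L, Y = NA_integer_, A = 0L)
  ), class = "price_state")
  st3 <- step_month(st, cfg)
  expect_equal(st3$prices[["X"]], 80)  # revision due but skipped
})

test_that("updates are synchronous: no within-month cascades, any order", {
  base <- builtin_base_case()
  traj <- run_simulation(base)
  perm <- base
  set.seed(7)
  perm$countries <- perm$countries[sample(names(perm$countries))]
  traj_perm <- run_simulation(perm)
  expect_equal(traj_matrix(traj_perm, rownames(traj)), traj_matrix(traj))

  # Germany: kick-off plus no revision = constant 100 for all 121 columns
  expect_equal(unname(traj["DE", ]), rep(100, 121))
  expect_equal(ncol(traj), 121)
})

test_that("availability is monotone and set prices never unset", {
  set.seed(11)
  for (seed in 1:20) {
    cfg <- generate_system(system_recipe(seed = seed,
                                         n_countries = sample(4:9, 1),
                                         horizon = 36L))
    traj <- run_simulation(cfg)
    set_pattern <- !is.na(traj)
    expect_true(all(set_pattern[, -1] >= set_pattern[, -ncol(traj)]))
  }
})

test_that("scaling all launch prices scales the whole trajectory", {
  base <- builtin_base_case(horizon = 60L)
  traj <- run_simulation(base)
  lam <- 3.7
  scaled <- base
  scaled$kickoff <- lam * scaled$kickoff
  scaled$exogenous <- lam * scaled$exogenous
  expect_equal(traj_matrix(run_simulation(scaled)), lam * traj_matrix(traj),
               tolerance = 1e-12)
})

test_that("trajectories export to long format with empty unset prices", {
  fix <- fixture_cascade(horizon = 3)
  traj <- run_simulation(fix$config)
  df <- as.data.frame(traj)
  expect_equal(nrow(df), 3 * 4)
  expect_equal(df$is_set, !is.na(df$price))

  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(list(fixture = traj), path)
  back <- read.csv(path)
  expect_equal(nrow(back), 12)
  expect_equal(unique(back$scenario), "fixture")
  expect_true(is.na(back$price[back$country == "C" & back$month == 0]))
})
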