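test_that("awareness budget reproduces the itemised arithmetic", {
  b <- awareness_budget()
  items <- awareness_cost_items()
  expect_equal(b$broadcast, sum(items$amount))
  sms <- sms_campaign()
  expect_equal(b$sms,
               round(sms$unit_cost * sms$population_reached *
                       sms$messages_per_month * sms$months, 2))
  expect_equal(b$sms, 6888324.57)
  expect_equal(b$per_capita, 0.28)
  empty <- awareness_budget(items = NULL, sms = NULL, population = 100)
  expect_equal(empty$total, 0)
  expect_equal(empty$per_capita, 0)
  expect_error(awareness_budget(population = 0), "positive")
})

test_that("DALY conversion is the published linear factor", {
  expect_equal(deaths_to_daly(0), 0)
  expect_equal(deaths_to_daly(5857), 137112.37)
  expect_equal(deaths_to_daly(117), 2739, tolerance = 1e-3)
  a <- runif(1, 0, 100); b <- runif(1, 0, 100)
  expect_equal(deaths_to_daly(a + b), deaths_to_daly(a) + deaths_to_daly(b))
  expect_error(deaths_to_daly(-1), "nonnegative")
})

test_that("the sequential ICER walk reproduces the published dominance analysis", {
  res <- icer_analysis(table9_outcomes)
  first <- res$steps[[1]]
  expect_equal(round(first$icer, 1), c(1103.2, 2244.5, 1480.4))
  expect_equal(res$dominated, "B")
  expect_equal(round(res$final$icer, 2), c(1103.21, 620.07))
  expect_equal(res$recommended, "C")
  expect_equal(res$classification, "highly cost-effective")
  # DALY-scaled effects give the published cost-per-DALY walk
  daly <- table9_outcomes
  daly$effect <- deaths_to_daly(daly$effect)
  res_daly <- icer_analysis(daly)
  expect_equal(round(res_daly$steps[[1]]$icer, 2), c(47.13, 95.88, 63.24))
  expect_equal(res_daly$dominated, "B")
  expect_equal(round(res_daly$final$icer, 2), c(47.13, 26.49))
  expect_equal(res_daly$recommended, "C")
})

test_that("effect ties are broken towards the cheaper strategy", {
  tied <- data.frame(strategy = c("X", "Y", "Z"),
                     effect = c(10, 10, 20),
                     cost = c(100, 80, 300))
  expect_message(res <- icer_analysis(tied), "tied")
  expect_false("X" %in% res$final$strategy)
})

test_that("the frontier matches a brute-force convex-hull oracle", {
  set.seed(20)
  for (rep in 1:50) {
    n <- sample(2:6, 1)
    out <- data.frame(strategy = letters[1:n],
                      effect = round(runif(n, 1, 100), 2),
                      cost = round(runif(n, 10, 1e4), 2))
    out <- out[!duplicated(out$effect), , drop = FALSE]
    if (nrow(out) < 2) next
    fr <- ce_frontier(out)
    # brute-force oracle: a strategy is on the frontier iff no convex
    # combination of the others (plus do-nothing) weakly dominates it
    on_frontier <- vapply(seq_len(nrow(out)), function(i) {
      e <- out$effect[i]; cst <- out$cost[i]
      others <- rbind(c(0, 0), cbind(out$effect, out$cost)[-i, , drop = FALSE])
      for (a in seq_len(nrow(others))) for (b in seq_len(nrow(others))) {
        ea <- others[a, 1]; eb <- others[b, 1]
        if (ea > e || eb < e || ea == eb) next
        lamb <- (e - ea) / (eb - ea)
        mix_cost <- (1 - lamb) * others[a, 2] + lamb * others[b, 2]
        if (mix_cost < cst - 1e-9) return(FALSE)
      }
      TRUE
    }, logical(1))
    expect_setequal(fr$strategy, out$strategy[on_frontier])
    expect_true(all(diff(fr$icer) >= -1e-9))
  }
})

test_that("GDP threshold classification assigns the stated bands", {
  cfg <- cea_config()
  expect_equal(gdp_classify(620.07, cfg), "highly cost-effective")
  expect_equal(gdp_classify(cfg$gdp_per_capita, cfg), "cost-effective")
  expect_equal(gdp_classify(3 * cfg$gdp_per_capita, cfg),
               "not cost-effective")
  expect_error(gdp_classify(-1, cfg), "nonnegative")
})

test_that("scaling ICERs to the observed toll reproduces the budget figures", {
  expect_equal(scale_cost_to_observed(620.07, 117), 72548)
  expect_equal(scale_cost_to_observed(1103.2, 117), 129074)
  expect_equal(scale_cost_to_observed(2244.5, 117), 262607)
  expect_equal(scale_cost_to_observed(0, 1e6), 0)
})

test_that("discounted cost integrates the published integrand", {
  p <- sbe_parameters()
  times <- seq(0, 12, by = 0.1)
  n <- length(times)
  states <- matrix(0, n, 11)
  sol <- list(times = times, states = states,
              u1 = numeric(n), u2 = numeric(n))
  expect_equal(discounted_control_cost(sol, cea_config(), p), 0)
  # undiscounted constant integrand: C1 * eps * S_U per unit time
  states2 <- states; states2[, 1] <- 1e6
  sol2 <- list(times = times, states = states2, u1 = rep(1, n),
               u2 = numeric(n))
  cfg0 <- cea_config(discount_rate = 0)
  expect_equal(discounted_control_cost(sol2, cfg0, p),
               cfg0$c1 * p$epsilon * 1e6 * 12)
  # discounting monotonicity in r
  states3 <- states2; states3[, 4] <- 5e3; states3[, 6] <- 1e3
  sol3 <- list(times = times, states = states3, u1 = rep(1, n),
               u2 = rep(0.5, n))
  costs <- vapply(c(0, 0.03, 0.05, 0.10, 0.25), function(r)
    discounted_control_cost(sol3, cea_config(discount_rate = r), p),
    numeric(1))
  expect_true(all(diff(costs) < 0))
  bad <- sol3; bad$u1 <- bad$u1[-1]
  expect_error(discounted_control_cost(bad, cea_config(), p), "mismatch")
})
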