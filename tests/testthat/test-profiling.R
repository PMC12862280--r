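test_that("RUCA classes split exactly at the 3/7 boundaries", {
  expect_equal(as.character(ruca_class(c(1, 3, 4, 7, 8, 10))),
               c("urban", "urban", "suburban", "suburban", "rural", "rural"))
  expect_error(ruca_class(0), "1..10")
  expect_error(ruca_class(11), "1..10")
  expect_error(ruca_class(2.5), "1..10")
})

test_that("RUCA cross-tab percentages are 100 * count / cluster size", {
  # reference profile: 140-tract cluster split 36/23/81
  labels <- rep(c("HH", "NS"), c(140, 10))
  ruca <- c(rep(9, 36), rep(5, 23), rep(2, 81), rep(2, 10))
  ct <- crosstab_ruca(labels, ruca, "HH")
  expect_equal(unname(ct$counts), c(36, 23, 81))
  expect_equal(ct$percentages[["rural"]], 100 * 36 / 140, tolerance = 1e-12)
  expect_equal(round(ct$percentages[["rural"]], 1), 25.7)
  expect_equal(round(ct$percentages[["suburban"]], 1), 16.4)
  # a 283-tract cluster split 1/5/277
  labels2 <- rep("LL", 283)
  ruca2 <- c(9, rep(5, 5), rep(1, 277))
  ct2 <- crosstab_ruca(labels2, ruca2, "LL")
  expect_equal(ct2$percentages[["urban"]], 100 * 277 / 283)
  # single-tract rural cluster
  ct3 <- crosstab_ruca(c("HL", "NS"), c(10, 1), "HL")
  expect_equal(unname(ct3$percentages), c(100, 0, 0))
  # empty cluster: zero counts, missing percentages
  ct4 <- crosstab_ruca(c("NS", "NS"), c(1, 9), "LH")
  expect_equal(unname(ct4$counts), c(0, 0, 0))
  expect_true(all(is.na(ct4$percentages)))
})

test_that("cluster population summary uses ratio-of-sums density", {
  tracts <- data.frame(pop_total = c(100, 300, 50),
                       area_sqmi = c(1, 1, 5))
  s <- cluster_population_summary(c("HH", "HH", "NS"), tracts, "HH")
  expect_equal(s$tracts, 2L)
  expect_equal(s$population, 400)
  expect_equal(s$density, 200)
  # empty cluster
  e <- cluster_population_summary(c("NS", "NS", "NS"), tracts, "LL")
  expect_equal(e$tracts, 0L)
  expect_equal(e$population, 0)
  expect_true(is.na(e$density))
  # conservation when everything is one cluster
  a <- cluster_population_summary(rep("HH", 3), tracts, "HH")
  expect_equal(a$population, sum(tracts$pop_total))
})

test_that("label counts over all quadrant types sum to n", {
  fx <- small_tract_data()
  fit <- lisa(p_flood_high ~ ice_income, data = fx$tab,
              weights = fx$td$weights, permutations = 199, seed = 4)
  prof <- cluster_profile(fit, fx$tab)
  expect_equal(sum(prof$membership$tracts), fit$n)
  expect_true(all(prof$membership$cluster_type ==
                    c("HH", "LL", "LH", "HL", "NS", "ISLAND")))
  # RUCA percentages per non-empty cluster sum to 100
  r <- prof$ruca
  tot <- r$rural_pct + r$suburban_pct + r$urban_pct
  expect_true(all(is.na(tot) | abs(tot - 100) < 1e-9))
})

test_that("demographic comparison deltas and Welch tests behave", {
  set.seed(6)
  n <- 60
  tracts <- data.frame(
    pop_total = rep(1000, n), area_sqmi = rep(1, n),
    inc = c(rnorm(20, 40), rnorm(40, 60)),
    flat = rep(5, n),
    sep = rep(c(1, 0), c(20, 40)))
  labels <- rep(c("HH", "NS"), c(20, 40))
  cmp <- demographic_comparison(labels, tracts, "HH",
                                c("inc", "flat", "sep"))
  # delta is cluster mean minus the all-tract mean
  expect_equal(cmp$delta, cmp$cluster_mean - cmp$state_mean)
  expect_lt(cmp$delta[cmp$indicator == "inc"], 0)
  expect_true(cmp$significant[cmp$indicator == "inc"])
  expect_equal(cmp$stars[cmp$indicator == "inc"], "***")
  # constant everywhere: no test
  expect_true(is.na(cmp$t[cmp$indicator == "flat"]))
  # two distinct constants: infinite separation, p at the numerical floor
  row <- cmp[cmp$indicator == "sep", ]
  expect_true(is.infinite(row$t))
  expect_lte(row$p, .Machine$double.eps)
  # identical means give delta exactly zero
  tracts$same <- rep(3.5, n) + c(rep(0, 20), rep(0, 40))
  tracts$same[1:20] <- mean(tracts$same)  # cluster mean == state mean
  cmp2 <- demographic_comparison(labels, tracts, "HH", "same")
  expect_equal(cmp2$delta, 0)
})

test_that("one-sample mode tests against the fixed state mean", {
  set.seed(9)
  tracts <- data.frame(pop_total = rep(1, 30), area_sqmi = rep(1, 30),
                       v = c(rnorm(10, 10), rnorm(20, 0)))
  labels <- rep(c("HH", "NS"), c(10, 20))
  cmp <- demographic_comparison(labels, tracts, "HH", "v", mode = "one.sample")
  expect_true(cmp$p < 0.01)
  expect_equal(cmp$delta, cmp$cluster_mean - mean(tracts$v))
})
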