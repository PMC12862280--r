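test_that("ICE hits its extremes and center exactly", {
  # every resident in the deprived extreme -> -1
  expect_equal(ice(privileged = 0, deprived = 100, total = 100), -1)
  # every resident in the privileged extreme -> +1
  expect_equal(ice(privileged = 100, deprived = 0, total = 100), 1)
  # balanced extremes -> 0
  expect_equal(ice(privileged = 40, deprived = 40, total = 200), 0)
})

test_that("ICE is antisymmetric in the two groups and bounded", {
  set.seed(31)
  for (i in 1:20) {
    t <- sample(50:500, 1)
    a <- sample.int(t, 1); p <- sample.int(t - a + 1, 1) - 1L
    expect_equal(ice(p, a, t), -ice(a, p, t))
    expect_true(abs(ice(p, a, t)) <= 1)
  }
})

test_that("ICE flags zero denominators and impossible counts", {
  expect_warning(v <- ice(c(10, 0), c(5, 0), c(100, 0)), "zero denominator")
  expect_true(is.na(v[2]) && !is.na(v[1]))
  expect_error(ice(80, 30, 100), "exceed")
  expect_error(ice(-1, 0, 10), "non-negative")
})

test_that("inversion negates once and refuses a second time", {
  iv <- index_vector(c(-1, 0, 0.5), "ice_race")
  inv <- invert(iv)
  expect_equal(as.numeric(inv), c(1, 0, -0.5))
  expect_true(attr(inv, "inverted"))
  expect_error(invert(inv), "already inverted")
})

test_that("flood-risk proportions respect the category boundaries and sum to 1", {
  expect_equal(flood_risk_proportions(c(1, 5, 9)),
               c(low = 1 / 3, moderate = 1 / 3, high = 1 / 3))
  expect_equal(flood_risk_proportions(rep(10, 4)),
               c(low = 0, moderate = 0, high = 1))
  # 2 is low, 3 and 6 moderate, 7 high
  expect_equal(flood_risk_proportions(c(2, 3, 6, 7)),
               c(low = 0.25, moderate = 0.5, high = 0.25))
  set.seed(8)
  for (i in 1:10)
    expect_equal(sum(flood_risk_proportions(sample(1:10, 30, TRUE))), 1)
  expect_error(flood_risk_proportions(integer(0)), "zero properties")
  expect_error(flood_risk_proportions(c(1, 11)), "1..10")
})

test_that("per-level FF proportions count exact matches only", {
  expect_equal(flood_level_proportion(c(7, 7, 8, 10), 7), 0.5)
  expect_equal(flood_level_proportion(c(1, 2, 3), 9), 0)
  expect_equal(flood_level_proportion(c(9, 9, 9), 9), 1)
  expect_error(flood_level_proportion(c(7, 8), 5), "7, 8, 9, 10")
})

test_that("grouped Gini matches hand-computed cases", {
  br2 <- list(c(0, 2), c(2, 4))
  # single occupied bracket: perfect equality under the midpoint convention
  expect_equal(gini_grouped(c(10, 0), br2), 0)
  # two equal groups at midpoints m and 3m -> 0.25
  expect_equal(gini_grouped(c(5, 5), br2), 0.25)
  # classic two-point case {0, x}: G = 1/2
  br0x <- list(c(0, 1e-9), c(7, 9))
  expect_equal(gini_grouped(c(1, 1), br0x), 0.5, tolerance = 1e-6)
})

test_that("Gini is scale-invariant and bounded by (N-1)/N", {
  set.seed(12)
  br <- default_brackets <- list(c(0, 25000), c(25000, 50000), c(50000, 75000),
                                 c(75000, 125000), c(125000, Inf))
  for (i in 1:10) {
    cts <- rpois(5, 40)
    cts[1] <- cts[1] + 1  # ensure positive
    g1 <- gini_grouped(cts, br)
    br_scaled <- lapply(br, function(b) 3.7 * b)
    expect_equal(gini_grouped(cts, br_scaled), g1)
    expect_lt(g1, (sum(cts) - 1) / sum(cts))
  }
  expect_error(gini_grouped(c(0, 0), list(c(0, 1), c(1, 2))), "zero")
})

test_that("dissimilarity index matches its definition and invariances", {
  expect_equal(dissimilarity_index(c(10, 20, 30), c(5, 10, 15)), 0)
  expect_equal(dissimilarity_index(c(50, 0), c(0, 80)), 1)
  expect_equal(dissimilarity_index(c(30, 10), c(10, 30)), 0.5)
  # relabeling subunits and scaling one group's counts change nothing
  b <- c(12, 7, 31, 2); w <- c(5, 9, 14, 22)
  d <- dissimilarity_index(b, w)
  o <- c(3, 1, 4, 2)
  expect_equal(dissimilarity_index(b[o], w[o]), d)
  expect_equal(dissimilarity_index(b, 10 * w), d)
  expect_error(dissimilarity_index(c(1, 2), c(0, 0)), "positive total")
  expect_error(dissimilarity_index(c(1), c(2)), "2 subunits")
})

test_that("regional dissimilarity assigns each tract its region's D", {
  b <- c(30, 10, 1, 1); w <- c(10, 30, 1, 1)
  region <- c("A", "A", "B", "B")
  d <- dissimilarity_by_region(b, w, region)
  expect_equal(d, c(0.5, 0.5, 0, 0))
})

test_that("compute_indices assembles all analysis variables with correct orientation", {
  fx <- small_tract_data()
  tab <- fx$tab
  expect_true(all(c("ice_income", "ice_race", "ice_race_income",
                    "p_flood_low", "p_flood_moderate", "p_flood_high",
                    "p_ff7", "p_ff8", "p_ff9", "p_ff10", "gini", "iod")
                  %in% names(tab)))
  expect_true(all(abs(tab$ice_income) <= 1))
  expect_equal(tab$p_flood_low + tab$p_flood_moderate + tab$p_flood_high,
               rep(1, nrow(tab)))
  expect_true(all(tab$gini >= 0 & tab$gini < 1))
  expect_true(all(tab$iod >= 0 & tab$iod <= 1, na.rm = TRUE))
  # inverted orientation: more low-income households => *higher* ice_income
  hi <- which.max(tab$hh_low_income / tab$hh_total)
  lo <- which.min(tab$hh_low_income / tab$hh_total)
  expect_gt(tab$ice_income[hi], tab$ice_income[lo])
})
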