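test_that("identical configs give bit-identical tract tables", {
  a <- synthesize_tracts(small_config(seed = 5))
  b <- synthesize_tracts(small_config(seed = 5))
  expect_identical(a$tracts, b$tracts)
  expect_identical(a$properties, b$properties)
  c <- synthesize_tracts(small_config(seed = 6))
  expect_false(identical(a$tracts, c$tracts))
})

test_that("counts are consistent non-negative integers with A + P <= T", {
  tt <- small_tract_data()$td$tracts
  for (col in c("pop_total", "hh_total", "pop_nonwhite", "pop_white",
                "hh_low_income", "hh_high_income",
                "pop_nonwhite_low_income", "pop_white_high_income")) {
    expect_true(all(tt[[col]] >= 0), label = col)
    expect_true(all(tt[[col]] == round(tt[[col]])), label = col)
  }
  expect_true(all(tt$hh_low_income + tt$hh_high_income <= tt$hh_total))
  expect_true(all(tt$pop_nonwhite + tt$pop_white <= tt$pop_total))
  expect_true(all(tt$pop_nonwhite_low_income + tt$pop_white_high_income <=
                    tt$pop_total))
  expect_true(all(tt$pop_nonwhite_low_income <= tt$pop_nonwhite))
  expect_true(all(tt$pop_white_high_income <= tt$pop_white))
  # bracket counts reconstruct the household total
  bcols <- grep("^hh_inc_b", names(tt), value = TRUE)
  expect_equal(rowSums(tt[, bcols]), tt$hh_total, ignore_attr = TRUE)
})

test_that("every FloodFactor level occurs at background settings and scores stay in 1..10", {
  cfg <- sim_config(n_rows = 8, n_cols = 8, rho = 0.4, planted_blocks = list(),
                    n_properties_per_tract = 40, seed = 21)
  td <- synthesize_tracts(cfg)
  expect_true(all(td$properties$ff %in% 1:10))
  expect_setequal(sort(unique(td$properties$ff)), 1:10)
})

test_that("planted blocks raise the high-risk share, monotonically in effect size", {
  p_high_block <- function(effect, seed) {
    cfg <- sim_config(n_rows = 8, n_cols = 8, rho = 0.3,
                      planted_blocks = list(planted_block(c(2, 4), c(2, 4),
                                                          flood = effect,
                                                          inequality = 1)),
                      n_properties_per_tract = 20, seed = seed)
    td <- synthesize_tracts(cfg)
    tab <- compute_indices(td)
    c(inside = mean(tab$p_flood_high[tab$in_planted_block]),
      outside = mean(tab$p_flood_high[!tab$in_planted_block]))
  }
  seeds <- 1:50
  at1 <- vapply(seeds, function(s) p_high_block(1, s), numeric(2))
  at2 <- vapply(seeds, function(s) p_high_block(2.5, s), numeric(2))
  # block tracts exceed background at the default-scale effect
  expect_gt(mean(at2["inside", ]), mean(at2["outside", ]))
  # expectation increases strictly with the planted effect
  expect_gt(mean(at2["inside", ]), mean(at1["inside", ]))
})

test_that("no planted structure and rho = 0 leaves fields at the Moran null", {
  n_seeds <- 100
  vals <- matrix(NA_real_, n_seeds, 3)
  geom <- make_lattice(7, 7)
  w <- queen_weights(geom)
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_rows = 7, n_cols = 7, rho = 0, planted_blocks = list(),
                      n_properties_per_tract = 10, seed = 3000 + s)
    tab <- compute_indices(synthesize_tracts(cfg))
    vals[s, ] <- c(
      global_moran(standardize(tab$ice_income), w),
      global_moran(standardize(tab$p_flood_high), w),
      global_moran(standardize(tab$prev_asthma), w))
  }
  null_mean <- -1 / (49 - 1)
  for (j in 1:3) {
    se <- sd(vals[, j]) / sqrt(n_seeds)
    expect_lt(abs(mean(vals[, j]) - null_mean), 4 * se)
  }
})

test_that("out-of-range planted effects are clipped with a warning", {
  cfg <- sim_config(n_rows = 6, n_cols = 6,
                    planted_blocks = list(planted_block(c(2, 4), c(2, 4),
                                                        flood = 50,
                                                        inequality = 0)),
                    seed = 9)
  expect_warning(synthesize_tracts(cfg), "clipped")
})

test_that("RUCA codes form concentric urban-to-rural rings and cover all classes", {
  td <- synthesize_tracts(sim_config(n_rows = 12, n_cols = 12, seed = 2,
                                     planted_blocks = list()))
  tt <- td$tracts
  expect_true(all(tt$ruca %in% 1:10))
  cls <- ruca_class(tt$ruca)
  expect_setequal(levels(droplevels(cls)), c("urban", "suburban", "rural"))
  # the lattice center is urban, the far corner rural
  center <- which(tt$row == 6 & tt$col == 6)
  expect_equal(as.character(cls[center]), "urban")
  expect_equal(as.character(cls[tt$row == 1 & tt$col == 1]), "rural")
  # density gradient: urban tracts are more populous than rural ones
  expect_gt(mean(tt$pop_total[cls == "urban"]),
            mean(tt$pop_total[cls == "rural"]))
})

test_that("config validation rejects malformed setups", {
  expect_error(sim_config(n_rows = 5, n_cols = 5, seed = 1,
                          planted_blocks = list(planted_block(c(4, 7), c(1, 2)))),
               "outside the lattice")
  expect_error(sim_config(rho = 1.2, seed = 1), "0, 0.99")
  expect_error(sim_config(n_rows = 5, n_cols = 5), "seed")
  expect_error(sim_config(seed = 1, income_brackets = list(c(0, 10), c(10, 20), c(20, Inf))),
               "25,000")
})

test_that("stochastic counts mode stays consistent and deterministic under its seed", {
  cfg <- small_config(seed = 14, stochastic_counts = TRUE)
  a <- synthesize_tracts(cfg)
  b <- synthesize_tracts(cfg)
  expect_identical(a$tracts, b$tracts)
  tt <- a$tracts
  expect_true(all(tt$hh_low_income + tt$hh_high_income <= tt$hh_total))
  expect_true(all(tt$pop_nonwhite + tt$pop_white <= tt$pop_total))
  expect_true(all(a$properties$ff %in% 1:10))
})
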