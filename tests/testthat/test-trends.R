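test_that("percent-change series is zero at base and plain arithmetic elsewhere", {
  s <- percent_change_series(
    tibble::tibble(year = c(1961, 1990, 2016), value = c(100, 100, 140.6)), 1961
  )
  expect_equal(s$pct_change, c(0, 0, 40.6))
  down <- percent_change_series(tibble::tibble(year = 1:2, value = c(100, 50)), 1)
  expect_equal(down$pct_change[2], -50)
  expect_error(
    percent_change_series(tibble::tibble(year = 1:2, value = c(0, 50)), 1),
    class = "cropdivr_validation_error"
  )
})

test_that("annual growth rate matches closed forms and reason-codes degeneracies", {
  expect_equal(annual_growth_rate(123, 123, 1961, 2016)$rate, 0)
  expect_equal(annual_growth_rate(100, 200, 1961, 2016)$rate,
               100 * (2^(1 / 55) - 1), tolerance = 1e-12)
  expect_equal(annual_growth_rate(100, 140.6, 1961, 2016)$rate, 0.6214664,
               tolerance = 1e-6)
  z <- annual_growth_rate(c(0, 100, NA), c(10, 0, 5), 1961, 2016)
  expect_true(all(is.na(z$rate)))
  expect_equal(z$reason, c("nonpositive_start", "nonpositive_end", "missing"))
  expect_error(annual_growth_rate(1, 2, 2016, 1961), class = "cropdivr_validation_error")
})

test_that("compounding identity and endpoint antisymmetry hold", {
  set.seed(11)
  for (i in 1:100) {
    x0 <- stats::rlnorm(1, 10, 2)
    x1 <- stats::rlnorm(1, 10, 2)
    y0 <- 1961; y1 <- sample(1970:2016, 1)
    r <- annual_growth_rate(x0, x1, y0, y1)$rate
    expect_equal(x0 * (1 + r / 100)^(y1 - y0), x1, tolerance = 1e-10)
    r_back <- annual_growth_rate(x1, x0, y0, y1)$rate
    expect_equal((1 + r / 100) * (1 + r_back / 100), 1, tolerance = 1e-12)
  }
})

test_that("proportional growth moves area but not diversity", {
  # every crop at exactly +2 %/yr: shares frozen, so diversity flat
  years <- c(1961L, 2016L)
  crops <- c("w", "s", "b")
  base <- c(100, 50, 25)
  panel <- as_crop_area_panel(tibble::tibble(
    entity = "A",
    crop = rep(crops, 2),
    year = rep(years, each = 3),
    area = c(base, base * 1.02^55)
  ))
  tab <- as_dependence_table(tibble::tibble(crop = crops,
                                            category = c("none", "modest", "none")))
  gt <- country_growth_table(panel, tab)
  expect_equal(gt$d_area, 2, tolerance = 1e-10)
  expect_equal(gt$d_diversity, 0, tolerance = 1e-10)
  expect_equal(gt$d_richness, 0, tolerance = 1e-10)
  expect_equal(gt$d_evenness, 0, tolerance = 1e-10)
  expect_equal(gt$d_dependence, 0, tolerance = 1e-10)
})

test_that("undefined endpoints carry reason codes through the growth table", {
  # dependence share 0 in 1961 -> log-undefined rate, not an error
  panel <- make_panel(~entity, ~crop, ~year, ~area,
                      "A", "wheat", 1961, 100,
                      "A", "wheat", 2016, 80,
                      "A", "soy",   2016, 20)
  gt <- country_growth_table(panel, tiny_dependence())
  expect_true(is.na(gt$d_dependence))
  expect_equal(gt$r_dependence, "nonpositive_start")
  expect_false(is.na(gt$d_area))
  # single-crop endpoints leave evenness undefined
  expect_true(is.na(gt$d_evenness))
})

test_that("vulnerability indices are the literal rate differences", {
  gt <- tibble::tibble(entity = c("A", "B", "C"), region = "America",
                       d_area = c(2, 1, NA), d_dependence = c(1, 0.5, 1),
                       d_diversity = c(0.5, 0.5, 0.2),
                       d_richness = 0, d_evenness = 0)
  v <- vulnerability_indices(gt)
  expect_equal(v$area_vulnerability, c(1.5, 0.5, NA))
  expect_equal(v$dependence_vulnerability, c(0.5, 0, 0.8))
  expect_equal(v$dependence_vulnerability,
               gt$d_dependence - gt$d_diversity)
})

test_that("crop expansion ranking sorts, tie-breaks, and cross-tabulates", {
  years <- c(1961L, 2016L)
  crops <- tibble::tibble(
    crop = c("fast1", "fast2", "slow1", "slow2"),
    category = c("high", "modest", "none", "none"),
    r = c(5, 3, -1, -2)
  )
  panel <- as_crop_area_panel(tibble::tibble(
    entity = "World", crop = rep(crops$crop, 2), year = rep(years, each = 4),
    area = c(rep(1000, 4), 1000 * (1 + crops$r / 100)^55)
  ))
  tab <- as_dependence_table(crops[c("crop", "category")])
  res <- rank_crop_expansion(panel, tab, k = 2)
  expect_equal(res$ranking$crop[1:2], c("fast1", "fast2"))
  expect_equal(unname(res$counts["top", ]), c(2, 0))
  expect_equal(unname(res$counts["bottom", ]), c(0, 2))
  expect_error(rank_crop_expansion(panel, tab, k = 3),
               class = "cropdivr_validation_error")

  # tie on rate: larger absolute area change ranks first
  tie <- as_crop_area_panel(tibble::tibble(
    entity = "World", crop = rep(c("big", "small", "c", "d"), 2),
    year = rep(years, each = 4),
    area = c(1000, 10, 500, 600, 2000, 20, 400, 300)
  ))
  tie_tab <- as_dependence_table(tibble::tibble(crop = c("big", "small", "c", "d"),
                                                category = "none"))
  rk <- rank_crop_expansion(tie, tie_tab, k = 2)
  expect_equal(rk$ranking$crop[1:2], c("big", "small"))

  # crops absent at an endpoint are reported as novel/discontinued
  nov <- as_crop_area_panel(tibble::tibble(
    entity = "World", crop = c("w", "s", "n", "w", "s", "n", "x", "y"),
    year = c(rep(1961L, 3), rep(2016L, 5)),
    area = c(10, 20, 0, 15, 25, 5, 1, 2)
  ))
  nov_tab <- as_dependence_table(tibble::tibble(crop = c("w", "s", "n", "x", "y"),
                                                category = "none"))
  rn <- rank_crop_expansion(nov, nov_tab, k = 1)
  expect_setequal(rn$excluded$crop, c("n", "x", "y"))
  expect_true(all(rn$excluded$status == "novel"))
})

test_that("G-test matches frozen oracles and handles corrections", {
  even <- g_test_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(even$G, 0)
  expect_equal(even$p_value, 1)
  tab <- matrix(c(16, 6, 4, 14), 2)
  expect_equal(g_test_2x2(tab)$G, 10.60044, tolerance = 1e-6)
  expect_equal(g_test_2x2(tab, "williams")$G, 10.21232, tolerance = 1e-6)
  expect_equal(g_test_2x2(tab, "yates")$G, 8.50131, tolerance = 1e-6)
  expect_error(g_test_2x2(matrix(c(0, 0, 1, 2), 2)), class = "cropdivr_validation_error")
  expect_error(g_test_2x2(matrix(c(1.5, 1, 1, 1), 2)), class = "cropdivr_validation_error")
})

test_that("uncorrected G agrees with an independent likelihood-ratio fit", {
  set.seed(42)
  for (i in 1:200) {
    tab <- matrix(stats::rpois(4, lambda = 12) + 1, 2)
    lr <- MASS::loglm(~1 + 2, data = tab)$lrt # independent LR oracle
    expect_equal(g_test_2x2(tab)$G, unname(lr), tolerance = 1e-8)
  }
})

test_that("pearson_r matches the hand oracle and drops incomplete pairs", {
  expect_equal(pearson_r(1:10, 2 * (1:10))$r, 1)
  fixed <- pearson_r(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(fixed$r, 0.8)
  expect_equal(fixed$n, 5)
  with_na <- pearson_r(c(1, 2, 3, 4, 5, NA), c(2, 1, 4, 3, 5, 100))
  expect_equal(with_na$r, 0.8) # NA pair dropped pairwise
  set.seed(9)
  null <- pearson_r(stats::rnorm(2000), stats::rnorm(2000))
  expect_lt(abs(null$r), 0.08)
  expect_error(pearson_r(1:5, rep(1, 5)), class = "cropdivr_validation_error")
})

test_that("global trends stack five zero-based series", {
  gen <- generate_panel(preset_scenarios(seed = 5)$soy_takeover)
  tr <- global_trends(gen$panel, gen$dependence)
  expect_setequal(unique(tr$variable),
                  c("area", "dependence", "diversity", "richness", "evenness"))
  base <- tr[tr$year == 1961, ]
  expect_true(all(base$pct_change == 0))
  # soy takeover: global dependence rises, evenness falls by 2016
  last <- tr[tr$year == 2016, ]
  expect_gt(last$pct_change[last$variable == "dependence"], 0)
  expect_lt(last$pct_change[last$variable == "evenness"], 0)
})
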