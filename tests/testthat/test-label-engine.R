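toy_tl <- function() {
  tab <- tibble::tibble(
    nutrient = c("fat", "satfat", "sugars", "sodium"),
    low = c(1, 1, 1, 100), high = c(2, 2, 2, 200)
  )
  tl_thresholds(food = tab, beverage = tab)
}

test_that("traffic-light colours follow the low/high cutoffs", {
  for (case in list(list(v = 0.5, col = "GREEN"), list(v = 1.5, col = "AMBER"),
                    list(v = 2.5, col = "RED"),
                    list(v = 1.0, col = "GREEN"),   # at low: still green
                    list(v = 2.0, col = "AMBER"))) { # at high: still amber
    lab <- traffic_light(flat_product(sugars_g_100 = case$v), toy_tl())
    expect_equal(lab$payload$colour[lab$payload$nutrient == "sugars"], case$col)
  }
})

test_that("traffic-light colour severity is monotone in the nutrient amount", {
  sev <- c(GREEN = 1, AMBER = 2, RED = 3)
  sweep <- seq(0, 4, by = 0.25)
  cols <- vapply(sweep, function(v) {
    lab <- traffic_light(flat_product(fat_g_100 = v), toy_tl())
    sev[[lab$payload$colour[lab$payload$nutrient == "fat"]]]
  }, numeric(1))
  expect_true(all(diff(cols) >= 0))
})

test_that("beverages use the beverage cutoff table", {
  th <- tl_thresholds()  # FSA defaults: sugar high is 22.5 (food) vs 11.25 (bev)
  p <- flat_product(sugars_g_100 = 15)
  food_col <- traffic_light(p, th)$payload
  bev_col <- traffic_light(utils::modifyList(p, list(is_beverage = TRUE)), th)$payload
  expect_equal(food_col$colour[food_col$nutrient == "sugars"], "AMBER")
  expect_equal(bev_col$colour[bev_col$nutrient == "sugars"], "RED")
})

test_that("a missing nutrient is a labeling error naming the nutrient", {
  p <- flat_product()
  p$satfat_g_100 <- NA
  expect_error(traffic_light(p, toy_tl()), "satfat",
               class = "labelrct_label_error")
})

test_that("%DI is per-serving over the reference, to one decimal", {
  # energy 870 kJ per serving against an 8700 kJ reference -> 10.0%
  p <- flat_product(energy_kj_100 = 870, serving_size = 100)
  lab <- daily_intake(p, di_references())
  expect_equal(lab$payload$pct_di[lab$payload$component == "energy_kj"], 10.0)
  expect_equal(lab$payload$per_serving[lab$payload$component == "energy_kj"], 870)
})

test_that("an all-zero product gives 0.0% for every component", {
  lab <- daily_intake(flat_product(), di_references())
  expect_equal(lab$payload$pct_di, rep(0, 5))
})

test_that("%DI doubles exactly when the serving size doubles", {
  p1 <- flat_product(energy_kj_100 = 400, fat_g_100 = 7, satfat_g_100 = 2.4,
                     sugars_g_100 = 9, sodium_mg_100 = 230, serving_size = 50)
  p2 <- utils::modifyList(p1, list(serving_size = 100))
  expect_equal(daily_intake(p2)$payload$pct_di,
               2 * daily_intake(p1)$payload$pct_di)
})

test_that("%DI rounding is half-up at one decimal place", {
  # 8700 * 0.10250 / 100 per serving -> 10.25% -> rounds up to 10.3
  p <- flat_product(energy_kj_100 = 891.75, serving_size = 100)
  lab <- daily_intake(p, di_references())
  expect_equal(lab$payload$pct_di[lab$payload$component == "energy_kj"], 10.3)
})

test_that("a non-positive reference is a configuration error", {
  expect_error(di_references(energy_kj = 0), class = "labelrct_config_error")
})

# Toy health-star tables small enough to verify by hand table-lookup.
toy_hsr <- function() {
  hsr_tables(
    baseline_food = list(
      energy = band_table(c(100, 200, 300), 1:3),
      satfat = band_table(c(1, 2), 1:2),
      sugars = band_table(c(5, 10), 1:2),
      sodium = band_table(c(100, 200, 400), 1:3)
    ),
    modifying = list(
      fvnl = band_table(c(40, 80), c(1L, 2L)),
      protein = band_table(c(5, 10), 1:2),
      fibre = band_table(c(3, 6), 1:2)
    ),
    star_map_food = data.frame(max_score = c(0, 2, 4, 5, 7, Inf),
                               stars = c(5, 4.5, 3.5, 2.5, 1.5, 0.5))
  )
}

test_that("health-star final score is baseline minus modifying points, mapped to stars", {
  # hand lookup: energy 350 -> 3 pts; satfat 1.5 -> 1; sugars 4 -> 0;
  # sodium 250 -> 2  => baseline 6. fvnl 50 -> 1 => modifying 1. score 5 -> 2.5
  p <- flat_product(energy_kj_100 = 350, satfat_g_100 = 1.5, sugars_g_100 = 4,
                    sodium_mg_100 = 250, fvnl_pct = 50, protein_g_100 = 2,
                    fibre_g_100 = 0)
  lab <- health_star(p, toy_hsr())
  expect_equal(sum(lab$payload$baseline_points), 6)
  expect_equal(sum(lab$payload$modifying_points), 1)
  expect_equal(lab$payload$final_score, 5)
  expect_equal(lab$payload$stars, 2.5)
})

test_that("degenerate tables that award no points give every product 5 stars", {
  degenerate <- hsr_tables(
    baseline_food = list(energy = band_table(Inf, 1L),
                         satfat = band_table(Inf, 1L),
                         sugars = band_table(Inf, 1L),
                         sodium = band_table(Inf, 1L)),
    modifying = list(fvnl = band_table(Inf, 1L),
                     protein = band_table(Inf, 1L),
                     fibre = band_table(Inf, 1L)),
    star_map_food = data.frame(max_score = c(0, Inf), stars = c(5, 5))
  )
  for (p in list(flat_product(), flat_product(energy_kj_100 = 3000,
                                              sugars_g_100 = 50))) {
    expect_equal(health_star(p, degenerate)$payload$stars, 5.0)
  }
})

test_that("stars never increase as sodium increases, all else fixed", {
  stars <- vapply(seq(0, 1200, by = 50), function(na) {
    health_star(flat_product(energy_kj_100 = 800, sugars_g_100 = 20,
                             sodium_mg_100 = na))$payload$stars
  }, numeric(1))
  expect_true(all(diff(stars) <= 0))
})

test_that("stars never decrease as fibre increases, all else fixed", {
  stars <- vapply(seq(0, 12, by = 0.5), function(fb) {
    health_star(flat_product(energy_kj_100 = 1500, sugars_g_100 = 20,
                             fibre_g_100 = fb))$payload$stars
  }, numeric(1))
  expect_true(all(diff(stars) >= 0))
})

test_that("star values stay on the half-star scale 0.5..5.0", {
  tab <- simulate_food_db(50, seed = 5)
  stars <- vapply(seq_len(nrow(tab)), function(i) {
    health_star(tab[i, ])$payload$stars
  }, numeric(1))
  expect_true(all(stars %in% seq(0.5, 5, by = 0.5)))
})

test_that("the nutrition panel reports 7 nutrients per 100 and per serving", {
  p <- flat_product(energy_kj_100 = 2000, serving_size = 50)
  lab <- nip(p)
  expect_equal(dim(lab$payload), c(7L, 3L))
  expect_equal(lab$payload$per_serving[lab$payload$nutrient == "energy_kj"], 1000)
  zero <- nip(flat_product())
  expect_equal(zero$payload$per_100, rep(0, 7))
  expect_equal(zero$payload$per_serving, rep(0, 7))
})

test_that("the control panel has no interpretive elements", {
  lab <- nip(toy_products()[2, ])
  expect_false(any(c("colour", "stars", "pct_di", "text") %in%
                     names(lab$payload)))
})

test_that("warning flags use a strict threshold comparison", {
  rule <- warning_rule(tibble::tibble(
    nutrient = c("sugars", "sodium"), threshold = c(20, 400),
    text = c("HIGH_IN_SUGARS", "HIGH_IN_SODIUM")
  ))
  none <- warning_label(flat_product(sugars_g_100 = 5, sodium_mg_100 = 100), rule)
  expect_equal(nrow(none$payload), 0)
  boundary <- warning_label(flat_product(sugars_g_100 = 20, sodium_mg_100 = 400), rule)
  expect_equal(nrow(boundary$payload), 0)  # exactly at threshold: no flag
  both <- warning_label(flat_product(sugars_g_100 = 21, sodium_mg_100 = 401), rule)
  expect_setequal(both$payload$text, c("HIGH_IN_SUGARS", "HIGH_IN_SODIUM"))
})

test_that("label_for dispatches on the allocated arm", {
  cfg_au <- trial_config_australia()
  p <- toy_products()[2, ]
  expect_equal(label_for(p, "NIP", cfg_au)$arm, "NIP")
  expect_equal(label_for(p, "HSR", cfg_au)$arm, "HSR")
  expect_true(is.numeric(label_for(p, "HSR", cfg_au)$payload$stars))
  expect_equal(label_for(p, "DIG", cfg_au)$arm, "DIG")
  expect_equal(label_for(p, "WARNING", cfg_au)$arm, "WARNING")
})

test_that("an arm outside the configuration is a configuration error", {
  cfg_nz <- trial_config_new_zealand()  # has no DIG or WARNING arm
  expect_error(label_for(toy_products()[1, ], "DIG", cfg_nz),
               class = "labelrct_config_error")
})

test_that("labels serialize to JSON with their arm tag", {
  js <- jsonlite::fromJSON(label_to_json(nip(toy_products()[1, ])))
  expect_equal(js$arm, "NIP")
  expect_equal(nrow(js$payload), 7)
})

test_that("scheme tables round-trip through YAML unchanged", {
  cfg <- trial_config_new_zealand()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_trial_config(cfg, path)
  back <- read_trial_config(path)
  p <- toy_products()[2, ]
  for (arm in cfg$arms) {
    expect_equal(label_for(p, arm, back)$payload, label_for(p, arm, cfg)$payload)
  }
  expect_equal(back$arms, cfg$arms)
  expect_equal(back$strat_factors, cfg$strat_factors)
})
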