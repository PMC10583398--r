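# raw questionnaire rows with every item answered; overrides applied on top
raw_answers <- function(n = 1, ...) {
  base <- data.frame(
    beef_freq = "once_week", lamb_freq = "once_week", pork_freq = "less_than_once_week",
    processed_meat_freq = "less_than_once_week", poultry_freq = "once_week",
    oily_fish_freq = "once_week", nonoily_fish_freq = "once_week",
    cheese_freq = "two_to_four_week", fresh_fruit_pieces = 2, dried_fruit_pieces = 0,
    cooked_veg_tbsp = 6, salad_veg_tbsp = 3, coffee_cups = 1, tea_cups = 3,
    cereal_bowls = 1, milk_type = "semi_skimmed", alcohol_freq = "once_or_twice_week",
    stringsAsFactors = FALSE)
  out <- base[rep(1, n), , drop = FALSE]
  over <- list(...)
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  rownames(out) <- NULL
  out
}

test_that("food groups aggregate via the frequency midpoints", {
  # midpoint oracle: <1/wk = 0.5, 1/wk = 1, 2-4 = 3, 5-6 = 5.5, daily = 7
  g <- derive_food_groups(raw_answers())
  expect_equal(g$red_meat, 1 + 1 + 0.5)          # 2.5 times/week
  expect_equal(as.character(g$red_meat_cat), "2 to <3")
  g2 <- derive_food_groups(raw_answers(
    beef_freq = "less_than_once_week", lamb_freq = "less_than_once_week",
    pork_freq = "less_than_once_week"))
  expect_equal(g2$red_meat, 1.5)
  expect_equal(as.character(g2$red_meat_cat), "<2")

  expect_equal(g$total_fish, 2)                   # oily + non-oily
  expect_equal(g$total_veg, (6 + 3) / 3)          # tablespoons -> servings
  expect_equal(g$milk, 1 * 125 + (1 + 3) * 30)    # bowls + milky drinks
  expect_equal(as.character(g$milk_cat), "200 to <300")
  g3 <- derive_food_groups(raw_answers(milk_type = "none"))
  expect_equal(g3$milk, 0)
})

test_that("missing constituents propagate and unknown tokens are rejected", {
  g <- derive_food_groups(raw_answers(2, lamb_freq = c("missing", "once_week")))
  expect_true(is.na(g$red_meat[1]) && is.na(g$red_meat_cat[1]))
  expect_false(is.na(g$red_meat[2]))
  expect_true(is.na(derive_food_groups(raw_answers(fresh_fruit_pieces = NA))$total_fruit))
  expect_error(derive_food_groups(raw_answers(beef_freq = "sometimes")),
               "beef_freq")
  expect_error(derive_food_groups(raw_answers(alcohol_freq = "weekly")),
               "alcohol")
})

test_that("WCRF score counts the three recommendations", {
  # all adherent: meat < 4/wk, fruit+veg > 5/day, alcohol special occasions
  g <- derive_food_groups(raw_answers(
    fresh_fruit_pieces = 3, cooked_veg_tbsp = 9, salad_veg_tbsp = 3,
    alcohol_freq = "special_occasions"))
  s <- wcrf_score(g)
  expect_equal(s$wcrf_score, 3)
  expect_equal(as.character(s$wcrf_group), "2-3")

  # none adherent: meat 5+2=7/wk is >= 4, fruit+veg 3, alcohol daily
  g0 <- derive_food_groups(raw_answers(
    beef_freq = "two_to_four_week", lamb_freq = "two_to_four_week",
    pork_freq = "once_week", processed_meat_freq = "two_to_four_week",
    fresh_fruit_pieces = 1, cooked_veg_tbsp = 3, salad_veg_tbsp = 3,
    alcohol_freq = "daily_or_almost_daily"))
  s0 <- wcrf_score(g0)
  expect_equal(s0$wcrf_score, 0)
  expect_equal(as.character(s0$wcrf_group), "0-1")

  # exactly one component (meat) adherent
  g1 <- derive_food_groups(raw_answers(
    fresh_fruit_pieces = 1, cooked_veg_tbsp = 3, salad_veg_tbsp = 3))
  s1 <- wcrf_score(g1)
  expect_equal(s1$wcrf_score, 1)
  expect_equal(as.character(s1$wcrf_group), "0-1")
  expect_equal(s1$wcrf_score,
               s1$wcrf_meat + s1$wcrf_fruit_veg + s1$wcrf_alcohol)
})

test_that("CI-to-SE weights follow the closed form", {
  w <- derive_weight_table(data.frame(food = "red_meat", category = ">=3",
                                      hr = 1.16, lower = 1.08, upper = 1.25))
  expect_equal(w$se, (log(1.25) - log(1.08)) / (2 * 1.959964))
  expect_equal(w$weight, log(1.16) / w$se)
  expect_equal(w$weight, 3.98, tolerance = 1e-3)

  expect_equal(derive_weight_table(data.frame(
    food = "x", category = "c", hr = 1, lower = 0.9, upper = 1.1))$weight, 0)
  wm <- derive_weight_table(data.frame(food = "milk", category = ">=300",
                                       hr = 0.85, lower = 0.79, upper = 0.92))
  expect_lt(wm$weight, 0)
  expect_error(derive_weight_table(data.frame(
    food = "x", category = "c", hr = 1.2, lower = 1.25, upper = 1.3)),
    "lower <= HR <= upper")
})

test_that("IV-weighted diet score is an additive per-category sum", {
  wt <- default_diet_weights()
  ref <- reference_categories(1)
  expect_equal(as.numeric(iv_diet_score(ref, wt)), 0)

  one <- reference_categories(1)
  one$red_meat_cat[1] <- ">=3"
  w_red <- wt$weight[wt$food == "red_meat" & wt$category == ">=3"]
  expect_equal(as.numeric(iv_diet_score(one, wt)), w_red)

  # additivity over disjoint foods
  two <- one
  two$tea_cat[1] <- ">=5"
  w_tea <- wt$weight[wt$food == "tea" & wt$category == ">=5"]
  expect_equal(as.numeric(iv_diet_score(two, wt)), w_red + w_tea)

  # monotone in per-food risk: the higher-HR category always scores higher
  for (food in unique(wt$food)) {
    sub <- wt[wt$food == food, ]
    sub <- sub[order(sub$hr), ]
    expect_true(all(diff(sub$weight) > 0) || all(sub$hr == sub$hr[1]),
                label = paste("monotone weights for", food))
  }
})

test_that("cohort scores stay inside the attainable min/max envelope", {
  wt <- default_diet_weights()
  # brute-force oracle over a 3-food subspace, rest at reference
  foods <- c("red_meat", "milk", "tea")
  cats <- lapply(foods, function(f) diet_cutpoints()[[f]]$labels)
  grid <- expand.grid(cats, stringsAsFactors = FALSE)
  brute <- apply(grid, 1, function(row) {
    cc <- reference_categories(1)
    for (i in seq_along(foods)) {
      cc[[paste0(foods[i], "_cat")]][1] <- row[i]
    }
    as.numeric(iv_diet_score(cc, wt))
  })
  set.seed(2)
  sim <- simulate_cohort(sim_config(2000, seed = 2, genotypes = FALSE))
  g <- derive_food_groups(sim$cohort)
  sc <- iv_diet_score(g, wt)
  rng <- attr(sc, "range")
  expect_true(min(brute) >= rng[1] && max(brute) <= rng[2])
  expect_true(all(sc >= rng[1] & sc <= rng[2], na.rm = TRUE))
  # attainable envelope brackets the published tertile span of the score
  expect_lt(rng[1], -13.0)
  expect_gt(rng[2], 13.0)
})

test_that("WCRF and IV-weighted scores are anti-correlated under the latent factor", {
  set.seed(9)
  sim <- simulate_cohort(sim_config(4000, seed = 9, genotypes = FALSE))
  g <- derive_food_groups(sim$cohort)
  s <- wcrf_score(g)
  iv <- iv_diet_score(g)
  ok <- !is.na(s$wcrf_score) & !is.na(iv)
  expect_lt(cor(s$wcrf_score[ok], iv[ok], method = "spearman"), 0)
})

test_that("weight tables round-trip through TSV", {
  wt <- default_diet_weights()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_weight_table(wt, f)
  back <- read_weight_table(f)
  expect_equal(back$weight, wt$weight, tolerance = 1e-9)
})
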