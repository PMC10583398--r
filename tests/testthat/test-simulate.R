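test_that("a zero baseline hazard yields no events and full follow-up", {
  cfg <- sim_config(500, seed = 4, baseline_hazard_rate = 0, ltfu_rate = 0,
                    genotypes = FALSE)
  sim <- simulate_cohort(cfg)
  expect_equal(sum(sim$cohort$event), 0)
  expect_true(all(sim$cohort$followup_time == cfg$followup_years))
  expect_true(all(sim$cohort$event_subtype == "none"))
})

test_that("event subtype is none exactly when no event occurred", {
  sim <- simulate_cohort(sim_config(5000, seed = 6, genotypes = FALSE))
  expect_true(all((sim$cohort$event == 0) == (sim$cohort$event_subtype == "none")))
  expect_true(all(sim$cohort$followup_time > 0))
})

test_that("genotype dosages follow Binomial(2, eaf)", {
  man <- toy_manifest(0.1, 0.05, eaf = 0.5)
  sim <- simulate_cohort(sim_config(1e5, seed = 12, manifest = man))
  m <- mean(sim$genotypes[, 1])
  se <- sqrt(2 * 0.5 * 0.5 / 1e5)   # binomial mean/variance oracle
  expect_lt(abs(m - 1), 3 * se)

  man5 <- toy_manifest(rep(0.1, 5), rep(0.05, 5), eaf = c(0.1, 0.3, 0.5, 0.7, 0.9))
  sim5 <- simulate_cohort(sim_config(1e5, seed = 13, manifest = man5))
  mu <- colMeans(sim5$genotypes)
  se5 <- sqrt(2 * man5$eaf * (1 - man5$eaf) / 1e5)
  expect_true(all(abs(mu - 2 * man5$eaf) < 4 * se5))
})

test_that("the draw is bit-for-bit reproducible given the seed", {
  cfg <- sim_config(2000, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$genotypes, b$genotypes)
  c_ <- simulate_cohort(sim_config(2000, seed = 100))
  expect_false(identical(a$cohort$followup_time, c_$cohort$followup_time))
})

test_that("event fraction is calibrated and monotone in the baseline rate", {
  sim <- simulate_cohort(sim_config(20000, seed = 21, genotypes = FALSE))
  target <- 4686 / 374004
  mc_se <- sqrt(target * (1 - target) / 20000)
  expect_lt(abs(mean(sim$cohort$event) - target), 3.5 * mc_se)

  fr <- vapply(c(1e-4, 5e-4, 2e-3), function(r) {
    mean(simulate_cohort(sim_config(5000, seed = 22, baseline_hazard_rate = r,
                                    genotypes = FALSE))$cohort$event)
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("configured effects are recovered by the adjusted Cox fit (null included)", {
  # null case: a term whose preset effect is zeroed fits an HR near 1
  eff <- crc_true_effects()
  eff$wcrf_group["0-1"] <- 0
  sim <- simulate_cohort(sim_config(30000, seed = 31, genotypes = FALSE,
                                    active_terms = c("sex", "wcrf_group"),
                                    effects = eff))
  d <- build_analysis_table(sim$cohort)
  ft <- fit_cox(d, "wcrf_group", adjust = "sex")
  row <- ft$terms[ft$terms$level == "0-1", ]
  expect_lt(abs(row$coef), 3 * row$se)
})

test_that("overflowing configured effects are a configuration error", {
  eff <- crc_true_effects()
  eff$sex["man"] <- 1e4
  expect_error(
    simulate_cohort(sim_config(200, seed = 1, effects = eff, genotypes = FALSE,
                               baseline_hazard_rate = 1e-3)),
    "configuration error")
})

test_that("exclusion cascade removes rows in order with a faithful ledger", {
  raw <- data.frame(participant_id = 1:10,
                    has_genetics = TRUE, sex_discordant = FALSE,
                    aneuploidy = FALSE, non_white_british = FALSE,
                    prevalent_cancer = FALSE, withdrew = FALSE)
  out <- apply_exclusion_cascade(raw)
  expect_equal(nrow(out$cohort), 10)         # no flags -> identity
  expect_true(all(out$ledger$removed == 0))

  raw2 <- raw
  raw2$has_genetics <- FALSE                 # all rows flagged -> empty
  out2 <- apply_exclusion_cascade(raw2)
  expect_equal(nrow(out2$cohort), 0)
  expect_equal(sum(out2$ledger$removed), 10)

  # overlapping flags: a row already removed is not counted again
  raw3 <- raw
  raw3$has_genetics[1] <- FALSE
  raw3$sex_discordant[1] <- TRUE
  raw3$sex_discordant[2] <- TRUE
  out3 <- apply_exclusion_cascade(raw3)
  expect_equal(out3$ledger$removed[1:2], c(1L, 1L))
  expect_equal(nrow(out3$cohort), 8)
})
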