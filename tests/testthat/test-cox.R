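test_that("fit_cox matches a brute-force Efron partial likelihood", {
  # six subjects, no censoring, tied event times
  d <- data.frame(followup_time = c(2, 2, 3, 5, 5, 8),
                  event = 1L,
                  exposure = factor(c("b", "a", "b", "a", "b", "a"),
                                    levels = c("a", "b")),
                  event_subtype = factor("colon", c("none", "colon", "rectal")))
  ft <- fit_cox(d, "exposure")
  x <- as.integer(d$exposure) - 1
  grid <- optimize(function(b) -efron_loglik(b, d$followup_time, d$event, x),
                   c(-5, 5), tol = 1e-9)
  expect_equal(ft$terms$coef[ft$terms$level == "b"], grid$minimum,
               tolerance = 1e-5)
  expect_equal(ft$loglik, -grid$objective, tolerance = 1e-8)

  # local optimality: perturbing the coefficient can only lower the likelihood
  bhat <- ft$terms$coef[2]
  for (eps in c(-0.2, -0.05, 0.05, 0.2)) {
    expect_lt(efron_loglik(bhat + eps, d$followup_time, d$event, x),
              efron_loglik(bhat, d$followup_time, d$event, x))
  }
})

test_that("a null exposure fits an HR within Monte-Carlo error of 1", {
  set.seed(41)
  d <- make_surv_data(3000, c(a = 0, b = 0))
  ft <- fit_cox(d, "exposure")
  row <- ft$terms[ft$terms$level == "b", ]
  expect_lt(abs(row$coef), 3 * row$se)
  expect_true(row$lower <= row$hr & row$hr <= row$upper)
})

test_that("estimates are equivariant under exposure relabeling", {
  set.seed(42)
  d <- make_surv_data(2000, c(a = 0, b = 0.4, c = 0.8))
  f1 <- fit_cox(d, "exposure")
  f2 <- fit_cox(d, "exposure", ref = "c")
  hr_ab <- f1$terms$hr[f1$terms$level == "b"]
  hr_cb <- f2$terms$hr[f2$terms$level == "b"]
  hr_ca <- f2$terms$hr[f2$terms$level == "a"]
  expect_equal(hr_ab, hr_cb / hr_ca, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("reported 95% CIs have near-nominal coverage on null-free simulations", {
  set.seed(43)
  hits <- vapply(1:150, function(i) {
    d <- make_surv_data(400, c(a = 0, b = 0.5), rate0 = 0.15)
    row <- fit_cox(d, "exposure")$terms[2, ]
    row$lower <= exp(0.5) && exp(0.5) <= row$upper
  }, logical(1))
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})

test_that("zero-event exposure levels are flagged and withheld", {
  set.seed(44)
  d <- make_surv_data(300, c(a = 0, b = 0))
  d$event[d$exposure == "b"] <- 0L
  expect_warning(ft <- fit_cox(d, "exposure"), "zero events")
  expect_true(is.na(ft$terms$hr[ft$terms$level == "b"]))
  expect_equal(ft$flags, "zero_event_level")
})

test_that("complete-case handling drops missing exposures but keeps missing adjusters", {
  set.seed(45)
  d <- make_surv_data(1000, c(a = 0, b = 0.3))
  d$exposure[1:50] <- NA
  d$covar <- factor(sample(c("x", "y", NA), 1000, replace = TRUE))
  ft <- fit_cox(d, "exposure", adjust = "covar")
  expect_equal(ft$n, 950)
  expect_true("covarmissing" %in% names(coef(ft$model)))
})

test_that("p_trend detects a monotone dose-response and is calibrated under the null", {
  set.seed(46)
  d <- make_surv_data(2000, c(l1 = 0, l2 = 0.4, l3 = 0.8))
  tr <- p_trend(d, "exposure")
  expect_lt(tr$p, 1e-6)
  expect_gt(tr$coef, 0)

  # flat effects at large n: no spurious trend
  d0 <- make_surv_data(4000, c(l1 = 0, l2 = 0, l3 = 0))
  expect_gt(p_trend(d0, "exposure")$p, 0.01)

  # null calibration: p-values uniform on (0, 1) across replicates
  ps <- vapply(1:200, function(i) {
    p_trend(make_surv_data(300, c(l1 = 0, l2 = 0, l3 = 0), rate0 = 0.2),
            "exposure")$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the interaction LRT is non-negative and reference-invariant", {
  set.seed(47)
  d <- make_surv_data(3000, c(a = 0, b = 0.3))
  d$modifier <- factor(sample(c("lo", "mid", "hi"), 3000, replace = TRUE),
                       levels = c("lo", "mid", "hi"))
  l1 <- lrt_interaction(d, "exposure", "modifier")
  expect_gte(l1$statistic, 0)
  expect_equal(l1$df, 2)
  expect_true(l1$p >= 0 && l1$p <= 1)

  d2 <- d
  d2$exposure <- relevel(d2$exposure, "b")
  d2$modifier <- relevel(d2$modifier, "hi")
  l2 <- lrt_interaction(d2, "exposure", "modifier")
  expect_equal(l1$statistic, l2$statistic, tolerance = 1e-6)
})

test_that("joint tables carry the reference cell at HR 1 and stay null under the null", {
  set.seed(48)
  d <- make_surv_data(4000, c(a = 0, b = 0))
  d$prs <- factor(sample(c("low", "intermediate", "high"), 4000, replace = TRUE),
                  levels = c("low", "intermediate", "high"))
  jt <- joint_effect_table(d, "exposure", "prs")
  expect_equal(nrow(jt$terms), 6)
  ref <- jt$terms[jt$terms$diet_level == "a" & jt$terms$prs_level == "low", ]
  expect_equal(ref$hr, 1)
  others <- jt$terms[-1, ]
  expect_true(all(abs(others$coef) < 3.5 * others$se))
  expect_equal(sum(jt$terms$n), jt$n)
})

test_that("stratified fits are homogeneous under homogeneity and conserve subtype events", {
  set.seed(49)
  d <- make_surv_data(6000, c(a = 0, b = 0.5), rate0 = 0.05)
  d$stratum <- factor(sample(c("s1", "s2"), 6000, replace = TRUE))
  st <- stratified_fits(d, "exposure", strata = "stratum")
  b1 <- st$s1$terms[2, ]; b2 <- st$s2$terms[2, ]
  expect_lt(abs(b1$coef - b2$coef), 3 * sqrt(b1$se^2 + b2$se^2))

  d$event_subtype <- factor(ifelse(d$event == 1,
                                   sample(c("colon", "rectal"), 6000, TRUE), "none"),
                            levels = c("none", "colon", "rectal"))
  ss <- stratified_fits(d, "exposure", strata = "subsite")
  expect_equal(ss$colon$n_events + ss$rectal$n_events, sum(d$event))
})
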