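# Future pseudo-samples, frame assembly, pooling and Wilson intervals.

test_that("wilson interval matches its closed form and stays inside [0, 1]", {
  w <- wilson_interval(0.5, 100, 0.95)
  expect_equal(w$low, 0.4038, tolerance = 1e-4)
  expect_equal(w$high, 0.5962, tolerance = 1e-4)
  expect_equal(wilson_interval(0, 50)$low, 0)
  expect_equal(wilson_interval(1, 50)$high, 1)
  expect_error(wilson_interval(0.5, 100, 1.2), "level")
  ps <- withr::with_seed(41, runif(500))
  ns <- withr::with_seed(42, sample(1e6, 500))
  w <- wilson_interval(ps, ns)
  expect_true(all(w$low >= 0 & w$high <= 1 & w$low <= w$high))
  expect_true(all(w$low <= ps & ps <= w$high))
})

test_that("future samples honour the projection in both allocation modes", {
  cfg <- scenario_config(seed = 51)
  years <- seq(2020, 2040, 5)
  proj <- generate_population_projection(cfg, years)
  fs <- future_sample_spec(years, 2000, proj)
  fut <- build_future_samples(fs)
  expect_equal(nrow(fut), 10000)  # 5 years x 2000
  expect_equal(as.vector(table(fut$year)), rep(2000, 5))
  # deterministic allocation: realised counts equal rounded expected counts
  counts <- table(fut$age[fut$year == 2020], fut$sex[fut$year == 2020])
  expect_true(all(abs(counts - 2000 / (2 * 40)) <= 1))
  # all survey columns missing, area missing, participation FALSE
  for (col in c("marital", "smoking", "bmi_cat", "diabetes")) {
    expect_true(all(is.na(fut[[col]])))
  }
  expect_true(all(is.na(fut$area)))
  expect_true(all(!fut$participation))

  # sampling mode: uniform projection passes a chi-square goodness-of-fit
  fs2 <- future_sample_spec(2030, 4000, proj, mode = "sample")
  fut2 <- build_future_samples(fs2, seed = 4)
  tab <- table(fut2$age)
  gof <- chisq.test(tab, p = rep(1 / length(tab), length(tab)))
  expect_gt(gof$p.value, 0.001)

  expect_error(future_sample_spec(2050, 100, proj), "2050")
})

test_that("joint frame assembly is additive and schema-checked", {
  cfg <- smoking_scenario(n_per_sex = 100, seed = 52,
                          years = c(1997, 2002))
  obs <- complete_series(cfg)
  proj <- generate_population_projection(cfg, 2030)
  fut <- build_future_samples(future_sample_spec(2030, 300, proj))
  joint <- assemble_joint_frame(obs, fut)
  expect_equal(nrow(joint), nrow(obs) + nrow(fut))
  expect_setequal(unique(joint$source), c("observed", "future"))
  fut_rows <- joint$source == "future"
  expect_true(all(is.na(joint$smoking[fut_rows])))
  bad <- fut; bad$smoking <- NULL
  expect_error(assemble_joint_frame(obs, bad), "smoking")
})

test_that("survey frames round-trip through CSV plus schema sidecar", {
  cfg <- smoking_scenario(n_per_sex = 50, seed = 53, years = 1997)
  f <- apply_nonresponse(complete_series(cfg), cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey_frame(f, path)
  g <- read_survey_frame(path)
  expect_equal(g, f, ignore_attr = TRUE)
})

test_that("pooling averages within-imputation proportions", {
  base <- new_survey_frame(10)
  base$year <- 2000L
  base$sex <- factor(rep(c("female", "male"), 5), levels = c("female", "male"))
  f1 <- base; f1$smoking <- rep(c(1L, 0L, 0L, 0L, 0L), 2)  # 0.2
  f2 <- base; f2$smoking <- rep(c(1L, 1L, 0L, 0L, 0L), 2)  # 0.4
  cs <- structure(list(imputations = list(f1, f2),
                       config = mice_config(m = 2, iterations = 1),
                       specs = list(), miss = list()),
                  class = "completed_set")
  pooled <- pool_prevalence(cs, "smoking", by = "year")
  expect_equal(pooled$prevalence, 0.3)  # mean of 0.2 and 0.4
  expect_equal(pooled$n_effective, 10)
  # identical copies: pooled equals the single-frame proportion
  cs2 <- cs; cs2$imputations <- list(f1, f1)
  expect_equal(pool_prevalence(cs2, "smoking", by = "year")$prevalence, 0.2)
  expect_equal(pool_prevalence(cs2, "smoking", by = "year")$between_var, 0)
})

test_that("BMI category prevalences partition each stratum", {
  cfg <- scenario_config(invited_n = flat_invited(300), seed = 54)
  frame <- complete_series(cfg)
  cs <- run_chain(frame, list(imputation_spec(
    "bmi_cat", "polytomous", c("age", "sex", "year"))),
    mice_config(m = 2, iterations = 1, seed = 1))
  pooled <- pool_prevalence(cs, "bmi_cat", by = c("sex", "year"))
  sums <- tapply(pooled$prevalence,
                 interaction(pooled$sex, pooled$year), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(pooled$indicator %in%
                    c("bmi_normal", "bmi_overweight", "bmi_obese")))
})

test_that("projected logit prevalence is linear in year under a linear model", {
  cfg <- smoking_scenario(p0 = 0.3, slope = -0.02, n_per_sex = 1000,
                          seed = 55)
  obs <- complete_series(cfg)
  years <- seq(2020, 2040, 5)
  proj <- generate_population_projection(cfg, years)
  series <- run_projection(obs, list(smoking_spec()),
                           future_sample_spec(years, 1500, proj),
                           mice_config(m = 10, iterations = 5, seed = 2))
  expect_s3_class(series, "prevalence_series")
  expect_true(all(series$interval_low <= series$prevalence &
                    series$prevalence <= series$interval_high))
  proj_rows <- series$source == "projected" & series$sex == "female"
  lp <- qlogis(series$prevalence[proj_rows])
  fit <- lm(lp ~ series$year[proj_rows])
  expect_lt(summary(fit)$sigma, 0.12)          # near-linear up to MC noise
  expect_lt(abs(unname(coef(fit)[2]) - (-0.02)), 0.012)
})

test_that("an ageing projection raises age-driven prevalence above fixed demographics", {
  tp <- default_trend_params()
  tp$hypertension <- c(intercept = qlogis(0.3), year = 0, male = 0,
                       age = 0.07)
  cfg <- scenario_config(invited_n = flat_invited(800), trend_params = tp,
                         dependence_params = c(diabetes_obesity = 0,
                                               hypertension_obesity = 0),
                         seed = 56)
  obs <- complete_series(cfg)
  spec <- imputation_spec("hypertension", "logistic", c("age", "sex", "year"))
  mc <- mice_config(m = 8, iterations = 5, seed = 3)
  flat <- run_projection(obs, list(spec),
                         future_sample_spec(2040, 3000,
                                            generate_population_projection(cfg, 2040)),
                         mc, indicators = "hypertension")
  old <- run_projection(obs, list(spec),
                        future_sample_spec(2040, 3000,
                                           generate_population_projection(cfg, 2040,
                                                                          ageing_drift = 0.003)),
                        mc, indicators = "hypertension")
  p_flat <- weighted.mean(flat$prevalence[flat$year == 2040],
                          flat$n_effective[flat$year == 2040])
  p_old <- weighted.mean(old$prevalence[old$year == 2040],
                         old$n_effective[old$year == 2040])
  expect_gt(p_old, p_flat)
})
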