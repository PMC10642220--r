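# Shared scenario builders for the tests. All fixtures are generated in code.

flat_invited <- function(n_per_sex, years = c(1997, 2002, 2007, 2012, 2017)) {
  do.call(rbind, lapply(years, function(y) {
    data.frame(year = y, sex = c("female", "male"), n = n_per_sex)
  }))
}

# Scenario in which only the smoking indicator matters: configurable
# intercept/slope, no sex or age effect, so the analytic prevalence is a
# plain expit of the trend line.
smoking_scenario <- function(p0 = 0.30, slope = -0.03, n_per_sex = 1500,
                             seed = 20400101,
                             years = c(1997, 2002, 2007, 2012, 2017)) {
  tp <- default_trend_params()
  tp$smoking <- c(intercept = qlogis(p0), year = slope, male = 0, age = 0)
  scenario_config(wave_years = years,
                  invited_n = flat_invited(n_per_sex, years),
                  trend_params = tp, seed = seed)
}

# Complete (pre-non-response) multi-wave frame for a config.
complete_series <- function(cfg) {
  do.call(rbind, lapply(cfg$wave_years, function(y) {
    simulate_indicators(generate_population_frame(cfg, y), cfg)
  }))
}

smoking_spec <- function() {
  imputation_spec("smoking", "logistic", c("age", "sex", "year"))
}

# Monte-Carlo standard error of a proportion.
prop_se <- function(p, n) sqrt(p * (1 - p) / n)
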