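# Synthetic multi-wave survey generator.
#
# Emulates the structure of a series of national health examination surveys:
# five waves every five years (1997-2017), per-wave invited sample sizes and
# questionnaire/examination response rates, item non-response, a structurally
# unmeasured diabetes indicator in the waves without HbA1c assays, and
# logit-linear secular trends in six risk-factor indicators. All randomness is
# governed by one master seed with deterministic per-wave/per-mechanism
# substreams, so the generated history of one wave never depends on how many
# other waves are requested.

SEX_LEVELS <- c("female", "male")
BMI_LEVELS <- c("normal", "overweight", "obese")
EDUCATION_LEVELS <- c("basic", "secondary", "tertiary")

# Column roles of a survey frame. Demographics come from the sampling frame
# and are always observed for invited individuals; survey columns exist only
# for participants. Measured columns additionally require attendance at the
# health examination.
DEMOGRAPHIC_COLUMNS <- c("year", "sex", "age", "area")
QUESTIONNAIRE_COLUMNS <- c("marital", "education", "smoking", "sedentary")
MEASURED_COLUMNS <- c("hypertension", "elevated_tc", "bmi_cat", "diabetes")
SURVEY_COLUMNS <- c(QUESTIONNAIRE_COLUMNS, MEASURED_COLUMNS)
BINARY_INDICATORS <- c("smoking", "sedentary", "hypertension", "elevated_tc",
                       "diabetes")

# Questionnaire response rates (%) and examination participation rates (%)
# by wave and sex used as generator defaults.
default_response_rates <- function(wave_years) {
  ref_years <- c(1997, 2002, 2007, 2012, 2017)
  resp <- rbind(
    data.frame(year = ref_years, sex = "male",
               response_rate = c(67.9, 65.0, 60.3, 56.9, 60.6) / 100),
    data.frame(year = ref_years, sex = "female",
               response_rate = c(72.3, 75.3, 70.5, 66.5, 70.0) / 100)
  )
  part <- rbind(
    data.frame(year = ref_years, sex = "male",
               participation_rate = c(67.9, 58.8, 56.1, 51.5, 51.9) / 100),
    data.frame(year = ref_years, sex = "female",
               participation_rate = c(72.3, 69.8, 65.6, 59.7, 61.9) / 100)
  )
  # waves outside the reference grid reuse the nearest reference wave
  pick <- function(tab, value_col) {
    do.call(rbind, lapply(wave_years, function(y) {
      j <- which.min(abs(ref_years - y))
      out <- tab[tab$year == ref_years[j], ]
      out$year <- y
      out
    }))
  }
  list(unit = pick(resp, "response_rate"),
       examination = pick(part, "participation_rate"))
}

default_invited_n <- function(wave_years) {
  ref_years <- c(1997, 2002, 2007, 2012, 2017)
  men <- c(5000, 4999, 4000, 4000, 1635)
  women <- c(5000, 5000, 4000, 4000, 1542)
  do.call(rbind, lapply(wave_years, function(y) {
    j <- which.min(abs(ref_years - y))
    data.frame(year = y, sex = SEX_LEVELS, n = c(women[j], men[j]))
  }))
}

#' Default logit-scale trend parameters of the synthetic generator
#'
#' Per-indicator coefficient vectors `c(intercept, year, male, age)` (for BMI
#' and education: one vector per non-reference category). The year slope is
#' per calendar year since the first wave; age is centred at the midpoint of
#' the age range. Values give 1997 prevalences and 20-year secular changes of
#' the order seen in Finnish risk-factor monitoring. Modify entries to build
#' scenarios with known ground truth.
#'
#' @return a named list suitable as `trend_params` in [scenario_config()].
#' @export
default_trend_params <- function() {
  list(
    smoking      = c(intercept = stats::qlogis(0.24), year = -0.017,
                     male = 0.55, age = -0.012),
    sedentary    = c(intercept = stats::qlogis(0.22), year = 0.004,
                     male = 0.05, age = 0.012),
    hypertension = c(intercept = stats::qlogis(0.28), year = -0.012,
                     male = 0.55, age = 0.065),
    elevated_tc  = c(intercept = stats::qlogis(0.60), year = -0.012,
                     male = 0.12, age = 0.050),
    diabetes     = c(intercept = stats::qlogis(0.03), year = 0.035,
                     male = 0.45, age = 0.055),
    bmi = list(
      overweight = c(intercept = -0.25, year = 0.002, male = 0.45, age = 0.020),
      obese      = c(intercept = -1.10, year = 0.022, male = 0.15, age = 0.030)
    ),
    marital   = c(intercept = stats::qlogis(0.62), year = 0, male = 0,
                  age = 0.02),
    education = list(
      secondary = c(intercept = log(0.4 / 0.3), year = 0, male = 0, age = 0),
      tertiary  = c(intercept = log(0.3 / 0.3), year = 0, male = 0, age = 0)
    )
  )
}

#' Scenario configuration for the synthetic survey generator
#'
#' Bundles everything the generator needs: wave calendar, invited sample sizes
#' per wave and sex, age range and number of study areas, logit-scale trend
#' parameters for each indicator, cross-indicator dependence (obesity raising
#' the odds of diabetes and hypertension), the non-response mechanism, the
#' structurally missing cells, and the master seed.
#'
#' Defaults reproduce the study conditions of the Finnish 1997-2017 survey
#' series: five waves every five years, the published invited sample sizes and
#' questionnaire/examination response rates, ages 25-64 in five areas, and a
#' diabetes indicator that cannot be observed for non-medicated participants
#' of the 1997 and 2007 waves (no HbA1c assay), represented as the indicator
#' being forced missing in those waves.
#'
#' @param wave_years strictly increasing calendar years of the observed waves.
#' @param invited_n data frame with columns `year`, `sex`, `n`: invited
#'   individuals per wave and sex.
#' @param age_range closed integer age interval sampled uniformly.
#' @param n_areas number of geographical study areas.
#' @param trend_params named list of logit-scale coefficient vectors
#'   `c(intercept, year, male, age)` for each binary indicator and `marital`;
#'   for `bmi` and `education` a list of such vectors per non-reference
#'   category (reference: normal weight / basic education). The `year`
#'   coefficient is per calendar year since the first wave; `age` is per year
#'   of age centred at the midpoint of `age_range`.
#' @param dependence_params logit coefficients added for obese individuals:
#'   `c(diabetes_obesity, hypertension_obesity)`.
#' @param nonresponse list with components `unit` (data frame `year`, `sex`,
#'   `response_rate`), `unit_age_coef` (logit slope of response on centred
#'   age; the intercept is recalibrated so the marginal rate still matches),
#'   `examination` (data frame `year`, `sex`, `participation_rate`,
#'   unconditional; participants are drawn among questionnaire respondents),
#'   `item_rates` (named per-column missingness probabilities), and `item_mar`
#'   (optional `c(age, male)` logit shifts making item missingness depend on
#'   demographics).
#' @param structural_missing data frame `year`, `variable`: cells forced
#'   missing regardless of participation.
#' @param seed master integer seed.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(wave_years = c(1997, 2002, 2007, 2012, 2017),
                            invited_n = default_invited_n(wave_years),
                            age_range = c(25, 64),
                            n_areas = 5,
                            trend_params = default_trend_params(),
                            dependence_params = c(diabetes_obesity = 1.0,
                                                  hypertension_obesity = 0.8),
                            nonresponse = NULL,
                            structural_missing = data.frame(
                              year = c(1997, 2007),
                              variable = "diabetes"),
                            seed = 20400101) {
  if (length(wave_years) < 1 || is.unsorted(wave_years, strictly = TRUE))
    stop("wave_years must be strictly increasing")
  stopifnot(all(c("year", "sex", "n") %in% names(invited_n)),
            all(invited_n$n >= 0),
            length(age_range) == 2, age_range[1] <= age_range[2],
            n_areas >= 1)
  if (is.null(nonresponse)) {
    rates <- default_response_rates(wave_years)
    nonresponse <- list(unit = rates$unit,
                        unit_age_coef = 0,
                        examination = rates$examination,
                        item_rates = stats::setNames(
                          rep(0.02, length(SURVEY_COLUMNS)), SURVEY_COLUMNS),
                        item_mar = NULL)
  }
  cfg <- structure(
    list(wave_years = wave_years, invited_n = invited_n,
         age_range = age_range, n_areas = n_areas,
         trend_params = trend_params, dependence_params = dependence_params,
         nonresponse = nonresponse, structural_missing = structural_missing,
         seed = as.integer(seed)),
    class = "scenario_config")
  validate_trend_params(cfg)
  cfg
}

# All logits implied by the trend parameters must stay finite over the
# demographic grid, so the implied probabilities are inside (0, 1).
validate_trend_params <- function(cfg) {
  grid <- expand.grid(t = range(cfg$wave_years) - cfg$wave_years[1],
                      male = c(0, 1),
                      age_c = range(cfg$age_range) - mean(cfg$age_range))
  eval_one <- function(beta) {
    beta["intercept"] + beta["year"] * grid$t + beta["male"] * grid$male +
      beta["age"] * grid$age_c
  }
  flat <- unlist(lapply(cfg$trend_params, function(p) {
    if (is.list(p)) lapply(p, eval_one) else eval_one(p)
  }))
  if (!all(is.finite(flat)))
    stop("trend_params imply non-finite logits over the demographic grid")
  invisible(cfg)
}

# Empty survey frame with the full column schema.
new_survey_frame <- function(n = 0) {
  data.frame(
    year = integer(n),
    sex = factor(character(n), levels = SEX_LEVELS),
    age = integer(n),
    area = factor(character(n), levels = as.character(seq_len(99))),
    marital = rep(NA_integer_, n),
    education = factor(rep(NA_character_, n), levels = EDUCATION_LEVELS),
    smoking = rep(NA_integer_, n),
    sedentary = rep(NA_integer_, n),
    hypertension = rep(NA_integer_, n),
    elevated_tc = rep(NA_integer_, n),
    bmi_cat = factor(rep(NA_character_, n), levels = BMI_LEVELS),
    diabetes = rep(NA_integer_, n),
    participation = logical(n)
  )
}

#' Generate the sampling-frame rows for one survey wave
#'
#' Produces one row per invited individual with demographics (sex, age, area,
#' survey year) filled from the sampling frame and every survey-derived column
#' empty, ready for [simulate_indicators()].
#'
#' @param config a [scenario_config()].
#' @param year a wave year listed in `config$wave_years`.
#' @return a survey frame (data frame) with `sum(invited_n)` rows.
#' @export
generate_population_frame <- function(config, year) {
  stopifnot(inherits(config, "scenario_config"))
  if (!year %in% config$wave_years)
    stop("year ", year, " is not one of the configured wave years")
  tab <- config$invited_n[config$invited_n$year == year, ]
  n <- sum(tab$n)
  frame <- new_survey_frame(n)
  if (n == 0) return(frame)
  with_substream(config$seed, c("frame", year), {
    frame$year <- as.integer(year)
    frame$sex <- factor(rep(tab$sex, tab$n), levels = SEX_LEVELS)
    frame$age <- sample(seq(config$age_range[1], config$age_range[2]),
                        n, replace = TRUE)
    frame$area <- factor(sample(seq_len(config$n_areas), n, replace = TRUE),
                         levels = levels(frame$area))
    frame$participation <- NA
  })
  droplevels_area(frame, config$n_areas)
}

droplevels_area <- function(frame, n_areas) {
  frame$area <- factor(as.character(frame$area),
                       levels = as.character(seq_len(n_areas)))
  frame
}

# Linear predictor for one indicator given demographics.
trend_logit <- function(beta, t, male, age_c) {
  beta[["intercept"]] + beta[["year"]] * t + beta[["male"]] * male +
    beta[["age"]] * age_c
}

#' Simulate indicator values for a demographics-complete frame
#'
#' Draws the six risk-factor indicators plus marital status and education for
#' every row. Binary indicators follow Bernoulli draws on the logit scale with
#' a linear secular trend (per year since the first wave) and additive sex and
#' age effects; the BMI category follows a three-category multinomial logit
#' (reference: normal weight). Obesity feeds forward into the diabetes and
#' hypertension logits through `config$dependence_params`, emulating the known
#' dependence of those conditions on obesity.
#'
#' @param frame output of [generate_population_frame()] (demographics filled).
#' @param config the [scenario_config()] used to create the frame.
#' @return the frame with all survey columns filled (complete ground truth;
#'   apply [apply_nonresponse()] to obtain a realistic observed frame).
#' @export
simulate_indicators <- function(frame, config) {
  stopifnot(inherits(config, "scenario_config"))
  if (nrow(frame) == 0) return(frame)
  if (anyNA(frame$sex) || anyNA(frame$age) || anyNA(frame$year))
    stop("demographics (sex, age, year) must be complete before simulation")
  tp <- config$trend_params
  dep <- config$dependence_params
  out <- frame
  for (year in sort(unique(frame$year))) {
    idx <- which(frame$year == year)
    t <- year - config$wave_years[1]
    male <- as.integer(frame$sex[idx] == "male")
    age_c <- frame$age[idx] - mean(config$age_range)
    with_substream(config$seed, c("indicators", year), {
      # BMI first: obesity enters the diabetes and hypertension models
      eta_ow <- trend_logit(tp$bmi$overweight, t, male, age_c)
      eta_ob <- trend_logit(tp$bmi$obese, t, male, age_c)
      denom <- 1 + exp(eta_ow) + exp(eta_ob)
      prob <- cbind(1 / denom, exp(eta_ow) / denom, exp(eta_ob) / denom)
      out$bmi_cat[idx] <- factor(BMI_LEVELS[sample_categories(prob)],
                                  levels = BMI_LEVELS)
      obese <- as.integer(out$bmi_cat[idx] == "obese")

      draw_binary <- function(beta, extra = 0) {
        p <- stats::plogis(trend_logit(beta, t, male, age_c) + extra)
        stats::rbinom(length(idx), 1L, p)
      }
      out$smoking[idx] <- draw_binary(tp$smoking)
      out$sedentary[idx] <- draw_binary(tp$sedentary)
      out$hypertension[idx] <- draw_binary(
        tp$hypertension, dep[["hypertension_obesity"]] * obese)
      out$elevated_tc[idx] <- draw_binary(tp$elevated_tc)
      out$diabetes[idx] <- draw_binary(
        tp$diabetes, dep[["diabetes_obesity"]] * obese)
      out$marital[idx] <- draw_binary(tp$marital)

      eta_sec <- trend_logit(tp$education$secondary, t, male, age_c)
      eta_ter <- trend_logit(tp$education$tertiary, t, male, age_c)
      d2 <- 1 + exp(eta_sec) + exp(eta_ter)
      prob_edu <- cbind(1 / d2, exp(eta_sec) / d2, exp(eta_ter) / d2)
      out$education[idx] <- factor(EDUCATION_LEVELS[sample_categories(prob_edu)],
                                    levels = EDUCATION_LEVELS)
    })
  }
  out$participation <- TRUE
  out
}

# Solve the unit-response intercept so the marginal response probability over
# the realised ages equals the target rate when response depends on age.
calibrate_response_intercept <- function(rate, age_c, age_coef) {
  if (age_coef == 0 || rate <= 0 || rate >= 1) return(stats::qlogis(min(max(rate, 1e-12), 1 - 1e-12)))
  f <- function(b0) mean(stats::plogis(b0 + age_coef * age_c)) - rate
  stats::uniroot(f, interval = c(-20, 20))$root
}

#' Apply unit, examination, item, and structural non-response
#'
#' Unit non-respondents (questionnaire non-response) lose every survey-derived
#' column while keeping their sampling-frame demographics; among respondents,
#' examination non-participants additionally lose the measured columns (blood
#' pressure/cholesterol/BMI/HbA1c-based indicators); item non-response is
#' applied independently per column at the configured rates (MCAR by default,
#' optionally missing-at-random on age and sex); finally the structurally
#' missing cells (by default the diabetes indicator in the waves without an
#' HbA1c assay) are forced missing for everyone. The logical `participation`
#' column records questionnaire response.
#'
#' @param frame a fully simulated frame from [simulate_indicators()].
#' @param config the [scenario_config()].
#' @return the frame with missingness applied.
#' @export
apply_nonresponse <- function(frame, config) {
  stopifnot(inherits(config, "scenario_config"))
  if (nrow(frame) == 0) return(frame)
  nr <- config$nonresponse
  out <- frame
  for (year in sort(unique(frame$year))) {
    with_substream(config$seed, c("nonresponse", year), {
      for (sex in SEX_LEVELS) {
        idx <- which(frame$year == year & frame$sex == sex)
        if (!length(idx)) next
        age_c <- frame$age[idx] - mean(config$age_range)

        resp_rate <- nr$unit$response_rate[
          nr$unit$year == year & nr$unit$sex == sex]
        if (!length(resp_rate)) resp_rate <- 1
        b0 <- calibrate_response_intercept(resp_rate, age_c, nr$unit_age_coef)
        p_resp <- stats::plogis(b0 + nr$unit_age_coef * age_c)
        respond <- stats::runif(length(idx)) < p_resp
        out$participation[idx] <- respond
        nonresp <- idx[!respond]
        for (col in SURVEY_COLUMNS) out[[col]][nonresp] <- NA

        # examination participation nested within questionnaire response
        part_rate <- nr$examination$participation_rate[
          nr$examination$year == year & nr$examination$sex == sex]
        if (length(part_rate) && part_rate < resp_rate) {
          p_exam <- min(part_rate / resp_rate, 1)
          resp_idx <- idx[respond]
          skip_exam <- resp_idx[stats::runif(length(resp_idx)) >= p_exam]
          for (col in MEASURED_COLUMNS) out[[col]][skip_exam] <- NA
        }

        # item non-response among respondents
        resp_idx <- idx[respond]
        if (length(resp_idx)) {
          age_cr <- frame$age[resp_idx] - mean(config$age_range)
          male <- as.integer(sex == "male")
          for (col in SURVEY_COLUMNS) {
            rate <- nr$item_rates[[col]]
            if (is.null(rate) || rate <= 0) next
            eta <- stats::qlogis(rate)
            if (!is.null(nr$item_mar))
              eta <- eta + nr$item_mar[["age"]] * age_cr +
                nr$item_mar[["male"]] * male
            hit <- resp_idx[stats::runif(length(resp_idx)) < stats::plogis(eta)]
            out[[col]][hit] <- NA
          }
        }
      }
    })
  }
  for (k in seq_len(nrow(config$structural_missing))) {
    y <- config$structural_missing$year[k]
    v <- config$structural_missing$variable[k]
    out[[v]][out$year == y] <- NA
  }
  out
}

#' Generate a synthetic population projection table
#'
#' Returns per-year age and sex weights over the configured age range,
#' normalised to sum to one within each year. The uniform scenario gives each
#' (sex, age) cell equal weight; a positive `ageing_drift` tilts the age
#' distribution progressively older in later years (an exponential tilt of
#' `exp(drift * (year - first wave) * centred age)`), emulating projected
#' population ageing.
#'
#' @param config a [scenario_config()].
#' @param years calendar years to cover (observed and/or future).
#' @param ageing_drift per-(year x age-year) log-weight tilt; 0 gives the
#'   uniform scenario.
#' @return a data frame `year`, `sex`, `age`, `weight` of class
#'   `population_projection`.
#' @export
generate_population_projection <- function(config, years, ageing_drift = 0) {
  stopifnot(inherits(config, "scenario_config"), length(years) >= 1)
  ages <- seq(config$age_range[1], config$age_range[2])
  grid <- expand.grid(age = ages, sex = SEX_LEVELS, year = as.integer(years),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  age_c <- grid$age - mean(config$age_range)
  t <- grid$year - config$wave_years[1]
  w <- exp(ageing_drift * t * age_c)
  grid$weight <- as.numeric(stats::ave(w, grid$year, FUN = function(x) x / sum(x)))
  out <- grid[, c("year", "sex", "age", "weight")]
  class(out) <- c("population_projection", "data.frame")
  out
}

#' Generate the complete observed multi-wave survey frame
#'
#' Convenience wrapper running [generate_population_frame()],
#' [simulate_indicators()] and [apply_nonresponse()] for every configured
#' wave and binding the results.
#'
#' @param config a [scenario_config()].
#' @param nonresponse apply the non-response mechanism (set `FALSE` to keep
#'   the complete ground truth).
#' @return a survey frame covering all waves.
#' @export
generate_survey_series <- function(config, nonresponse = TRUE) {
  waves <- lapply(config$wave_years, function(y) {
    f <- simulate_indicators(generate_population_frame(config, y), config)
    if (nonresponse) f <- apply_nonresponse(f, config)
    f
  })
  do.call(rbind, waves)
}

#' BMI trend parameters for a polarisation scenario
#'
#' Constructs multinomial-logit BMI trend parameters in which the
#' normal-weight share stays (almost) constant while probability mass drifts
#' from overweight to obese: the overweight and obese logits drift in opposite
#' directions at the same rate, crossing at `mid_year`. Around the crossing
#' the summed odds of the two non-normal categories are nearly constant, so
#' the normal-weight share moves by well under a percentage point for the
#' default drift while obesity rises by roughly fourteen points over
#' 1997-2040.
#'
#' @param normal_share normal-weight share at `mid_year`.
#' @param drift per-year opposite drift of the overweight/obese logits.
#' @param mid_year calendar year at which the two categories have equal odds.
#' @param base_year first wave year (trend intercepts refer to it).
#' @param male,age sex and age coefficients shared by both categories.
#' @return a list with `overweight` and `obese` coefficient vectors, suitable
#'   as the `bmi` entry of `trend_params` in [scenario_config()].
#' @export
bmi_polarisation_params <- function(normal_share = 0.45, drift = 0.012,
                                    mid_year = 2018.5, base_year = 1997,
                                    male = 0, age = 0) {
  stopifnot(normal_share > 0, normal_share < 1, drift >= 0)
  odds_each <- (1 - normal_share) / normal_share / 2
  offset <- mid_year - base_year
  list(
    overweight = c(intercept = log(odds_each) + drift * offset,
                   year = -drift, male = male, age = age),
    obese = c(intercept = log(odds_each) - drift * offset,
              year = drift, male = male, age = age)
  )
}
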