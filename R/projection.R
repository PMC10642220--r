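# Projection pipeline: future pseudo-samples matched to a population
# projection are appended to the observed frame as fully missing data, the
# imputation engine fills them, and prevalences are pooled by indicator, sex
# and year with Wilson score intervals as prediction intervals.

#' Specification of the future pseudo-samples
#'
#' @param years projection years (default 2020-2040 annually; a 5-year grid
#'   is a cheaper alternative).
#' @param n_per_year pseudo-sample size per projection year (default 10,000).
#' @param projection a population projection table (`year`, `sex`, `age`,
#'   `weight`) covering every requested year and the analysis age range,
#'   e.g. from [generate_population_projection()].
#' @param mode `"allocate"` (deterministic largest-remainder allocation of
#'   the `n_per_year` rows to the age/sex cells, the default: one less
#'   Monte-Carlo layer) or `"sample"` (multinomial sampling of cells).
#' @return an object of class `future_sample_spec`.
#' @export
future_sample_spec <- function(years = 2020:2040, n_per_year = 10000,
                               projection, mode = c("allocate", "sample")) {
  mode <- match.arg(mode)
  stopifnot(length(years) >= 1, n_per_year >= 1)
  missing_years <- setdiff(years, unique(projection$year))
  if (length(missing_years))
    stop("projection table lacks year(s): ",
         paste(missing_years, collapse = ", "))
  structure(list(years = as.integer(years),
                 n_per_year = as.integer(n_per_year),
                 projection = projection, mode = mode),
            class = "future_sample_spec")
}

#' Build the future pseudo-sample frame
#'
#' For each projection year, `n_per_year` rows receive sex and age according
#' to the population projection weights; every survey-derived column (and
#' area) is missing, to be filled by the imputation engine.
#'
#' @param spec a [future_sample_spec()].
#' @param seed seed for the `"sample"` mode (ignored under allocation).
#' @return a survey frame of `length(years) * n_per_year` rows.
#' @export
build_future_samples <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "future_sample_spec"))
  proj <- spec$projection
  frames <- lapply(spec$years, function(y) {
    cells <- proj[proj$year == y, ]
    if (!nrow(cells)) stop("projection table lacks year ", y)
    if (any(cells$weight < 0)) stop("negative projection weight in year ", y)
    counts <- if (spec$mode == "allocate") {
      largest_remainder(cells$weight, spec$n_per_year)
    } else {
      with_substream(seed, c("future", y), {
        drop(stats::rmultinom(1, spec$n_per_year,
                              cells$weight / sum(cells$weight)))
      })
    }
    f <- new_survey_frame(sum(counts))
    f$year <- as.integer(y)
    f$sex <- factor(rep(as.character(cells$sex), counts), levels = SEX_LEVELS)
    f$age <- rep(cells$age, counts)
    f$area <- factor(NA_character_, levels = levels(f$area))
    f$participation <- FALSE
    f
  })
  do.call(rbind, frames)
}

#' Concatenate observed and future frames into the joint imputation frame
#'
#' @param observed survey frame of the observed waves.
#' @param future survey frame from [build_future_samples()].
#' @return the row-bound frame with a `source` column
#'   (`"observed"`/`"future"`).
#' @export
assemble_joint_frame <- function(observed, future) {
  obs_cols <- setdiff(names(observed), "source")
  fut_cols <- setdiff(names(future), "source")
  if (!identical(sort(obs_cols), sort(fut_cols))) {
    diff <- union(setdiff(obs_cols, fut_cols), setdiff(fut_cols, obs_cols))
    stop("column schemas differ: ", paste(diff, collapse = ", "))
  }
  observed$source <- "observed"
  future <- future[, names(observed)[names(observed) != "source"]]
  future$source <- "future"
  out <- rbind(observed, future)
  rownames(out) <- NULL
  out
}

#' Pool prevalences over the completed datasets
#'
#' Per stratum (by default sex by year), the prevalence of a binary indicator
#' is the mean over the `m` imputations of the within-imputation proportion;
#' for the BMI category each level becomes its own row (labelled
#' `bmi_normal`, `bmi_overweight`, `bmi_obese`) and the per-stratum level
#' prevalences sum to one. The between-imputation variance of the proportion
#' is reported alongside.
#'
#' @param completed a `completed_set` from [run_chain()].
#' @param indicator column name (binary indicator or `"bmi_cat"`).
#' @param by stratification columns.
#' @return a data frame: `indicator`, strata, `prevalence`, `n_effective`,
#'   `between_var`.
#' @export
pool_prevalence <- function(completed, indicator, by = c("sex", "year")) {
  stopifnot(inherits(completed, "completed_set"))
  frames <- completed$imputations
  if (is.null(frames[[1]][[indicator]]))
    stop("indicator '", indicator, "' not present in the completed frames")
  f1 <- frames[[1]]
  strata <- unique(f1[by])
  strata <- strata[do.call(order, strata), , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(strata))) {
    sel <- rep(TRUE, nrow(f1))
    for (b in by) sel <- sel & f1[[b]] == strata[[b]][r]
    n_eff <- sum(sel)
    if (n_eff == 0) {
      warning("empty stratum: ",
              paste(b, "=", unlist(strata[r, ]), collapse = ", "))
      next
    }
    if (is.factor(f1[[indicator]])) {
      for (lv in levels(f1[[indicator]])) {
        props <- vapply(frames,
                        function(f) mean(f[[indicator]][sel] == lv),
                        numeric(1))
        out[[length(out) + 1]] <- data.frame(
          indicator = paste0("bmi_", lv), strata[r, , drop = FALSE],
          prevalence = mean(props), n_effective = n_eff,
          between_var = if (length(props) > 1) stats::var(props) else 0)
      }
    } else {
      props <- vapply(frames, function(f) mean(f[[indicator]][sel]),
                      numeric(1))
      out[[length(out) + 1]] <- data.frame(
        indicator = indicator, strata[r, , drop = FALSE],
        prevalence = mean(props), n_effective = n_eff,
        between_var = if (length(props) > 1) stats::var(props) else 0)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Wilson score interval for a binomial proportion
#'
#' `centre = (p + z^2/2n) / (1 + z^2/n)`,
#' `half-width = z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n)`; the interval
#' is always inside `[0, 1]` and behaves well near the boundaries, which is
#' why it serves as the prediction interval of the pooled prevalences.
#'
#' @param p proportion(s) in `[0, 1]`.
#' @param n effective count(s), at least 1.
#' @param level confidence level in (0, 1).
#' @return a data frame with columns `low`, `high` (vectorised over `p`, `n`).
#' @export
wilson_interval <- function(p, n, level = 0.95) {
  if (any(level <= 0) || any(level >= 1)) stop("level must be inside (0, 1)")
  stopifnot(all(p >= 0 & p <= 1), all(n >= 1))
  z <- stats::qnorm((1 + level) / 2)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  data.frame(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' Run the full prevalence projection
#'
#' End-to-end: append the future pseudo-samples to the observed frame, run
#' chained-equations multiple imputation over the joint frame, pool the
#' requested indicators by sex and year, and attach Wilson prediction
#' intervals (with `n` equal to the stratum row count). Observed-year rows
#' are labelled `observed-imputed` (they are non-response-corrected, being
#' computed on the imputed full invited sample); projection-year rows are
#' labelled `projected`.
#'
#' @param observed survey frame of the observed waves.
#' @param specs list of [imputation_spec()]s (e.g. from [select_all_specs()]
#'   or [default_specs()]).
#' @param future_spec a [future_sample_spec()].
#' @param config a [mice_config()].
#' @param indicators indicators to pool (defaults to the spec targets other
#'   than the auxiliary covariates).
#' @param level confidence level of the Wilson intervals.
#' @return an object of class `prevalence_series` (data frame with columns
#'   `indicator`, `sex`, `year`, `prevalence`, `interval_low`,
#'   `interval_high`, `n_effective`, `between_var`, `source`); the
#'   `completed_set` is attached as attribute `completed`.
#' @export
run_projection <- function(observed, specs, future_spec,
                           config = mice_config(), indicators = NULL,
                           level = 0.95) {
  specs <- as_spec_list(specs)
  if (is.null(indicators))
    indicators <- intersect(names(specs),
                            c(BINARY_INDICATORS, "bmi_cat"))
  future <- build_future_samples(future_spec, seed = config$seed)
  joint <- assemble_joint_frame(observed, future)
  completed <- run_chain(joint, specs, config)
  last_observed <- max(observed$year)
  series <- do.call(rbind, lapply(indicators, function(ind) {
    pooled <- pool_prevalence(completed, ind, by = c("sex", "year"))
    ci <- wilson_interval(pooled$prevalence, pooled$n_effective, level)
    pooled$interval_low <- ci$low
    pooled$interval_high <- ci$high
    pooled$source <- ifelse(pooled$year > last_observed,
                            "projected", "observed-imputed")
    pooled
  }))
  series <- series[, c("indicator", "sex", "year", "prevalence",
                       "interval_low", "interval_high", "n_effective",
                       "between_var", "source")]
  rownames(series) <- NULL
  class(series) <- c("prevalence_series", "data.frame")
  attr(series, "completed") <- completed
  series
}
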