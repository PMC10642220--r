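# Choice of imputation models: predictor subsets and the functional form of
# the secular (survey-year) trend, scored by the Bayesian information
# criterion on complete cases of the observed waves.

#' Bayesian information criterion of a fitted imputation model
#'
#' `BIC = k * ln(n) - 2 * ln(L)` with `k` the parameter count, `n` the
#' sample size and `L` the maximised likelihood. Lower is better.
#'
#' @param fit an object carrying `loglik`, `k`, `n` (e.g. a
#'   [fit_binary_model()] or [fit_polytomous_model()] result).
#' @return the BIC score (numeric scalar).
#' @export
bic <- function(fit) {
  if (is.null(fit$n) || fit$n <= 0) stop("fit must carry a positive sample size")
  fit$k * log(fit$n) - 2 * fit$loglik
}

#' Restricted (natural) cubic spline basis
#'
#' Natural cubic spline basis over the given knots: `k` knots yield `k - 1`
#' basis columns spanning the linear function, with continuity and continuous
#' second derivatives at the knots and linearity beyond the boundary knots —
#' the property that keeps extrapolation to future survey years tame.
#' Built on [splines::ns] with the outer knots as boundary knots.
#'
#' @param x evaluation points (e.g. survey years).
#' @param knots at least 3 distinct knot locations.
#' @return a matrix with `length(knots) - 1` columns.
#' @export
spline_basis <- function(x, knots) {
  knots <- sort(as.numeric(knots))
  if (length(knots) < 3) stop("need at least 3 knots")
  if (anyDuplicated(knots)) stop("duplicate knots")
  splines::ns(as.numeric(x), knots = knots[-c(1, length(knots))],
              Boundary.knots = knots[c(1, length(knots))])
}

#' Default spline knots for the survey-year trend
#'
#' Knots at the 10th, 50th and 90th percentiles of the observed survey years
#' (with five equally sized waves: the first, middle and last wave).
#'
#' @param years vector of observed survey years (one entry per row).
#' @return numeric vector of 3 knots.
#' @export
default_year_knots <- function(years) {
  as.numeric(stats::quantile(as.numeric(years), c(0.1, 0.5, 0.9), names = FALSE))
}

#' Candidate space for imputation-model selection
#'
#' @param target the variable whose imputation model is being chosen.
#' @param optional predictors to search over (the other indicators, area,
#'   marital status, education); the mandatory set (age, sex, year) is always
#'   included.
#' @param mandatory always-included predictors.
#' @param knots spline knots for the non-linear year form (`NULL`: derived
#'   from the data at selection time via [default_year_knots()]).
#' @return an object of class `candidate_space`.
#' @export
candidate_space <- function(target, optional = character(0),
                            mandatory = c("age", "sex", "year"),
                            knots = NULL) {
  if (target %in% optional) stop("target cannot be an optional predictor")
  if (!is.null(knots) && length(knots) < 3)
    stop("spline form requires at least 3 knots")
  structure(list(target = target, mandatory = mandatory, optional = optional,
                 knots = knots),
            class = "candidate_space")
}

fit_candidate <- function(y, data, predictors, sampler, year_form, knots) {
  X <- design_matrix(data, predictors, year_form, knots)
  if (sampler == "logistic") fit_binary_model(as.integer(y), X)
  else fit_polytomous_model(y, X)
}

#' Select an imputation model by BIC
#'
#' Exhaustively scores every subset of the optional predictors (the search
#' space is at most a few hundred models at this scale) on complete cases of
#' the observed waves with a linear year term, keeps the minimum-BIC subset,
#' then compares the linear year form against a restricted-cubic-spline year
#' form within that subset. Ties (within `1e-9`) go to the smaller model, and
#' among equal sizes to the lexicographically first predictor set; a spline
#' form must strictly beat the linear form to be chosen.
#'
#' @param target variable to model (binary 0/1 or factor).
#' @param space a [candidate_space()].
#' @param data complete-case data of the observed waves (rows with the target
#'   or any candidate predictor missing are dropped internally).
#' @param sampler `"logistic"` or `"polytomous"`; default chosen from the
#'   target's type.
#' @return an [imputation_spec()] with attributes `bic_table` (all scored
#'   candidates) and `bic` (winning score).
#' @export
select_spec <- function(target, space, data, sampler = NULL) {
  stopifnot(inherits(space, "candidate_space"))
  y0 <- data[[target]]
  if (is.null(y0)) stop("target '", target, "' not in data")
  if (is.null(sampler))
    sampler <- if (is.factor(y0)) "polytomous" else "logistic"

  vars <- unique(c(target, space$mandatory, space$optional))
  cc <- stats::complete.cases(data[vars])
  dat <- data[cc, vars, drop = FALSE]
  y <- if (is.factor(y0)) droplevels_keep(y0[cc]) else y0[cc]

  n_opt <- length(space$optional)
  subsets <- lapply(seq_len(2^n_opt) - 1L, function(code) {
    space$optional[bitwAnd(code, bitwShiftL(1L, seq_len(n_opt) - 1L)) > 0]
  })
  # order: smaller subsets first, then lexicographic => the first strict
  # minimum encountered realises the tie-breaking rule
  key <- vapply(subsets, function(s) paste(sort(s), collapse = ","), "")
  ord <- order(lengths(subsets), key)
  subsets <- subsets[ord]

  biggest_k <- 1 + length(space$mandatory) + n_opt + 2  # rough upper bound
  if (nrow(dat) <= 10 * biggest_k)
    stop("too few complete cases (", nrow(dat), ") for the largest candidate")

  best <- NULL
  rows <- list()
  for (s in subsets) {
    preds <- c(space$mandatory, s)
    fit <- fit_candidate(y, dat, preds, sampler, "linear", NULL)
    score <- bic(fit)
    rows[[length(rows) + 1]] <- data.frame(
      predictors = paste(preds, collapse = "+"), year_form = "linear",
      k = fit$k, bic = score)
    if (is.null(best) || score < best$score - 1e-9)
      best <- list(preds = preds, score = score)
  }

  year_form <- "linear"
  knots <- NULL
  if ("year" %in% space$mandatory &&
      length(unique(dat$year)) >= 3) {
    kn <- if (is.null(space$knots)) default_year_knots(dat$year) else space$knots
    if (length(unique(kn)) >= 3) {
      fit_s <- fit_candidate(y, dat, best$preds, sampler, "spline", kn)
      score_s <- bic(fit_s)
      rows[[length(rows) + 1]] <- data.frame(
        predictors = paste(best$preds, collapse = "+"), year_form = "spline",
        k = fit_s$k, bic = score_s)
      if (score_s < best$score - 1e-9) {
        year_form <- "spline"
        knots <- kn
        best$score <- score_s
      }
    }
  }

  spec <- imputation_spec(target, sampler, best$preds, year_form, knots)
  attr(spec, "bic_table") <- do.call(rbind, rows)
  attr(spec, "bic") <- best$score
  spec
}

#' Select imputation models for every incomplete indicator
#'
#' Runs [select_spec()] per indicator on the observed waves, with the other
#' five indicators (plus area, marital status and education) as optional
#' predictors, and returns the spec list for [run_chain()]. Marital status
#' and education themselves get mandatory-only specs (they are imputed as
#' auxiliary covariates, not selected over).
#'
#' @param observed survey frame of the observed waves.
#' @param targets indicators to select models for.
#' @param optional_extra additional optional predictors beyond the other
#'   indicators (default area, marital, education).
#' @return a named list of [imputation_spec()]s.
#' @export
select_all_specs <- function(observed,
                             targets = c(BINARY_INDICATORS, "bmi_cat"),
                             optional_extra = c("area", "marital",
                                                "education")) {
  specs <- lapply(targets, function(tg) {
    others <- setdiff(c(BINARY_INDICATORS, "bmi_cat"), tg)
    select_spec(tg, candidate_space(tg, c(others, optional_extra)), observed)
  })
  names(specs) <- targets
  aux <- list(
    marital = imputation_spec("marital", "logistic", c("age", "sex", "year")),
    education = imputation_spec("education", "polytomous",
                                c("age", "sex", "year")))
  specs <- c(specs, aux[setdiff(names(aux), targets)])
  # any selected predictor that is itself incomplete needs a spec too:
  # give it a mandatory-only model of the matching sampler family
  chosen <- unique(unlist(lapply(specs, `[[`, "predictors")))
  needs <- setdiff(chosen[vapply(chosen, function(p) anyNA(observed[[p]]),
                                 logical(1))], names(specs))
  for (p in needs) {
    sampler <- if (is.factor(observed[[p]])) "polytomous" else "logistic"
    specs[[p]] <- imputation_spec(p, sampler, c("age", "sex", "year"))
  }
  specs
}
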