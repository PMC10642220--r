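# Chained-equations (fully conditional specification) multiple imputation
# with logistic and polytomous-logistic samplers.
#
# The engine fills item and unit non-response in the observed waves and the
# entirely unobserved future pseudo-samples in one combined frame. Each
# incomplete variable gets a conditional model fitted on the rows where it
# was observed; parameters are drawn (posterior-normal or bootstrap) to
# propagate estimation uncertainty; missing cells are redrawn from the
# resulting predictive distribution; and the cycle repeats for a fixed number
# of sweeps per imputation stream.

#' Imputation model specification for one target variable
#'
#' @param target name of the variable to impute.
#' @param sampler `"logistic"` for binary targets, `"polytomous"` for
#'   categorical ones.
#' @param predictors character vector of predictor variable names (may
#'   include `"year"`, `"age"`, `"sex"`, `"area"`, `"marital"`, `"education"`
#'   and the other indicators).
#' @param year_form `"linear"` or `"spline"` (restricted cubic spline in the
#'   survey year, linear beyond the boundary knots so extrapolation to future
#'   years stays tame).
#' @param knots spline knots (calendar years); required when
#'   `year_form = "spline"`.
#' @return an object of class `imputation_spec`.
#' @export
imputation_spec <- function(target, sampler = c("logistic", "polytomous"),
                            predictors, year_form = c("linear", "spline"),
                            knots = NULL) {
  sampler <- match.arg(sampler)
  year_form <- match.arg(year_form)
  if (target %in% predictors)
    stop("target '", target, "' cannot be among its own predictors")
  if (year_form == "spline" && (is.null(knots) || length(knots) < 3))
    stop("spline year form requires at least 3 knots")
  structure(list(target = target, sampler = sampler,
                 predictors = predictors, year_form = year_form,
                 knots = knots),
            class = "imputation_spec")
}

#' Configuration of a multiple-imputation run
#'
#' @param m number of completed datasets (default 100).
#' @param iterations sweeps of the chained-equations cycle per stream
#'   (default 10).
#' @param seed master integer seed; each of the `m` streams derives its own
#'   substream, so results do not depend on execution order.
#' @param parameter_draw named character vector selecting how parameter
#'   uncertainty is propagated per sampler family: `"posterior"`
#'   (multivariate-normal draw around the MLE) or `"bootstrap"`
#'   (refit on a resample).
#' @return an object of class `mice_config`.
#' @export
mice_config <- function(m = 100, iterations = 10, seed = 1L,
                        parameter_draw = c(logistic = "posterior",
                                           polytomous = "bootstrap")) {
  stopifnot(m >= 1, iterations >= 1,
            all(parameter_draw %in% c("posterior", "bootstrap")))
  structure(list(m = as.integer(m), iterations = as.integer(iterations),
                 seed = as.integer(seed), parameter_draw = parameter_draw),
            class = "mice_config")
}

# --- design matrices -------------------------------------------------------

# Build the model matrix for a spec's predictors on (currently complete)
# data. The year enters either linearly or through a restricted cubic spline
# with fixed knots, so the same basis is used for fitting on observed waves
# and for prediction at future years.
design_matrix <- function(data, predictors, year_form = "linear",
                          knots = NULL) {
  cols <- list(`(Intercept)` = rep(1, nrow(data)))
  for (p in predictors) {
    v <- data[[p]]
    if (is.null(v)) stop("predictor '", p, "' not found in data")
    if (p == "year" && year_form == "spline") {
      b <- spline_basis(as.numeric(v), knots)
      colnames(b) <- paste0("year_rcs", seq_len(ncol(b)))
      cols[[p]] <- b
    } else if (is.factor(v)) {
      v <- droplevels(v)
      if (nlevels(v) < 2) next
      mm <- stats::model.matrix(~x, data.frame(x = v))[, -1, drop = FALSE]
      colnames(mm) <- paste0(p, levels(v)[-1])
      cols[[p]] <- mm
    } else {
      cols[[p]] <- as.numeric(v)
    }
  }
  out <- do.call(cbind, cols)
  colnames(out)[1] <- "(Intercept)"
  out
}

# --- binary (logistic) sampler --------------------------------------------

#' Fit a maximum-likelihood logistic regression by IRLS
#'
#' Newton/IRLS fit with the observed-information covariance. Perfect or
#' quasi-perfect separation and rank deficiency are detected and handled by
#' an escalating ridge penalty (scaled to the sample size) rather than an
#' abort, since sparse cells are expected once future pseudo-samples enter
#' the frame; the fallback is flagged on the returned object.
#'
#' @param y binary 0/1 response (no NA).
#' @param X design matrix including the intercept column.
#' @param ridge initial ridge penalty (0 = plain MLE).
#' @param max_iter,tol Newton iteration controls.
#' @return an object of class `binfit` with elements `coef`, `vcov`,
#'   `loglik`, `k`, `n`, `separation`, `ridge`, and the training `y`, `X`
#'   (kept for bootstrap redraws).
#' @export
fit_binary_model <- function(y, X, ridge = 0, max_iter = 50, tol = 1e-8) {
  stopifnot(is.matrix(X), length(y) == nrow(X), !anyNA(y))
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    stop("binary response has a single observed class; cannot fit")
  p <- ncol(X)
  n <- nrow(X)
  irls <- function(lambda) {
    beta <- rep(0, p)
    pen <- diag(lambda, p)
    pen[1, 1] <- 0  # never penalise the intercept
    for (it in seq_len(max_iter)) {
      eta <- drop(X %*% beta)
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      H <- crossprod(X, X * w) + pen
      g <- crossprod(X, y - mu) - lambda * c(0, beta[-1])
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step)) return(list(ok = FALSE, singular = TRUE))
      beta <- beta + drop(step)
      if (max(abs(step)) < tol)
        return(list(ok = TRUE, beta = beta, H = H,
                    diverged = max(abs(drop(X %*% beta))) > 30))
    }
    list(ok = FALSE, singular = FALSE)
  }
  separation <- FALSE
  lambda <- ridge
  res <- irls(lambda)
  while ((!res$ok || isTRUE(res$diverged)) && lambda < n) {
    separation <- TRUE
    lambda <- if (lambda == 0) 1e-4 * n else lambda * 100
    res <- irls(lambda)
  }
  if (!res$ok) stop("logistic fit failed to converge even with ridge penalty")
  beta <- res$beta
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  loglik <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  structure(list(coef = stats::setNames(drop(beta), colnames(X)),
                 vcov = solve(res$H), loglik = loglik, k = p, n = n,
                 separation = separation, ridge = lambda,
                 y = y, X = X),
            class = "binfit")
}

#' Draw one parameter vector from a fitted imputation model
#'
#' Posterior-normal mode draws from a multivariate normal centred at the MLE
#' with the fit's covariance (repaired to the nearest positive-definite
#' matrix if needed, with a flag); bootstrap mode refits the model on a
#' resample of its training rows.
#'
#' @param fit a `binfit` or `polyfit`.
#' @param mode `"posterior"` or `"bootstrap"`.
#' @return for `binfit`, a named coefficient vector; for `polyfit`, a
#'   coefficient matrix (rows = non-reference categories).
#' @export
draw_parameters <- function(fit, mode = c("posterior", "bootstrap")) {
  UseMethod("draw_parameters")
}

#' @export
draw_parameters.binfit <- function(fit, mode = c("posterior", "bootstrap")) {
  mode <- match.arg(mode)
  if (mode == "bootstrap") {
    idx <- sample.int(fit$n, fit$n, replace = TRUE)
    refit <- fit_binary_model(fit$y[idx], fit$X[idx, , drop = FALSE],
                              ridge = if (fit$separation) fit$ridge else 0)
    return(refit$coef)
  }
  if (all(fit$vcov == 0)) return(fit$coef)  # degenerate: draw is the MLE
  V <- repair_pd(fit$vcov)
  L <- chol(V)
  stats::setNames(fit$coef + drop(t(L) %*% stats::rnorm(length(fit$coef))),
                  names(fit$coef))
}

# Clip negative eigenvalues to restore positive definiteness.
repair_pd <- function(V, eps = 1e-10) {
  V <- (V + t(V)) / 2
  ok <- tryCatch({ chol(V); TRUE }, error = function(e) FALSE)
  if (ok) return(V)
  e <- eigen(V, symmetric = TRUE)
  lam <- pmax(e$values, eps)
  V2 <- e$vectors %*% (lam * t(e$vectors))
  (V2 + t(V2)) / 2
}

#' Impute missing cells of a binary variable
#'
#' Missing cells are redrawn as Bernoulli with probability
#' `plogis(X beta)`; observed cells are never touched.
#'
#' @param y binary vector with NA at the cells to impute.
#' @param X design matrix (all rows complete).
#' @param beta coefficient vector (typically a [draw_parameters()] draw).
#' @return `y` with the missing cells filled.
#' @export
impute_binary <- function(y, X, beta) {
  miss <- which(is.na(y))
  if (!length(miss)) return(y)
  p <- stats::plogis(drop(X[miss, , drop = FALSE] %*% beta))
  y[miss] <- stats::rbinom(length(miss), 1L, p)
  y
}

# --- polytomous (multinomial) sampler -------------------------------------

#' Fit a polytomous (multinomial) logistic regression
#'
#' Multinomial-logit fit on complete cases via [nnet::multinom] with the
#' first factor level as the reference category (its log-odds are identically
#' zero). Coefficients are returned as a matrix over the design columns so
#' that prediction at arbitrary rows is a plain matrix product.
#'
#' @param y factor response (no NA); every level must be present.
#' @param X design matrix including the intercept column.
#' @return an object of class `polyfit` with `coef` (matrix, rows =
#'   non-reference levels), `loglik`, `k`, `n`, `levels`, and the training
#'   data for bootstrap redraws.
#' @export
fit_polytomous_model <- function(y, X) {
  stopifnot(is.factor(y), !anyNA(y), is.matrix(X), nrow(X) == length(y))
  tab <- table(y)
  if (any(tab == 0))
    stop("category '", names(tab)[tab == 0][1],
         "' has no observations among complete cases")
  Xd <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  safe <- make.names(colnames(Xd), unique = TRUE)
  df <- as.data.frame(Xd)
  names(df) <- safe
  df$.y <- y
  fml <- stats::as.formula(paste(".y ~", paste(c("1", safe), collapse = " + ")))
  fit <- nnet::multinom(fml, data = df, trace = FALSE, maxit = 500)
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                     dimnames = list(levels(y)[2], names(cf)))
  # reorder columns to match the design matrix (intercept first)
  cf <- cf[, c("(Intercept)", safe), drop = FALSE]
  colnames(cf) <- colnames(X)
  ll <- as.numeric(stats::logLik(fit))
  structure(list(coef = cf, loglik = ll,
                 k = length(cf), n = length(y),
                 levels = levels(y), y = y, X = X),
            class = "polyfit")
}

#' @export
draw_parameters.polyfit <- function(fit, mode = c("bootstrap", "posterior")) {
  mode <- match.arg(mode)
  if (mode == "bootstrap") {
    for (try in 1:25) {
      idx <- sample.int(fit$n, fit$n, replace = TRUE)
      yb <- fit$y[idx]
      if (all(table(yb) > 0)) {
        refit <- fit_polytomous_model(yb, fit$X[idx, , drop = FALSE])
        return(refit$coef)
      }
    }
    stop("bootstrap resample kept losing a category after 25 attempts")
  }
  # posterior-normal on the vectorised coefficients; covariance from the
  # observed information of the multinomial likelihood
  V <- repair_pd(polytomous_vcov(fit))
  L <- chol(V)
  draw <- as.vector(t(fit$coef)) + drop(t(L) %*% stats::rnorm(length(fit$coef)))
  matrix(draw, nrow = nrow(fit$coef), byrow = TRUE,
         dimnames = dimnames(fit$coef))
}

# Observed information of the multinomial logit at the MLE, ordered to match
# vec(t(coef)) (per-category coefficient blocks).
polytomous_vcov <- function(fit) {
  P <- polytomous_probs(fit$X, fit$coef)
  K1 <- nrow(fit$coef)
  p <- ncol(fit$X)
  H <- matrix(0, K1 * p, K1 * p)
  for (a in seq_len(K1)) {
    for (b in seq_len(K1)) {
      w <- if (a == b) P[, a + 1] * (1 - P[, a + 1]) else -P[, a + 1] * P[, b + 1]
      blk <- crossprod(fit$X, fit$X * w)
      ra <- (a - 1) * p + seq_len(p)
      rb <- (b - 1) * p + seq_len(p)
      H[ra, rb] <- blk
    }
  }
  solve(H + diag(1e-10, nrow(H)))
}

# Row-wise category probabilities (first column = reference level).
polytomous_probs <- function(X, coefmat) {
  eta <- X %*% t(coefmat)
  expEta <- exp(cbind(0, eta))
  expEta / rowSums(expEta)
}

#' Impute missing cells of a categorical variable
#'
#' Missing cells are drawn from the multinomial predictive distribution
#' implied by a coefficient matrix (reference category first level).
#'
#' @param y factor with NA at the cells to impute.
#' @param X design matrix (all rows complete).
#' @param coefmat coefficient matrix from [fit_polytomous_model()] or a
#'   [draw_parameters()] draw.
#' @return `y` with the missing cells filled.
#' @export
impute_polytomous <- function(y, X, coefmat) {
  miss <- which(is.na(y))
  if (!length(miss)) return(y)
  P <- polytomous_probs(X[miss, , drop = FALSE], coefmat)
  y[miss] <- factor(levels(y)[sample_categories(P)], levels = levels(y))
  y
}

# --- the chain -------------------------------------------------------------

#' Run chained-equations multiple imputation
#'
#' For each of the `m` streams: missing cells are initialised by sampling
#' observed values of the same variable (within the same sex stratum, when
#' observed values exist there); then for `iterations` sweeps the targets are
#' visited in order of ascending missingness, each being refitted on its
#' originally observed rows with the other variables at their current
#' (partly imputed) values, parameters drawn, and the originally missing
#' cells redrawn. Observed cells are never modified.
#'
#' @param frame a survey frame (may include future pseudo-sample rows).
#' @param specs list of [imputation_spec()]s covering every incomplete
#'   variable used anywhere as target or predictor. Fully observed variables
#'   (age, sex, survey year, area in the observed waves) need no spec.
#' @param config a [mice_config()].
#' @param visit_order optional explicit target ordering; the default orders
#'   targets by ascending fraction of missing cells.
#' @return an object of class `completed_set`: list with `imputations`
#'   (list of `m` completed frames), `chain_means` (array target x iteration
#'   x stream of the means of the imputed cells, categorical targets coded by
#'   level index), `specs`, `config`.
#' @export
run_chain <- function(frame, specs, config = mice_config(),
                      visit_order = NULL) {
  stopifnot(inherits(config, "mice_config"))
  specs <- as_spec_list(specs)
  targets <- names(specs)

  for (s in specs) {
    missing_preds <- setdiff(s$predictors, names(frame))
    if (length(missing_preds))
      stop("spec for '", s$target, "': predictors not in frame: ",
           paste(missing_preds, collapse = ", "))
    incomplete <- s$predictors[vapply(s$predictors,
                                      function(p) anyNA(frame[[p]]), logical(1))]
    uncovered <- setdiff(incomplete, targets)
    if (length(uncovered))
      stop("spec for '", s$target, "': incomplete predictors without a spec: ",
           paste(uncovered, collapse = ", "))
  }
  for (v in targets) {
    if (is.null(frame[[v]])) stop("target '", v, "' not in frame")
  }

  miss <- lapply(targets, function(v) which(is.na(frame[[v]])))
  names(miss) <- targets
  frac <- vapply(miss, length, numeric(1)) / nrow(frame)
  if (is.null(visit_order)) visit_order <- targets[order(frac)]
  stopifnot(setequal(visit_order, targets))

  chain_means <- array(NA_real_,
                       dim = c(length(targets), config$iterations, config$m),
                       dimnames = list(targets, NULL, NULL))
  imputations <- vector("list", config$m)

  for (i in seq_len(config$m)) {
    imputations[[i]] <- with_substream(config$seed, c("imputation", i), {
      cur <- frame
      # initialise: sample observed values within the sex stratum
      for (v in targets) {
        mi <- miss[[v]]
        if (!length(mi)) next
        obs <- which(!is.na(frame[[v]]))
        if (!length(obs))
          stop("target '", v, "' has no observed values to initialise from")
        for (sx in levels(frame$sex)) {
          mi_s <- mi[frame$sex[mi] == sx]
          if (!length(mi_s)) next
          obs_s <- obs[frame$sex[obs] == sx]
          if (!length(obs_s)) obs_s <- obs
          cur[[v]][mi_s] <- cur[[v]][obs_s[sample.int(length(obs_s),
                                                      length(mi_s),
                                                      replace = TRUE)]]
        }
      }
      for (it in seq_len(config$iterations)) {
        for (v in visit_order) {
          mi <- miss[[v]]
          if (!length(mi)) next
          s <- specs[[v]]
          X <- design_matrix(cur, s$predictors, s$year_form, s$knots)
          obs <- setdiff(seq_len(nrow(cur)), mi)
          if (s$sampler == "logistic") {
            fit <- fit_binary_model(as.integer(frame[[v]][obs]),
                                    X[obs, , drop = FALSE])
            beta <- draw_parameters(fit, config$parameter_draw[["logistic"]])
            cur[[v]] <- impute_binary(replace(cur[[v]], mi, NA), X, beta)
            chain_means[v, it, i] <- mean(cur[[v]][mi])
          } else {
            fit <- fit_polytomous_model(droplevels_keep(frame[[v]][obs]),
                                        X[obs, , drop = FALSE])
            cf <- draw_parameters(fit, config$parameter_draw[["polytomous"]])
            cur[[v]] <- impute_polytomous(replace(cur[[v]], mi, NA), X, cf)
            chain_means[v, it, i] <- mean(as.integer(cur[[v]][mi]))
          }
        }
      }
      cur
    })
  }
  structure(list(imputations = imputations, chain_means = chain_means,
                 specs = specs, config = config, miss = miss),
            class = "completed_set")
}

# keep full level set (multinom must see identical levels across calls)
droplevels_keep <- function(y) factor(y, levels = levels(y))

as_spec_list <- function(specs) {
  if (inherits(specs, "imputation_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "imputation_spec")))
  stats::setNames(specs, vapply(specs, `[[`, character(1), "target"))
}

#' @export
print.completed_set <- function(x, ...) {
  cat("completed_set:", length(x$imputations), "imputations,",
      x$config$iterations, "iterations,",
      length(x$specs), "target(s):", paste(names(x$specs), collapse = ", "),
      "\n")
  invisible(x)
}

#' Default imputation specs for the standard indicator frame
#'
#' Binary indicators and marital status get logistic specs; the BMI category
#' and education get polytomous specs. All use age, sex and a linear year
#' term plus the cross-indicator predictors named in `extra`.
#'
#' @param extra named list: per-target additional predictor names (e.g.
#'   `list(diabetes = "bmi_cat")`).
#' @param year_form,knots year-effect form shared by all specs.
#' @return list of [imputation_spec()]s.
#' @export
default_specs <- function(extra = list(diabetes = "bmi_cat",
                                       hypertension = "bmi_cat"),
                          year_form = "linear", knots = NULL) {
  base <- c("age", "sex", "year")
  mk <- function(target, sampler) {
    imputation_spec(target, sampler,
                    c(base, extra[[target]]), year_form, knots)
  }
  c(lapply(stats::setNames(BINARY_INDICATORS, BINARY_INDICATORS), mk,
           sampler = "logistic"),
    list(marital = mk("marital", "logistic"),
         bmi_cat = mk("bmi_cat", "polytomous"),
         education = mk("education", "polytomous")))
}
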