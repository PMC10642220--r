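# The chained-equations engine: samplers, parameter draws and the chain's
# invariants (observed-cell immutability, proper-MI variability, seed
# reproducibility, stabilised chain means).

make_design <- function(n, p, seed = 1) {
  withr::with_seed(seed, cbind(`(Intercept)` = 1,
                               matrix(rnorm(n * p), n,
                                      dimnames = list(NULL, paste0("x", 1:p)))))
}

test_that("intercept-only logistic MLE is the logit of the proportion", {
  y <- rep(c(1, 0), c(30, 70))
  fit <- fit_binary_model(y, matrix(1, 100, 1,
                                    dimnames = list(NULL, "(Intercept)")))
  expect_equal(unname(fit$coef), qlogis(0.3), tolerance = 1e-6)
  expect_equal(fit$n, 100)
  expect_equal(fit$k, 1)
})

test_that("logistic IRLS agrees with glm and recovers simulated truth", {
  X <- make_design(5000, 3, seed = 2)
  beta <- c(-0.5, 0.8, -0.4, 0.2)
  y <- withr::with_seed(3, rbinom(5000, 1, plogis(drop(X %*% beta))))
  fit <- fit_binary_model(y, X)
  # independent oracle: stats::glm on the same data
  oracle <- glm(y ~ X[, -1], family = binomial())
  expect_equal(unname(fit$coef), unname(coef(oracle)), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(oracle)), tolerance = 1e-6)
  expect_equal(unname(fit$vcov), unname(vcov(oracle)), tolerance = 1e-4)
  # consistency: estimates within 3 SE of the generating coefficients
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$coef - beta) < 3 * se))
  expect_false(fit$separation)
})

test_that("perfect separation is flagged and resolved by the ridge fallback", {
  X <- make_design(200, 1, seed = 4)
  y <- as.integer(X[, 2] > 0)
  fit <- expect_silent(fit_binary_model(y, X))
  expect_true(fit$separation)
  expect_gt(fit$ridge, 0)
  expect_true(all(is.finite(fit$coef)))
  expect_error(fit_binary_model(rep(1, 50), matrix(1, 50, 1)),
               "single observed class")
})

test_that("posterior parameter draws have the fit's mean and covariance", {
  X <- make_design(2000, 2, seed = 5)
  y <- withr::with_seed(6, rbinom(2000, 1, plogis(drop(X %*% c(0, 0.5, -0.5)))))
  fit <- fit_binary_model(y, X)

  degenerate <- fit
  degenerate$vcov <- matrix(0, 3, 3)
  expect_equal(draw_parameters(degenerate, "posterior"), fit$coef)

  draws <- withr::with_seed(7, t(replicate(10000,
                                           draw_parameters(fit, "posterior"))))
  se_mean <- sqrt(diag(fit$vcov) / 10000)
  expect_true(all(abs(colMeans(draws) - fit$coef) < 3 * se_mean))
  expect_equal(unname(cov(draws)), unname(fit$vcov), tolerance = 0.1)

  d1 <- withr::with_seed(8, draw_parameters(fit, "posterior"))
  d2 <- withr::with_seed(8, draw_parameters(fit, "posterior"))
  expect_identical(d1, d2)
  # bootstrap mode also returns a finite coefficient vector
  db <- withr::with_seed(9, draw_parameters(fit, "bootstrap"))
  expect_true(all(is.finite(db)))
})

test_that("binary imputation saturates, preserves observed cells, and is calibrated", {
  X <- matrix(1, 10000, 1, dimnames = list(NULL, "(Intercept)"))
  y <- rep(NA_integer_, 10000)
  expect_true(all(impute_binary(y, X, beta = 50) == 1L))
  y_obs <- rep(c(0L, 1L), 5000)
  expect_identical(impute_binary(y_obs, X, beta = 50), y_obs)  # identity
  filled <- withr::with_seed(10, impute_binary(y, X, beta = 0))
  expect_gt(mean(filled), 0.485)
  expect_lt(mean(filled), 0.515)
})

test_that("polytomous fit and imputation reproduce a known multinomial model", {
  n <- 6000
  X <- make_design(n, 1, seed = 11)
  b_ow <- c(0.3, 0.5); b_ob <- c(-0.4, -0.6)
  eta <- cbind(0, X %*% b_ow, X %*% b_ob)
  P <- exp(eta) / rowSums(exp(eta))
  y <- withr::with_seed(12, factor(c("a", "b", "c")[
    apply(P, 1, function(p) sample(3, 1, prob = p))], levels = c("a", "b", "c")))
  fit <- fit_polytomous_model(y, X)
  expect_equal(unname(fit$coef["b", ]), b_ow, tolerance = 0.15)
  expect_equal(unname(fit$coef["c", ]), b_ob, tolerance = 0.15)
  # per-row predicted probabilities sum to one
  probs <- prevproj:::polytomous_probs(X, fit$coef)
  expect_true(all(abs(rowSums(probs) - 1) < 1e-12))
  # uniform generating model: imputed shares near 1/3 each
  Xu <- matrix(1, 9000, 1, dimnames = list(NULL, "(Intercept)"))
  cf0 <- matrix(0, 2, 1, dimnames = list(c("b", "c"), "(Intercept)"))
  filled <- withr::with_seed(13, impute_polytomous(
    factor(rep(NA_character_, 9000), levels = c("a", "b", "c")), Xu, cf0))
  shares <- as.vector(table(filled)) / 9000
  expect_true(all(abs(shares - 1 / 3) < 3 * prop_se(1 / 3, 9000)))
  # an empty category among complete cases is an error naming it
  y_bad <- factor(rep(c("a", "b"), 10), levels = c("a", "b", "c"))
  expect_error(fit_polytomous_model(y_bad, matrix(1, 20, 1,
                                                  dimnames = list(NULL, "(Intercept)"))),
               "'c'")
})

test_that("a frame with no missing data passes through the chain unchanged", {
  cfg <- smoking_scenario(n_per_sex = 200, seed = 21)
  frame <- complete_series(cfg)
  cs <- run_chain(frame, list(smoking_spec()),
                  mice_config(m = 3, iterations = 2, seed = 1))
  for (f in cs$imputations) expect_identical(f, frame)
})

test_that("the chain never modifies observed cells and is seed-reproducible", {
  cfg <- smoking_scenario(n_per_sex = 300, seed = 22)
  frame <- complete_series(cfg)
  miss <- withr::with_seed(23, sample(nrow(frame), 0.3 * nrow(frame)))
  frame$smoking[miss] <- NA

  cs1 <- run_chain(frame, list(smoking_spec()),
                   mice_config(m = 2, iterations = 3, seed = 5))
  cs2 <- run_chain(frame, list(smoking_spec()),
                   mice_config(m = 2, iterations = 3, seed = 5))
  cs3 <- run_chain(frame, list(smoking_spec()),
                   mice_config(m = 2, iterations = 3, seed = 6))

  expect_identical(cs1$imputations, cs2$imputations)
  obs <- setdiff(seq_len(nrow(frame)), miss)
  for (cs in list(cs1, cs3)) {
    for (f in cs$imputations) {
      expect_identical(f$smoking[obs], frame$smoking[obs])  # cell-by-cell
      expect_false(anyNA(f$smoking))
    }
  }
  # different seeds differ only at originally-missing cells
  diff_cells <- which(cs1$imputations[[1]]$smoking !=
                        cs3$imputations[[1]]$smoking)
  expect_true(length(diff_cells) > 0)
  expect_true(all(diff_cells %in% miss))
})

test_that("between-imputation variability is strictly positive under missingness", {
  cfg <- smoking_scenario(n_per_sex = 300, seed = 24)
  frame <- complete_series(cfg)
  miss <- withr::with_seed(25, sample(nrow(frame), 0.3 * nrow(frame)))
  frame$smoking[miss] <- NA
  cs <- run_chain(frame, list(smoking_spec()),
                  mice_config(m = 5, iterations = 3, seed = 7))
  imp_means <- sapply(cs$imputations, function(f) mean(f$smoking[miss]))
  expect_gt(var(imp_means), 0)
})

test_that("chain means stabilise (no monotone drift over the last sweeps)", {
  cfg <- smoking_scenario(slope = 0, n_per_sex = 500, seed = 26)
  frame <- complete_series(cfg)
  miss <- withr::with_seed(27, sample(nrow(frame), 0.3 * nrow(frame)))
  frame$smoking[miss] <- NA
  cs <- run_chain(frame, list(smoking_spec()),
                  mice_config(m = 5, iterations = 10, seed = 8))
  late <- 6:10
  means <- apply(cs$chain_means["smoking", late, , drop = FALSE], 2, mean)
  fit <- lm(means ~ late)
  slope_t <- abs(coef(fit)[2]) / coef(summary(fit))[2, "Std. Error"]
  expect_lt(slope_t, 3)
})

test_that("spec validation catches uncovered incomplete predictors", {
  cfg <- smoking_scenario(n_per_sex = 100, seed = 28)
  frame <- complete_series(cfg)
  frame$smoking[1:50] <- NA
  frame$sedentary[1:50] <- NA
  bad <- imputation_spec("smoking", "logistic", c("age", "sex", "sedentary"))
  expect_error(run_chain(frame, list(bad), mice_config(m = 1, iterations = 1)),
               "without a spec")
  missing_pred <- imputation_spec("smoking", "logistic", c("age", "nosuch"))
  expect_error(run_chain(frame, list(missing_pred),
                         mice_config(m = 1, iterations = 1)),
               "not in frame")
  expect_error(imputation_spec("smoking", "logistic", c("age", "smoking")),
               "own predictors")
})
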