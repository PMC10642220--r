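# Internal helpers shared across modules.

#' Derive a reproducible substream seed from a master seed and a key
#'
#' A master seed plus a string key (e.g. "wave/1997" or "imputation/3") is
#' hashed to an integer seed below 2^31, so that adding a wave or running
#' imputations in a different order never perturbs the random numbers used by
#' the other substreams.
#'
#' @param seed master integer seed.
#' @param ... character/numeric components of the substream key.
#' @return an integer seed in [0, 2^31).
#' @keywords internal
substream_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  codes <- utf8ToInt(key)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer(((as.numeric(seed) %% 1000000) * 2039 + h) %% 2147483647)
}

# Evaluate `expr` under a derived substream seed without disturbing the
# caller's RNG state.
with_substream <- function(seed, key, expr) {
  withr::with_seed(substream_seed(seed, key), expr)
}

#' Three-valued (Kleene) logical OR over binary 0/1 vectors
#'
#' Returns 1 where any criterion is observed true, 0 where every criterion is
#' observed false, and NA otherwise: an unobserved criterion only matters when
#' no observed criterion already forces the answer. This is the missingness
#' semantics used for OR-of-criteria indicator definitions, so that
#' non-respondents get a missing (imputable) indicator rather than a spurious
#' zero.
#'
#' @param ... integer/logical vectors with NA allowed.
#' @return an integer vector of 0, 1, NA.
#' @export
#' @examples
#' kleene_or(c(1, 0, NA, NA), c(0, 0, 1, NA))
kleene_or <- function(...) {
  args <- lapply(list(...), function(x) as.integer(x))
  n <- max(lengths(args))
  args <- lapply(args, rep_len, n)
  any1 <- Reduce(`|`, lapply(args, function(x) !is.na(x) & x == 1L))
  all0 <- Reduce(`&`, lapply(args, function(x) !is.na(x) & x == 0L))
  out <- rep(NA_integer_, n)
  out[any1] <- 1L
  out[all0] <- 0L
  out
}

# Largest-remainder rounding of n * proportions to integer counts summing to n.
largest_remainder <- function(weights, n) {
  expected <- n * weights / sum(weights)
  counts <- floor(expected)
  short <- n - sum(counts)
  if (short > 0) {
    frac <- expected - counts
    top <- order(frac, decreasing = TRUE)[seq_len(short)]
    counts[top] <- counts[top] + 1
  }
  as.integer(counts)
}

# Sample category indices from a matrix of row-wise probabilities.
sample_categories <- function(prob) {
  stopifnot(is.matrix(prob))
  cum <- t(apply(prob, 1, cumsum))
  u <- stats::runif(nrow(prob)) * cum[, ncol(cum)]
  1L + rowSums(u > cum[, -ncol(cum), drop = FALSE], na.rm = FALSE)
}
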