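# Internal helpers shared across modules.

# Population-form weighted mean: sum(w*x)/sum(w).
wmean <- function(x, w) sum(w * x) / sum(w)

# Population-form weighted covariance, normalised by total weight (not
# total weight minus one): needed so that C = (2/mu) cov(y, gamma)
# coincides with the summation formula C = (2/(n mu)) sum(y_i gamma_i) - 1.
wcov <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  sum(w * (x - mx) * (y - my)) / sw
}

wvar <- function(x, w) wcov(x, x, w)

check_weights <- function(weights, n, arg = "weights") {
  if (is.null(weights)) weights <- rep(1, n)
  weights <- as.numeric(weights)
  if (length(weights) != n) {
    stop(sprintf("'%s' must have length %d", arg, n), call. = FALSE)
  }
  if (anyNA(weights) || any(weights <= 0)) {
    stop(sprintf("'%s' must be positive and non-missing", arg), call. = FALSE)
  }
  weights
}

check_binary <- function(y, arg = "outcome") {
  y <- as.numeric(y)
  if (length(y) == 0L) stop(sprintf("'%s' is empty", arg), call. = FALSE)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop(sprintf("'%s' must be coded 0/1 with no missing values", arg),
         call. = FALSE)
  }
  y
}

# Half-away-from-zero rounding to `digits`, matching how the published
# tables format percentages (base round() rounds half to even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
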