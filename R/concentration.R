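#' Concentration index of a health outcome
#'
#' Estimates the (relative) concentration index
#' \deqn{C = \frac{2}{\mu}\,\mathrm{cov}(y, \gamma)}
#' where \eqn{\gamma} are the weighted fractional income ranks and
#' \eqn{\mu} the weighted outcome mean. The covariance is in population
#' form (normalised by total weight), so \eqn{C} coincides with the
#' summation formula \eqn{2/(n\mu)\sum y_i \gamma_i - 1} under unit
#' weights. A positive index means utilization concentrated among the
#' better-off; negative, among the poor.
#'
#' Standard errors come from the "convenient regression"
#' \deqn{2\sigma^2_\gamma\, (y_i/\mu) = \alpha + \beta \gamma_i + \varepsilon_i}
#' whose weighted least-squares slope is algebraically identical to the
#' covariance-form \eqn{C}; the reported standard error is
#' heteroskedasticity-robust (HC1), or cluster-robust by the supplied
#' community identifier, which respects within-community correlation of
#' utilization. Both are stored when a cluster is given.
#'
#' @param x a \code{ranked_outcome}, a formula of the form
#'   \code{outcome ~ income}, or a numeric outcome vector.
#' @param ... passed to methods.
#' @return an object of class \code{concindex}; see Details.
#' @seealso [concentration_curve()], [ci_decomp()]
#' @export
concindex <- function(x, ...) UseMethod("concindex")

#' @rdname concindex
#' @param data data frame holding the formula variables.
#' @param weights optional positive sampling weights (vector, or a
#'   column name / one-sided formula for the formula method).
#' @param cluster optional community identifier for cluster-robust
#'   standard errors (same forms as \code{weights}).
#' @param conf_level confidence level for the limits, default 0.95.
#' @export
concindex.formula <- function(x, data, weights = NULL, cluster = NULL,
                              conf_level = 0.95, ...) {
  v <- all.vars(x)
  if (length(v) != 2L) {
    stop("formula must be of the form outcome ~ income", call. = FALSE)
  }
  pull <- function(spec) {
    if (is.null(spec)) return(NULL)
    if (inherits(spec, "formula")) spec <- all.vars(spec)
    if (is.character(spec) && length(spec) == 1L && spec %in% names(data)) {
      return(data[[spec]])
    }
    spec
  }
  out <- concindex.default(data[[v[1]]], data[[v[2]]],
                           weights = pull(weights),
                           cluster = pull(cluster),
                           conf_level = conf_level)
  out$call <- match.call()
  out
}

#' @rdname concindex
#' @param income numeric ranking variable (default method).
#' @export
concindex.default <- function(x, income, weights = NULL, cluster = NULL,
                              conf_level = 0.95, ...) {
  r <- ranked_outcome(x, income, weights)
  concindex.ranked_outcome(r, cluster = cluster, conf_level = conf_level)
}

#' @rdname concindex
#' @export
concindex.ranked_outcome <- function(x, cluster = NULL, conf_level = 0.95,
                                     ...) {
  y <- x$y; g <- x$gamma; w <- x$weights; mu <- x$mu
  n <- length(y)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (mu <= 0) stop("outcome mean must be positive", call. = FALSE)
  vg <- wvar(g, w)
  if (vg < .Machine$double.eps) {
    stop("all incomes tied: concentration index undefined", call. = FALSE)
  }
  C <- 2 * wcov(y, g, w) / mu

  # Convenient regression: slope is identical to C; robust vcov gives se.
  z <- 2 * vg * y / mu
  fit <- stats::lm(z ~ g, weights = w)
  # suppressWarnings: degenerate inputs (outcome an exact linear function
  # of the rank) make the auxiliary fit perfect, which summary.lm flags.
  se_robust <- sqrt(suppressWarnings(
    sandwich::vcovHC(fit, type = "HC1"))[2, 2])
  se_cluster <- NA_real_
  if (!is.null(cluster)) {
    if (length(cluster) != n) {
      stop("'cluster' must match the number of observations", call. = FALSE)
    }
    se_cluster <- sqrt(suppressWarnings(
      sandwich::vcovCL(fit, cluster = cluster))[2, 2])
  }
  se <- if (is.na(se_cluster)) se_robust else se_cluster
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)

  curve <- if (all(y >= 0) && sum(y) > 0) {
    concentration_curve(x)
  } else NULL

  structure(
    list(C = C, se = se, cl_low = C - zq * se, cl_high = C + zq * se,
         se_robust = se_robust, se_cluster = se_cluster,
         mu = mu, n = n, conf_level = conf_level, curve = curve,
         ranked = x, call = match.call()),
    class = "concindex"
  )
}

#' Concentration curve coordinates
#'
#' Cumulative weighted outcome share against cumulative population
#' (weight) share, respondents ordered poorest to richest. The curve
#' runs from (0,0) to (1,1); lying above the diagonal means the outcome
#' is concentrated among the poor.
#'
#' @param ranked a \code{ranked_outcome}.
#' @return data frame with columns \code{pop_share}, \code{outcome_share}.
#' @export
concentration_curve <- function(ranked) {
  stopifnot(inherits(ranked, "ranked_outcome"))
  y <- ranked$y; w <- ranked$weights
  if (any(y < 0)) stop("curve requires a non-negative outcome", call. = FALSE)
  if (sum(w * y) == 0) {
    stop("all-zero outcome: cumulative shares undefined", call. = FALSE)
  }
  ord <- order(ranked$gamma)
  cw <- cumsum(w[ord]) / sum(w)
  cy <- cumsum((w * y)[ord]) / sum(w * y)
  data.frame(pop_share = c(0, cw), outcome_share = c(0, cy))
}

# Trapezoid-rule area under the concentration curve.
curve_auc <- function(curve) {
  x <- curve$pop_share; y <- curve$outcome_share
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.concindex <- function(x, digits = 4, ...) {
  cat(sprintf("Concentration index: %.*f (95%% CL: %.*f, %.*f)\n",
              digits, x$C, digits, x$cl_low, digits, x$cl_high))
  cat(sprintf("  se = %.*f (%s), mu = %.*f, n = %d\n",
              digits, x$se,
              if (is.na(x$se_cluster)) "HC1 robust" else "cluster robust",
              digits, x$mu, x$n))
  invisible(x)
}

#' @export
summary.concindex <- function(object, ...) {
  out <- data.frame(
    estimate = object$C,
    se_robust = object$se_robust,
    se_cluster = object$se_cluster,
    cl_low = object$cl_low,
    cl_high = object$cl_high,
    mu = object$mu,
    n = object$n
  )
  class(out) <- c("summary.concindex", class(out))
  out
}

#' @export
print.summary.concindex <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.concindex <- function(object, ...) c(C = object$C)

#' @export
confint.concindex <- function(object, parm, level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$C - zq * object$se, object$C + zq * object$se),
              nrow = 1,
              dimnames = list("C", sprintf("%.1f %%",
                                           100 * c((1 - level) / 2,
                                                   1 - (1 - level) / 2))))
  m
}

#' @export
plot.concindex <- function(x, ...) {
  if (is.null(x$curve)) stop("no curve stored for this fit", call. = FALSE)
  graphics::plot(x$curve$pop_share, x$curve$outcome_share, type = "l",
                 xlab = "Cumulative population share (poorest first)",
                 ylab = "Cumulative outcome share",
                 main = sprintf("Concentration curve (C = %.4f)", x$C), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}
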