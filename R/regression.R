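#' Fit the outcome model for a binary utilization indicator
#'
#' Logistic regression of a 0/1 utilization outcome on categorical
#' covariates (reference-cell dummies; the reference is each factor's
#' first level), with a community-level random intercept fitted by
#' maximum likelihood (\code{lme4::glmer}). When the random-intercept
#' standard deviation is estimated at the boundary (singular fit or SD
#' below 1e-3), or when non-unit weights are supplied, the model falls
#' back to a plain logistic fit with cluster-robust (CR0 sandwich)
#' standard errors — the fixed effects are then what the boundary GLMM
#' would return, with honest clustered uncertainty.
#'
#' @param data data frame of respondents.
#' @param outcome name of the 0/1 outcome column.
#' @param covariates character vector of covariate column names
#'   (coerced to factors; first level is the reference).
#' @param cluster name of the community identifier column.
#' @param weights name of a positive weight column, or NULL for unit
#'   weights.
#' @param method \code{"auto"} (default: GLMM with fallback),
#'   \code{"glmm"}, or \code{"logit"} (plain logistic, cluster-robust).
#' @param nAGQ adaptive Gauss-Hermite quadrature points for the GLMM.
#' @return object of class \code{outcome_model}: coefficients, robust
#'   or model-based vcov, OR table with 95\% limits, random-intercept
#'   SD, convergence flag, log-likelihood, and the underlying fit.
#' @export
fit_outcome_model <- function(data, outcome, covariates,
                              cluster = "cluster", weights = NULL,
                              method = c("auto", "glmm", "logit"),
                              nAGQ = 1L) {
  method <- match.arg(method)
  check_binary(data[[outcome]], outcome)
  for (v in covariates) {
    if (!v %in% names(data)) {
      stop(sprintf("covariate '%s' not found", v), call. = FALSE)
    }
    if (!is.factor(data[[v]])) data[[v]] <- factor(data[[v]])
  }
  w <- if (is.null(weights)) rep(1, nrow(data)) else
    check_weights(data[[weights]], nrow(data), weights)
  unit_w <- all(w == 1)
  if (!unit_w && method == "glmm") {
    stop("the random-intercept fit requires unit weights; use method = 'logit'",
         call. = FALSE)
  }
  if (is.null(cluster) && method == "glmm") {
    stop("the random-intercept fit needs a cluster column", call. = FALSE)
  }

  rhs <- paste(covariates, collapse = " + ")
  use_glmm <- method == "glmm" ||
    (method == "auto" && unit_w && !is.null(cluster))
  fit <- NULL
  re_sd <- 0
  fitted_method <- "logit"

  if (use_glmm) {
    fml <- stats::as.formula(
      paste(outcome, "~", rhs, "+ (1 |", cluster, ")"))
    gfit <- suppressMessages(
      lme4::glmer(fml, data = data, family = stats::binomial(),
                  nAGQ = nAGQ))
    re_sd <- sqrt(unname(lme4::VarCorr(gfit)[[cluster]][1, 1]))
    boundary <- lme4::isSingular(gfit, tol = 1e-4) || re_sd < 1e-3
    if (method == "glmm" || !boundary) {
      fit <- gfit
      fitted_method <- "glmm"
    }
  }
  if (is.null(fit)) {
    fml <- stats::as.formula(paste(outcome, "~", rhs))
    data$.w <- w
    fit <- suppressWarnings(
      stats::glm(fml, data = data, family = stats::binomial(),
                 weights = .w))
    fitted_method <- "logit"
  }

  if (fitted_method == "glmm") {
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    converged <- length(fit@optinfo$conv$lme4) == 0 &&
      fit@optinfo$conv$opt == 0
    ll <- as.numeric(stats::logLik(fit))
  } else {
    beta <- stats::coef(fit)
    V <- if (is.null(cluster)) sandwich::vcovHC(fit, type = "HC0")
         else sandwich::vcovCL(fit, cluster = data[[cluster]])
    converged <- fit$converged
    ll <- as.numeric(stats::logLik(fit))
    re_sd <- if (use_glmm) re_sd else NA_real_
  }
  if (!converged) {
    warning("outcome model did not converge; estimates withheld from ",
            "the OR table", call. = FALSE)
  }
  se <- sqrt(diag(V))
  z <- beta / se
  or_table <- data.frame(
    term = names(beta),
    estimate = unname(beta),
    se = unname(se),
    OR = exp(unname(beta)),
    cl_low = exp(unname(beta - 1.96 * se)),
    cl_high = exp(unname(beta + 1.96 * se)),
    p = 2 * stats::pnorm(-abs(unname(z))),
    stringsAsFactors = FALSE
  )
  if (!converged) or_table <- or_table[0, ]

  structure(
    list(fit = fit, method = fitted_method, outcome = outcome,
         covariates = covariates, coefficients = beta, vcov = V,
         or_table = or_table, random_intercept_sd = re_sd,
         converged = converged, logLik = ll,
         cluster = cluster, weights_col = weights),
    class = "outcome_model"
  )
}

#' @export
print.outcome_model <- function(x, digits = 3, ...) {
  cat(sprintf("Outcome model for '%s' (%s%s)\n", x$outcome,
              if (x$method == "glmm") "random-intercept logistic"
              else "logistic, cluster-robust",
              if (!is.na(x$random_intercept_sd))
                sprintf(", community SD = %.3f", x$random_intercept_sd)
              else ""))
  if (nrow(x$or_table)) {
    tab <- x$or_table[x$or_table$term != "(Intercept)",
                      c("term", "OR", "cl_low", "cl_high", "p")]
    print(format(tab, digits = digits), row.names = FALSE)
  } else cat("  (not converged)\n")
  invisible(x)
}

#' @export
coef.outcome_model <- function(object, ...) object$coefficients

#' @export
vcov.outcome_model <- function(object, ...) object$vcov

# Predicted probabilities on newdata, fixed effects only for the GLMM.
predict_response <- function(model, newdata) {
  if (model$method == "glmm") {
    unname(stats::predict(model$fit, newdata = newdata,
                          type = "response", re.form = NA))
  } else {
    unname(stats::predict(model$fit, newdata = newdata,
                          type = "response"))
  }
}

#' Average marginal effects of the outcome model
#'
#' For each non-reference category of each covariate: the discrete
#' change in predicted probability when the category is switched on for
#' every respondent versus the reference category, averaged (weighted)
#' over the sample. For a numeric covariate the derivative
#' \eqn{p(1-p)\beta} is averaged instead. GLMM predictions are on the
#' fixed-effects (median community) profile.
#'
#' @param model an \code{outcome_model}.
#' @param data the data frame to average over (typically the estimation
#'   sample).
#' @param weights optional positive weight vector.
#' @return data frame with columns \code{covariate}, \code{level}
#'   (\code{NA} for numeric terms), \code{term}, \code{ame},
#'   \code{xbar} (weighted mean of the dummy / variable).
#' @export
average_marginal_effects <- function(model, data, weights = NULL) {
  stopifnot(inherits(model, "outcome_model"))
  if (!model$converged) {
    stop("model did not converge; marginal effects unavailable",
         call. = FALSE)
  }
  w <- check_weights(weights, nrow(data))
  rows <- list()
  for (v in model$covariates) {
    x <- data[[v]]
    if (is.numeric(x)) {
      p <- predict_response(model, data)
      beta <- model$coefficients[[v]]
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = v, level = NA_character_, term = v,
        ame = wmean(p * (1 - p) * beta, w), xbar = wmean(x, w),
        stringsAsFactors = FALSE)
      next
    }
    if (!is.factor(x)) x <- factor(x)
    lev <- levels(x)
    d0 <- data
    d0[[v]] <- factor(lev[1], levels = lev)
    p0 <- predict_response(model, d0)
    for (L in lev[-1]) {
      dL <- data
      dL[[v]] <- factor(L, levels = lev)
      pL <- predict_response(model, dL)
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = v, level = L, term = paste0(v, L),
        ame = wmean(pL - p0, w), xbar = wmean(x == L, w),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
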