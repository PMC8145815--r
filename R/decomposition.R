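#' Concentration index of a determinant
#'
#' The determinant's own concentration index \eqn{c_k}: the same
#' population-form covariance formula as the outcome index, applied to
#' \eqn{x_k} (for reference-cell dummies, a 0/1 category indicator
#' whose mean is the category share).
#'
#' @param x numeric determinant vector (dummy or continuous).
#' @param gamma fractional income ranks.
#' @param weights optional positive weights.
#' @return scalar \eqn{c_k}.
#' @export
determinant_index <- function(x, gamma, weights = NULL) {
  x <- as.numeric(x)
  w <- check_weights(weights, length(x))
  m <- wmean(x, w)
  if (abs(m) < .Machine$double.eps) {
    stop("determinant has zero mean: recode it (dummies are 0/1, so ",
         "category shares are positive)", call. = FALSE)
  }
  2 * wcov(x, gamma, w) / m
}

#' Decompose a concentration index into determinant contributions
#'
#' Regression-based decomposition of the outcome concentration index
#' \eqn{C}. With a linear approximation
#' \eqn{y_i = \alpha + \sum_k \beta_k x_{ki} + \varepsilon_i},
#' \deqn{C = \sum_k \left(\beta_k \bar x_k / \mu\right) c_k + GC_\varepsilon/\mu,}
#' where \eqn{\beta_k \bar x_k/\mu} is the elasticity of the outcome
#' with respect to determinant \eqn{k}, \eqn{c_k} its concentration
#' index, and \eqn{GC_\varepsilon} the generalized concentration index
#' of the residual. For a binary outcome the default \code{"ame"}
#' method takes \eqn{\beta_k} as the average marginal effect from a
#' logistic model (nonlinear-model approximation); \code{"ols"} uses a
#' weighted linear probability model, under which the identity is
#' exact. In both modes the reported residual is the remainder
#' \eqn{C - \sum_k \eta_k c_k} so that the rows always total \eqn{C};
#' the directly computed \eqn{GC_\varepsilon/\mu} is kept as a
#' diagnostic (identical to the remainder under OLS).
#'
#' The horizontal inequity index removes the contribution of need
#' variables (demographics and health status — legitimate drivers of
#' utilization): \eqn{HI = C - \sum_{k \in need} \eta_k c_k}. Because
#' published decompositions are ambiguous about whether the economic
#' status stratum counts as need, both groupings are reported:
#' \code{HI} (need excludes economic status, the conventional reading)
#' and \code{HI_excl_econ_other} treating need plus economic status as
#' removed.
#'
#' @param formula model formula \code{outcome ~ det1 + det2 + ...}; all
#'   determinants are entered as reference-cell dummies (factor first
#'   level = reference).
#' @param data respondent-level data frame.
#' @param rank name of the income column providing the ranking
#'   variable.
#' @param need character vector of need covariate names; default
#'   demographics + health status.
#' @param weights optional weight column name.
#' @param cluster optional community column name (cluster-robust limits
#'   for the total index; passed to the logistic fallback fit).
#' @param method \code{"ame"} (logistic average marginal effects,
#'   default) or \code{"ols"} (linear probability model, exact
#'   identity).
#' @param use_glmm logical: fit the \code{"ame"} model with a community
#'   random intercept (slower); default FALSE uses plain logistic with
#'   cluster-robust errors, whose AMEs are what the decomposition
#'   consumes.
#' @return object of class \code{ci_decomp}; see Details and
#'   [summary.ci_decomp()].
#' @export
ci_decomp <- function(formula, data, rank = "income", need = NULL,
                      weights = NULL, cluster = NULL,
                      method = c("ame", "ols"), use_glmm = FALSE) {
  method <- match.arg(method)
  outcome <- all.vars(formula[[2]])
  determinants <- attr(stats::terms(formula, data = data), "term.labels")
  if (!outcome %in% names(data)) {
    stop(sprintf("outcome '%s' not found", outcome), call. = FALSE)
  }
  if (is.null(need)) {
    need <- intersect(c("sex", "age_group", "disability", "body_pain",
                        "chronic_diseases"), determinants)
  }
  unknown <- setdiff(need, determinants)
  if (length(unknown)) {
    stop("need set names unknown determinants: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  y <- as.numeric(data[[outcome]])
  w <- if (is.null(weights)) rep(1, nrow(data)) else
    check_weights(data[[weights]], nrow(data), weights)
  cl <- if (is.null(cluster)) NULL else data[[cluster]]
  gamma <- fractional_rank(data[[rank]], w)
  mu <- wmean(y, w)
  if (mu <= 0) stop("outcome mean must be positive", call. = FALSE)

  total <- concindex(ranked_outcome(y, data[[rank]], w), cluster = cl)
  C <- total$C

  for (v in determinants) {
    if (!is.numeric(data[[v]]) && !is.factor(data[[v]])) {
      data[[v]] <- factor(data[[v]])
    }
  }

  if (method == "ols") {
    data$.w <- w
    fml <- stats::as.formula(paste(outcome, "~",
                                   paste(determinants, collapse = " + ")))
    fit <- stats::lm(fml, data = data, weights = .w)
    mm <- stats::model.matrix(fit)
    asgn <- attr(mm, "assign")
    labs <- attr(stats::terms(fit), "term.labels")
    keep <- which(asgn > 0)
    rows <- data.frame(
      covariate = labs[asgn[keep]],
      term = colnames(mm)[keep],
      beta = unname(stats::coef(fit)[keep]),
      stringsAsFactors = FALSE)
    rows$level <- substring(rows$term, nchar(rows$covariate) + 1)
    rows$level[rows$level == ""] <- NA_character_
    rows$xbar <- vapply(keep, function(j) wmean(mm[, j], w), numeric(1))
    xmat <- mm[, keep, drop = FALSE]
    fitted_y <- unname(stats::fitted(fit))
    model <- fit
  } else {
    model <- fit_outcome_model(
      data, outcome, determinants,
      cluster = if (is.null(cluster)) NULL else cluster,
      weights = weights,
      method = if (use_glmm) "auto" else "logit")
    ame <- average_marginal_effects(model, data, w)
    rows <- data.frame(covariate = ame$covariate, term = ame$term,
                       beta = ame$ame, level = ame$level,
                       xbar = ame$xbar, stringsAsFactors = FALSE)
    mm <- stats::model.matrix(
      stats::as.formula(paste("~", paste(determinants, collapse = " + "))),
      data = data)
    xmat <- mm[, match(rows$term, colnames(mm)), drop = FALSE]
    fitted_y <- predict_response(model, data)
  }

  rows$c_k <- vapply(seq_len(nrow(rows)), function(i)
    determinant_index(xmat[, i], gamma, w), numeric(1))
  rows$elasticity <- rows$beta * rows$xbar / mu
  rows$contribution <- rows$elasticity * rows$c_k
  rows$pct <- 100 * rows$contribution / C

  explained <- sum(rows$contribution)
  residual <- C - explained
  gc_resid <- 2 * wcov(y - fitted_y, gamma, w) / mu

  econ <- intersect("economic_status", determinants)
  other <- setdiff(determinants, c(need, econ))
  grp_sum <- function(vs) sum(rows$contribution[rows$covariate %in% vs])
  need_contribution <- grp_sum(need)
  groups <- data.frame(
    group = c("CI", "Needs variables", "Economic status",
              "Other variables", "Residuals"),
    contribution = c(C, need_contribution, grp_sum(econ), grp_sum(other),
                     residual),
    stringsAsFactors = FALSE)
  groups$pct <- 100 * groups$contribution / C

  structure(
    list(table = rows[, c("covariate", "level", "term", "beta", "xbar",
                          "c_k", "elasticity", "contribution", "pct")],
         groups = groups,
         C = C, total = total, mu = mu,
         residual = residual, gc_residual = gc_resid,
         need = need, need_contribution = need_contribution,
         HI = C - need_contribution,
         HI_excl_econ_other = C - need_contribution - grp_sum(econ),
         outcome = outcome, method = method, model = model,
         n = length(y), call = match.call()),
    class = "ci_decomp"
  )
}

#' Horizontal inequity index
#'
#' The concentration index remaining after the need-variable
#' contributions are removed: inequality not justified by differences
#' in need ("equal treatment for equal need"). Negative values mean
#' pro-poor utilization beyond what need explains.
#'
#' @param decomp a \code{ci_decomp}.
#' @return scalar HI.
#' @export
horizontal_inequity <- function(decomp) {
  stopifnot(inherits(decomp, "ci_decomp"))
  decomp$HI
}

#' @export
print.ci_decomp <- function(x, digits = 4, ...) {
  cat(sprintf("Decomposition of the concentration index for '%s' (%s)\n",
              x$outcome, if (x$method == "ame")
                "logistic average marginal effects" else "OLS"))
  g <- x$groups
  g$contribution <- round(g$contribution, digits)
  g$pct <- round(g$pct, 2)
  print(g, row.names = FALSE)
  cat(sprintf("HI = %.*f  (need variables: %s)\n", digits, x$HI,
              paste(x$need, collapse = ", ")))
  invisible(x)
}

#' Per-determinant decomposition table
#'
#' @param object a \code{ci_decomp}.
#' @param ... unused.
#' @return the per-term table: marginal effect, mean, determinant
#'   index, elasticity, contribution and percent share.
#' @export
summary.ci_decomp <- function(object, ...) {
  out <- object$table
  attr(out, "C") <- object$C
  attr(out, "HI") <- object$HI
  attr(out, "residual") <- object$residual
  class(out) <- c("summary.ci_decomp", class(out))
  out
}

#' @export
print.summary.ci_decomp <- function(x, digits = 4, ...) {
  df <- x
  class(df) <- "data.frame"
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  cat(sprintf("C = %.*f, residual = %.*f, HI = %.*f\n",
              digits, attr(x, "C"), digits, attr(x, "residual"),
              digits, attr(x, "HI")))
  invisible(x)
}

#' @export
coef.ci_decomp <- function(object, ...) {
  stats::setNames(object$table$contribution, object$table$term)
}
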