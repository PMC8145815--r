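#' Utilization rate with 95% confidence limits
#'
#' Weighted utilization rate of a binary outcome (share of respondents
#' using the service in the reference window), with Wilson score
#' confidence limits computed on the effective sample size
#' \eqn{(\sum w)^2 / \sum w^2}. Wilson limits are asymmetric and behave
#' well at the 8–20\% prevalences typical of outpatient/inpatient
#' utilization; normal-approximation (Wald) limits are available for
#' comparison with published symmetric limits.
#'
#' @param outcome binary 0/1 vector.
#' @param weights optional positive weights.
#' @param conf_level confidence level, default 0.95.
#' @param method \code{"wilson"} (default) or \code{"wald"}.
#' @return an object of class \code{rate_result}: list with
#'   \code{numerator}, \code{denominator} (weighted totals), \code{rate},
#'   \code{cl_low}, \code{cl_high}, \code{n_eff}, \code{method}.
#' @export
utilization_rate <- function(outcome, weights = NULL,
                             conf_level = 0.95,
                             method = c("wilson", "wald")) {
  method <- match.arg(method)
  y <- check_binary(outcome)
  w <- check_weights(weights, length(y))
  p <- wmean(y, w)
  n_eff <- sum(w)^2 / sum(w^2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (method == "wilson") {
    denom <- 1 + z^2 / n_eff
    centre <- (p + z^2 / (2 * n_eff)) / denom
    half <- z * sqrt(p * (1 - p) / n_eff + z^2 / (4 * n_eff^2)) / denom
    lo <- max(0, centre - half)
    hi <- min(1, centre + half)
  } else {
    half <- z * sqrt(p * (1 - p) / n_eff)
    lo <- max(0, p - half)
    hi <- min(1, p + half)
  }
  structure(
    list(numerator = sum(w * y), denominator = sum(w), rate = p,
         cl_low = lo, cl_high = hi, n_eff = n_eff, method = method),
    class = "rate_result"
  )
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("Rate %.2f%% (95%% CL: %.2f, %.2f)  [%s, n_eff = %.1f]\n",
              100 * x$rate, 100 * x$cl_low, 100 * x$cl_high,
              x$method, x$n_eff))
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Cross-tabulated counts with the uncorrected Pearson statistic
#' \eqn{\sum (O - E)^2 / E}, df = (r-1)(c-1) and the upper-tail
#' chi-square p-value. No continuity correction is applied; the
#' uncorrected statistic is what published 2x2 utilization tables
#' report.
#'
#' @param counts r x c matrix of non-negative integer counts, r, c >= 2.
#' @return an object of class \code{contingency_table}: list with
#'   \code{counts}, \code{chi2}, \code{df}, \code{p_value},
#'   \code{row_labels}, \code{col_labels}.
#' @examples
#' chi_square(rbind(c(9712, 1844), c(10515, 2672)))  # chi2 = 76.51
#' @export
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("contingency table needs at least 2 rows and 2 columns",
         call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and non-missing", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero row or column marginal: expected counts undefined",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(
    list(counts = counts,
         chi2 = unname(ct$statistic),
         df = unname(ct$parameter),
         p_value = unname(ct$p.value),
         row_labels = rownames(counts),
         col_labels = colnames(counts)),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  print(x$counts)
  cat(sprintf("Pearson chi2 = %.2f, df = %d, p = %.3g\n",
              x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Sample composition table
#'
#' Counts and percentages per category of each categorical covariate,
#' the descriptive table of a utilization study. Percentages use the
#' per-variable total (covariates can carry item missingness, so row
#' totals may fall short of the headline n) and are reported both raw
#' and rounded half-away-from-zero to 2 decimals as tables print them.
#'
#' @param data data frame of respondents.
#' @param variables character vector of categorical column names;
#'   defaults to all factor/character columns.
#' @return data frame with columns \code{variable}, \code{category},
#'   \code{n}, \code{pct} (exact), \code{pct_printed} (2 dp).
#' @export
composition_table <- function(data, variables = NULL) {
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, function(col)
      is.factor(col) || is.character(col), logical(1))]
  }
  out <- lapply(variables, function(v) {
    x <- data[[v]]
    if (is.null(x)) stop(sprintf("column '%s' not found", v), call. = FALSE)
    x <- x[!is.na(x)]
    tab <- table(if (is.factor(x)) droplevels(x) else x)
    pct <- 100 * as.numeric(tab) / sum(tab)
    data.frame(variable = v, category = names(tab),
               n = as.integer(tab), pct = pct,
               pct_printed = round_half_up(pct, 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
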