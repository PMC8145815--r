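#' Weighted fractional income ranks
#'
#' Computes the fractional rank of each observation in the (weighted)
#' income distribution: the cumulative weight share of all strictly
#' poorer observations plus half the observation's own weight share.
#' This is the living-standards axis used by concentration curves and
#' concentration indices; its weighted mean is exactly 0.5.
#'
#' Tied incomes share a single rank: the midpoint of the total weight
#' span the tied group occupies, which equals the weighted average of
#' the ranks the group members would have received had the tie been
#' broken, and keeps the result invariant to row order.
#'
#' @param income numeric vector of the ranking variable (household
#'   income, or per-capita income if the caller divides by household
#'   size first). Any strictly increasing transform gives the same
#'   ranks.
#' @param weights optional positive sampling weights, recycled to 1.
#' @return numeric vector of ranks, strictly inside (0, 1), same order
#'   as the input.
#' @examples
#' fractional_rank(c(10, 20, 30, 40, 50))     # 0.1 0.3 0.5 0.7 0.9
#' fractional_rank(c(1, 1, 2))                # 1/3 1/3 5/6
#' @export
fractional_rank <- function(income, weights = NULL) {
  income <- as.numeric(income)
  n <- length(income)
  if (n == 0L) stop("'income' is empty", call. = FALSE)
  if (anyNA(income)) stop("'income' contains missing values", call. = FALSE)
  weights <- check_weights(weights, n)

  ord <- order(income)
  w <- weights[ord]
  total <- sum(w)
  # Midpoint of each tied group's weight span.
  grp <- cumsum(!duplicated(income[ord]))
  gw <- tapply(w, grp, sum)
  ghi <- cumsum(gw)
  gmid <- (ghi - gw / 2) / total
  gamma <- numeric(n)
  gamma[ord] <- gmid[grp]
  gamma
}

#' Pair an outcome with its income ranks
#'
#' Bundles an outcome vector with the fractional income ranks, weights
#' and weighted outcome mean — the inputs every concentration measure
#' consumes.
#'
#' @param outcome numeric outcome vector (binary utilization indicators
#'   in the intended use, but any non-negative outcome is accepted).
#' @param income numeric ranking variable, same length.
#' @param weights optional positive weights.
#' @return an object of class \code{ranked_outcome}: a list with
#'   elements \code{y}, \code{gamma}, \code{weights}, \code{mu}.
#' @export
ranked_outcome <- function(outcome, income, weights = NULL) {
  y <- as.numeric(outcome)
  if (length(y) != length(income)) {
    stop("'outcome' and 'income' lengths differ", call. = FALSE)
  }
  if (anyNA(y)) stop("'outcome' contains missing values", call. = FALSE)
  weights <- check_weights(weights, length(y))
  gamma <- fractional_rank(income, weights)
  structure(
    list(y = y, gamma = gamma, weights = weights,
         mu = wmean(y, weights)),
    class = "ranked_outcome"
  )
}

#' @export
print.ranked_outcome <- function(x, ...) {
  cat("Ranked outcome: n =", length(x$y),
      " weighted mean =", format(x$mu, digits = 4),
      " mean rank =", format(wmean(x$gamma, x$weights), digits = 4), "\n")
  invisible(x)
}
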