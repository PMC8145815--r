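# Shared fixtures: published-table readers and small generator configs.

printed_tables <- function() {
  utils::read.csv(system.file("extdata", "printed_contingency_tables.csv",
                              package = "equidecomp"),
                  stringsAsFactors = FALSE)
}

printed_counts <- function(outcome, variable) {
  tab <- printed_tables()
  rows <- tab[tab$outcome == outcome & tab$variable == variable, ]
  m <- as.matrix(rows[, c("no", "yes")])
  rownames(m) <- rows$category
  m
}

published_composition <- function() {
  utils::read.csv(system.file("extdata", "published_composition.csv",
                              package = "equidecomp"),
                  stringsAsFactors = FALSE)
}

# A generator config with every systematic effect switched off: flat
# covariates, no income gradient, no clustering. Used wherever a null
# structure is the ground truth.
null_config <- function(p_outpatient = 0.1, n = 5000, seed = 1) {
  cov <- default_covariates()
  flat <- lapply(cov, function(cv) {
    p <- cv$probs
    if (!is.null(dim(p))) p <- colMeans(p)
    list(levels = cv$levels, probs = p / sum(p))
  })
  sim_config(
    n_respondents = n, n_clusters = 50,
    covariates = flat,
    outcomes = list(outpatient = list(
      intercept = stats::qlogis(p_outpatient),
      income_gradient = 0, effects = list())),
    cluster_sd = 0, seed = seed)
}

# Deterministic 6-row worked dataset for the decomposition; the
# expected values below were computed independently by direct matrix
# arithmetic (normal equations and covariance sums) and frozen:
#   C = 1/4, c_need = 1/2, c_other = 1/6,
#   contribution_need = 3/16, contribution_other = 1/16,
#   residual = 0, HI = 1/16.
toy_decomp_data <- function() {
  data.frame(
    y = c(0, 1, 0, 1, 1, 1),
    income = 1:6,
    need_var = factor(c("No", "No", "No", "Yes", "Yes", "Yes"),
                      levels = c("No", "Yes")),
    other_var = factor(c("No", "Yes", "No", "Yes", "No", "Yes"),
                       levels = c("No", "Yes")))
}
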