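# Synthetic survey generator: respondent-level data shaped like a rural
# middle-aged/elderly utilization survey, with a known ground-truth
# inequality structure, so the whole pipeline can be exercised and
# tested without restricted microdata.

#' Default covariate layout for the synthetic survey
#'
#' Categorical covariates with category probabilities close to the
#' marginal frequencies of a rural middle-aged/elderly utilization
#' survey (roughly 53\% female, 55\% with chronic disease, 25/50/25
#' economic strata, ...). Health-status covariates (disability, body
#' pain, chronic diseases) have probabilities that step across income
#' tertiles — the poor carry more morbidity — which is what makes need
#' contributions and the horizontal inequity construction non-trivial.
#' Economic status steps across income quartile bands with overlap, so
#' it is strongly but imperfectly rank-correlated, as a self-assessed
#' wealth measure would be.
#'
#' Each covariate is a list with \code{levels} (first level = reference)
#' and \code{probs}: either a probability vector (income-independent) or
#' a matrix with one row per equal-width income-rank band and one column
#' per level (piecewise rank-dependent).
#'
#' @return named list of covariate definitions.
#' @export
default_covariates <- function() {
  list(
    sex = list(levels = c("Male", "Female"),
               probs = c(0.4675, 0.5325)),
    age_group = list(levels = c("45-50", "51-60", "61-70", "71+"),
                     probs = c(0.1742, 0.3458, 0.3022, 0.1778)),
    education = list(levels = c("Illiterate", "Elementary", "MiddleUp"),
                     probs = c(0.3062, 0.4525, 0.2413)),
    economic_status = list(levels = c("Low", "Middle", "High"),
                           probs = rbind(c(0.55, 0.40, 0.05),
                                         c(0.30, 0.55, 0.15),
                                         c(0.15, 0.55, 0.30),
                                         c(0.05, 0.40, 0.55))),
    living_status = list(levels = c("WithOthers", "Alone"),
                         probs = c(0.789, 0.211)),
    sleeping_hours = list(levels = c("7-8h", "<=6h", ">8h"),
                          probs = c(0.3594, 0.5030, 0.1376)),
    smoking = list(levels = c("No", "Yes"),
                   probs = c(0.7304, 0.2696)),
    alcohol = list(levels = c("No", "Yes"),
                   probs = c(0.6762, 0.3238)),
    disability = list(levels = c("No", "Yes"),
                      probs = rbind(c(0.75, 0.25),
                                    c(0.81, 0.19),
                                    c(0.87, 0.13))),
    body_pain = list(levels = c("No", "Yes"),
                     probs = rbind(c(0.44, 0.56),
                                   c(0.515, 0.485),
                                   c(0.59, 0.41))),
    chronic_diseases = list(levels = c("No", "Yes"),
                            probs = rbind(c(0.38, 0.62),
                                          c(0.45, 0.55),
                                          c(0.52, 0.48)))
  )
}

default_outcomes <- function() {
  list(
    outpatient = list(
      intercept = -2.32,
      income_gradient = -0.20,
      effects = list(
        sex = c(Female = 0.06),
        education = c(Elementary = 0.10, MiddleUp = 0.10),
        economic_status = c(Middle = -0.03, High = -0.08),
        living_status = c(Alone = 0.02),
        sleeping_hours = c("<=6h" = 0.19, ">8h" = 0.04),
        smoking = c(Yes = 0.06),
        alcohol = c(Yes = 0.24),
        disability = c(Yes = 0.04),
        body_pain = c(Yes = 0.67),
        chronic_diseases = c(Yes = 0.68)
      )
    ),
    inpatient = list(
      intercept = -3.58,
      income_gradient = -0.15,
      effects = list(
        sex = c(Female = -0.16),
        age_group = c("51-60" = 0.17, "61-70" = 0.57, "71+" = 0.87),
        education = c(Elementary = 0.16, MiddleUp = 0.09),
        economic_status = c(Middle = -0.14, High = -0.07),
        living_status = c(Alone = -0.06),
        sleeping_hours = c("<=6h" = 0.09, ">8h" = 0.10),
        smoking = c(Yes = 0.06),
        alcohol = c(Yes = 0.46),
        disability = c(Yes = 0.35),
        body_pain = c(Yes = 0.32),
        chronic_diseases = c(Yes = 0.73)
      )
    )
  )
}

#' Configuration for the synthetic survey generator
#'
#' Bundles and validates every knob of the generator: wave size, number
#' of community clusters, the log-normal household income distribution,
#' covariate category probabilities (optionally stepping across income
#' rank bands), and per-outcome logistic coefficients
#' (\code{intercept}, \code{income_gradient} on the fractional rank,
#' and named per-level log-odds \code{effects}). Outcomes are generated
#' as Bernoulli with
#' \deqn{\mathrm{logit}\,p_i = a + g\,\gamma_i + \textstyle\sum_k \beta_k x_{ki} + b_{c(i)}}
#' with community random intercepts \eqn{b_c \sim N(0, \mathrm{cluster\_sd}^2)}.
#'
#' @param n_respondents respondents per wave.
#' @param n_clusters number of community clusters.
#' @param income_meanlog,income_sdlog log-normal income parameters
#'   (currency units; defaults give a long-right-tailed household
#'   income around 20,000).
#' @param covariates covariate definitions, see [default_covariates()].
#' @param outcomes per-outcome coefficient lists, see Details.
#' @param cluster_sd standard deviation of the community random
#'   intercept on the log-odds scale.
#' @param period period label stamped on every row.
#' @param seed integer RNG seed.
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_respondents = 12000,
                       n_clusters = 450,
                       income_meanlog = log(20000),
                       income_sdlog = 0.9,
                       covariates = default_covariates(),
                       outcomes = default_outcomes(),
                       cluster_sd = 0.3,
                       period = "before",
                       seed = 1L) {
  cfg <- structure(
    list(n_respondents = as.integer(n_respondents),
         n_clusters = as.integer(n_clusters),
         income_meanlog = income_meanlog,
         income_sdlog = income_sdlog,
         covariates = covariates,
         outcomes = outcomes,
         cluster_sd = cluster_sd,
         period = as.character(period),
         seed = as.integer(seed)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg a \code{sim_config} to validate.
#' @export
validate_sim_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid config field '%s': %s", field, msg), call. = FALSE)
  }
  if (is.na(cfg$n_respondents) || cfg$n_respondents < 1)
    fail("n_respondents", "must be a positive integer")
  if (is.na(cfg$n_clusters) || cfg$n_clusters < 1)
    fail("n_clusters", "must be a positive integer")
  if (cfg$n_respondents < cfg$n_clusters)
    fail("n_clusters", "cannot exceed n_respondents")
  if (!is.finite(cfg$income_sdlog) || cfg$income_sdlog <= 0)
    fail("income_sdlog", "must be > 0")
  if (!is.finite(cfg$cluster_sd) || cfg$cluster_sd < 0)
    fail("cluster_sd", "must be >= 0")
  if (is.na(cfg$seed)) fail("seed", "must be an integer")
  for (nm in names(cfg$covariates)) {
    cov <- cfg$covariates[[nm]]
    if (is.null(cov$levels) || length(cov$levels) < 2)
      fail(nm, "needs at least 2 levels")
    p <- cov$probs
    if (is.null(dim(p))) p <- matrix(p, nrow = 1)
    if (ncol(p) != length(cov$levels))
      fail(nm, "probs columns must match levels")
    if (any(p < 0) || any(p > 1))
      fail(nm, "probabilities must lie in [0, 1]")
    if (any(abs(rowSums(p) - 1) > 1e-8))
      fail(nm, "probabilities must sum to 1 within each band")
  }
  for (onm in names(cfg$outcomes)) {
    oc <- cfg$outcomes[[onm]]
    if (!is.finite(oc$intercept))
      fail(paste0(onm, "$intercept"), "must be finite")
    if (!is.finite(oc$income_gradient))
      fail(paste0(onm, "$income_gradient"), "must be finite")
    for (cn in names(oc$effects)) {
      cov <- cfg$covariates[[cn]]
      if (is.null(cov))
        fail(paste0(onm, "$effects$", cn), "unknown covariate")
      eff <- oc$effects[[cn]]
      bad <- setdiff(names(eff), cov$levels[-1])
      if (length(bad))
        fail(paste0(onm, "$effects$", cn),
             sprintf("levels not among non-reference levels: %s",
                     paste(bad, collapse = ", ")))
    }
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic survey config:", x$n_respondents, "respondents,",
      x$n_clusters, "clusters, period =", x$period,
      ", seed =", x$seed, "\n")
  cat("  outcomes:", paste(names(x$outcomes), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic survey wave
#'
#' Draws a respondent-level dataset from a [sim_config()]: log-normal
#' household incomes, community assignments with normal random
#' intercepts, categorical covariates (probabilities possibly stepping
#' across income rank bands), and Bernoulli outcomes with the
#' configured logit structure. Deterministic given the seed.
#'
#' @param config a \code{sim_config}.
#' @param seed optional seed overriding \code{config$seed}.
#' @return data frame with columns \code{income}, \code{weight},
#'   \code{cluster}, \code{period}, one factor column per covariate and
#'   one 0/1 column per outcome.
#' @export
simulate_survey <- function(config, seed = NULL) {
  config <- validate_sim_config(config)
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  n <- config$n_respondents

  income <- stats::rlnorm(n, config$income_meanlog, config$income_sdlog)
  gamma <- fractional_rank(income)
  cluster <- sample.int(config$n_clusters, n, replace = TRUE)
  b <- stats::rnorm(config$n_clusters, 0, config$cluster_sd)

  d <- data.frame(income = income, weight = 1,
                  cluster = cluster, period = config$period,
                  stringsAsFactors = FALSE)

  for (nm in names(config$covariates)) {
    cov <- config$covariates[[nm]]
    p <- cov$probs
    if (is.null(dim(p))) p <- matrix(p, nrow = 1)
    nb <- nrow(p)
    band <- pmin(pmax(ceiling(gamma * nb), 1L), nb)
    val <- character(n)
    for (bnd in seq_len(nb)) {
      idx <- which(band == bnd)
      if (length(idx)) {
        val[idx] <- sample(cov$levels, length(idx), replace = TRUE,
                           prob = p[bnd, ])
      }
    }
    d[[nm]] <- factor(val, levels = cov$levels)
  }

  for (onm in names(config$outcomes)) {
    oc <- config$outcomes[[onm]]
    eta <- oc$intercept + oc$income_gradient * gamma + b[cluster]
    for (cn in names(oc$effects)) {
      eff <- oc$effects[[cn]]
      lv <- config$covariates[[cn]]$levels
      full <- stats::setNames(numeric(length(lv)), lv)
      full[names(eff)] <- eff
      eta <- eta + unname(full[as.character(d[[cn]])])
    }
    d[[onm]] <- stats::rbinom(n, 1, stats::plogis(eta))
  }
  d
}

#' Simulate a two-period study
#'
#' Stacks a "before" and an "after" wave generated from two configs
#' (typically the after config alters outcome intercepts or gradients
#' to emulate a policy change). The configs' \code{period} labels and
#' seeds should differ.
#'
#' @param config_before,config_after \code{sim_config}s for each wave.
#' @return stacked data frame of both waves.
#' @export
simulate_study <- function(config_before, config_after) {
  rbind(simulate_survey(config_before), simulate_survey(config_after))
}

#' Ground-truth concentration index implied by a config
#'
#' Monte-Carlo estimate of the large-sample concentration index a
#' config implies for one outcome: repeated fresh draws of
#' \code{n_montecarlo} respondents, with the index computed on each and
#' the spread reported as a Monte-Carlo standard error. Used as the
#' oracle in parameter-recovery tests.
#'
#' @param config a \code{sim_config}.
#' @param outcome outcome name, default the first configured one.
#' @param n_montecarlo rows per replicate draw.
#' @param nrep number of replicate draws.
#' @return list with \code{value} (mean index), \code{mc_se},
#'   \code{nrep}, \code{n_montecarlo}.
#' @export
true_concentration_index <- function(config, outcome = NULL,
                                     n_montecarlo = 1e5, nrep = 5) {
  config <- validate_sim_config(config)
  if (is.null(outcome)) outcome <- names(config$outcomes)[1]
  if (!outcome %in% names(config$outcomes)) {
    stop(sprintf("unknown outcome '%s'", outcome), call. = FALSE)
  }
  cfg <- config
  cfg$n_respondents <- as.integer(n_montecarlo)
  vals <- vapply(seq_len(nrep), function(r) {
    rep_seed <- (config$seed + r * 1000003L) %% .Machine$integer.max
    d <- simulate_survey(cfg, seed = rep_seed)
    r <- ranked_outcome(d[[outcome]], d$income)
    2 * wcov(r$y, r$gamma, r$weights) / r$mu
  }, numeric(1))
  list(value = mean(vals),
       mc_se = stats::sd(vals) / sqrt(nrep),
       nrep = nrep, n_montecarlo = n_montecarlo)
}

#' Validate a respondent-level survey dataset
#'
#' Checks the contract every analysis stage assumes: named outcome
#' columns strictly 0/1, positive income and weights, non-missing
#' cluster and period, no missing covariate values.
#'
#' @param data data frame.
#' @param outcomes character vector of outcome column names.
#' @param income,weight,cluster,period column names (weight optional:
#'   if absent a unit-weight column is added).
#' @return the validated data frame, invisibly modified (weight column
#'   added when missing).
#' @export
validate_survey <- function(data, outcomes = c("outpatient", "inpatient"),
                            income = "income", weight = "weight",
                            cluster = "cluster", period = "period") {
  need <- c(outcomes, income, cluster, period)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (o in outcomes) check_binary(data[[o]], o)
  inc <- data[[income]]
  if (anyNA(inc) || any(inc <= 0)) {
    stop(sprintf("'%s' must be positive and non-missing", income),
         call. = FALSE)
  }
  if (!weight %in% names(data)) {
    data[[weight]] <- 1
  } else {
    check_weights(data[[weight]], nrow(data), weight)
  }
  if (anyNA(data[[cluster]]) || anyNA(data[[period]])) {
    stop("cluster and period must be non-missing", call. = FALSE)
  }
  if (anyNA(data)) stop("dataset contains missing values", call. = FALSE)
  invisible(data)
}

#' Write / read a survey dataset as CSV
#'
#' Plain UTF-8 CSV with a header row and "." decimal separator; factor
#' columns round-trip as character and are restored by level-order of
#' appearance on read.
#'
#' @param data data frame to write.
#' @param path file path.
#' @return \code{read_survey_csv} returns the data frame.
#' @export
write_survey_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
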