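test_that("logistic coefficients recover the generator truth", {
  cfg <- sim_config(n_respondents = 20000, n_clusters = 200,
                    cluster_sd = 0, seed = 41)
  cfg$outcomes$outpatient$income_gradient <- 0  # model then matches the DGP
  d <- simulate_survey(cfg)
  covs <- names(cfg$covariates)
  m <- fit_outcome_model(d, "outpatient", covs, method = "logit",
                         cluster = "cluster")
  truth <- c("(Intercept)" = cfg$outcomes$outpatient$intercept)
  for (cn in names(cfg$outcomes$outpatient$effects)) {
    eff <- cfg$outcomes$outpatient$effects[[cn]]
    names(eff) <- paste0(cn, names(eff))
    truth <- c(truth, eff)
  }
  # every configured non-zero effect within 3 robust SEs
  tab <- m$or_table
  idx <- match(names(truth), tab$term)
  expect_false(anyNA(idx))
  zdev <- abs(tab$estimate[idx] - truth) / tab$se[idx]
  expect_true(all(zdev < 3))
})

test_that("odds-ratio table regenerates exactly from the coefficients", {
  d <- simulate_survey(sim_config(n_respondents = 3000, n_clusters = 50,
                                  seed = 42))
  m <- fit_outcome_model(d, "inpatient", c("sex", "age_group"),
                         method = "logit", cluster = "cluster")
  expect_equal(m$or_table$OR, exp(m$or_table$estimate), tolerance = 1e-12)
  expect_equal(unname(coef(m)), m$or_table$estimate, tolerance = 1e-12)
  expect_equal(dim(vcov(m)), rep(length(coef(m)), 2))
})

test_that("duplicating rows at half weight leaves estimates unchanged", {
  d <- simulate_survey(sim_config(n_respondents = 2000, n_clusters = 40,
                                  seed = 43))
  m1 <- fit_outcome_model(d, "outpatient", c("sex", "chronic_diseases"),
                          method = "logit", cluster = "cluster")
  dd <- rbind(d, d)
  dd$weight <- 0.5
  m2 <- fit_outcome_model(dd, "outpatient", c("sex", "chronic_diseases"),
                          method = "logit", cluster = "cluster",
                          weights = "weight")
  expect_equal(coef(m1), coef(m2), tolerance = 1e-8)
})

test_that("random-intercept fit recovers the community variance and falls back at the boundary", {
  cfg <- sim_config(n_respondents = 6000, n_clusters = 60,
                    cluster_sd = 0.8, seed = 44)
  cfg$covariates <- cfg$covariates[c("sex", "chronic_diseases")]
  cfg$outcomes <- list(outpatient = list(
    intercept = -1.5, income_gradient = 0,
    effects = list(chronic_diseases = c(Yes = 0.7))))
  d <- simulate_survey(cfg)
  m <- fit_outcome_model(d, "outpatient", c("sex", "chronic_diseases"),
                         cluster = "cluster", method = "glmm")
  expect_identical(m$method, "glmm")
  expect_gt(m$random_intercept_sd, 0.5)
  expect_lt(m$random_intercept_sd, 1.2)

  # boundary: no community variance in the data -> plain logistic with
  # cluster-robust errors, coefficients close to the GLMM fixed effects
  cfg0 <- cfg; cfg0$cluster_sd <- 0
  d0 <- simulate_survey(cfg0)
  m0 <- fit_outcome_model(d0, "outpatient", c("sex", "chronic_diseases"),
                          cluster = "cluster", method = "auto")
  expect_identical(m0$method, "logit")
  expect_lt(m0$random_intercept_sd, 1e-3)
  mg <- suppressWarnings(  # forced GLMM at the boundary warns, by design
    fit_outcome_model(d0, "outpatient", c("sex", "chronic_diseases"),
                      cluster = "cluster", method = "glmm"))
  expect_lt(max(abs(coef(m0) - coef(mg))), 0.02)
})

test_that("GLMM coefficients are stable across quadrature resolutions", {
  cfg <- sim_config(n_respondents = 3000, n_clusters = 60,
                    cluster_sd = 0.5, seed = 45)
  cfg$covariates <- cfg$covariates[c("sex", "body_pain")]
  cfg$outcomes <- list(outpatient = list(
    intercept = -1.3, income_gradient = 0,
    effects = list(body_pain = c(Yes = 0.6))))
  d <- simulate_survey(cfg)
  m10 <- fit_outcome_model(d, "outpatient", c("sex", "body_pain"),
                           cluster = "cluster", method = "glmm", nAGQ = 10)
  m25 <- fit_outcome_model(d, "outpatient", c("sex", "body_pain"),
                           cluster = "cluster", method = "glmm", nAGQ = 25)
  expect_lt(max(abs(coef(m10) - coef(m25))), 1e-4)
})

test_that("average marginal effects follow the closed-form logistic evaluation", {
  set.seed(46)
  n <- 4000
  x <- factor(sample(c("No", "Yes"), n, TRUE), levels = c("No", "Yes"))
  y <- rbinom(n, 1, plogis(-0.5 + 1.2 * (x == "Yes")))
  d <- data.frame(y = y, x = x)
  m <- fit_outcome_model(d, "y", "x", cluster = NULL, method = "logit")
  ame <- average_marginal_effects(m, d)
  a <- coef(m)[["(Intercept)"]]; b <- coef(m)[["xYes"]]
  # discrete change is constant over the sample for a single binary x
  expect_equal(ame$ame, plogis(a + b) - plogis(a), tolerance = 1e-10)
  expect_equal(ame$xbar, mean(x == "Yes"))
  expect_true(abs(ame$ame) < 1)
})

test_that("a zero coefficient yields a zero marginal effect", {
  set.seed(47)
  n <- 1000
  d <- data.frame(
    y = rbinom(n, 1, 0.3),
    x = factor(sample(c("A", "B"), n, TRUE)),
    z = factor(sample(c("No", "Yes"), n, TRUE), levels = c("No", "Yes")))
  m <- fit_outcome_model(d, "y", c("x", "z"), cluster = NULL,
                         method = "logit")
  m$fit$coefficients["zYes"] <- 0
  m$coefficients["zYes"] <- 0
  ame <- average_marginal_effects(m, d)
  expect_equal(ame$ame[ame$term == "zYes"], 0, tolerance = 1e-12)
})

test_that("marginal effects match finite differences of predicted probabilities", {
  d <- simulate_survey(sim_config(n_respondents = 2500, n_clusters = 50,
                                  seed = 48))
  m <- fit_outcome_model(d, "outpatient",
                         c("sex", "economic_status", "chronic_diseases"),
                         cluster = "cluster", method = "logit")
  ame <- average_marginal_effects(m, d)
  for (i in seq_len(nrow(ame))) {
    v <- ame$covariate[i]; L <- ame$level[i]
    lev <- levels(d[[v]])
    dL <- d; dL[[v]] <- factor(L, levels = lev)
    d0 <- d; d0[[v]] <- factor(lev[1], levels = lev)
    manual <- mean(predict(m$fit, dL, type = "response") -
                     predict(m$fit, d0, type = "response"))
    expect_equal(ame$ame[i], manual, tolerance = 1e-8)
  }
})

test_that("null effects give a z distribution consistent with the null", {
  cfg <- null_config(p_outpatient = 0.2, n = 8000, seed = 49)
  d <- simulate_survey(cfg)
  covs <- setdiff(names(default_covariates()), "economic_status")
  m <- fit_outcome_model(d, "outpatient", covs, cluster = "cluster",
                         method = "logit")
  tab <- m$or_table[m$or_table$term != "(Intercept)", ]
  z <- abs(tab$estimate / tab$se)
  # about 5% of truly-null terms should exceed 1.96; allow sampling slack
  expect_lte(sum(z > 1.96), ceiling(0.25 * length(z)))
  expect_gt(mean(z < 1.2), 0.4)
})
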