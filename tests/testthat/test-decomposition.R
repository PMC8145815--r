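test_that("determinant index matches closed-form oracles", {
  # x = gamma itself: c -> 2 var(gamma)/E(gamma) = 2*(1/12)/(1/2) = 1/3
  n <- 10001
  g <- (2 * seq_len(n) - 1) / (2 * n)
  expect_equal(determinant_index(g, g), 1 / 3, tolerance = 1e-3)

  # constant determinant: zero concentration
  expect_equal(determinant_index(rep(1, 100), fractional_rank(1:100)), 0)

  # indicator of the richest half on evenly spaced ranks: exactly 0.5
  n <- 1000
  g <- (2 * seq_len(n) - 1) / (2 * n)
  x <- as.numeric(g > 0.5)
  expect_equal(determinant_index(x, g), 0.5, tolerance = 1e-12)

  expect_error(determinant_index(rep(0, 10), fractional_rank(1:10)),
               "zero mean")
})

test_that("OLS decomposition satisfies the identity exactly", {
  d <- simulate_survey(sim_config(n_respondents = 4000, n_clusters = 80,
                                  seed = 51))
  dc <- ci_decomp(outpatient ~ sex + age_group + education +
                    economic_status + chronic_diseases,
                  data = d, method = "ols", cluster = "cluster")
  # remainder residual coincides with the residual generalized index
  expect_equal(dc$residual, dc$gc_residual, tolerance = 1e-9)
  # rows + residual total the index
  expect_equal(sum(dc$table$contribution) + dc$residual, dc$C,
               tolerance = 1e-9)
  expect_equal(sum(dc$groups$contribution[-1]), dc$C, tolerance = 1e-9)
  # and it also holds under non-unit weights
  d$weight <- runif(nrow(d), 0.5, 2)
  dcw <- ci_decomp(outpatient ~ sex + economic_status + chronic_diseases,
                   data = d, method = "ols", weights = "weight")
  expect_equal(dcw$residual, dcw$gc_residual, tolerance = 1e-9)
})

test_that("the 6-row worked example reproduces the hand-computed values", {
  d <- toy_decomp_data()
  dc <- ci_decomp(y ~ need_var + other_var, data = d, need = "need_var",
                  method = "ols")
  expect_equal(dc$C, 1 / 4, tolerance = 1e-12)
  tab <- dc$table
  expect_equal(tab$c_k[tab$covariate == "need_var"], 1 / 2,
               tolerance = 1e-12)
  expect_equal(tab$c_k[tab$covariate == "other_var"], 1 / 6,
               tolerance = 1e-12)
  expect_equal(tab$contribution[tab$covariate == "need_var"], 3 / 16,
               tolerance = 1e-12)
  expect_equal(tab$contribution[tab$covariate == "other_var"], 1 / 16,
               tolerance = 1e-12)
  expect_equal(dc$residual, 0, tolerance = 1e-12)
  expect_equal(horizontal_inequity(dc), 1 / 16, tolerance = 1e-12)
})

test_that("horizontal inequity arithmetic follows C minus need contribution", {
  d <- toy_decomp_data()
  # empty need set: nothing subtracted, HI equals the index
  dc0 <- ci_decomp(y ~ need_var + other_var, data = d,
                   need = character(0), method = "ols")
  expect_equal(horizontal_inequity(dc0), dc0$C)
  # the full determinant set as need: HI is the residual
  dc1 <- ci_decomp(y ~ need_var + other_var, data = d,
                   need = c("need_var", "other_var"), method = "ols")
  expect_equal(horizontal_inequity(dc1), dc1$residual, tolerance = 1e-12)
  expect_error(
    ci_decomp(y ~ need_var, data = d, need = "ghost", method = "ols"),
    "unknown determinants")
})

test_that("rank-independent determinants contribute nothing", {
  # x is exactly balanced across the income ranks: cov(x, gamma) = 0
  d <- data.frame(
    y = c(1, 0, 1, 0, 0, 1, 0, 1),
    income = 1:8,
    x = factor(c("B", "A", "A", "B", "B", "A", "A", "B")))
  dc <- ci_decomp(y ~ x, data = d, need = character(0), method = "ols")
  expect_equal(dc$table$c_k, 0, tolerance = 1e-12)
  expect_equal(dc$table$contribution, 0, tolerance = 1e-12)
  expect_equal(dc$residual, dc$C, tolerance = 1e-12)
})

test_that("a determinant orthogonal to outcome and income leaves HI unchanged", {
  # z is exactly orthogonal to the intercept, x, income order and y
  d <- data.frame(
    y = c(0, 0, 0, 0, 1, 1, 1, 1),
    income = 1:8,
    x = factor(c("A", "A", "A", "A", "B", "B", "B", "B")),
    z = factor(c("N", "Y", "Y", "N", "N", "Y", "Y", "N")))
  with_z <- ci_decomp(y ~ x + z, data = d, need = "x", method = "ols")
  without_z <- ci_decomp(y ~ x, data = d, need = "x", method = "ols")
  expect_lt(abs(with_z$HI - without_z$HI), 1e-6)
})

test_that("percent contributions are invariant to outcome rescaling", {
  set.seed(52)
  n <- 500
  d <- data.frame(
    income = rlnorm(n, 9, 1),
    x = factor(sample(c("No", "Yes"), n, TRUE)))
  d$y <- 2 + 0.5 * (d$x == "Yes") + rnorm(n, 0, 0.3) +
    fractional_rank(d$income)
  d2 <- d; d2$y <- 3 * d$y
  p1 <- ci_decomp(y ~ x, data = d, need = character(0), method = "ols")
  p2 <- ci_decomp(y ~ x, data = d2, need = character(0), method = "ols")
  expect_equal(p1$table$pct, p2$table$pct, tolerance = 1e-9)
  expect_equal(p1$C, p2$C, tolerance = 1e-12)
})

test_that("AME and OLS decompositions agree on the broad structure", {
  d <- simulate_survey(sim_config(n_respondents = 6000, n_clusters = 100,
                                  seed = 53))
  fml <- outpatient ~ sex + age_group + economic_status + chronic_diseases
  ame <- ci_decomp(fml, data = d, cluster = "cluster", method = "ame")
  ols <- ci_decomp(fml, data = d, cluster = "cluster", method = "ols")
  expect_equal(ame$C, ols$C, tolerance = 1e-12)  # same total index
  expect_lt(abs(ame$HI - ols$HI), 0.02)          # approximations agree
  # AME-mode remainder and direct residual index are close at this n
  expect_lt(abs(ame$residual - ame$gc_residual), 0.02)
  # grouped table mirrors the published layout
  expect_identical(ame$groups$group,
                   c("CI", "Needs variables", "Economic status",
                     "Other variables", "Residuals"))
  expect_equal(sum(ame$groups$pct[-1]), 100, tolerance = 1e-9)
})
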