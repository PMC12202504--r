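test_that("univariate screen advances real effects and flags separation", {
  co <- simulate_cohort(seed = 17)
  sc <- univariate_screen(co)
  expect_true(all(c("hu_delta", "hu_ratio") %in% sc$advancing))
  expect_true(all(sc$fits$ci_lo <= sc$fits$estimate &
                    sc$fits$estimate <= sc$fits$ci_hi, na.rm = TRUE))
  # a covariate identical to the outcome separates perfectly
  df <- data.frame(outcome = factor(rep(c("residual", "closed"), each = 20),
                                    levels = c("residual", "closed")))
  df$mirror <- as.numeric(df$outcome == "residual")
  expect_warning(sc2 <- univariate_screen(df), "separation|convergence")
  expect_false(sc2$fits$converged)
  expect_false("mirror" %in% sc2$advancing)
})

test_that("VIF matches its closed form and removes collinear variables", {
  set.seed(9)
  n <- 200
  # orthogonal predictors: all VIFs 1, nothing removed
  z1 <- rnorm(n); z2 <- residuals(lm(rnorm(n) ~ z1))
  df <- data.frame(a = z1, b = z2)
  vf <- vif_filter(df, c("a", "b"))
  expect_equal(unname(vf$vif), c(1, 1), tolerance = 1e-8)
  expect_length(vf$removed, 0)
  # exact sample correlation rho = 0.95: VIF = 1/(1 - rho^2), one removed
  rho <- 0.95
  u1 <- scale(z1)[, 1]; u2 <- scale(z2)[, 1]
  df2 <- data.frame(a = u1, b = rho * u1 + sqrt(1 - rho^2) * u2)
  vifs <- vif_filter(df2, c("a", "b"), limit = Inf)$vif
  expect_equal(unname(vifs), rep(1 / (1 - rho^2), 2), tolerance = 1e-8)
  vf2 <- vif_filter(df2, c("a", "b"), limit = 10)
  expect_length(vf2$retained, 1)
  expect_length(vf2$removed, 1)
  # duplicated predictor: infinite VIF, one copy removed first
  df3 <- data.frame(a = z1, b = z1, c = z2)
  vf3 <- vif_filter(df3, c("a", "b", "c"))
  expect_length(vf3$retained, 2)
  expect_true(vf3$removed %in% c("a", "b"))
  expect_true(all(vf3$vif <= 10))
})

test_that("VIF agrees with an independent implementation on a real fit", {
  skip_if_not_installed("car")
  co <- simulate_cohort(seed = 12)
  vars <- c("hu_delta", "hu_ratio", "wbc", "aptt")
  ours <- vif_filter(co, vars, limit = Inf)$vif
  ref <- car::vif(lm(rnorm(nrow(co)) ~ hu_delta + hu_ratio + wbc + aptt,
                     data = co))
  expect_equal(unname(ours[vars]), unname(ref[vars]), tolerance = 1e-6)
})

test_that("multivariate fit reports Wald intervals, VIFs and sign pattern", {
  co <- simulate_cohort(seed = 4)
  fit <- multivariate_logistic(co, c("hu_delta", "hu_ratio"))
  expect_true(fit$converged)
  cf <- fit$coefficients
  expect_true(all(cf$ci_lo <= cf$estimate & cf$estimate <= cf$ci_hi))
  expect_true(all(cf$vif >= 1))
  # under the two-group structure the delta coefficient is positive and the
  # ratio coefficient negative (higher delta / lower ratio in cases)
  expect_gt(cf$estimate[cf$term == "hu_delta"], 0)
  expect_lt(cf$estimate[cf$term == "hu_ratio"], 0)
  expect_lt(max(cf$p_value), 0.05)
})

test_that("screen advancement matches its nominal rate under the null", {
  set.seed(6)
  hits <- 0; total <- 0
  for (s in 1:150) {
    df <- data.frame(
      outcome = factor(rep(c("residual", "closed"), c(56, 76)),
                       levels = c("residual", "closed")),
      z1 = rnorm(132), z2 = rnorm(132))
    sc <- suppressWarnings(univariate_screen(df))
    hits <- hits + length(sc$advancing); total <- total + 2
  }
  rate <- hits / total
  se <- sqrt(0.05 * 0.95 / total)
  expect_lt(abs(rate - 0.05), 3 * se)
})
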