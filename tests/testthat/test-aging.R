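test_that("exact linear and quadratic data are interpolated", {
  ages <- c(20, 30, 40, 55, 70, 82)
  fits <- fit_age_models(2 + 3 * ages, ages)
  expect_equal(fits$linear$coef, c(2, 3), tolerance = 1e-10)
  expect_equal(fits$linear$sse, 0, tolerance = 1e-16)
  y <- 1 - 0.05 * ages + 0.002 * ages^2
  fits2 <- fit_age_models(y, ages)
  expect_equal(fits2$quadratic$coef, c(1, -0.05, 0.002), tolerance = 1e-8)
  expect_equal(fits2$quadratic$sse, 0, tolerance = 1e-12)
  expect_gt(fits2$linear$sse, 0)
  expect_error(fit_age_models(y[1:3], ages[1:3]), "at least 4")
  expect_error(fit_age_models(y, rep(50, 6)), "all equal")
})

test_that("OLS coefficients match the normal-equations oracle", {
  ages <- seq(20, 70, by = 10)
  y <- 0.4 - 0.001 * ages + c(0.003, -0.002, 0.001, 0.004, -0.003, -0.001)
  fits <- fit_age_models(y, ages)
  expect_equal(fits$linear$coef, ols_normal_eq(y, cbind(1, ages)),
               tolerance = 1e-10)
  expect_equal(fits$quadratic$coef, ols_normal_eq(y, cbind(1, ages, ages^2)),
               tolerance = 1e-10)
  set.seed(9)
  for (i in 1:100) {
    n <- sample(5:12, 1)
    a <- runif(n, 20, 82)
    yy <- rnorm(n)
    fits <- fit_age_models(yy, a)
    expect_equal(fits$linear$coef, ols_normal_eq(yy, cbind(1, a)),
                 tolerance = 1e-8)
    expect_equal(fits$quadratic$coef, ols_normal_eq(yy, cbind(1, a, a^2)),
                 tolerance = 1e-6)
    # nesting: the quadratic model can never fit worse
    expect_lte(fits$quadratic$sse, fits$linear$sse + 1e-12)
    expect_true(fits$linear$r >= 0 && fits$linear$r <= 1)
  }
})

test_that("model selection follows the extra-sum-of-squares F test", {
  ages <- c(20, 28, 37, 45, 51, 60, 68, 75, 82)
  # noise-free linear: both SSE 0, keep the simpler model
  fit <- select_model(fit_age_models(5 - 0.01 * ages, ages))
  expect_equal(fit$kind, "linear")
  # noise-free quadratic: quadratic wins with p ~ 0
  fitq <- select_model(fit_age_models(5 - 0.1 * ages + 0.01 * ages^2, ages))
  expect_equal(fitq$kind, "quadratic")
  expect_lt(fitq$p_quad, 1e-10)
  # noisy linear: F statistic nonnegative, selection defaults to linear
  set.seed(10)
  picks <- replicate(50, {
    y <- 1 - 0.005 * ages + rnorm(length(ages), 0, 0.05)
    f <- select_model(fit_age_models(y, ages))
    expect_gte(f$f_quad, 0)
    f$kind
  })
  expect_gt(mean(picks == "linear"), 0.7)
})

test_that("predictions and lifespan change follow the reporting rules", {
  fit <- age_model_from_coef(c(0.34, -0.88e-3))
  pr <- predict_and_diff(fit)
  expect_equal(pr$reported$pred_low, 0.32)
  expect_equal(pr$reported$pred_high, 0.27)
  expect_equal(pr$raw$pred_low, 0.3224, tolerance = 1e-12)
  fit2 <- age_model_from_coef(c(2.29, 5.26e-3))
  expect_equal(predict_and_diff(fit2)$reported$pct_diff, 13.2)
  flat <- age_model_from_coef(c(0.5, 0))
  prf <- predict_and_diff(flat)
  expect_equal(prf$raw$pct_diff, 0)
  expect_equal(prf$reported$pred_low, prf$reported$pred_high)
  # rounding is half away from zero and applied only at the report layer
  expect_equal(predict_and_diff(age_model_from_coef(c(0.125, 0)))$reported$pred_low, 0.13)
  expect_equal(predict_and_diff(age_model_from_coef(c(-0.125, 0)))$reported$pred_low, -0.13)
})

test_that("tertile grouping splits cohorts with remainder to the oldest", {
  g67 <- tertile_groups(sample_cohort_ages(67, c(20, 82), seed = 3))
  expect_equal(as.vector(table(g67)), c(22L, 22L, 23L))
  g6 <- tertile_groups(1:6)
  expect_equal(as.vector(g6), rep(c("young", "middle", "old"), each = 2),
               ignore_attr = TRUE)
  expect_equal(as.vector(table(tertile_groups(c(30, 50, 70)))), c(1L, 1L, 1L))
  # ages assigned by rank, not input order
  g <- tertile_groups(c(80, 30, 55))
  expect_equal(as.character(g), c("old", "young", "middle"))
})

test_that("group matrix summaries compute elementwise mean and CoV", {
  w1 <- matrix(c(1, 0.2, 0.2, 1), 2, 2,
               dimnames = list(c("1", "2"), c("1", "2")))
  w2 <- matrix(c(1, 0.4, 0.4, 1), 2, 2,
               dimnames = list(c("1", "2"), c("1", "2")))
  gs <- group_matrix_summary(list(w1, w2, w1, w1),
                             factor(c("a", "a", "b", "b")))
  expect_equal(gs$a$mean[1, 2], 0.3)
  expect_equal(gs$a$cov[1, 2], sd(c(0.2, 0.4)) / 0.3, tolerance = 1e-12)
  expect_equal(gs$a$cov[1, 2], 0.4714, tolerance = 1e-4)
  expect_true(all(gs$b$cov[1, 2] == 0))
  w3 <- w2; rownames(w3) <- c("1", "3")
  expect_error(group_matrix_summary(list(w1, w3), factor(c("a", "a"))),
               "node sets")
})

test_that("the cohort report recovers designed effects and marks null scopes", {
  atlas <- small_atlas(sizes = c(hit = 6L, null = 6L), seed = 2)
  eff <- age_effect_model(c("hit", "null"),
                          list(hit = age_effect_linear(change = 0.4)))
  coh <- simulate_cohort(atlas, n = 24, effects = eff, seed = 77)
  matrices <- lapply(coh$subjects, function(s) subject_matrix(s$volume, atlas))
  res <- run_full_analysis(matrices, atlas$parcels, coh$cohort$age,
                           metrics = c("strength", "path_length"))
  rep <- res$report
  hit_str <- rep[rep$scope == "hit" & rep$metric == "strength", ]
  expect_equal(hit_str$model, "linear")
  expect_lt(hit_str$b1, 0)
  null_str <- rep[rep$scope == "null" & rep$metric == "strength", ]
  expect_equal(null_str$model, "/")
  expect_true(is.na(null_str$pct_diff))
  # declining strength means rising path length in the affected network
  # (whichever model the F test selects)
  hit_pl <- rep[rep$scope == "hit" & rep$metric == "path_length", ]
  expect_true(hit_pl$significant)
  expect_gt(hit_pl$pct_diff, 0)
  # between-network pair analyzed
  expect_true("hit:null" %in% rep$scope)
  # hub counts table covers all scopes and the groups partition the cohort
  expect_equal(as.vector(table(res$groups)), c(8L, 8L, 8L))
  expect_true(all(c("whole_brain", "hit", "null") %in% res$hub_counts$scope))
})
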