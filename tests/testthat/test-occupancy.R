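test_that("covariate reduction: independent covariates keep eigenvalues near 1", {
  set.seed(4)
  X <- matrix(rnorm(200 * 5), 200, 5, dimnames = list(NULL, paste0("v", 1:5)))
  cr <- reduce_covariates(X)
  expect_true(all(abs(cr$eigenvalues - 1) < 0.35))
  ## two perfectly correlated covariates among five: one PC soaks both
  X2 <- cbind(X[, 1:4], dup = X[, 1])
  cr2 <- reduce_covariates(X2)
  expect_lt(cr2$n_retained, 5)
  top <- which.max(cr2$eigenvalues)
  ld <- abs(cr2$loadings[, 1])
  expect_true(all(ld[c("v1", "dup")] > 0.7))
  ## constant covariate dropped with warning
  expect_warning(reduce_covariates(cbind(X, k = 1)), "constant")
  expect_error(reduce_covariates(X[1:2, ]), ">= 2 covariates")
})

test_that("latent-factor structure sets the retained components and loadings", {
  ## 16 covariates: three multi-covariate factors (forest block, human
  ## pressure, prey) plus 8 standalone covariates whose eigenvalues sit at
  ## the retention boundary of 1 (as in real covariate panels, where the
  ## printed eigenvalues straddle 1.0)
  set.seed(6)
  for (r in 1:3) {
    F3 <- matrix(rnorm(400 * 3), 400, 3)
    X <- cbind(F3[, 1] + rnorm(400, 0, .4), F3[, 1] + rnorm(400, 0, .4),
               F3[, 1] + rnorm(400, 0, .4),
               F3[, 2] + rnorm(400, 0, .4), F3[, 2] + rnorm(400, 0, .4),
               F3[, 2] + rnorm(400, 0, .4),
               F3[, 3] + rnorm(400, 0, .4), F3[, 3] + rnorm(400, 0, .4),
               matrix(rnorm(400 * 8), 400, 8))
    colnames(X) <- sprintf("v%02d", 1:16)
    cr <- reduce_covariates(X)
    ## the three blocks are always retained; standalone covariates add a
    ## boundary-dependent handful
    expect_gte(cr$n_retained, 3)
    expect_lte(cr$n_retained, 11)
    expect_gte(sort(cr$eigenvalues, decreasing = TRUE)[3], 1)
    ## varimax assigns each block to a single rotated component
    block1 <- abs(cr$loadings[1:3, ])
    expect_equal(length(unique(apply(block1, 1, which.max))), 1)
    expect_true(all(apply(block1, 1, max) > 0.7))
    ## explained variance accounting stays within 100%
    expect_lte(max(cr$cumulative), 100 + 1e-9)
  }
})

test_that("perfect detection collapses the fit to naive occupancy", {
  cfg <- sim_config(seed = 5, surveys_per_grid = c(4, 4))
  h <- gen_detection_histories(rep(0.5, 400), 1, cfg, seed = 2)
  fit <- fit_occupancy(h, ~ 1, "constant")
  naive <- mean(vapply(h$y, max, 0))
  expect_equal(mean(fit$psi_hat), naive, tolerance = 1e-4)
  expect_gt(mean(fit$p_hat), 0.99)
})

test_that("the likelihood at the MLE dominates the generating parameters", {
  cfg <- sim_config(seed = 8, surveys_per_grid = c(5, 5))
  h <- gen_detection_histories(rep(0.6, 250), 0.3, cfg, seed = 3)
  fit <- fit_occupancy(h, ~ 1, "constant")
  ## hand likelihood at the truth
  ll_at <- function(psi, p) {
    sum(vapply(h$y, function(yv) {
      cond <- prod(ifelse(yv == 1, p, 1 - p))
      log(psi * cond + (1 - psi) * all(yv == 0))
    }, 0))
  }
  expect_gte(fit$logLik, ll_at(0.6, 0.3) - 1e-8)
  ## coefficient table machinery
  s <- summary(fit, c_hat = 1.4)
  expect_equal(s$inflation, sqrt(1.4))
  expect_equal(s$coefficients$exponent, exp(coef(fit)), ignore_attr = TRUE)
  expect_equal(AIC(fit), fit$aic)
})

test_that("occupancy MLE recovers psi with covariates and ragged surveys", {
  set.seed(12)
  cfg <- sim_config(seed = 12, surveys_per_grid = c(2, 8))
  x <- rnorm(400)
  psi <- plogis(0.3 + 0.9 * x)
  h <- gen_detection_histories(psi, 0.35, cfg,
                               covariates = data.frame(x = x), seed = 4)
  fit <- fit_occupancy(h, ~ x, "constant")
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[["psi_x"]] - 0.9), 0.5)
  expect_true(all(fit$psi_hat >= 0 & fit$psi_hat <= 1))
  pr <- predict(fit, newdata = data.frame(x = c(-1, 0, 1)))
  expect_true(all(diff(pr) > 0))
})

test_that("abundance-driven detection wins the AIC race when it generated data", {
  wins <- 0
  for (r in 1:3) {
    set.seed(30 + r)
    cfg <- sim_config(seed = 30 + r, surveys_per_grid = c(4, 6))
    ab <- runif(300, 0, 2)
    h <- gen_detection_histories(rep(0.55, 300), plogis(-1.6 + 1.4 * ab), cfg,
                                 covariates = data.frame(ab = ab),
                                 seed = 60 + r)
    f_ab <- fit_occupancy(h, ~ 1, "abundance_index", abundance = "ab")
    f_c <- fit_occupancy(h, ~ 1, "constant")
    f_s <- fit_occupancy(h, ~ 1, "survey_specific")
    msa <- model_select_average(list(f_ab, f_c, f_s))
    if (grepl("abundance", msa$table$model[1])) wins <- wins + 1
    expect_equal(sum(msa$table$weight), 1, tolerance = 1e-9)
  }
  expect_gte(wins, 2)
})

test_that("Akaike weights follow the closed form and the averaging cut", {
  f1 <- structure(list(aic = 100, model = "m1", n_params = 2, logLik = -48,
                       psi_hat = rep(0.5, 4)), class = "occu_fit")
  f2 <- structure(list(aic = 102, model = "m2", n_params = 3, logLik = -48,
                       psi_hat = rep(0.7, 4)), class = "occu_fit")
  msa <- model_select_average(list(f1, f2))
  expect_equal(msa$table$weight, c(0.7311, 0.2689), tolerance = 1e-4)
  expect_equal(msa$psi_averaged, rep(0.7311 * 0.5 + 0.2689 * 0.7, 4),
               tolerance = 1e-4)
  ## a model at delta AIC 20.67 gets ~zero weight and leaves the average
  f3 <- structure(list(aic = 120.67, model = "m3", n_params = 4, logLik = -50,
                       psi_hat = rep(0.99, 4)), class = "occu_fit")
  msa3 <- model_select_average(list(f1, f2, f3))
  expect_lt(msa3$table$weight[msa3$table$model == "m3"], 1e-4)
  expect_equal(msa3$psi_averaged, msa$psi_averaged, tolerance = 1e-3)
  ## single model: averaging is the identity
  m1 <- model_select_average(list(f1))
  expect_equal(m1$psi_averaged, f1$psi_hat)
  expect_equal(m1$table$weight, 1)
})

test_that("parametric-bootstrap c-hat is near 1 on self-generated data", {
  ok <- 0
  for (r in 1:3) {
    cfg <- sim_config(seed = 40 + r, surveys_per_grid = c(3, 35))
    h <- gen_detection_histories(rep(0.6, 300), 0.35, cfg, seed = 80 + r)
    fit <- fit_occupancy(h, ~ 1, "constant")
    gof <- gof_bootstrap(fit, n_boot = 100, seed = r)
    if (gof$c_hat > 0.8 && gof$c_hat < 1.2) ok <- ok + 1
    expect_gt(gof$c_hat, 0)
  }
  expect_gte(ok, 2)
  expect_warning(gof_bootstrap(fit_occupancy(
    gen_detection_histories(rep(0.5, 50), 0.5,
                            sim_config(surveys_per_grid = c(3, 3)), seed = 1),
    ~ 1, "constant"), n_boot = 50, seed = 1), "unstable")
})

test_that("standard-error inflation is the square root of overdispersion", {
  expect_equal(se_inflation(1.4), sqrt(1.4))
  expect_equal(se_inflation(1), 1)
  expect_error(se_inflation(-2))
})

test_that("area summaries: limits and the model >= naive property", {
  ## psi = 1 everywhere: model habitat equals total habitat
  s1 <- occupancy_area_summary(rep(1, 5), rep(10, 5), rep(TRUE, 5))
  expect_equal(s1$model_habitat, 50)
  ## detections everywhere with p < 1: model estimate >= naive
  cfg <- sim_config(seed = 3, surveys_per_grid = c(4, 4))
  h <- gen_detection_histories(rep(0.7, 300), 0.4, cfg, seed = 5)
  fit <- fit_occupancy(h, ~ 1, "constant")
  det <- vapply(fit$y, max, 0) == 1
  s2 <- occupancy_area_summary(fit$psi_hat, rep(1, length(det)), det)
  expect_gte(s2$model_occupancy, s2$naive_occupancy - 1e-9)
})

test_that("simulate() reproduces the fitted design and respects closure", {
  cfg <- sim_config(seed = 6, surveys_per_grid = c(2, 7))
  h <- gen_detection_histories(rep(0.6, 100), 0.3, cfg, seed = 6)
  fit <- fit_occupancy(h, ~ 1, "constant")
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_equal(lengths(sims[[1]]), lengths(fit$y))
  expect_true(all(unlist(sims) %in% 0:1))
})
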