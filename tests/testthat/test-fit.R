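test_that("the 2PL recovers its generating parameters", {
  set.seed(120)
  bank <- item_bank(loading = rep(c(0.4, 0.8), 10),
                    difficulty = runif(20, -1, 1))
  dat <- simulate_mimic_dataset(bank, latent_structure(numeric(0)), 5000)
  fit <- fit_2pl(dat$y, se = "none", control = fast_ctrl())
  expect_true(fit$converged)
  rmse <- sqrt(mean((fit$bank$loading - bank$loading)^2))
  expect_lt(rmse, 0.05)
  expect_lt(sqrt(mean((fit$bank$threshold - bank$threshold)^2)), 0.08)
})

test_that("fits are equivariant under item permutation", {
  dat <- toy_data(n = 300, I = 8, gamma = 0, seed = 121)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  f1 <- fit_2pl(dat$y, se = "none", control = fast_ctrl())
  f2 <- fit_2pl(dat$y[, perm], se = "none", control = fast_ctrl())
  expect_equal(f2$bank$loading, f1$bank$loading[perm], tolerance = 1e-5)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-6)
})

test_that("an all-missing respondent is scored at the prior", {
  dat <- toy_data(n = 200, I = 6, gamma = 0, seed = 122)
  y <- dat$y
  y[7, ] <- NA
  fit <- fit_2pl(y, se = "none", control = fast_ctrl())
  expect_equal(fit$ability$eap[7], 0, tolerance = 1e-8)
  expect_equal(fit$ability$psd[7], 1, tolerance = 1e-8)
  expect_true(all(fit$ability$psd > 0))
})

test_that("the MIMIC estimator recovers the causal coefficient", {
  dat <- toy_data(n = 5000, I = 10, gamma = 0.6, seed = 123)
  fit <- fit_mimic(dat$y, dat$x, se = "none", control = fast_ctrl())
  expect_true(fit$converged)
  expect_equal(fit$latent$gamma[1], 0.6, tolerance = 0.03)
  expect_equal(fit$latent$resid_var, 1 - fit$latent$gamma[1]^2,
               tolerance = 1e-10)
})

test_that("negating the cause flips gamma but not the likelihood", {
  dat <- toy_data(n = 400, I = 8, gamma = 0.5, seed = 124)
  f1 <- fit_mimic(dat$y, dat$x, se = "none", control = fast_ctrl())
  f2 <- fit_mimic(dat$y, -dat$x, se = "none", control = fast_ctrl())
  expect_equal(f2$latent$gamma, -f1$latent$gamma, tolerance = 1e-4)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-6)
})

test_that("gamma estimates are stable under quadrature refinement", {
  dat <- toy_data(n = 500, I = 10, gamma = 0.4, seed = 125)
  f61 <- fit_mimic(dat$y, dat$x, se = "none",
                   control = mimic_control(quadrature = 61))
  f122 <- fit_mimic(dat$y, dat$x, se = "none",
                    control = mimic_control(quadrature = 122))
  expect_lt(abs(f61$latent$gamma - f122$latent$gamma), 1e-4)
})

test_that("degenerate items are dropped with a warning", {
  dat <- toy_data(n = 150, I = 6, gamma = 0, seed = 126)
  y <- dat$y
  y[, 4] <- 1
  expect_warning(fit <- fit_2pl(y, se = "none", control = fast_ctrl()),
                 "degenerate")
  expect_equal(fit$n_items, 5L)
  expect_equal(fit$kept_items, c(1:3, 5:6))
})

test_that("freeing DIF terms never lowers the likelihood and finds planted DIF", {
  bank <- dif_bank(I = 8, item = 3, kind = "uniform", coefficient = 0.9)
  set.seed(127)
  dat <- simulate_mimic_dataset(bank, latent_structure(0.3), 1500)
  f0 <- fit_mimic(dat$y, dat$x, se = "none", control = fast_ctrl())
  f1 <- fit_mimic_with_dif(dat$y, dat$x, item_index = 3, kind = "uniform",
                           control = fast_ctrl())
  expect_gte(f1$loglik, f0$loglik - 1e-6)
  expect_gt(abs(f1$dif_test$t[1]), 1.96)
  expect_equal(f1$dif_test$estimate[1], 0.9, tolerance = 0.25)
})

test_that("nonuniform DIF is picked up by the moderated-loading fit", {
  bank <- dif_bank(I = 8, item = 5, kind = "nonuniform", coefficient = 0.5)
  set.seed(128)
  dat <- simulate_mimic_dataset(bank, latent_structure(0.3), 2000)
  f1 <- fit_mimic_with_dif(dat$y, dat$x, item_index = 5, kind = "nonuniform",
                           control = fast_ctrl())
  expect_gt(f1$dif_test$t[1], 1.96)   # positive: discrimination rises with x
})

test_that("logit fits recover 2PL discriminations", {
  set.seed(129)
  bank <- item_bank(loading = rep(c(0.4, 0.8), 10),
                    difficulty = runif(20, -1, 1), link = "logit")
  dat <- simulate_mimic_dataset(bank, latent_structure(0.4), 4000)
  fit <- fit_mimic(dat$y, dat$x, link = "logit", se = "none",
                   control = fast_ctrl())
  expect_lt(sqrt(mean((fit$bank$loading - bank$loading)^2)), 0.08)
  expect_equal(fit$latent$gamma[1], 0.4, tolerance = 0.05)
})

test_that("fit methods expose the usual accessor surface", {
  dat <- toy_data(n = 250, I = 6, gamma = 0.4, seed = 130)
  fit <- fit_mimic(dat$y, dat$x, cluster = rep(1:50, 5), se = "model",
                   control = fast_ctrl())
  expect_s3_class(fit, "mimic_fit")
  expect_named(coef(fit)[13], "gamma1")
  expect_equal(unname(attr(logLik(fit), "nobs")), 250)
  V <- vcov(fit)
  expect_true(isSymmetric(V))
  expect_true(all(eigen(V, only.values = TRUE)$values > -1e-8))
  Vs <- vcov(fit, type = "sandwich")
  expect_equal(dim(Vs), dim(V))
  sm <- summary(fit)
  expect_s3_class(sm, "summary.mimic_fit")
  expect_equal(nrow(sm$items), 6)
  pr <- predict(fit, type = "eap")
  expect_equal(nrow(pr), 250)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]$y), dim(dat$y))
})
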