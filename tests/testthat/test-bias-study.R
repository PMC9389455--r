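test_that("sum scores standardize linearly and guard zero variance", {
  y <- rbind(rep(0, 4), c(1, 1, 1, 1), c(1, 1, 0, 0))
  # sums (0, 4, 2) -> z = (-1, 1, 0)
  expect_equal(summarize_sumscore(y), c(-1, 1, 0))
  expect_error(summarize_sumscore(diag(3) * 0 + diag(3)), "variance")
  # an all-zero column changes nothing
  expect_equal(summarize_sumscore(cbind(y, 0)), summarize_sumscore(y))
  # missing responses count as not endorsed
  y_na <- y; y_na[2, 1] <- NA
  expect_equal(summarize_sumscore(y_na),
               as.numeric(scale(c(0, 3, 2))))
})

test_that("the two-stage estimate is the standardized OLS slope", {
  set.seed(160)
  x <- rnorm(500)
  xz <- (x - mean(x)) / sd(x)
  expect_equal(two_stage_estimate(xz, x), 1, tolerance = 1e-12)
  z <- rnorm(500)
  expect_equal(two_stage_estimate(z, x), cor(z, x) * sd(z),
               tolerance = 1e-12)
  expect_equal(two_stage_estimate(rnorm(1e5), rnorm(1e5)), 0,
               tolerance = 0.02)
})

test_that("cohens_f implements the eta-squared identity", {
  expect_equal(cohens_f(0), 0)
  expect_equal(cohens_f(0.5), 1)
  expect_equal(cohens_f(0.152)^2 / (1 + cohens_f(0.152)^2), 0.152,
               tolerance = 1e-12)
  expect_error(cohens_f(1), "eta2")
  expect_error(cohens_f(-0.1), "eta2")
})

test_that("bias records are deterministic and satisfy bias + estimate = gamma", {
  grid <- build_condition_grid()
  cond <- grid[grid$n == 200 & grid$gamma == 0.4 &
                 grid$loading_even == 0.8 & grid$loading_odd == 0.8 &
                 grid$diff_lo == -1, ][1, ]
  r1 <- run_condition(cond, "sumscore", reps = 3, root_seed = 9)
  r2 <- run_condition(cond, "sumscore", reps = 3, root_seed = 9)
  expect_identical(r1, r2)
  expect_equal(r1$bias + r1$estimate, rep(0.4, 3))
  r3 <- run_condition(cond, "sumscore", reps = 3, root_seed = 10)
  expect_false(isTRUE(all.equal(r1$estimate, r3$estimate)))
})

test_that("methods share datasets within a replication", {
  grid <- build_condition_grid()
  cond <- grid[grid$n == 200 & grid$gamma == 0.6 &
                 grid$loading_even == 0.4 & grid$loading_odd == 0.4 &
                 grid$diff_lo == 0, ][1, ]
  rs <- run_condition(cond, "sumscore", reps = 2, root_seed = 5)
  tab <- run_full_study(cond, reps = 2, root_seed = 5,
                        methods = c("sumscore", "mimic"))
  expect_equal(tab$estimate[tab$method == "sumscore"], rs$estimate,
               tolerance = 1e-12)
})

test_that("a reduced full study has the expected shape", {
  grid <- build_condition_grid()
  sub <- grid[grid$n == 200 & grid$diff_lo == -1 & grid$gamma != 0.4, ]
  tab <- run_full_study(sub, reps = 1, root_seed = 3,
                        methods = c("sumscore"))
  expect_equal(nrow(tab), nrow(sub))
  expect_s3_class(tab, "bias_table")
  tab3 <- run_full_study(sub[1:2, ], reps = 2, root_seed = 3)
  expect_equal(nrow(tab3), 2 * 2 * 3)
})

test_that("checkpointing resumes to an identical table", {
  grid <- build_condition_grid()[c(1, 25), ]
  dir <- file.path(tempdir(), "bias_ckpt")
  unlink(dir, recursive = TRUE)
  t1 <- run_full_study(grid, reps = 2, root_seed = 4, methods = "sumscore",
                       checkpoint_dir = dir)
  # second run must reuse the checkpoints and reproduce the table
  t2 <- run_full_study(grid, reps = 2, root_seed = 4, methods = "sumscore",
                       checkpoint_dir = dir)
  expect_equal(t1$estimate, t2$estimate, tolerance = 1e-12)
  expect_equal(length(list.files(dir, pattern = "cell")), 2L)
  unlink(dir, recursive = TRUE)
})

make_noise_table <- function(reps = 4, seed = 161) {
  grid <- build_condition_grid()
  tab <- expand.grid(idx = seq_len(nrow(grid)), rep = seq_len(reps),
                     method = c("sumscore", "irt", "mimic"),
                     stringsAsFactors = FALSE)
  out <- cbind(grid[tab$idx, ], method = tab$method, rep = tab$rep)
  set.seed(seed)
  out$estimate <- rnorm(nrow(out))
  out$bias <- out$gamma - out$estimate
  out$failed <- FALSE
  out$seed <- 0
  class(out) <- c("bias_table", "data.frame")
  out
}

test_that("the bias ANOVA enumerates 30 effect terms with coherent effect sizes", {
  tab <- make_noise_table()
  an <- bias_anova(tab)
  eff <- an[an$term != "Residuals", ]
  expect_equal(nrow(eff), 30)
  n_way <- lengths(strsplit(eff$term, ":"))
  expect_equal(as.vector(table(n_way)), c(5L, 10L, 10L, 5L))
  expect_equal(sum(an$eta2), 1, tolerance = 1e-12)
  expect_equal(eff$cohens_f, sqrt(eff$eta2 / (1 - eff$eta2)),
               tolerance = 1e-12)
  # with a pure-noise DV no term dominates
  expect_lt(max(eff$eta2), 0.05)
})

test_that("the bias ANOVA requires the full factorial design", {
  tab <- make_noise_table()
  expect_error(bias_anova(tab[tab$method != "irt", ]), "missing levels")
  expect_error(bias_anova(tab[tab$gamma != 0.4, ]), "missing levels")
})

test_that("failed replications are dropped listwise with a reported count", {
  tab <- make_noise_table()
  tab$failed[c(3, 400)] <- TRUE
  tab$estimate[c(3, 400)] <- NA
  an <- bias_anova(tab)
  expect_equal(attr(an, "n_dropped"), 2L)
  expect_false(anyNA(an$eta2))
})

test_that("sums of squares are order-invariant in the balanced design", {
  tab <- make_noise_table(reps = 2)
  an <- bias_anova(tab)
  dat <- as.data.frame(tab)
  dat$method <- factor(dat$method)
  dat$cause <- factor(dat$gamma)
  dat$indicator <- factor(paste0(dat$loading_odd, "/", dat$loading_even))
  dat$intercept <- factor(dat$diff_lo)
  dat$nsize <- factor(dat$n)
  rev_fit <- aov(bias ~ (nsize + intercept + indicator + cause + method)^4,
                 data = dat)
  ss <- summary(rev_fit)[[1]]
  ss_method_rev <- ss[["Sum Sq"]][trimws(rownames(ss)) == "method"]
  expect_equal(an$sum_sq[an$term == "method"], ss_method_rev,
               tolerance = 1e-8)
})
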