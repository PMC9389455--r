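test_that("bh_fdr matches the hand-enumerated step-up oracle", {
  # step-up by hand for (0.01, 0.04, 0.03, 0.005), m = 4:
  # sorted (0.005, 0.01, 0.03, 0.04); m/i * p = (0.02, 0.02, 0.04, 0.04);
  # running min from the top gives (0.02, 0.02, 0.04, 0.04)
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_fdr(0.031), 0.031)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_true(all(bh_fdr(runif(20)) <= 1))
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  expect_error(bh_fdr(c(0.1, NA)), "0, 1")
})

test_that("purification removes the union of flagged items", {
  mk <- function(items, flagged, kind) {
    data.frame(group = "g", item = rep(items, each = 1), kind = kind,
               covariate = "x1", estimate = 0, se = 1, t = 0, p = 0.5,
               flagged = items %in% flagged, error = NA_character_)
  }
  uni <- mk(1:24, c(3, 17), "uniform")
  non <- mk(1:24, c(3, 9, 12), "nonuniform")
  pur <- purify_itemset(uni, non, n_items = 24)
  expect_equal(pur$removed, c(3, 9, 12, 17))
  expect_length(pur$retained, 20)
  expect_setequal(c(pur$retained, pur$removed), 1:24)
  # no flags -> identity
  pur0 <- purify_itemset(mk(1:10, integer(0), "uniform"),
                         mk(1:10, integer(0), "nonuniform"), n_items = 10)
  expect_equal(pur0$retained, 1:10)
  expect_equal(pur0$removed, integer(0))
})

test_that("purification reproduces the study-scale itemset arithmetic", {
  # 96 items, 7 uniform and 9 nonuniform flags with no overlap -> 80 retained
  mk <- function(flagged, kind) {
    data.frame(group = "all", item = 1:96, kind = kind, covariate = "int",
               estimate = 0, se = 1, t = 0, p = ifelse(1:96 %in% flagged,
                                                       0.01, 0.5),
               flagged = 1:96 %in% flagged, error = NA_character_)
  }
  pur <- purify_itemset(mk(c(2, 11, 20, 29, 38, 47, 56), "uniform"),
                        mk(c(5, 14, 23, 32, 41, 50, 59, 68, 77),
                           "nonuniform"), n_items = 96)
  expect_length(pur$retained, 80)
})

test_that("scans detect planted DIF of the matching kind", {
  # enough clean anchor items that the planted item's DIF is not absorbed
  # into the latent trait and smeared over its neighbours
  bank <- dif_bank(I = 10, item = 3, kind = "uniform", coefficient = 1.2)
  set.seed(150)
  dat <- simulate_mimic_dataset(bank, latent_structure(0.3), 800)
  sc_u <- scan_uniform(dat$y, dat$x, alpha = 0.05, flag_on = 1,
                       control = fast_ctrl())
  expect_true(3 %in% flagged_items(sc_u))
  # the planted item should carry the largest |t| in the matching scan
  tt <- sc_u$t[sc_u$covariate == "x1"]
  expect_equal(which.max(abs(tt)), 3L)
})

test_that("nonuniform scans respond to loading DIF with the stated sign", {
  bank <- dif_bank(I = 6, item = 2, kind = "nonuniform", coefficient = 0.6)
  set.seed(151)
  dat <- simulate_mimic_dataset(bank, latent_structure(0.3), 2000)
  sc_n <- scan_nonuniform(dat$y, dat$x, alpha = 0.05, flag_on = 1,
                          control = fast_ctrl())
  expect_true(2 %in% flagged_items(sc_n))
  expect_gt(sc_n$estimate[sc_n$item == 2 & sc_n$covariate == "x1"], 0)
})

test_that("scans are deterministic and invariant to item order", {
  bank <- dif_bank(I = 5, item = 4, kind = "uniform", coefficient = 1.3)
  set.seed(152)
  dat <- simulate_mimic_dataset(bank, latent_structure(0.2), 400)
  s1 <- scan_uniform(dat$y, dat$x, flag_on = 1, control = fast_ctrl())
  s2 <- scan_uniform(dat$y, dat$x, flag_on = 1, control = fast_ctrl())
  expect_identical(s1, s2)
  perm <- c(3, 5, 1, 4, 2)
  s3 <- scan_uniform(dat$y[, perm], dat$x, flag_on = 1, control = fast_ctrl())
  expect_setequal(match(flagged_items(s1), perm), flagged_items(s3))
  expect_equal(s3$estimate[s3$item == which(perm == 4)][1],
               s1$estimate[s1$item == 4][1], tolerance = 1e-5)
})

test_that("alpha = 0 flags nothing", {
  bank <- dif_bank(I = 4, item = 1, kind = "uniform", coefficient = 2)
  set.seed(153)
  dat <- simulate_mimic_dataset(bank, latent_structure(0), 300)
  sc <- scan_uniform(dat$y, dat$x, alpha = 0, flag_on = 1,
                     control = fast_ctrl())
  expect_length(flagged_items(sc), 0)
})
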