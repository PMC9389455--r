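test_that("the default fixture has the study's structure", {
  cfg <- fixture_config()
  st <- simulate_empirical_fixture(cfg, seed = 170)
  potential <- cfg$n_subjects * cfg$n_cycles * 4 * cfg$items_per_emotion
  expect_equal(potential, 23424)
  # every potential trial appears exactly once (plus injected duplicates)
  key <- with(st$responses, paste(subject, cycle, emotion, item))
  expect_equal(length(unique(key)), potential)
  expect_gte(nrow(st$responses), potential)
  # covariates: one row per subject x emotion, z-scored
  expect_equal(nrow(st$covariates), cfg$n_subjects * 4)
  expect_equal(anyDuplicated(st$covariates[, c("subject", "emotion")]), 0L)
  amp <- st$covariates$amplitude[st$covariates$emotion == "happy"]
  expect_equal(mean(amp), 0, tolerance = 1e-12)
  expect_equal(sd(amp), 1, tolerance = 1e-12)
  expect_equal(st$covariates$interaction,
               st$covariates$amplitude * st$covariates$latency)
})

test_that("fixture validation rejects impossible planted DIF", {
  expect_error(fixture_config(planted_dif = data.frame(
    emotion = "neutral", item = 99, kind = "uniform", coefficient = 1)),
    "nonexistent")
  expect_error(fixture_config(planted_dif = data.frame(
    emotion = "bored", item = 1, kind = "uniform", coefficient = 1)),
    "nonexistent")
  expect_error(fixture_config(planted_dif = data.frame(
    emotion = "happy", item = 1, kind = "weird", coefficient = 1)),
    "kind")
  expect_equal(nrow(default_planted_dif()), 16)
})

test_that("P200 extraction returns the windowed peak, earliest on ties", {
  t_ms <- seq(0, 400, by = 1)
  bump <- function(center, amp) amp * exp(-(t_ms - center)^2 / 200)
  p <- extract_p200(bump(210, 5), t_ms)
  expect_equal(p$amplitude, 5)
  expect_equal(p$latency, 210)
  # monotone decreasing waveform peaks at the window's left edge
  p2 <- extract_p200(10 - 0.02 * t_ms, t_ms)
  expect_equal(p2$latency, 180)
  # a larger bump before the window must be ignored
  p3 <- extract_p200(bump(170, 8) + bump(230, 3), t_ms)
  expect_equal(p3$latency, 230, tolerance = 2)
  # exact tie: two equal samples -> earliest wins
  w <- rep(0, length(t_ms)); w[t_ms %in% c(200, 240)] <- 4
  expect_equal(extract_p200(w, t_ms)$latency, 200)
  expect_error(extract_p200(w[t_ms <= 200], t_ms[t_ms <= 200]), "window")
})

test_that("preprocessing applies the three quality rules", {
  cfg <- fixture_config(n_subjects = 4L, n_cycles = 1L,
                        items_per_emotion = 2L, missing_rate = 0,
                        fast_rt_rate = 0, duplicate_rate = 0)
  st <- simulate_empirical_fixture(cfg, seed = 171)
  r <- st$responses
  # subject 1: one response at exactly 150 ms (kept), one at 149 ms (recoded)
  r$rt_ms[r$subject == 1] <- c(150, 149, rep(400, 6))[seq_len(sum(r$subject == 1))]
  # subject 2: wipe out more than half of the 8 potential responses
  wipe <- which(r$subject == 2)[1:5]
  r$correct[wipe] <- NA
  # subject 3: a triple response on one trial; the last (slowest) must win
  tr <- r[r$subject == 3, ][1, ]
  extra1 <- tr; extra1$rt_ms <- tr$rt_ms - 100; extra1$correct <- 1 - tr$correct
  extra2 <- tr; extra2$rt_ms <- tr$rt_ms - 50; extra2$correct <- 1 - tr$correct
  st$responses <- rbind(r, extra1, extra2)
  clean <- preprocess_responses(st)
  rc <- clean$responses
  expect_true(2 %in% clean$exclusions$subjects)
  expect_false(any(rc$subject == 2))
  expect_false(1 %in% clean$exclusions$subjects)
  s1 <- rc[rc$subject == 1, ]
  expect_equal(sum(is.na(s1$correct)), 1)          # only the 149 ms trial
  expect_true(150 %in% s1$rt_ms)
  s3 <- rc[rc$subject == 3 & rc$cycle == tr$cycle & rc$emotion == tr$emotion &
             rc$item == tr$item, ]
  expect_equal(nrow(s3), 1)
  expect_equal(s3$correct, tr$correct)             # last response retained
  expect_equal(clean$exclusions$n_duplicates_trimmed, 2)
})

test_that("studies round-trip through the delimited-file contract", {
  cfg <- fixture_config(n_subjects = 6L, n_cycles = 2L,
                        items_per_emotion = 3L,
                        planted_dif = data.frame(emotion = "happy", item = 2,
                                                 kind = "nonuniform",
                                                 coefficient = -0.8))
  st <- simulate_empirical_fixture(cfg, seed = 172)
  dir <- file.path(tempdir(), "study_io")
  unlink(dir, recursive = TRUE)
  write_study(st, dir, seed = 172)
  back <- read_study(dir)
  expect_equal(back$responses, st$responses)
  expect_equal(back$covariates, st$covariates)
  expect_equal(back$planted_dif$coefficient, -0.8)
  expect_equal(back$config$n_subjects, 6L)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  unlink(dir, recursive = TRUE)
})

test_that("study matrices align rows, covariates and clusters", {
  cfg <- fixture_config(n_subjects = 5L, n_cycles = 3L,
                        items_per_emotion = 4L, missing_rate = 0,
                        fast_rt_rate = 0, duplicate_rate = 0)
  st <- simulate_empirical_fixture(cfg, seed = 173)
  m <- study_matrices(st, "discomfort")
  expect_equal(dim(m$y), c(15, 4))
  expect_equal(length(m$cluster), 15)
  expect_equal(sum(m$cluster == 1), 3)
  # covariates constant within subject
  expect_equal(m$x[m$subject == 2, "amplitude"],
               rep(m$x[m$subject == 2, "amplitude"][1], 3),
               ignore_attr = TRUE)
  # the matrix reproduces the long-format values
  long <- st$responses[st$responses$emotion == "discomfort", ]
  probe <- long[long$subject == 4 & long$cycle == 2, ]
  expect_equal(unname(m$y[m$subject == 4 & m$cycle == 2, probe$item]),
               probe$correct)
})
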