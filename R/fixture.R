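#' Configuration for the synthetic emotional-identification fixture
#'
#' Defines a synthetic study shaped like the emotional-identification (iDemo)
#' EEG design: `n_subjects` subjects each complete `n_cycles` cycles of
#' `items_per_emotion` items within each of four emotions (happy, neutral,
#' discomfort, distress), for 61 x 4 x 96 = 23,424 potential trials at the
#' defaults. Per subject and emotion, P200 amplitude and latency are drawn
#' from a bivariate normal and z-scored; the modelling covariate set is
#' (amplitude, latency, amplitude x latency). The latent identification
#' ability per subject x emotion follows the MIMIC structural model with the
#' emotion's `gamma` row, and responses are generated per cycle from the
#' measurement model, with planted uniform/nonuniform DIF on selected items.
#'
#' @param n_subjects number of subjects.
#' @param n_cycles task cycles per subject.
#' @param items_per_emotion items within each emotion.
#' @param emotions emotion labels.
#' @param gamma 4 x 3 matrix (rows = emotions, columns = amplitude, latency,
#'   interaction) of standardized causal coefficients. The default plants an
#'   amplitude effect on neutral identification and a negative
#'   amplitude-by-latency interaction effect on discomfort, the two
#'   brain-behavior relationships the design is built to detect.
#' @param loading_range loadings are drawn uniformly from this range.
#' @param difficulty_range difficulties drawn uniformly from this range.
#' @param amp_lat_cor correlation between raw amplitude and latency.
#' @param planted_dif data.frame with columns `emotion`, `item`, `kind`
#'   (`"uniform"`/`"nonuniform"`) and `coefficient` (the DIF effect on the
#'   interaction covariate). Defaults to no DIF; see [default_planted_dif()].
#' @param missing_rate fraction of trials with no response.
#' @param fast_rt_rate fraction of responded trials faster than 150 ms.
#' @param duplicate_rate fraction of trials that record multiple keypresses.
#' @return a list of class `"fixture_config"`.
#' @export
fixture_config <- function(n_subjects = 61L, n_cycles = 4L,
                           items_per_emotion = 24L,
                           emotions = c("happy", "neutral", "discomfort",
                                        "distress"),
                           gamma = NULL,
                           loading_range = c(0.4, 0.8),
                           difficulty_range = c(-1, 1),
                           amp_lat_cor = 0.3,
                           planted_dif = NULL,
                           missing_rate = 0.06,
                           fast_rt_rate = 0.01,
                           duplicate_rate = 0.005) {
  if (is.null(gamma)) {
    gamma <- matrix(0, length(emotions), 3,
                    dimnames = list(emotions,
                                    c("amplitude", "latency", "interaction")))
    gamma["neutral", "amplitude"] <- 0.25
    gamma["discomfort", "interaction"] <- -0.25
  }
  gamma <- as.matrix(gamma)
  stopifnot(nrow(gamma) == length(emotions), ncol(gamma) == 3)
  rownames(gamma) <- emotions
  if (is.null(planted_dif)) {
    planted_dif <- data.frame(emotion = character(), item = integer(),
                              kind = character(), coefficient = numeric())
  }
  if (nrow(planted_dif)) {
    bad <- !(planted_dif$emotion %in% emotions) |
      planted_dif$item < 1 | planted_dif$item > items_per_emotion
    if (any(bad)) stop("planted DIF refers to a nonexistent emotion or item")
    if (!all(planted_dif$kind %in% c("uniform", "nonuniform"))) {
      stop("planted DIF kind must be 'uniform' or 'nonuniform'")
    }
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_cycles = as.integer(n_cycles),
                 items_per_emotion = as.integer(items_per_emotion),
                 emotions = emotions, gamma = gamma,
                 loading_range = loading_range,
                 difficulty_range = difficulty_range,
                 amp_lat_cor = amp_lat_cor, planted_dif = planted_dif,
                 missing_rate = missing_rate, fast_rt_rate = fast_rt_rate,
                 duplicate_rate = duplicate_rate),
            class = "fixture_config")
}

#' Default planted DIF pattern for the synthetic fixture
#'
#' Plants 7 uniform and 9 nonuniform DIF items on the interaction covariate,
#' spread over the emotions with the per-emotion counts and coefficient
#' magnitudes of the kind the DIF scans are designed to detect (synthetic
#' values; item positions are arbitrary).
#'
#' @return a `planted_dif` data.frame for [fixture_config()].
#' @export
default_planted_dif <- function() {
  rbind(
    data.frame(emotion = c("distress", "discomfort", "neutral", "neutral",
                           "happy", "happy", "happy"),
               item = c(3L, 7L, 5L, 14L, 2L, 11L, 20L),
               kind = "uniform",
               coefficient = c(0.9, -0.8, -1.0, 0.8, -0.9, -1.1, 0.9)),
    data.frame(emotion = c("distress", "distress", "distress", "neutral",
                           "neutral", "neutral", "happy", "happy", "happy"),
               item = c(9L, 15L, 21L, 8L, 17L, 22L, 6L, 15L, 23L),
               kind = "nonuniform",
               coefficient = c(1.2, 1.0, -1.0, 1.3, 1.0, -1.2, -1.0, -0.9,
                               1.2)))
}

#' Simulate the synthetic emotional-identification study
#'
#' Generates a complete long-format study from a [fixture_config()]: one
#' response row per subject x cycle x emotion x item with response time, and
#' one covariate row per subject x emotion. See [fixture_config()] for the
#' generative model.
#'
#' @param config a [fixture_config()].
#' @param seed optional seed set before generation.
#' @return an object of class `"empirical_study"`: list with `responses`
#'   (subject, cycle, emotion, item, correct, rt_ms), `covariates` (subject,
#'   emotion, amplitude, latency, interaction), `true_theta`, `banks` (the
#'   per-emotion item banks actually used), `planted_dif` and `config`.
#' @export
simulate_empirical_fixture <- function(config = fixture_config(),
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ns <- config$n_subjects; nc <- config$n_cycles
  I <- config$items_per_emotion
  emos <- config$emotions
  rho <- config$amp_lat_cor

  # per-subject-per-emotion P200 features, z-scored within emotion
  cov_list <- lapply(emos, function(e) {
    z1 <- stats::rnorm(ns); z2 <- stats::rnorm(ns)
    amp_raw <- 5 + 2 * z1
    lat_raw <- 215 + 15 * (rho * z1 + sqrt(1 - rho^2) * z2)
    amp <- as.numeric(scale(amp_raw))
    lat <- as.numeric(scale(lat_raw))
    data.frame(subject = seq_len(ns), emotion = e, amplitude = amp,
               latency = lat, interaction = amp * lat,
               stringsAsFactors = FALSE)
  })
  covariates <- do.call(rbind, cov_list)

  banks <- list(); theta_tab <- list(); resp <- list()
  for (e in emos) {
    lam <- stats::runif(I, config$loading_range[1], config$loading_range[2])
    b <- stats::runif(I, config$difficulty_range[1], config$difficulty_range[2])
    dif_int <- matrix(0, I, 3); dif_load <- matrix(0, I, 3)
    pd <- config$planted_dif[config$planted_dif$emotion == e, , drop = FALSE]
    if (nrow(pd)) {
      for (r in seq_len(nrow(pd))) {
        if (pd$kind[r] == "uniform") {
          dif_int[pd$item[r], 3] <- pd$coefficient[r]
        } else {
          dif_load[pd$item[r], 3] <- pd$coefficient[r]
        }
      }
    }
    bank <- item_bank(loading = lam, difficulty = b, dif_intercept = dif_int,
                      dif_loading = dif_load)
    banks[[e]] <- bank
    g <- config$gamma[e, ]
    latent <- latent_structure(g)
    xe <- as.matrix(covariates[covariates$emotion == e,
                               c("amplitude", "latency", "interaction")])
    theta <- drop(xe %*% g) + stats::rnorm(ns, sd = sqrt(latent$resid_var))
    theta_tab[[e]] <- data.frame(subject = seq_len(ns), emotion = e,
                                 theta = theta)
    for (cy in seq_len(nc)) {
      sim <- simulate_mimic_dataset(bank, latent, ns, x = xe, theta = theta)
      resp[[paste(e, cy)]] <- data.frame(
        subject = seq_len(ns), cycle = cy, emotion = e,
        item = rep(seq_len(I), each = ns),
        correct = as.integer(sim$y),
        stringsAsFactors = FALSE)
    }
  }
  responses <- do.call(rbind, resp)
  nresp <- nrow(responses)
  responses$rt_ms <- round(stats::rlnorm(nresp, log(650), 0.35), 1)

  # planted data-quality problems: missing trials, too-fast responses,
  # occasional multiple keypresses (an extra earlier row for the same trial)
  miss <- stats::runif(nresp) < config$missing_rate
  responses$correct[miss] <- NA_integer_
  responses$rt_ms[miss] <- NA_real_
  fast <- !miss & stats::runif(nresp) < config$fast_rt_rate
  responses$rt_ms[fast] <- round(stats::runif(sum(fast), 50, 149), 1)
  dup_idx <- which(!miss & stats::runif(nresp) < config$duplicate_rate)
  if (length(dup_idx)) {
    dups <- responses[dup_idx, ]
    dups$correct <- 1L - dups$correct       # first (discarded) keypress
    dups$rt_ms <- pmax(60, dups$rt_ms - round(stats::runif(nrow(dups), 50, 250), 1))
    responses <- rbind(dups, responses)
  }
  ord <- order(responses$subject, responses$cycle, responses$emotion,
               responses$item, responses$rt_ms)
  responses <- responses[ord, ]
  rownames(responses) <- NULL

  structure(list(responses = responses, covariates = covariates,
                 true_theta = do.call(rbind, theta_tab), banks = banks,
                 planted_dif = config$planted_dif, config = config),
            class = "empirical_study")
}

#' @export
print.empirical_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("Synthetic emotional-identification study: %d subjects, ",
                     "%d cycles, %d emotions x %d items\n"),
              cfg$n_subjects, cfg$n_cycles, length(cfg$emotions),
              cfg$items_per_emotion))
  cat(sprintf("  %d response rows, %d planted DIF item(s)\n",
              nrow(x$responses), nrow(x$planted_dif)))
  invisible(x)
}

#' Extract P200 amplitude and latency from a waveform
#'
#' Returns the largest positive deflection of an averaged event-related
#' waveform inside a post-stimulus window (default 180-250 ms) and the time
#' at which it occurs; ties are broken by the earliest time.
#'
#' @param waveform numeric vector of microvolt values.
#' @param times_ms sampling times in ms, same length as `waveform`.
#' @param window two-element window in ms; must be covered by `times_ms`.
#' @return list with `amplitude` (microvolts) and `latency` (ms).
#' @export
extract_p200 <- function(waveform, times_ms, window = c(180, 250)) {
  stopifnot(length(waveform) == length(times_ms), length(window) == 2L)
  if (min(times_ms) > window[1] || max(times_ms) < window[2]) {
    stop("waveform does not cover the extraction window")
  }
  in_win <- which(times_ms >= window[1] & times_ms <= window[2])
  vals <- waveform[in_win]
  peak <- in_win[which.max(vals)]   # which.max takes the earliest maximum
  list(amplitude = waveform[peak], latency = times_ms[peak])
}

#' Preprocess behavioral responses
#'
#' Applies the study's data-quality rules: (1) when a trial has multiple
#' recorded responses the last one (largest response time) is kept; (2)
#' responses faster than 150 ms are recoded as missing (150 ms exactly is
#' retained); (3) subjects missing more than half of their potential
#' responses are flagged as outliers and excluded.
#'
#' @param study an `"empirical_study"`.
#' @return the cleaned study, with an `exclusions` element: the excluded
#'   subject ids, their missing fractions, and counts of fast-response and
#'   duplicate trims.
#' @export
preprocess_responses <- function(study) {
  resp <- study$responses
  # (1) keep the last response per trial
  key <- paste(resp$subject, resp$cycle, resp$emotion, resp$item, sep = "\r")
  ord <- order(key, resp$rt_ms, na.last = TRUE)
  resp <- resp[ord, ]
  key <- key[ord]
  last <- !duplicated(key, fromLast = TRUE)
  n_dup <- sum(!last)
  resp <- resp[last, ]
  # (2) strictly-fast responses become missing
  fast <- !is.na(resp$rt_ms) & resp$rt_ms < 150
  resp$correct[fast] <- NA_integer_
  resp$rt_ms[fast] <- NA_real_
  # (3) subjects with more than half of potential responses missing
  cfg <- study$config
  potential <- cfg$n_cycles * cfg$items_per_emotion * length(cfg$emotions)
  miss_by_subj <- tapply(is.na(resp$correct), resp$subject, sum)
  seen_by_subj <- tapply(resp$subject, resp$subject, length)
  missing_frac <- (miss_by_subj + (potential - seen_by_subj)) / potential
  excluded <- as.integer(names(missing_frac))[missing_frac > 0.5]
  keep <- !(resp$subject %in% excluded)
  out <- study
  out$responses <- resp[keep, ]
  rownames(out$responses) <- NULL
  out$covariates <- study$covariates[!(study$covariates$subject %in% excluded), ]
  out$exclusions <- list(subjects = excluded,
                         missing_fraction = missing_frac,
                         n_fast = sum(fast), n_duplicates_trimmed = n_dup)
  out
}

#' Wide response matrix and covariates for one emotion
#'
#' Reshapes one emotion's long-format responses into the row layout the
#' fitting functions use: one row per subject x cycle, one column per item,
#' with the subject's covariates repeated across cycles and the subject id
#' as cluster label.
#'
#' @param study an `"empirical_study"` (ideally after
#'   [preprocess_responses()]).
#' @param emotion which emotion to extract.
#' @return list with `y` (matrix), `x` (matrix with columns amplitude,
#'   latency, interaction), `cluster` (subject ids), `subject`, `cycle`.
#' @export
study_matrices <- function(study, emotion) {
  stopifnot(emotion %in% study$config$emotions)
  resp <- study$responses[study$responses$emotion == emotion, ]
  I <- study$config$items_per_emotion
  subjects <- sort(unique(resp$subject))
  rows <- expand.grid(cycle = sort(unique(resp$cycle)), subject = subjects)
  row_id <- paste(rows$subject, rows$cycle)
  y <- matrix(NA_integer_, nrow(rows), I,
              dimnames = list(row_id, paste0("item", seq_len(I))))
  idx <- match(paste(resp$subject, resp$cycle), row_id)
  y[cbind(idx, resp$item)] <- resp$correct
  cov <- study$covariates[study$covariates$emotion == emotion, ]
  m <- match(rows$subject, cov$subject)
  x <- as.matrix(cov[m, c("amplitude", "latency", "interaction")])
  rownames(x) <- row_id
  list(y = y, x = x, cluster = rows$subject, subject = rows$subject,
       cycle = rows$cycle)
}

#' Write a study to delimited text files
#'
#' Writes `responses.csv`, `covariates.csv`, `planted_dif.csv` and a
#' `manifest.json` (seed, configuration, file inventory) into `dir`.
#' [read_study()] restores the study from these files bit-exactly.
#'
#' @param study an `"empirical_study"`.
#' @param dir output directory (created if needed).
#' @param seed the seed recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$responses, file.path(dir, "responses.csv"),
                   row.names = FALSE)
  utils::write.csv(study$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(study$planted_dif, file.path(dir, "planted_dif.csv"),
                   row.names = FALSE)
  cfg <- study$config
  manifest <- list(seed = seed,
                   n_subjects = cfg$n_subjects, n_cycles = cfg$n_cycles,
                   items_per_emotion = cfg$items_per_emotion,
                   emotions = cfg$emotions,
                   gamma = as.data.frame(cfg$gamma),
                   missing_rate = cfg$missing_rate,
                   fast_rt_rate = cfg$fast_rt_rate,
                   duplicate_rate = cfg$duplicate_rate,
                   files = c("responses.csv", "covariates.csv",
                             "planted_dif.csv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a study written by [write_study()]
#'
#' @param dir directory holding the study files.
#' @return an `"empirical_study"` (without the generating banks and true
#'   latent values, which are not part of the file contract).
#' @export
read_study <- function(dir) {
  responses <- utils::read.csv(file.path(dir, "responses.csv"),
                               stringsAsFactors = FALSE)
  covariates <- utils::read.csv(file.path(dir, "covariates.csv"),
                                stringsAsFactors = FALSE)
  planted <- utils::read.csv(file.path(dir, "planted_dif.csv"),
                             stringsAsFactors = FALSE)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  cfg <- fixture_config(n_subjects = man$n_subjects, n_cycles = man$n_cycles,
                        items_per_emotion = man$items_per_emotion,
                        emotions = man$emotions,
                        gamma = as.matrix(man$gamma),
                        planted_dif = if (nrow(planted)) planted else NULL,
                        missing_rate = man$missing_rate,
                        fast_rt_rate = man$fast_rt_rate,
                        duplicate_rate = man$duplicate_rate)
  structure(list(responses = responses, covariates = covariates,
                 true_theta = NULL, banks = NULL, planted_dif = planted,
                 config = cfg),
            class = "empirical_study")
}
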