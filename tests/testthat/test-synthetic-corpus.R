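test_that("generation bookkeeping and determinism hold", {
  cfg <- synthetic_config(n_speakers = 20, sessions_per_speaker = 5, seed = 9)
  corp <- generate_corpus(cfg)
  expect_equal(nrow(corp$samples), 100)
  expect_true(all(table(corp$samples$speaker_id) == 5))

  corp2 <- generate_corpus(cfg)
  expect_equal(corp$speakers, corp2$speakers)
  expect_equal(corp$samples, corp2$samples)

  # byte-identical manifests from the same config
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  save_manifest(corp, d1); save_manifest(corp2, d2)
  expect_identical(readLines(file.path(d1, "samples.csv")),
                   readLines(file.path(d2, "samples.csv")))

  expect_error(synthetic_config(n_speakers = 0),
               class = "somnaudit_configuration_error")
})

test_that("adding a speaker never perturbs existing speakers' draws", {
  small <- generate_corpus(synthetic_config(n_speakers = 5, seed = 21))
  large <- generate_corpus(synthetic_config(n_speakers = 6, seed = 21))
  expect_equal(large$speakers[1:5, ], small$speakers)
})

test_that("labels are monotone in the latent trait", {
  corp <- generate_corpus(synthetic_config(n_speakers = 1000,
                                           sessions_per_speaker = 1,
                                           trait_sd = 1.5, seed = 33))
  df <- dplyr::left_join(corp$samples,
                         corp$speakers[, c("speaker_id", "trait_truth")],
                         by = "speaker_id")
  decile <- cut(df$trait_truth,
                quantile(df$trait_truth, seq(0, 1, 0.1)),
                include.lowest = TRUE, labels = FALSE)
  mean_lat <- tapply(df$latency_min, decile, mean)
  mean_kss <- tapply(df$kss, decile, mean)
  expect_true(all(diff(mean_lat) <= 0))
  expect_true(all(diff(mean_kss) >= 0))
})

test_that("the empirical saturation mass matches the Gamma clip probability", {
  cfg <- synthetic_config(n_speakers = 500, sessions_per_speaker = 4,
                          latency_schema = "mslt", seed = 12)
  corp <- generate_corpus(cfg)
  observed <- saturation_fraction(corp$samples$latency_min, 20)

  # independent Monte-Carlo oracle of the same generative recipe
  set.seed(999)
  theta <- rnorm(1e5, cfg$trait_mean, cfg$trait_sd)
  s <- theta + rnorm(1e5, 0, cfg$state_sd)
  clip_rate <- mean(rgamma(1e5, shape = 2,
                           scale = cfg$latency_scale * exp(-s) / 2) >= 20)
  n <- nrow(corp$samples)
  se <- sqrt(clip_rate * (1 - clip_rate) / n)
  expect_lt(abs(observed - clip_rate), 3 * se + 3e-3)
})

test_that("synthesized utterances are deterministic with controllable F0", {
  m <- acoustic_state_model()
  w <- synthesize_utterance(0, m, 1, seed = 4)
  expect_length(w$samples, 16000)
  expect_equal(max(abs(w$samples)), 0.9, tolerance = 1e-9)
  w2 <- synthesize_utterance(0, m, 1, seed = 4)
  expect_identical(w$samples, w2$samples)

  spec <- feature_extractor_spec()
  f_a <- suppressWarnings(extract_features(synthesize_utterance(0, m, 2, seed = 5), spec))
  f_b <- suppressWarnings(extract_features(synthesize_utterance(2, m, 2, seed = 5), spec))
  # f0_delta_per_state is -10 Hz per unit: two units apart means ~20 Hz
  expect_equal(f_a[["f0_mean"]] - f_b[["f0_mean"]], 20, tolerance = 2)

  expect_error(synthesize_utterance(0, m, -1), class = "somnaudit_argument_error")
})

test_that("a noiseless jitterless utterance has its spectral peak at F0", {
  m <- acoustic_state_model(jitter_frac = 0, snr_db = Inf)
  w <- synthesize_utterance(0, m, 1, seed = 1)
  spec <- Mod(fft(w$samples))[1:8000]
  peak_hz <- (which.max(spec) - 1) * 16000 / length(w$samples)
  expect_equal(peak_hz, m$f0_base, tolerance = 16000 / length(w$samples) + 1e-9)
})

test_that("speaker oversampling replicates only the targeted speakers", {
  cfg <- synthetic_config(n_speakers = 20, sessions_per_speaker = 5, seed = 2)
  corp <- generate_corpus(cfg)
  target <- corp$speakers$speaker_id[3]
  over <- inject_speaker_oversampling(corp, n_outliers = 1, multiplier = 10,
                                      seed = 8, speaker_ids = target)
  counts <- table(over$samples$speaker_id)
  expect_equal(unname(counts[target]), 50)
  others <- setdiff(names(counts), target)
  expect_true(all(counts[others] == 5))
  # untouched speakers' samples are bit-identical
  expect_equal(over$samples[over$samples$speaker_id != target, ],
               corp$samples[corp$samples$speaker_id != target, ])

  expect_equal(inject_speaker_oversampling(corp, 0, 10), corp)
  expect_error(inject_speaker_oversampling(corp, 1, 0.5),
               class = "somnaudit_argument_error")
})

test_that("confound injection spans independence to deterministic coupling", {
  expect_error(inject_covariate_confound(synthetic_config(), "sex", 1.2),
               class = "somnaudit_argument_error")

  # strength 1: sex is a threshold function of the trait, so every speaker
  # sleepy at the trait level shares one sex
  cfg <- synthetic_config(n_speakers = 80, sessions_per_speaker = 5,
                          latency_schema = "none", trait_mean = 0.8,
                          trait_sd = 1, state_sd = 0.3, seed = 14)
  cfg <- inject_covariate_confound(cfg, "sex", 1)
  corp <- generate_corpus(cfg)
  cls <- binarize(corp$speakers$avg_kss, "kss7.5")
  expect_gte(sum(cls == "SL"), 3)
  expect_true(all(corp$speakers$sex[cls == "SL"] == "M"))

  # strength 1 on a continuous covariate: BMI is deterministic in the trait
  cfgb <- inject_covariate_confound(synthetic_config(n_speakers = 50, seed = 3),
                                    "bmi", 1)
  corp_b <- generate_corpus(cfgb)
  z_bmi <- (corp_b$speakers$bmi - cfgb$bmi_mean) / cfgb$bmi_sd
  z_th <- (corp_b$speakers$trait_truth - cfgb$trait_mean) / cfgb$trait_sd
  clipped <- corp_b$speakers$bmi %in% c(15, 55)
  expect_equal(z_bmi[!clipped], z_th[!clipped], tolerance = 1e-9)
})
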