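test_that("Tukey-fence outlier detection recovers over-recorded speakers", {
  even <- corpus(
    tibble::tibble(speaker_id = paste0("s", 1:10)),
    tibble::tibble(sample_id = paste0("x", 1:50),
                   speaker_id = rep(paste0("s", 1:10), each = 5),
                   duration_s = 10)
  )
  expect_identical(nrow(detect_outlier_speakers(even)), 0L)

  # 19 speakers at 60 samples, one at 909: zero IQR triggers the fallback
  counts <- c(rep(60, 19), 909)
  skewed <- corpus(
    tibble::tibble(speaker_id = sprintf("s%02d", 1:20)),
    tibble::tibble(
      sample_id = sprintf("x%05d", seq_len(sum(counts))),
      speaker_id = rep(sprintf("s%02d", 1:20), times = counts),
      duration_s = 8
    )
  )
  out <- detect_outlier_speakers(skewed)
  expect_identical(out$speaker_id, "s20")
  expect_identical(out$n_samples, 909L)

  too_few <- corpus(
    tibble::tibble(speaker_id = c("a", "b", "c")),
    tibble::tibble(sample_id = c("1", "2", "3"),
                   speaker_id = c("a", "b", "c"), duration_s = 5)
  )
  expect_error(detect_outlier_speakers(too_few),
               class = "somnaudit_insufficient_data_error")
})

test_that("injected oversampling is recovered exactly by the detector", {
  corp <- generate_corpus(synthetic_config(n_speakers = 30, seed = 6))
  targets <- c("spk0004", "spk0019")
  over <- inject_speaker_oversampling(corp, multiplier = 10, seed = 77,
                                      speaker_ids = targets)
  found <- detect_outlier_speakers(over)
  expect_setequal(found$speaker_id, targets)
})

test_that("exclusion impact is the identity for an empty exclusion", {
  corp <- generate_corpus(synthetic_config(n_speakers = 15, seed = 4))
  imp <- exclusion_impact(corp, character(), "kss")
  expect_equal(imp$shift_test$p_value, 1)
  expect_equal(imp$mean_before, imp$mean_after)
  expect_equal(imp$class_ratio_before, imp$class_ratio_after)
  expect_equal(imp$n_before, imp$n_after)
})

test_that("excluding oversampled sleepy speakers shifts the KSS distribution", {
  cfg <- synthetic_config(n_speakers = 30, sessions_per_speaker = 5,
                          latency_schema = "none", trait_sd = 1.5, seed = 19)
  corp <- generate_corpus(cfg)
  sleepiest <- corp$speakers$speaker_id[
    order(-corp$speakers$trait_truth)][1:2]
  over <- inject_speaker_oversampling(corp, multiplier = 15, seed = 5,
                                      speaker_ids = sleepiest)
  imp <- exclusion_impact(over, sleepiest, "kss")
  # conservation: removed samples are exactly the excluded speakers'
  n_excluded <- sum(over$samples$speaker_id %in% sleepiest)
  expect_equal(imp$n_before, imp$n_after + n_excluded)
  expect_lt(imp$shift_test$p_value, 0.01)
  expect_gt(imp$mean_before, imp$mean_after)

  # when the oversampled speaker's label multiset equals every other
  # speaker's, replication cannot move the class ratio at all
  uniform <- corpus(
    tibble::tibble(speaker_id = sprintf("u%02d", 1:10)),
    tibble::tibble(
      sample_id = sprintf("u%02d_s%d", rep(1:10, each = 5), rep(1:5, 10)),
      speaker_id = rep(sprintf("u%02d", 1:10), each = 5),
      duration_s = 75, kss = rep(c(9L, 8L, 5L, 3L, 2L), 10)
    )
  )
  over2 <- inject_speaker_oversampling(uniform, multiplier = 15, seed = 5,
                                       speaker_ids = "u01")
  imp2 <- exclusion_impact(over2, "u01", "kss", rule = "kss7.5")
  expect_equal(imp2$class_ratio_before, imp2$class_ratio_after)

  expect_error(exclusion_impact(corp, corp$speakers$speaker_id, "kss"),
               class = "somnaudit_argument_error")
})

test_that("label cross-correlation separates coupled from independent labels", {
  # KSS and latency driven by the same latent state: strongly negative rho
  coupled <- generate_corpus(synthetic_config(n_speakers = 100,
                                              sessions_per_speaker = 5,
                                              latency_schema = "mslt",
                                              trait_sd = 1.5, seed = 23))
  res <- label_cross_correlation(coupled, "kss", "latency_min")
  expect_lt(res$with_saturated$rho, -0.3)
  expect_lt(res$with_saturated$p_value, 1e-6)
  expect_false(is.null(res$without_saturated))
  expect_gt(res$n_saturated, 0)

  # independent labels: correlation near zero
  indep <- generate_corpus(synthetic_config(n_speakers = 100,
                                            sessions_per_speaker = 5,
                                            latency_schema = "mslt",
                                            independent_kss = TRUE, seed = 29))
  res0 <- label_cross_correlation(indep, "kss", "latency_min")
  expect_lt(abs(res0$with_saturated$rho), 0.1)

  # a label against itself is perfectly correlated both ways
  self <- label_cross_correlation(coupled, "latency_min", "latency_min")
  expect_equal(self$with_saturated$rho, 1)
  expect_equal(self$without_saturated$rho, 1)
})

test_that("covariate audits flag injected confounds and match printed tables", {
  cfg <- inject_covariate_confound(
    synthetic_config(n_speakers = 80, latency_schema = "none",
                     trait_mean = 0.8, state_sd = 0.3, seed = 14),
    "sex", 1
  )
  report <- audit_covariates(generate_corpus(cfg), "kss7.5",
                             level = "speaker")
  sex_row <- report$rows[report$rows$covariate == "sex", ]
  expect_identical(sex_row$flag, "imbalance")

  # published sample-level sex-by-class counts: p = 9.6e-3
  fix <- mslt_sample_sex_fixture()
  rep_sample <- audit_covariates(fix, "mslt8", level = "sample",
                                 covariates = "sex")
  expect_equal(signif(rep_sample$rows$p_value, 2), 9.6e-3)
  expect_identical(rep_sample$rows$flag, "imbalance")

  # published speaker-level counts: p = 0.16, not significant
  fix_sp <- mslt_speaker_sex_fixture()
  rep_speaker <- audit_covariates(fix_sp, "mslt8", level = "speaker",
                                  covariates = "sex")
  expect_equal(round(rep_speaker$rows$p_value, 2), 0.16)
  expect_identical(rep_speaker$rows$flag, "ok")

  expect_error(audit_covariates(fix, "mslt8", covariates = "shoe_size"),
               class = "somnaudit_argument_error")
})

test_that("audit reports carry saturation summaries and are deterministic", {
  corp <- generate_corpus(synthetic_config(n_speakers = 40,
                                           latency_schema = "mslt", seed = 31))
  r1 <- audit_covariates(corp, "mslt8", level = "sample")
  r2 <- audit_covariates(corp, "mslt8", level = "sample")
  expect_equal(r1, r2)
  sat <- r1$saturation
  expect_true("mslt8" %in% sat$rule)
  expect_true(all(sat$fraction >= 0 & sat$fraction <= 1))
  expect_equal(sat$fraction[sat$level == "sample"],
               saturation_fraction(corp$samples$latency_min, 20))
  # markdown rendering stays in sync with the rows
  md <- format_audit_markdown(r1)
  expect_true(any(grepl("\\| sex \\|", md)))
})

test_that("the design linter flags the quantifiable guideline violations", {
  base <- generate_corpus(synthetic_config(n_speakers = 10, seed = 41))
  expect_identical(nrow(lint_design(base)$violations), 0L)

  short <- base
  short$samples$duration_s[1] <- 5
  v <- lint_design(short)$violations
  expect_true("MIN_SAMPLE_LENGTH" %in% v$rule)

  long <- base
  long$samples$duration_s[2] <- 300
  expect_true("MAX_SAMPLE_LENGTH" %in% lint_design(long)$violations$rule)

  uneq <- inject_speaker_oversampling(base, multiplier = 12, seed = 2,
                                      speaker_ids = base$speakers$speaker_id[1])
  expect_true("UNEQUAL_SAMPLES_PER_SPEAKER" %in%
                lint_design(uneq)$violations$rule)

  nosex <- base
  nosex$speakers$sex[3] <- NA
  v <- lint_design(nosex)$violations
  expect_true(any(v$rule == "MISSING_METADATA" & v$entity == "sex"))

  # KSS refilled 5 min apart violates the questionnaire's validity window
  timed <- base
  timed$samples$timestamp_min <- rep(seq(0, by = 5, length.out = 5),
                                     times = 10)
  expect_true("KSS_REPEAT_SPACING" %in% lint_design(timed)$violations$rule)

  # classes only, raw values stripped
  classed <- base
  classed$samples$state_class <- binarize(classed$samples$kss, "kss7.5")
  classed$samples$kss <- NA_integer_
  classed$samples$latency_min <- NA_real_
  expect_true("RAW_LABELS_ABSENT" %in% lint_design(classed)$violations$rule)
})
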