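test_that("a corpus assembles and round-trips through the manifest", {
  corp <- tiny_corpus()
  expect_s3_class(corp, "corpus")
  expect_equal(nrow(corp$speakers), 2)
  expect_equal(nrow(corp$samples), 4)

  dir <- withr::local_tempdir()
  save_manifest(corp, dir)
  back <- load_manifest(dir)
  expect_equal(back$speakers, corp$speakers)
  expect_equal(back$samples, corp$samples)
  expect_equal(names(back$schema), names(corp$schema))
  expect_equal(back$schema[["mwt19"]], corp$schema[["mwt19"]])
})

test_that("a synthetic corpus round-trips field-for-field, missing cells included", {
  corp <- generate_corpus(synthetic_config(n_speakers = 20, seed = 5))
  dir <- withr::local_tempdir()
  save_manifest(corp, dir)
  back <- load_manifest(dir)
  expect_equal(back$speakers, corp$speakers)
  expect_equal(back$samples, corp$samples)
  # optional fields absent in the source stay absent after the round trip
  expect_true(all(is.na(back$samples$kss_mixed)))
  expect_true(all(is.na(back$speakers$comorbidities)))
})

test_that("saving an empty corpus yields a loadable header-only manifest", {
  corp <- corpus(
    tibble::tibble(speaker_id = character()),
    tibble::tibble(sample_id = character(), speaker_id = character(),
                   duration_s = numeric())
  )
  dir <- withr::local_tempdir()
  save_manifest(corp, dir)
  expect_identical(length(readLines(file.path(dir, "samples.csv"))), 1L)
  back <- load_manifest(dir)
  expect_equal(nrow(back$samples), 0)
})

test_that("out-of-scale labels are rejected at load time", {
  corp <- tiny_corpus()
  dir <- withr::local_tempdir()
  save_manifest(corp, dir)
  sa <- readr::read_csv(file.path(dir, "samples.csv"), show_col_types = FALSE)
  sa$kss[1] <- 11
  readr::write_csv(sa, file.path(dir, "samples.csv"), na = "")
  expect_error(load_manifest(dir), "scale")
})

test_that("missing durations are filled from the WAV header", {
  dir <- withr::local_tempdir()
  write_wav(sin(2 * pi * 100 * (0:15999) / 16000),
            file.path(dir, "one_second.wav"), 16000)
  # header oracle: 16,000 frames at 16 kHz is exactly 1 s
  expect_equal(wav_duration(file.path(dir, "one_second.wav")), 1.0)

  corp <- corpus(
    tibble::tibble(speaker_id = "a"),
    tibble::tibble(sample_id = "a1", speaker_id = "a", duration_s = 1,
                   audio_ref = "one_second.wav")
  )
  save_manifest(corp, dir)
  sa <- readr::read_csv(file.path(dir, "samples.csv"), show_col_types = FALSE)
  sa$duration_s <- NA_real_
  readr::write_csv(sa, file.path(dir, "samples.csv"), na = "")
  back <- load_manifest(dir)
  expect_equal(back$samples$duration_s, 1.0)
})

test_that("manifests with missing required columns raise schema errors", {
  dir <- withr::local_tempdir()
  save_manifest(tiny_corpus(), dir)
  sa <- readr::read_csv(file.path(dir, "samples.csv"), show_col_types = FALSE)
  readr::write_csv(sa[, setdiff(names(sa), "sample_id")],
                   file.path(dir, "samples.csv"), na = "")
  expect_error(load_manifest(dir), "sample_id", class = "somnaudit_schema_error")
})

test_that("validation reports violations as data, one per broken invariant", {
  expect_identical(nrow(validate_corpus(tiny_corpus())), 0L)

  bad <- list(
    speakers = tibble::tibble(speaker_id = c("a", "a"), sex = "M",
                              age = 40, bmi = 24, comorbidities = NA_character_,
                              ess = c(30L, 10L), avg_latency_min = NA_real_,
                              avg_kss = NA_real_, trait_class = NA_character_),
    samples = tibble::tibble(sample_id = c("s1", "s1", "s2"),
                             speaker_id = c("a", "a", "ghost"),
                             session_index = 1L, task = NA_character_,
                             duration_s = c(10, 10, -1),
                             kss = NA_integer_, kss_mixed = NA_real_,
                             latency_min = c(45, NA, NA),
                             audio_ref = NA_character_,
                             state_class = NA_character_),
    schema = builtin_rules()
  )
  v <- validate_corpus(bad)
  expect_true("unique_id" %in% v$rule[v$entity == "speaker"])
  expect_true("unique_id" %in% v$rule[v$entity == "sample"])
  expect_true(any(v$rule == "referential" & v$id == "ghost"))
  expect_true(any(v$field == "ess" & v$rule == "range"))
  expect_true(any(v$field == "duration_s"))
  # latency above the 40 min MWT ceiling: exactly one violation for that cell
  expect_identical(sum(v$field == "latency_min" & v$id == "s1"), 1L)
})

test_that("per-class summaries aggregate durations and conserve totals", {
  corp <- corpus(
    tibble::tibble(speaker_id = c("a", "b")),
    tibble::tibble(
      sample_id = paste0("s", 1:4), speaker_id = c("a", "a", "b", "b"),
      duration_s = c(10, 10, 20, 20), kss = c(9L, 8L, 2L, 3L)
    )
  )
  s <- summarize_corpus(corp, "kss7.5", level = "sample")
  tab <- s$table
  get <- function(metric, col) tab[[col]][tab$metric == metric]
  expect_equal(get("total_length_s", "total"), 60)
  expect_equal(get("mean_length_s", "SL"), 10)
  expect_equal(get("mean_length_s", "NSL"), 20)
  expect_equal(get("samples", "SL") + get("samples", "NSL"),
               get("samples", "total"))
  expect_equal(get("total_length_s", "SL") + get("total_length_s", "NSL"),
               get("total_length_s", "total"))
})

test_that("summary of a corpus with a configured class ratio recovers it", {
  # one session per speaker: samples are then independent Bernoulli draws
  cfg <- synthetic_config(n_speakers = 1000, sessions_per_speaker = 1,
                          latency_schema = "none", kss_sl_fraction = 0.3,
                          seed = 17)
  corp <- generate_corpus(cfg)
  bal <- class_balance(corp, "kss7.5", level = "sample")
  n <- sum(bal$counts)
  share <- bal$counts[["SL"]] / n
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(share - 0.3), 3 * se + 1e-12)
})

test_that("summarize_corpus rejects labels that are absent everywhere", {
  corp <- corpus(
    tibble::tibble(speaker_id = "a"),
    tibble::tibble(sample_id = "s1", speaker_id = "a", duration_s = 10)
  )
  expect_error(summarize_corpus(corp, "kss7.5", "sample"),
               class = "somnaudit_empty_summary_error")
})
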