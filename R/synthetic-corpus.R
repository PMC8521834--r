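# Deterministic seed fan-out: one global seed plus an entity key (speaker or
# sample id) yields a child seed, so adding an entity never perturbs the
# draws of the others. Arithmetic stays below 2^53, modulus 2^31 - 1.
.child_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h * 48271 + (seed %% 2147483647) * 69621) %% 2147483647)
}

.clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Acoustic model linking a latent sleepiness state to utterance statistics
#'
#' A compact source-filter recipe: a harmonic source (sine fundamental plus a
#' glottal-like pulse train) whose F0 shifts linearly with the latent state,
#' passed through a state-dependent spectral-tilt filter and a cascade of
#' formant resonators, with additive white noise at a configured SNR. The
#' literature gives no validated effect sizes linking sleepiness to
#' acoustics, so these defaults are explicit placeholders: they produce
#' controllable, monotone state effects for testing audit machinery, not a
#' model of real sleepy speech.
#'
#' @param f0_base fundamental frequency at state 0, Hz.
#' @param f0_delta_per_state F0 shift per unit state, Hz (negative: sleepier
#'   means lower pitch).
#' @param jitter_frac slow multiplicative F0 perturbation, dimensionless.
#' @param spectral_tilt_delta change in spectral balance per unit state,
#'   dB/octave (applied through a one-pole smoothing filter).
#' @param snr_db signal-to-noise ratio of the additive noise floor; `Inf`
#'   disables noise.
#' @param formant_centers resonator centre frequencies, Hz.
#' @param sample_rate output rate, Hz (>= 8000).
#' @return A list of class `acoustic_state_model`.
#' @export
acoustic_state_model <- function(f0_base = 120, f0_delta_per_state = -10,
                                 jitter_frac = 0.01, spectral_tilt_delta = -1,
                                 snr_db = 30,
                                 formant_centers = c(500, 1500, 2500),
                                 sample_rate = 16000) {
  stopifnot(f0_base > 0, sample_rate >= 8000, jitter_frac >= 0)
  structure(
    list(f0_base = f0_base, f0_delta_per_state = f0_delta_per_state,
         jitter_frac = jitter_frac, spectral_tilt_delta = spectral_tilt_delta,
         snr_db = snr_db, formant_centers = formant_centers,
         sample_rate = sample_rate),
    class = "acoustic_state_model"
  )
}

#' Configuration of the synthetic corpus generator
#'
#' The generator draws a between-speaker sleepiness trait `theta ~ N(trait_mean,
#' trait_sd^2)`, per-session states `s = theta + N(0, state_sd^2)`, and from
#' each state a sleep latency (Gamma with shape 2 and mean
#' `latency_scale * exp(-s)`, clipped at the test ceiling) and a KSS score
#' (equal-width discretization of `plogis(s)` onto the scale, ties broken
#' toward the lower score). Defaults emulate the structure reported for the
#' clinical latency-test corpora: the `mwt` schema's `latency_scale = 60` min
#' puts roughly 60 percent of session latencies at the 40 min ceiling, and the
#' `mslt` schema's 15 min puts roughly a quarter at the 20 min ceiling,
#' matching the saturation masses those corpora exhibit.
#'
#' @param n_speakers number of speakers (> 0).
#' @param sessions_per_speaker recordings per speaker.
#' @param sex_ratio probability of sex `"M"`.
#' @param age_mean,age_sd age distribution, years.
#' @param bmi_mean,bmi_sd BMI distribution, kg/m^2.
#' @param trait_mean,trait_sd between-speaker sleepiness trait distribution.
#' @param state_sd within-speaker session noise.
#' @param latency_schema `"mwt"` (ceiling 40 min) or `"mslt"` (20 min), or
#'   `"none"` for KSS-only corpora.
#' @param latency_scale mean unsaturated latency at trait 0, minutes.
#' @param kss_scale `"1-9"` or `"1-10"`.
#' @param utterance_duration_s nominal recording length, seconds; the default
#'   75 s matches the reading-task durations typical of clinical corpora.
#' @param kss_sl_fraction optional target SL share under the KSS rule; when
#'   set, `trait_mean` is solved so the expected share matches.
#' @param independent_kss draw KSS from a latent independent of the latency's
#'   (for null-coupling experiments).
#' @param confound optional covariate confound created by
#'   [inject_covariate_confound()].
#' @param session_count_range optional length-2 integer range; session counts
#'   are drawn uniformly per speaker (an unequal-sessions design flaw).
#' @param acoustic an [acoustic_state_model()].
#' @param seed integer master seed; every draw fans out from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_speakers = 30, sessions_per_speaker = 5,
                             sex_ratio = 0.5, age_mean = 40, age_sd = 12,
                             bmi_mean = 25, bmi_sd = 4,
                             trait_mean = 0, trait_sd = 1, state_sd = 0.5,
                             latency_schema = c("mwt", "mslt", "none"),
                             latency_scale = NULL,
                             kss_scale = c("1-9", "1-10"),
                             utterance_duration_s = 75,
                             kss_sl_fraction = NULL,
                             independent_kss = FALSE,
                             confound = NULL,
                             session_count_range = NULL,
                             acoustic = acoustic_state_model(),
                             seed = 1L) {
  latency_schema <- match.arg(latency_schema)
  kss_scale <- match.arg(kss_scale)
  if (n_speakers <= 0) {
    abort("n_speakers must be positive; empty corpora are fixtures, not generator output",
          class = "somnaudit_configuration_error")
  }
  stopifnot(sessions_per_speaker >= 1, sex_ratio >= 0, sex_ratio <= 1,
            trait_sd >= 0, state_sd >= 0, age_sd >= 0, bmi_sd >= 0)
  latency_scale <- latency_scale %||%
    switch(latency_schema, mwt = 60, mslt = 15, none = NA_real_)
  kss_max <- if (kss_scale == "1-9") 9 else 10
  if (!is.null(kss_sl_fraction)) {
    # solve trait_mean so that P(KSS > 7.5) hits the target share:
    # KSS > 7.5 iff plogis(s) >= (8 - 1) / (kss_max - 1 + 1)
    cut <- stats::qlogis((8 - 1) / kss_max)
    sigma <- sqrt(trait_sd^2 + state_sd^2)
    trait_mean <- cut - sigma * qnorm(1 - kss_sl_fraction)
  }
  structure(
    list(n_speakers = as.integer(n_speakers),
         sessions_per_speaker = as.integer(sessions_per_speaker),
         sex_ratio = sex_ratio, age_mean = age_mean, age_sd = age_sd,
         bmi_mean = bmi_mean, bmi_sd = bmi_sd,
         trait_mean = trait_mean, trait_sd = trait_sd, state_sd = state_sd,
         latency_schema = latency_schema, latency_scale = latency_scale,
         kss_scale = kss_scale, utterance_duration_s = utterance_duration_s,
         independent_kss = independent_kss,
         confound = confound, session_count_range = session_count_range,
         acoustic = acoustic, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Couple a covariate to the sleepiness trait
#'
#' Returns a copy of the configuration whose generator couples the chosen
#' speaker covariate to the trait `theta` with the given strength: 0 leaves
#' them independent, 1 makes the covariate a deterministic function of the
#' trait. For `sex`, a speaker is assigned `"M"` with probability `strength`
#' by thresholding `theta` (at the trait quantile matching `sex_ratio`) and
#' otherwise by an independent coin; for `age` and `bmi` the covariate's
#' z-score is a `strength`-weighted mixture of the standardized trait and
#' fresh noise, keeping the marginal variance fixed.
#'
#' @param config a [synthetic_config()].
#' @param covariate `"sex"`, `"bmi"` or `"age"`.
#' @param strength coupling strength in `[0, 1]`.
#' @return A modified `synthetic_config`.
#' @export
inject_covariate_confound <- function(config, covariate = c("sex", "bmi", "age"),
                                      strength) {
  covariate <- match.arg(covariate)
  if (!is.numeric(strength) || strength < 0 || strength > 1) {
    abort("strength must lie in [0, 1]", class = "somnaudit_argument_error")
  }
  config$confound <- list(covariate = covariate, strength = strength)
  config
}

#' Generate a synthetic speech-health corpus
#'
#' Deterministic given the config (including its seed): per-entity child
#' seeds are derived from the master seed keyed by speaker and sample ids,
#' so the same config always yields a bit-identical corpus. Latencies are
#' monotonically decreasing and KSS monotonically increasing in the latent
#' trait, and the fraction of latencies at the ceiling equals the clip
#' probability of the configured Gamma mixture up to Monte-Carlo error.
#'
#' Ground-truth latents are carried in extra columns (`trait_truth` on
#' speakers, `state_truth` on samples) so recovery tests can compare audits
#' against the generative truth.
#'
#' @param config a [synthetic_config()].
#' @param audio_dir when non-`NULL`, a WAV is synthesized for every sample
#'   under `audio_dir/<speaker_id>/<sample_id>.wav` and referenced from the
#'   manifest. Audio is off by default: all statistical stages accept
#'   feature- or label-level input.
#' @return A [corpus()] whose provenance records the config.
#' @export
generate_corpus <- function(config, audio_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  kss_max <- if (config$kss_scale == "1-9") 9L else 10L
  l_max <- switch(config$latency_schema, mwt = 40, mslt = 20, none = NA_real_)
  conf <- config$confound
  sp_rows <- vector("list", config$n_speakers)
  sa_rows <- vector("list", config$n_speakers)
  required_sessions <- config$sessions_per_speaker

  for (i in seq_len(config$n_speakers)) {
    spk <- sprintf("spk%04d", i)
    set.seed(.child_seed(config$seed, spk))
    theta <- rnorm(1, config$trait_mean, config$trait_sd)
    z_theta <- if (config$trait_sd > 0) {
      (theta - config$trait_mean) / config$trait_sd
    } else 0

    sex <- if (runif(1) < config$sex_ratio) "M" else "F"
    age <- .clamp(rnorm(1, config$age_mean, config$age_sd), 18, 90)
    bmi <- .clamp(rnorm(1, config$bmi_mean, config$bmi_sd), 15, 55)
    if (!is.null(conf)) {
      s <- conf$strength
      if (conf$covariate == "sex") {
        theta_q <- qnorm(1 - config$sex_ratio, config$trait_mean, config$trait_sd)
        coupled_sex <- if (theta > theta_q) "M" else "F"
        if (runif(1) < s) sex <- coupled_sex
      } else if (conf$covariate == "bmi") {
        z <- s * z_theta + sqrt(1 - s^2) * rnorm(1)
        bmi <- .clamp(config$bmi_mean + config$bmi_sd * z, 15, 55)
      } else if (conf$covariate == "age") {
        z <- s * z_theta + sqrt(1 - s^2) * rnorm(1)
        age <- .clamp(config$age_mean + config$age_sd * z, 18, 90)
      }
    }
    ess <- as.integer(.clamp(round(rnorm(1, 11, 5)), 0, 24))

    n_sessions <- if (!is.null(config$session_count_range)) {
      r <- config$session_count_range
      sample(seq(r[1], r[2]), 1)
    } else {
      config$sessions_per_speaker
    }

    states <- theta + rnorm(n_sessions, 0, config$state_sd)
    kss_latent <- if (config$independent_kss) {
      rnorm(n_sessions, config$trait_mean, sqrt(config$trait_sd^2 + config$state_sd^2))
    } else {
      states
    }
    kss <- .discretize_kss(kss_latent, kss_max)
    if (config$latency_schema != "none") {
      lat_raw <- rgamma(n_sessions, shape = 2,
                        scale = config$latency_scale * exp(-states) / 2)
      latency <- pmin(lat_raw, l_max)
    } else {
      latency <- rep(NA_real_, n_sessions)
    }

    avg_lat <- if (config$latency_schema != "none" &&
                   n_sessions == required_sessions) {
      average_latency(latency, required_sessions)
    } else {
      NA_real_
    }

    sp_rows[[i]] <- tibble::tibble(
      speaker_id = spk, sex = sex, age = age, bmi = bmi,
      comorbidities = NA_character_, ess = ess,
      avg_latency_min = avg_lat, avg_kss = mean(kss),
      trait_class = NA_character_, trait_truth = theta
    )
    sa_rows[[i]] <- tibble::tibble(
      sample_id = sprintf("%s_s%02d", spk, seq_len(n_sessions)),
      speaker_id = spk, session_index = seq_len(n_sessions),
      task = "reading", duration_s = config$utterance_duration_s,
      kss = kss, kss_mixed = NA_real_, latency_min = latency,
      audio_ref = NA_character_, state_class = NA_character_,
      state_truth = states
    )
  }

  speakers <- dplyr::bind_rows(sp_rows)
  samples <- dplyr::bind_rows(sa_rows)

  schema <- builtin_rules(kss_scale = config$kss_scale)
  schema <- switch(config$latency_schema,
    mwt = schema[c("kss7.5", "mwt19")],
    mslt = schema[c("kss7.5", "mslt8")],
    none = schema["kss7.5"]
  )

  corp <- corpus(speakers, samples, schema = schema,
                 provenance = list(generator = "somnaudit synthetic corpus",
                                   synthetic_config = .config_to_list(config)))
  if (!is.null(audio_dir)) {
    corp <- .synthesize_corpus_audio(corp, config, audio_dir)
  }
  corp
}

# Equal-width binning of a logistic transform of the state onto the KSS
# scale; floor() breaks ties toward the lower score (conservative toward the
# non-sleepy class).
.discretize_kss <- function(s, kss_max) {
  u <- plogis(s)
  as.integer(.clamp(1 + floor(u * kss_max), 1, kss_max))
}

.config_to_list <- function(config) {
  out <- unclass(config)
  out$acoustic <- unclass(out$acoustic)
  out
}

.config_from_list <- function(lst) {
  lst$acoustic <- do.call(acoustic_state_model, lst$acoustic)
  lst$latency_schema <- lst$latency_schema
  do.call(synthetic_config, lst[names(lst) %in% names(formals(synthetic_config))])
}

.synthesize_corpus_audio <- function(corp, config, audio_dir) {
  for (i in seq_len(nrow(corp$samples))) {
    sid <- corp$samples$sample_id[i]
    spk <- corp$samples$speaker_id[i]
    state <- corp$samples$state_truth[i]
    rel <- file.path("audio", spk, paste0(sid, ".wav"))
    out <- file.path(audio_dir, rel)
    wav <- synthesize_utterance(state, config$acoustic,
                                corp$samples$duration_s[i],
                                seed = .child_seed(config$seed, paste0("wav:", sid)))
    write_wav(wav$samples, out, wav$sample_rate)
    corp$samples$audio_ref[i] <- rel
  }
  corp$provenance$audio_root <- audio_dir
  corp
}

#' Synthesize one utterance for a latent sleepiness state
#'
#' Harmonic source (sine fundamental plus pulse train, F0 =
#' `f0_base + f0_delta_per_state * state`, slow multiplicative jitter),
#' filtered through a state-dependent spectral-tilt one-pole and two-pole
#' resonators at the formant centres, plus white noise at `snr_db`;
#' amplitude-normalized to peak 0.9. Deterministic per seed.
#'
#' @param state latent sleepiness state (dimensionless).
#' @param model an [acoustic_state_model()].
#' @param duration_s utterance length in seconds (> 0).
#' @param seed integer seed for jitter and noise.
#' @param state_curve optional function of time (seconds) returning the
#'   instantaneous state, overriding the constant `state`; used to emulate
#'   nonstationary recordings.
#' @param gain_curve optional function of time returning a multiplicative
#'   amplitude envelope (applied before peak normalization of the envelope
#'   shape is preserved up to the global peak).
#' @return List with `samples` (numeric vector) and `sample_rate`.
#' @export
synthesize_utterance <- function(state, model, duration_s, seed = 1L,
                                 state_curve = NULL, gain_curve = NULL) {
  stopifnot(inherits(model, "acoustic_state_model"))
  if (!is.numeric(duration_s) || duration_s <= 0) {
    abort("duration_s must be positive", class = "somnaudit_argument_error")
  }
  sr <- model$sample_rate
  n <- round(duration_s * sr)
  set.seed(as.integer(seed))
  t <- (seq_len(n) - 1) / sr
  state_t <- if (is.null(state_curve)) rep(state, n) else state_curve(t)

  f0_t <- pmax(30, model$f0_base + model$f0_delta_per_state * state_t)
  if (model$jitter_frac > 0) {
    # slow multiplicative F0 perturbation: heavily smoothed white noise
    raw <- rnorm(n)
    smooth <- as.numeric(signal::filter(signal::Arma(b = 0.001, a = c(1, -0.999)), raw))
    if (sd(smooth) > 0) smooth <- smooth / sd(smooth)
    f0_t <- f0_t * (1 + model$jitter_frac * smooth)
  }
  phase <- 2 * pi * cumsum(f0_t) / sr
  fundamental <- sin(phase)
  cycles <- floor(phase / (2 * pi))
  pulses <- c(0, diff(cycles)) > 0
  src <- fundamental + as.numeric(pulses)

  # one-pole spectral balance filter; the coefficient shifts with the mean
  # state to emulate a tilt change (approximate dB/octave mapping)
  a_tilt <- .clamp(0.6 - 0.05 * model$spectral_tilt_delta * mean(state_t), 0, 0.98)
  y <- as.numeric(signal::filter(signal::Arma(b = 1 - a_tilt, a = c(1, -a_tilt)), src))

  for (fc in model$formant_centers) {
    bw <- 80 + fc / 20
    r <- exp(-pi * bw / sr)
    omega <- 2 * pi * fc / sr
    b <- (1 - r)
    a <- c(1, -2 * r * cos(omega), r^2)
    y <- as.numeric(signal::filter(signal::Arma(b = b, a = a), y))
  }

  if (is.finite(model$snr_db)) {
    sig_pow <- mean(y^2)
    noise_sd <- sqrt(sig_pow / 10^(model$snr_db / 10))
    y <- y + rnorm(n, 0, noise_sd)
  }
  if (!is.null(gain_curve)) y <- y * gain_curve(t)
  peak <- max(abs(y))
  if (peak > 0) y <- y * 0.9 / peak
  list(samples = y, sample_rate = sr)
}

#' Replicate selected speakers' samples to emulate speaker over-sampling
#'
#' Emulates the design flaw where a few subjects are recorded orders of
#' magnitude more often than the rest. Chosen speakers' samples are
#' regenerated (fresh sample ids, re-noised states and labels when the
#' corpus carries its generative config) until their count reaches
#' `multiplier` times their base count; all other speakers are untouched.
#'
#' @param corpus a [corpus()], ideally one from [generate_corpus()].
#' @param n_outliers how many speakers to oversample.
#' @param multiplier target ratio of final to base sample count (> 1).
#' @param seed integer seed for speaker choice and re-noising.
#' @param speaker_ids explicit speaker ids to oversample (overrides the
#'   random choice; `n_outliers` is then ignored).
#' @return A new `corpus`.
#' @export
inject_speaker_oversampling <- function(corpus, n_outliers, multiplier,
                                        seed = 1L, speaker_ids = NULL) {
  if (multiplier <= 1) {
    abort("multiplier must exceed 1", class = "somnaudit_argument_error")
  }
  if (is.null(speaker_ids)) {
    if (n_outliers == 0) return(corpus)
    if (n_outliers > nrow(corpus$speakers)) {
      abort("n_outliers exceeds the speaker count",
            class = "somnaudit_argument_error")
    }
    set.seed(.child_seed(seed, "oversample-choice"))
    speaker_ids <- sample(corpus$speakers$speaker_id, n_outliers)
  }
  cfg_list <- corpus$provenance$synthetic_config
  kss_max <- 9L
  l_max <- NA_real_
  lat_scale <- NA_real_
  state_sd <- 0.5
  if (!is.null(cfg_list)) {
    kss_max <- if (identical(cfg_list$kss_scale, "1-10")) 10L else 9L
    l_max <- switch(cfg_list$latency_schema, mwt = 40, mslt = 20, NA_real_)
    lat_scale <- cfg_list$latency_scale %||% NA_real_
    state_sd <- cfg_list$state_sd %||% 0.5
  }

  extra <- list()
  for (spk in speaker_ids) {
    base <- corpus$samples[corpus$samples$speaker_id == spk, ]
    n_base <- nrow(base)
    n_new <- round(multiplier * n_base) - n_base
    if (n_new <= 0) next
    set.seed(.child_seed(seed, paste0("oversample:", spk)))
    theta <- if ("trait_truth" %in% names(corpus$speakers)) {
      corpus$speakers$trait_truth[corpus$speakers$speaker_id == spk]
    } else {
      NA_real_
    }
    # balanced cycling keeps the replicated label multiset proportional to
    # the speaker's own (labels are redrawn anyway when a config is present)
    idx <- rep_len(seq_len(n_base), n_new)
    new_rows <- base[idx, ]
    new_rows$sample_id <- sprintf("%s_x%04d", spk, seq_len(n_new))
    base_max <- if (all(is.na(base$session_index))) 0L
                else max(base$session_index, na.rm = TRUE)
    new_rows$session_index <- base_max + seq_len(n_new)
    if (!is.na(theta) && !is.null(cfg_list)) {
      states <- theta + rnorm(n_new, 0, state_sd)
      if ("state_truth" %in% names(new_rows)) new_rows$state_truth <- states
      if (any(!is.na(base$kss))) {
        new_rows$kss <- .discretize_kss(states, kss_max)
      }
      if (!is.na(l_max) && !is.na(lat_scale) && any(!is.na(base$latency_min))) {
        new_rows$latency_min <- pmin(
          rgamma(n_new, shape = 2, scale = lat_scale * exp(-states) / 2), l_max)
      }
    }
    extra[[spk]] <- new_rows
  }
  corpus$samples <- dplyr::bind_rows(c(list(corpus$samples), unname(extra)))
  corpus
}

#' Waveform set for stationarity experiments
#'
#' Generates a set of utterances for probing the length-convergence
#' procedure: by default each utterance is a stationary noise-plus-harmonics
#' signal whose latent state differs per sample (so features have genuine
#' between-sample spread); with `nonstationary = TRUE` every utterance
#' additionally carries an early drift — the state ramps from
#' `drift_depth` below its final value, and the amplitude from `gain_floor`,
#' over the first `drift_s` seconds — emulating recordings whose opening
#' seconds are unrepresentative (microphone settling, initial hesitation).
#'
#' @param n_samples number of utterances.
#' @param duration_s utterance length, seconds.
#' @param nonstationary inject the early state and amplitude drift.
#' @param state_sd between-sample spread of the latent state.
#' @param drift_depth state offset at time 0 (nonstationary only).
#' @param drift_s duration of the drift, seconds.
#' @param gain_floor relative amplitude at time 0 (nonstationary only).
#' @param model an [acoustic_state_model()].
#' @param seed master seed; per-sample seeds fan out from it.
#' @return Named list of waveforms (`list(samples, sample_rate)`).
#' @export
stationarity_waveform_set <- function(n_samples = 40, duration_s = 30,
                                      nonstationary = FALSE, state_sd = 0.5,
                                      drift_depth = -3, drift_s = 10,
                                      gain_floor = 0.3,
                                      model = acoustic_state_model(),
                                      seed = 1L) {
  set.seed(.child_seed(seed, "stationarity-states"))
  states <- rnorm(n_samples, 0, state_sd)
  waves <- lapply(seq_len(n_samples), function(i) {
    s0 <- states[i]
    if (nonstationary) {
      synthesize_utterance(
        s0, model, duration_s,
        seed = .child_seed(seed, sprintf("stationarity-wav-%d", i)),
        state_curve = function(t) s0 + pmax(0, 1 - t / drift_s) * drift_depth,
        gain_curve = function(t) gain_floor + (1 - gain_floor) * pmin(1, t / drift_s)
      )
    } else {
      synthesize_utterance(
        s0, model, duration_s,
        seed = .child_seed(seed, sprintf("stationarity-wav-%d", i))
      )
    }
  })
  names(waves) <- sprintf("utt%03d", seq_len(n_samples))
  waves
}
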