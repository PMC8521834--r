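#' Specification of the built-in acoustic feature extractor
#'
#' Frame-level low-level descriptors (F0 by autocorrelation, RMS energy,
#' zero-crossing rate, spectral centroid, roll-off and flux, and 13 MFCCs)
#' plus their first-order deltas, summarized by 11 functionals (mean, sd,
#' min, max, range, median, quartiles, skewness, kurtosis, linear-regression
#' slope): `19 * 2 * 11 = 418` features, in a fixed documented order. This
#' built-in set is a compact stand-in for the large openSMILE challenge sets
#' used in the paralinguistics literature; [extract_features_external()]
#' lets any command-line extractor supply its own vectors instead.
#'
#' Deltas and flux are computed causally (backward differences, first frame
#' zero), so the features of a prefix equal the features of the truncated
#' recording — the property the length-convergence procedure relies on.
#'
#' @param name identifier recorded in caches and reports.
#' @param frame_length_ms,hop_ms framing, milliseconds.
#' @param target_rate_hz analysis rate; input audio is resampled (linear
#'   interpolation) when it differs.
#' @param n_mfcc number of cepstral coefficients (including c0).
#' @param f0_range_hz numeric length-2 search range for F0.
#' @return A list of class `feature_extractor_spec`.
#' @export
feature_extractor_spec <- function(name = "somnaudit-418",
                                   frame_length_ms = 25, hop_ms = 10,
                                   target_rate_hz = 16000, n_mfcc = 13,
                                   f0_range_hz = c(50, 500)) {
  llds <- c("f0", "rms", "zcr", "centroid", "rolloff", "flux",
            paste0("mfcc", seq_len(n_mfcc)))
  functionals <- c("mean", "sd", "min", "max", "range", "median",
                   "q1", "q3", "skew", "kurt", "slope")
  structure(
    list(name = name, frame_length_ms = frame_length_ms, hop_ms = hop_ms,
         target_rate_hz = target_rate_hz, n_mfcc = n_mfcc,
         f0_range_hz = f0_range_hz, llds = llds, functionals = functionals),
    class = "feature_extractor_spec"
  )
}

#' Names of the features a spec produces, in order
#'
#' @param spec a [feature_extractor_spec()].
#' @return Character vector of length `|llds| * 2 * |functionals|`.
#' @export
feature_names <- function(spec) {
  all_llds <- c(spec$llds, paste0(spec$llds, "_de"))
  as.vector(vapply(all_llds, function(l) paste0(l, "_", spec$functionals),
                   character(length(spec$functionals))))
}

.as_waveform <- function(waveform, sample_rate = NULL) {
  if (is.list(waveform) && !is.null(waveform$samples)) return(waveform)
  if (is.null(sample_rate)) {
    abort("sample_rate required when waveform is a bare numeric vector",
          class = "somnaudit_argument_error")
  }
  list(samples = as.numeric(waveform), sample_rate = sample_rate)
}

#' Slice a waveform into nested prefixes
#'
#' Returns the prefixes of duration `k * step_s` for `k = 1, 2, ...` up to
#' the waveform's duration, each starting at the first sample. Prefixes (as
#' opposed to disjoint chunks) make the vectors at consecutive lengths
#' maximally comparable and the procedure deterministic.
#'
#' @param waveform a `list(samples, sample_rate)` (as from [read_wav()]) or
#'   a numeric vector with `sample_rate` supplied.
#' @param step_s prefix increment in seconds (default 1).
#' @param sample_rate rate for bare numeric input.
#' @return List of waveforms; element `k` has duration `k * step_s`.
#' @export
slice_prefixes <- function(waveform, step_s = 1, sample_rate = NULL) {
  w <- .as_waveform(waveform, sample_rate)
  sr <- w$sample_rate
  dur <- length(w$samples) / sr
  if (dur < step_s) {
    abort(sprintf("waveform of %.2f s is shorter than step_s = %g", dur, step_s),
          class = "somnaudit_too_short_error")
  }
  k_max <- floor(dur / step_s + 1e-9)
  lapply(seq_len(k_max), function(k) {
    n <- floor(k * step_s * sr + 1e-9)
    list(samples = w$samples[seq_len(n)], sample_rate = sr)
  })
}

# --- frame-level low-level descriptors -------------------------------------

.resample_linear <- function(x, sr_from, sr_to) {
  if (sr_from == sr_to) return(x)
  n_out <- floor(length(x) * sr_to / sr_from)
  t_out <- (seq_len(n_out) - 1) / sr_to
  approx(x = (seq_along(x) - 1) / sr_from, y = x, xout = t_out, rule = 2)$y
}

.mel <- function(f) 2595 * log10(1 + f / 700)
.mel_inv <- function(m) 700 * (10^(m / 2595) - 1)

.mel_filterbank <- function(n_filters, nfft, sr) {
  f_pts <- .mel_inv(seq(.mel(0), .mel(sr / 2), length.out = n_filters + 2))
  bins <- floor(f_pts / sr * nfft) + 1
  fb <- matrix(0, n_filters, nfft / 2 + 1)
  for (m in seq_len(n_filters)) {
    lo <- bins[m]; ce <- bins[m + 1]; hi <- bins[m + 2]
    if (ce > lo) fb[m, lo:ce] <- (seq(lo, ce) - lo) / (ce - lo)
    if (hi > ce) fb[m, ce:hi] <- (hi - seq(ce, hi)) / (hi - ce)
  }
  fb
}

.dct_matrix <- function(n_out, n_in) {
  m <- outer(seq_len(n_out) - 1, seq_len(n_in) - 0.5,
             function(k, j) cos(pi * k * j / n_in))
  m * sqrt(2 / n_in)
}

# LLD matrix (frames x descriptors) for a whole waveform; computed once per
# recording and reused for every prefix.
.compute_llds <- function(w, spec) {
  sr <- spec$target_rate_hz
  x <- .resample_linear(w$samples, w$sample_rate, sr)
  L <- round(spec$frame_length_ms / 1000 * sr)
  H <- round(spec$hop_ms / 1000 * sr)
  n <- length(x)
  if (n < 2 * L) {
    abort("waveform too short for at least 2 frames",
          class = "somnaudit_too_short_error")
  }
  nf <- floor((n - L) / H) + 1
  idx <- outer(seq_len(L), (seq_len(nf) - 1) * H, `+`)
  frames <- matrix(x[idx], nrow = L)

  rms <- sqrt(colMeans(frames^2))
  zcr <- colMeans(abs(diff(sign(frames + 1e-18))) > 0)

  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))
  nfft <- 2^ceiling(log2(L))
  padded <- rbind(frames * win, matrix(0, nfft - L, nf))
  spec_mat <- Mod(mvfft(padded))[seq_len(nfft / 2 + 1), , drop = FALSE]
  freqs <- (seq_len(nfft / 2 + 1) - 1) * sr / nfft

  msum <- colSums(spec_mat)
  centroid <- colSums(spec_mat * freqs) / msum          # NaN on silent frames
  pow <- spec_mat^2
  psum <- colSums(pow)
  cum <- apply(pow, 2, cumsum)
  rolloff <- vapply(seq_len(nf), function(j) {
    if (psum[j] <= 0) return(NaN)
    freqs[which(cum[, j] >= 0.85 * psum[j])[1]]
  }, numeric(1))
  norm_spec <- sweep(spec_mat, 2, msum, `/`)            # NaN on silent frames
  flux <- c(0, sqrt(colSums((norm_spec[, -1, drop = FALSE] -
                             norm_spec[, -nf, drop = FALSE])^2)))

  fb <- .mel_filterbank(26, nfft, sr)
  log_mel <- log(fb %*% pow + 1e-10)
  dct <- .dct_matrix(spec$n_mfcc, 26)
  mfcc <- t(dct %*% log_mel)

  # autocorrelation F0 with parabolic peak interpolation
  nfft2 <- 2^ceiling(log2(2 * L))
  centered <- sweep(frames, 2, colMeans(frames))
  pad2 <- rbind(centered, matrix(0, nfft2 - L, nf))
  S <- mvfft(pad2)
  ac <- Re(mvfft(S * Conj(S), inverse = TRUE)) / nfft2
  lag_min <- max(2, floor(sr / spec$f0_range_hz[2]))
  lag_max <- min(L - 2, ceiling(sr / spec$f0_range_hz[1]))
  f0 <- vapply(seq_len(nf), function(j) {
    a <- ac[, j]
    if (a[1] <= 0) return(0)
    seg <- a[(lag_min + 1):(lag_max + 1)]
    k <- which.max(seg)
    if (seg[k] / a[1] < 0.3) return(0)
    lag <- lag_min + k - 1
    # parabolic interpolation around the peak
    y0 <- a[lag]; y1 <- a[lag + 1]; y2 <- a[lag + 2]
    denom <- y0 - 2 * y1 + y2
    delta <- if (abs(denom) > 1e-12) 0.5 * (y0 - y2) / denom else 0
    sr / (lag + .clamp(delta, -0.5, 0.5))
  }, numeric(1))

  lld <- cbind(f0, rms, zcr, centroid, rolloff, flux, mfcc)
  colnames(lld) <- spec$llds
  deltas <- rbind(0, diff(lld))
  colnames(deltas) <- paste0(spec$llds, "_de")
  out <- cbind(lld, deltas)
  attr(out, "frame_end_s") <- ((seq_len(nf) - 1) * H + L) / sr
  out
}

.skewness <- function(v) {
  s <- sd(v)
  if (is.na(s) || s == 0) return(NaN)
  mean((v - mean(v))^3) / s^3
}

.kurtosis <- function(v) {
  s <- sd(v)
  if (is.na(s) || s == 0) return(NaN)
  mean((v - mean(v))^4) / s^4 - 3
}

.slope <- function(v) {
  n <- length(v)
  if (n < 2) return(NaN)
  t <- seq_len(n)
  cov(t, v) / stats::var(t)
}

# Functionals over an LLD matrix (frames x descriptors); NaNs (degenerate
# trajectories) are replaced by 0 so vectors stay finite and comparable.
.apply_functionals <- function(lld, spec) {
  out <- apply(lld, 2, function(v) {
    v <- v[is.finite(v)]          # drop frames with undefined descriptors
    if (length(v) < 2) {
      return(rep(NaN, length(spec$functionals)))
    }
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, na.rm = FALSE)
    c(mean = mean(v), sd = sd(v), min = min(v), max = max(v),
      range = max(v) - min(v), median = q[2], q1 = q[1], q3 = q[3],
      skew = .skewness(v), kurt = .kurtosis(v), slope = .slope(v))
  })
  vec <- as.vector(out)
  names(vec) <- as.vector(vapply(colnames(lld),
                                 function(l) paste0(l, "_", spec$functionals),
                                 character(length(spec$functionals))))
  bad <- !is.finite(vec)
  if (any(bad)) vec[bad] <- 0
  attr(vec, "n_degenerate") <- sum(bad)
  vec
}

#' Extract the acoustic feature vector of one waveform
#'
#' Deterministic: resamples to the spec's analysis rate, computes the
#' frame-level descriptors, and summarizes each trajectory with the spec's
#' functionals. Degenerate functionals (e.g. skewness of a constant
#' trajectory, spectral moments of silence) are replaced by 0 and counted in
#' the `n_degenerate` attribute, with a warning.
#'
#' @param waveform `list(samples, sample_rate)` or numeric vector.
#' @param spec a [feature_extractor_spec()].
#' @param sample_rate rate for bare numeric input.
#' @return Named numeric vector of length `length(feature_names(spec))`.
#' @export
extract_features <- function(waveform, spec = feature_extractor_spec(),
                             sample_rate = NULL) {
  w <- .as_waveform(waveform, sample_rate)
  lld <- .compute_llds(w, spec)
  vec <- .apply_functionals(lld, spec)
  n_degenerate <- attr(vec, "n_degenerate")
  if (n_degenerate > 0) {
    warn(sprintf("%d degenerate functional(s) defaulted to 0", n_degenerate),
         class = "somnaudit_degenerate_feature_warning")
  }
  attr(vec, "n_degenerate") <- NULL
  vec
}

#' Run an external feature extractor on a WAV file
#'
#' Adapter contract: the executable takes a WAV path as its only argument
#' and writes a two-column CSV (`name,value`) to stdout. This lets a
#' full-scale toolkit extractor (e.g. an openSMILE challenge configuration)
#' replace the built-in descriptor set without changing any downstream
#' stage.
#'
#' @param wav_path path to a WAV file.
#' @param command path to the extractor executable.
#' @return Named numeric vector.
#' @export
extract_features_external <- function(wav_path, command) {
  out <- system2(command, shQuote(wav_path), stdout = TRUE)
  parsed <- readr::read_csv(I(paste(out, collapse = "\n")),
                            col_names = c("name", "value"),
                            show_col_types = FALSE)
  setNames(parsed$value, parsed$name)
}

#' Build the per-prefix-length feature table of a corpus
#'
#' For every sample with audio, the frame-level descriptors are computed
#' once and summarized over each nested prefix of `step_s, 2 * step_s, ...`
#' seconds. The matrix at length `n` holds one row per sample whose duration
#' is at least `n` seconds, so row counts shrink with `n`.
#'
#' @param corpus a [corpus()] whose samples carry `audio_ref`s, or a list of
#'   waveforms (`list(samples, sample_rate)`) for in-memory use.
#' @param spec a [feature_extractor_spec()].
#' @param step_s prefix increment, seconds.
#' @param audio_root directory against which `audio_ref` paths resolve
#'   (defaults to the corpus provenance's `audio_root`).
#' @return A `length_feature_table`: list with `matrices` (named by length in
#'   seconds; each samples x features with sample-id rownames), `lengths`,
#'   `spec`, `fingerprint`.
#' @export
build_length_feature_table <- function(corpus, spec = feature_extractor_spec(),
                                       step_s = 1, audio_root = NULL) {
  if (inherits(corpus, "corpus")) {
    refs <- corpus$samples$audio_ref
    if (all(is.na(refs))) {
      abort("corpus has no audio references", class = "somnaudit_argument_error")
    }
    audio_root <- audio_root %||% corpus$provenance$audio_root %||% "."
    ids <- corpus$samples$sample_id[!is.na(refs)]
    waveforms <- lapply(refs[!is.na(refs)], function(ref) {
      p <- if (file.exists(ref)) ref else file.path(audio_root, ref)
      read_wav(p)
    })
    names(waveforms) <- ids
    fingerprint <- .corpus_fingerprint(corpus)
  } else {
    waveforms <- corpus
    if (is.null(names(waveforms))) {
      names(waveforms) <- sprintf("wave%04d", seq_along(waveforms))
    }
    fingerprint <- NA_character_
  }

  per_sample <- lapply(names(waveforms), function(id) {
    w <- waveforms[[id]]
    lld <- .compute_llds(w, spec)
    ends <- attr(lld, "frame_end_s")
    dur <- length(w$samples) / w$sample_rate
    k_max <- floor(dur / step_s + 1e-9)
    vecs <- vector("list", k_max)
    for (k in seq_len(k_max)) {
      sub <- lld[ends <= k * step_s + 1e-9, , drop = FALSE]
      if (nrow(sub) < 2) { vecs[k] <- list(NULL); next }
      vecs[[k]] <- .apply_functionals(sub, spec)
    }
    vecs
  })
  names(per_sample) <- names(waveforms)

  n_max <- max(vapply(per_sample, length, integer(1)))
  fnames <- feature_names(spec)
  matrices <- list()
  for (k in seq_len(n_max)) {
    rows <- purrr::compact(lapply(per_sample, function(v) {
      if (length(v) >= k && !is.null(v[[k]])) v[[k]] else NULL
    }))
    if (!length(rows)) next
    m <- do.call(rbind, rows)
    colnames(m) <- fnames
    matrices[[as.character(round(k * step_s))]] <- m
  }

  structure(
    list(matrices = matrices,
         lengths = as.numeric(names(matrices)),
         step_s = step_s, spec = spec, fingerprint = fingerprint),
    class = "length_feature_table"
  )
}

#' Assemble a length-feature table from ready-made matrices
#'
#' Entry point for feature vectors produced outside the built-in extractor
#' (external adapters, simulations): supply one matrix (samples x features)
#' per prefix length.
#'
#' @param matrices named list of numeric matrices; names are prefix lengths
#'   in seconds. All matrices must share the feature dimension.
#' @param step_s prefix increment, seconds.
#' @return A `length_feature_table`.
#' @export
length_feature_table <- function(matrices, step_s = 1) {
  stopifnot(length(matrices) > 0, !is.null(names(matrices)))
  p <- unique(vapply(matrices, ncol, integer(1)))
  if (length(p) != 1) {
    abort("all matrices must share the feature dimension",
          class = "somnaudit_argument_error")
  }
  structure(
    list(matrices = matrices, lengths = as.numeric(names(matrices)),
         step_s = step_s, spec = NULL, fingerprint = NA_character_),
    class = "length_feature_table"
  )
}

#' @export
print.length_feature_table <- function(x, ...) {
  cat(sprintf("<length_feature_table> %d lengths (%g..%g s), %d features\n",
              length(x$matrices), min(x$lengths), max(x$lengths),
              ncol(x$matrices[[1]])))
  invisible(x)
}

#' Persist / reload a length-feature table
#'
#' Plain-text cache: a JSON header (spec, lengths, sample ids, fingerprint)
#' plus full-precision values, so a reloaded table is identical to the one
#' saved and can be reused across runs when the corpus fingerprint matches.
#'
#' @param table a `length_feature_table`.
#' @param path file path (JSON).
#' @return `path` invisibly; `load_feature_table()` returns the table.
#' @export
save_feature_table <- function(table, path) {
  payload <- list(
    step_s = table$step_s,
    fingerprint = table$fingerprint,
    spec = if (!is.null(table$spec)) unclass(table$spec) else NULL,
    lengths = names(table$matrices),
    feature_names = colnames(table$matrices[[1]]),
    matrices = lapply(table$matrices, function(m) {
      list(sample_ids = rownames(m), values = unname(m))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_feature_table
#' @export
load_feature_table <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  fnames <- payload$feature_names
  matrices <- lapply(payload$matrices, function(entry) {
    m <- entry$values
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    rownames(m) <- entry$sample_ids
    colnames(m) <- fnames
    m
  })
  names(matrices) <- payload$lengths
  spec <- if (!is.null(payload$spec)) {
    s <- payload$spec
    structure(s, class = "feature_extractor_spec")
  } else NULL
  structure(
    list(matrices = matrices, lengths = as.numeric(payload$lengths),
         step_s = payload$step_s, spec = spec,
         fingerprint = payload$fingerprint %||% NA_character_),
    class = "length_feature_table"
  )
}
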