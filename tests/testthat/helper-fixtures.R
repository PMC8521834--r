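# Fixtures are built in code: tiny hand-written corpora for exact checks,
# and count patterns taken from published per-class corpus tables.

tiny_corpus <- function() {
  corpus(
    speakers = tibble::tibble(
      speaker_id = c("a", "b"), sex = c("M", "F"),
      age = c(40, 35), bmi = c(24, 22)
    ),
    samples = tibble::tibble(
      sample_id = c("a1", "a2", "b1", "b2"),
      speaker_id = c("a", "a", "b", "b"),
      session_index = c(1L, 2L, 1L, 2L),
      duration_s = c(30, 25, 40, 35),
      kss = c(8L, 6L, 3L, 4L)
    )
  )
}

# Sample-level sex-by-class counts of the published MSLT corpus table:
# men 100 SL / 115 NSL, women 110 SL / 205 NSL. One speaker per sex carries
# the samples; latencies 4 min (below the 8 min cut) encode SL, 15 min NSL.
mslt_sample_sex_fixture <- function() {
  counts <- list(M = c(SL = 100, NSL = 115), F = c(SL = 110, NSL = 205))
  samples <- dplyr::bind_rows(lapply(names(counts), function(sex) {
    n_sl <- counts[[sex]]["SL"]; n_nsl <- counts[[sex]]["NSL"]
    tibble::tibble(
      sample_id = sprintf("%s%04d", tolower(sex), seq_len(n_sl + n_nsl)),
      speaker_id = paste0("spk_", sex),
      duration_s = 77,
      latency_min = c(rep(4, n_sl), rep(15, n_nsl))
    )
  }))
  corpus(
    speakers = tibble::tibble(speaker_id = c("spk_M", "spk_F"),
                              sex = c("M", "F")),
    samples = samples,
    schema = builtin_rules()["mslt8"]
  )
}

# Speaker-level sex-by-class counts of the same published table: men 15 SL /
# 28 NSL, women 13 SL / 50 NSL, classes encoded by averaged latency.
mslt_speaker_sex_fixture <- function() {
  rows <- rbind(
    data.frame(sex = "M", cls = "SL", n = 15),
    data.frame(sex = "M", cls = "NSL", n = 28),
    data.frame(sex = "F", cls = "SL", n = 13),
    data.frame(sex = "F", cls = "NSL", n = 50)
  )
  speakers <- dplyr::bind_rows(lapply(seq_len(nrow(rows)), function(i) {
    n <- rows$n[i]
    tibble::tibble(
      speaker_id = sprintf("%s_%s_%02d", rows$sex[i], rows$cls[i], seq_len(n)),
      sex = rows$sex[i],
      avg_latency_min = if (rows$cls[i] == "SL") 4.8 else 13.5
    )
  }))
  samples <- tibble::tibble(
    sample_id = paste0(speakers$speaker_id, "_s1"),
    speaker_id = speakers$speaker_id,
    duration_s = 77
  )
  corpus(speakers, samples, schema = builtin_rules()["mslt8"])
}

# Brute-force Mann-Whitney oracle: enumerate every assignment of the pooled
# values into the two groups and compute the exact two-sided p for the
# observed U (doubled one-tail, capped at 1, as the exact convention).
mw_exact_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_obs <- sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(ix) {
    xx <- pooled[ix]; yy <- pooled[-ix]
    sum(outer(xx, yy, `>`)) + 0.5 * sum(outer(xx, yy, `==`))
  })
  p <- 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9))
  list(u = u_obs, p = min(1, p))
}
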