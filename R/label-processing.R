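#' Define a clinical label binarization rule
#'
#' A rule captures the semantics of one clinical sleepiness instrument: its
#' scale bounds, the threshold separating the sleepy (SL) from the non-sleepy
#' (NSL) class, the direction of the comparison, and, for sleep-latency tests,
#' the saturation ceiling `L_max` assigned when the subject never fell asleep
#' (40 min for the Maintenance of Wakefulness Test, 20 min for the Multiple
#' Sleep Latency Test).
#'
#' Thresholds are strict in both directions: `high_is_SL` assigns SL iff
#' `value > threshold`, `low_is_SL` iff `value < threshold`. A value exactly
#' at the threshold is therefore NSL, keeping boundary cases on the
#' non-pathological side. KSS scores are integers, so the conventional 7.5
#' cut is never attained and the choice is moot there; for latencies it is a
#' deliberate conservative convention.
#'
#' @param name short identifier used in schemas, configs and the CLI.
#' @param label_name generic name of the measured quantity (e.g. `"kss"`,
#'   `"latency"`).
#' @param threshold the class cut, in label units.
#' @param direction `"high_is_SL"` or `"low_is_SL"`.
#' @param scale numeric length-2 vector, the attainable `(min, max)` bounds.
#' @param l_max saturation value, or `NA` for labels without a ceiling. When
#'   present it must equal the scale maximum.
#' @param sample_column,speaker_column manifest columns holding the label at
#'   each level (`NA` when the label does not exist at that level).
#' @return An object of class `binarization_rule`.
#' @export
#' @examples
#' mwt <- binarization_rule(
#'   "mwt19", "latency", threshold = 19, direction = "low_is_SL",
#'   scale = c(0, 40), l_max = 40,
#'   sample_column = "latency_min", speaker_column = "avg_latency_min"
#' )
#' binarize(10.36, mwt)
binarization_rule <- function(name, label_name, threshold, direction,
                              scale, l_max = NA_real_,
                              sample_column = NA_character_,
                              speaker_column = NA_character_) {
  direction <- match.arg(direction, c("high_is_SL", "low_is_SL"))
  stopifnot(length(scale) == 2, is.numeric(scale))
  if (!(scale[1] < threshold && threshold < scale[2])) {
    abort("threshold must lie strictly inside the scale bounds",
          class = "somnaudit_argument_error")
  }
  if (!is.na(l_max) && abs(l_max - scale[2]) > 1e-9) {
    abort("l_max must equal the scale maximum when present",
          class = "somnaudit_argument_error")
  }
  structure(
    list(name = name, label_name = label_name, threshold = threshold,
         direction = direction, scale = as.numeric(scale),
         l_max = as.numeric(l_max),
         sample_column = sample_column, speaker_column = speaker_column),
    class = "binarization_rule"
  )
}

#' @export
print.binarization_rule <- function(x, ...) {
  op <- if (x$direction == "high_is_SL") ">" else "<"
  cat(sprintf("<binarization_rule> %s: SL iff %s %s %g (scale [%g, %g]%s)\n",
              x$name, x$label_name, op, x$threshold, x$scale[1], x$scale[2],
              if (is.na(x$l_max)) "" else sprintf(", L_max %g", x$l_max)))
  invisible(x)
}

#' Built-in clinical rules
#'
#' The three standard instruments:
#' * `kss7.5` — Karolinska Sleepiness Scale on a 1-9 scale, SL above 7.5
#'   (the threshold above which micro-sleep events are observed under EEG);
#' * `mwt19` — averaged Maintenance of Wakefulness Test sleep latency, SL
#'   below 19 min, saturated at the 40 min session ceiling;
#' * `mslt8` — averaged Multiple Sleep Latency Test sleep latency, SL below
#'   the 8 min narcolepsy cut-off, saturated at the 20 min nap ceiling.
#'
#' @param kss_scale `"1-9"` (default) or `"1-10"`; the two KSS variants are
#'   clinically interchangeable but corpora must declare which one they use.
#' @return Named list of [binarization_rule()] objects.
#' @export
builtin_rules <- function(kss_scale = c("1-9", "1-10")) {
  kss_scale <- match.arg(kss_scale)
  kss_max <- if (kss_scale == "1-9") 9 else 10
  rules <- list(
    binarization_rule("kss7.5", "kss", threshold = 7.5,
                      direction = "high_is_SL", scale = c(1, kss_max),
                      sample_column = "kss", speaker_column = "avg_kss"),
    binarization_rule("mwt19", "latency", threshold = 19,
                      direction = "low_is_SL", scale = c(0, 40), l_max = 40,
                      sample_column = "latency_min",
                      speaker_column = "avg_latency_min"),
    binarization_rule("mslt8", "latency", threshold = 8,
                      direction = "low_is_SL", scale = c(0, 20), l_max = 20,
                      sample_column = "latency_min",
                      speaker_column = "avg_latency_min")
  )
  names(rules) <- vapply(rules, `[[`, character(1), "name")
  rules
}

#' Look a rule up by name
#'
#' Resolves `"kss7.5"`, `"mwt19"` or `"mslt8"` against [builtin_rules()], or
#' returns the argument unchanged when it already is a rule. Corpus schemas
#' take precedence when a corpus is supplied.
#'
#' @param rule a `binarization_rule` or a rule name.
#' @param corpus optional corpus whose schema is searched first.
#' @return A `binarization_rule`.
#' @export
resolve_rule <- function(rule, corpus = NULL) {
  if (inherits(rule, "binarization_rule")) return(rule)
  stopifnot(is.character(rule), length(rule) == 1)
  if (!is.null(corpus) && rule %in% names(corpus$schema)) {
    return(corpus$schema[[rule]])
  }
  all <- builtin_rules()
  if (rule %in% names(all)) return(all[[rule]])
  abort(sprintf("unknown rule '%s'", rule), class = "somnaudit_argument_error")
}

#' Binarize a clinical label value into SL/NSL
#'
#' Vectorized over `value`; `NA` values stay `NA` (missing labels are never
#' classified). Values outside the rule's scale raise a range error.
#'
#' @param value numeric label values.
#' @param rule a [binarization_rule()] or built-in rule name.
#' @return Character vector of `"SL"`/`"NSL"` (and `NA` where the input was
#'   missing).
#' @export
#' @examples
#' binarize(8, "kss7.5")   # SL
#' binarize(19, "mwt19")   # exactly at the threshold -> NSL
binarize <- function(value, rule) {
  rule <- resolve_rule(rule)
  ok <- is.na(value) | (value >= rule$scale[1] & value <= rule$scale[2])
  if (!all(ok)) {
    abort(sprintf("value %s outside scale [%g, %g] of rule '%s'",
                  format(value[!ok][1]), rule$scale[1], rule$scale[2],
                  rule$name),
          class = "somnaudit_range_error")
  }
  sl <- if (rule$direction == "high_is_SL") value > rule$threshold
        else value < rule$threshold
  ifelse(is.na(value), NA_character_, ifelse(sl, "SL", "NSL"))
}

#' Average per-iteration sleep latencies into the clinical trait measure
#'
#' The reference measure of both latency tests is the arithmetic mean across
#' a fixed number of iterations (four MWT sessions, five MSLT naps). Speakers
#' with an incomplete iteration set get a missing average rather than a mean
#' over fewer sessions: a partial average is not the validated measure.
#'
#' @param latencies numeric vector of per-iteration latencies, in minutes.
#'   `NA` entries count as absent iterations.
#' @param required_count number of iterations the protocol prescribes.
#' @return The mean latency, or `NA` when fewer than `required_count` values
#'   are present.
#' @export
average_latency <- function(latencies, required_count) {
  present <- latencies[!is.na(latencies)]
  if (length(present) > required_count) {
    abort(sprintf("got %d latencies but the protocol has %d iterations",
                  length(present), required_count),
          class = "somnaudit_protocol_error")
  }
  if (length(present) < required_count) return(NA_real_)
  mean(present)
}

#' Fraction of label values pinned at the saturation ceiling
#'
#' Sleep-latency tests assign the session maximum when the subject never fell
#' asleep; the mass of values exactly at that ceiling ("saturation") is a key
#' design diagnostic, since it both skews the label distribution and encodes
#' a qualitatively different outcome (no sleep onset) as a number. Equality
#' is tested to a 1e-9 tolerance to survive float round-trips through CSV.
#'
#' @param values numeric label values (`NA`s are dropped).
#' @param l_max the saturation value, in label units.
#' @return Fraction in `[0, 1]` of non-missing values equal to `l_max`.
#' @export
saturation_fraction <- function(values, l_max) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    abort("no non-missing values", class = "somnaudit_argument_error")
  }
  mean(abs(values - l_max) < 1e-9)
}

# Derive SL/NSL classes at a level. For speaker level the rule's speaker
# column is used when populated; otherwise the per-speaker mean of the sample
# column stands in (and a message records the fallback). Sample- and
# speaker-level labels are always computed independently of each other.
derive_classes <- function(corpus, rule, level = c("sample", "speaker")) {
  level <- match.arg(level)
  rule <- resolve_rule(rule, corpus)
  if (level == "sample") {
    col <- rule$sample_column
    if (is.na(col) || !col %in% names(corpus$samples)) {
      abort(sprintf("rule '%s' has no sample-level column", rule$name),
            class = "somnaudit_argument_error")
    }
    vals <- corpus$samples[[col]]
    return(tibble::tibble(id = corpus$samples$sample_id,
                          value = vals, class = binarize(vals, rule)))
  }
  col <- rule$speaker_column
  sp <- corpus$speakers
  if (!is.na(col) && col %in% names(sp) && any(!is.na(sp[[col]]))) {
    vals <- sp[[col]]
  } else {
    scol <- rule$sample_column
    agg <- corpus$samples |>
      dplyr::group_by(.data$speaker_id) |>
      dplyr::summarise(value = mean(.data[[scol]], na.rm = TRUE)) |>
      dplyr::mutate(value = ifelse(is.nan(.data$value), NA_real_, .data$value))
    vals <- agg$value[match(sp$speaker_id, agg$speaker_id)]
  }
  tibble::tibble(id = sp$speaker_id, value = vals,
                 class = binarize(vals, rule))
}

#' Class balance table
#'
#' Counts SL/NSL entities at the requested level, optionally cross-tabulated
#' by one categorical covariate (sample-level counts use each sample's
#' speaker's covariate value). Entities whose label is missing are reported
#' in the `missing` field, never silently dropped into a class.
#'
#' @param corpus a [corpus()].
#' @param rule label rule or name.
#' @param level `"sample"` or `"speaker"`.
#' @param by optional speaker covariate name (e.g. `"sex"`).
#' @return A list of class `balance_table` with `level`, `counts` (named
#'   SL/NSL), `missing`, and `by_covariate` (tibble or `NULL`).
#' @export
class_balance <- function(corpus, rule, level = c("sample", "speaker"),
                          by = NULL) {
  level <- match.arg(level)
  cls <- derive_classes(corpus, rule, level)
  counts <- c(SL = sum(cls$class == "SL", na.rm = TRUE),
              NSL = sum(cls$class == "NSL", na.rm = TRUE))
  by_cov <- NULL
  if (!is.null(by)) {
    if (!by %in% names(corpus$speakers)) {
      abort(sprintf("unknown covariate '%s'", by),
            class = "somnaudit_argument_error")
    }
    if (level == "speaker") {
      covariate <- corpus$speakers[[by]]
    } else {
      covariate <- corpus$speakers[[by]][
        match(corpus$samples$speaker_id, corpus$speakers$speaker_id)]
    }
    keep <- !is.na(cls$class) & !is.na(covariate)
    by_cov <- tibble::as_tibble(table(
      covariate = covariate[keep], class = cls$class[keep]
    )) |>
      tidyr::pivot_wider(names_from = "class", values_from = "n",
                         values_fill = 0L)
    for (need in c("SL", "NSL")) {
      if (!need %in% names(by_cov)) by_cov[[need]] <- 0L
    }
    by_cov <- by_cov[, c("covariate", "SL", "NSL")]
    by_cov$total <- by_cov$SL + by_cov$NSL
  }
  structure(
    list(level = level, rule = resolve_rule(rule, corpus)$name,
         counts = counts, missing = sum(is.na(cls$class)),
         by_covariate = by_cov),
    class = "balance_table"
  )
}

#' @export
print.balance_table <- function(x, ...) {
  cat(sprintf("<balance_table> %s level (rule %s): SL %d, NSL %d, missing %d\n",
              x$level, x$rule, x$counts[["SL"]], x$counts[["NSL"]], x$missing))
  if (!is.null(x$by_covariate)) print(x$by_covariate)
  invisible(x)
}
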