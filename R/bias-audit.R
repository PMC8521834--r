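# Polynomial rolling hash over a canonical serialization of the identifying
# columns; cheap, dependency-free, stable across sessions. Used to
# fingerprint corpora in reports and feature caches.
.corpus_fingerprint <- function(corpus) {
  key <- paste(
    nrow(corpus$speakers), nrow(corpus$samples),
    paste(corpus$samples$sample_id, collapse = ","),
    paste(format(corpus$samples$duration_s, digits = 12), collapse = ","),
    sep = "|"
  )
  h <- 5381
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Audit covariates for class imbalance
#'
#' For each covariate, tests whether its distribution differs between the SL
#' and NSL classes: numeric covariates by a two-sided Mann-Whitney U test,
#' categorical covariates by a Yates-corrected chi-squared test on a 2x2
#' table (non-binary categoricals are collapsed to most-frequent-versus-rest
#' with a warning). No multiple-testing correction is applied across rows —
#' the report states the number of tests so readers can adjust mentally;
#' this matches the per-test reporting convention of clinical corpus tables.
#'
#' The report also carries the saturation fraction of every latency label in
#' the schema and the samples-per-speaker outlier list.
#'
#' @param corpus a [corpus()].
#' @param rule label rule or name defining the classes.
#' @param level `"speaker"` or `"sample"` (sample level weights speakers by
#'   their recordings).
#' @param covariates character vector of speaker covariate names; defaults
#'   to sex, age and BMI.
#' @param alpha significance level for the `imbalance` flag.
#' @return A list of class `audit_report`: `rows` (one per covariate),
#'   `alpha`, `n_tests`, `fingerprint`, `saturation`, `outliers`.
#' @export
audit_covariates <- function(corpus, rule, level = c("speaker", "sample"),
                             covariates = c("sex", "age", "bmi"),
                             alpha = 0.05) {
  level <- match.arg(level)
  stopifnot(alpha > 0, alpha < 1)
  rule <- resolve_rule(rule, corpus)
  cls <- derive_classes(corpus, rule, level)

  sp <- corpus$speakers
  if (level == "speaker") {
    ent_class <- cls$class
    cov_value <- function(col) sp[[col]]
  } else {
    ent_class <- cls$class
    cov_value <- function(col) {
      if (col %in% names(corpus$samples)) {
        corpus$samples[[col]]
      } else {
        sp[[col]][match(corpus$samples$speaker_id, sp$speaker_id)]
      }
    }
  }

  rows <- list()
  for (cov in covariates) {
    src <- if (level == "sample" && cov %in% names(corpus$samples)) {
      corpus$samples
    } else sp
    if (!cov %in% names(src)) {
      abort(sprintf("unknown covariate '%s'", cov),
            class = "somnaudit_argument_error")
    }
    v <- cov_value(cov)
    keep <- !is.na(v) & !is.na(ent_class)
    v <- v[keep]
    k <- ent_class[keep]
    row <- tibble::tibble(
      covariate = cov, level = level, method = NA_character_,
      statistic = NA_real_, p_value = NA_real_,
      sl_mean = NA_real_, sl_sd = NA_real_, nsl_mean = NA_real_,
      nsl_sd = NA_real_, sl_n = sum(k == "SL"), nsl_n = sum(k == "NSL"),
      flag = "degenerate", note = NA_character_
    )
    if (row$sl_n > 0 && row$nsl_n > 0) {
      if (is.numeric(v)) {
        res <- mann_whitney_u(v[k == "SL"], v[k == "NSL"])
        row$method <- res$method
        row$statistic <- res$statistic
        row$p_value <- res$p_value
        row$sl_mean <- mean(v[k == "SL"]); row$sl_sd <- sd(v[k == "SL"])
        row$nsl_mean <- mean(v[k == "NSL"]); row$nsl_sd <- sd(v[k == "NSL"])
        row$flag <- if (res$p_value < alpha) "imbalance" else "ok"
      } else {
        lv <- names(sort(table(v), decreasing = TRUE))
        vv <- v
        if (length(lv) > 2) {
          vv <- ifelse(v == lv[1], lv[1], paste0("not_", lv[1]))
          row$note <- sprintf("collapsed %d categories to '%s' vs rest",
                              length(lv), lv[1])
        }
        tab <- table(factor(vv), factor(k, levels = c("SL", "NSL")))
        if (all(dim(tab) == c(2, 2)) && all(rowSums(tab) > 0) &&
            all(colSums(tab) > 0)) {
          res <- chi_squared_2x2(tab)
          row$method <- res$method
          row$statistic <- res$statistic
          row$p_value <- res$p_value
          row$flag <- if (res$p_value < alpha) "imbalance" else "ok"
          if (length(res$warnings)) {
            row$note <- paste(c(row$note[!is.na(row$note)], res$warnings),
                              collapse = "; ")
          }
        } else {
          row$note <- "degenerate contingency table"
        }
      }
    }
    rows[[length(rows) + 1]] <- row
  }

  saturation <- .saturation_summaries(corpus)
  outliers <- if (nrow(corpus$speakers) >= 4) {
    detect_outlier_speakers(corpus)
  } else {
    tibble::tibble(speaker_id = character(), n_samples = integer(),
                   fence = numeric())
  }

  structure(
    list(rows = dplyr::bind_rows(rows), alpha = alpha,
         n_tests = length(covariates), rule = rule$name, level = level,
         fingerprint = .corpus_fingerprint(corpus),
         saturation = saturation, outliers = outliers),
    class = "audit_report"
  )
}

.saturation_summaries <- function(corpus) {
  out <- list()
  for (r in corpus$schema) {
    if (is.na(r$l_max)) next
    col <- r$sample_column
    if (!is.na(col) && col %in% names(corpus$samples) &&
        any(!is.na(corpus$samples[[col]]))) {
      vals <- corpus$samples[[col]]
      out[[length(out) + 1]] <- tibble::tibble(
        rule = r$name, level = "sample",
        fraction = saturation_fraction(vals, r$l_max),
        n = sum(!is.na(vals))
      )
    }
    scol <- r$speaker_column
    if (!is.na(scol) && scol %in% names(corpus$speakers) &&
        any(!is.na(corpus$speakers[[scol]]))) {
      vals <- corpus$speakers[[scol]]
      out[[length(out) + 1]] <- tibble::tibble(
        rule = r$name, level = "speaker",
        fraction = saturation_fraction(vals, r$l_max),
        n = sum(!is.na(vals))
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(rule = character(), level = character(),
                          fraction = numeric(), n = integer()))
  }
  dplyr::bind_rows(out)
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf("<audit_report> rule %s, %s level, alpha = %g (%d uncorrected tests)\n",
              x$rule, x$level, x$alpha, x$n_tests))
  print(x$rows, n = Inf)
  if (nrow(x$saturation)) {
    cat("saturation:\n"); print(x$saturation)
  }
  if (nrow(x$outliers)) {
    cat("samples-per-speaker outliers:\n"); print(x$outliers)
  }
  invisible(x)
}

#' Detect speakers recorded disproportionately often
#'
#' Flags speakers whose samples-per-speaker count exceeds the Tukey upper
#' fence `Q3 + 1.5 * IQR` of the per-speaker counts. When the IQR is zero
#' (near-unanimous counts) the fence degenerates, so the rule falls back to
#' flagging counts above 1.5 times the third quartile.
#'
#' @param corpus a [corpus()] with at least 4 speakers.
#' @return Tibble with `speaker_id`, `n_samples`, `fence`, sorted by count
#'   descending; zero rows when no speaker exceeds the fence.
#' @export
detect_outlier_speakers <- function(corpus) {
  if (nrow(corpus$speakers) < 4) {
    abort("need at least 4 speakers for outlier detection",
          class = "somnaudit_insufficient_data_error")
  }
  counts <- table(factor(corpus$samples$speaker_id,
                         levels = corpus$speakers$speaker_id))
  n <- as.numeric(counts)
  q <- quantile(n, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  fence <- if (iqr > 0) q[2] + 1.5 * iqr else 1.5 * q[2]
  flagged <- which(n > fence)
  out <- tibble::tibble(
    speaker_id = names(counts)[flagged],
    n_samples = as.integer(n[flagged]),
    fence = fence
  )
  out[order(-out$n_samples), ]
}

#' Impact of excluding speakers on a label distribution
#'
#' Compares the distribution of a sample-level label over the whole corpus
#' against the distribution after removing the excluded speakers' samples
#' (Mann-Whitney U, whole-versus-remaining, as done when assessing how
#' over-sampled speakers distort a corpus), and reports the class ratio and
#' moments before and after.
#'
#' @param corpus a [corpus()].
#' @param excluded character vector of speaker ids (subset of the corpus).
#' @param label sample-level label column (e.g. `"kss"`).
#' @param rule optional rule for the class ratio; defaults to the schema rule
#'   whose sample column is `label`.
#' @return A list of class `exclusion_impact`.
#' @export
exclusion_impact <- function(corpus, excluded, label, rule = NULL) {
  if (!all(excluded %in% corpus$speakers$speaker_id)) {
    abort("excluded ids must be speakers of the corpus",
          class = "somnaudit_argument_error")
  }
  if (!label %in% names(corpus$samples)) {
    abort(sprintf("unknown label '%s'", label),
          class = "somnaudit_argument_error")
  }
  keep <- !corpus$samples$speaker_id %in% excluded
  if (!any(keep)) {
    abort("exclusion would empty the corpus",
          class = "somnaudit_argument_error")
  }
  before <- corpus$samples[[label]]
  after <- before[keep]
  before_v <- before[!is.na(before)]
  after_v <- after[!is.na(after)]
  shift <- mann_whitney_u(before_v, after_v)

  if (is.null(rule)) {
    match_rule <- Filter(function(r) identical(r$sample_column, label),
                         corpus$schema)
    rule <- if (length(match_rule)) match_rule[[1]] else NULL
  } else {
    rule <- resolve_rule(rule, corpus)
  }
  ratio <- function(vals) {
    if (is.null(rule)) return(NA_real_)
    cl <- binarize(vals[!is.na(vals)], rule)
    mean(cl == "SL")
  }

  structure(
    list(excluded = excluded, label = label,
         n_before = length(before_v), n_after = length(after_v),
         mean_before = mean(before_v), sd_before = sd(before_v),
         mean_after = mean(after_v), sd_after = sd(after_v),
         shift_test = shift,
         class_ratio_before = ratio(before_v),
         class_ratio_after = ratio(after_v)),
    class = "exclusion_impact"
  )
}

#' @export
print.exclusion_impact <- function(x, ...) {
  cat(sprintf("<exclusion_impact> label %s, %d speakers excluded\n",
              x$label, length(x$excluded)))
  cat(sprintf("  n: %d -> %d; mean: %.3f -> %.3f; SL ratio: %.3f -> %.3f\n",
              x$n_before, x$n_after, x$mean_before, x$mean_after,
              x$class_ratio_before, x$class_ratio_after))
  cat(sprintf("  distribution shift: p = %.3g (%s)\n",
              x$shift_test$p_value, x$shift_test$method))
  invisible(x)
}

#' Cross-correlation of two sample-level labels
#'
#' Spearman correlation over complete pairs, computed twice: once on all
#' pairs and once excluding pairs whose second label sits at its saturation
#' ceiling. Comparing the two isolates how much the ceiling mass drives (or
#' masks) the association between, say, subjective KSS and objective sleep
#' latency.
#'
#' @param corpus a [corpus()].
#' @param label_a,label_b sample-level label columns.
#' @return A list of class `label_cross_correlation` with `with_saturated`,
#'   `without_saturated` (both [spearman_rho()] results; the second is `NULL`
#'   when `label_b` has no ceiling or too few unsaturated pairs survive),
#'   and `n_saturated`.
#' @export
label_cross_correlation <- function(corpus, label_a, label_b) {
  for (lab in c(label_a, label_b)) {
    if (!lab %in% names(corpus$samples)) {
      abort(sprintf("unknown label '%s'", lab),
            class = "somnaudit_argument_error")
    }
  }
  a <- corpus$samples[[label_a]]
  b <- corpus$samples[[label_b]]
  keep <- !is.na(a) & !is.na(b)
  if (sum(keep) < 3) {
    abort("fewer than 3 complete pairs",
          class = "somnaudit_insufficient_data_error")
  }
  with_sat <- spearman_rho(a[keep], b[keep])

  match_rule <- Filter(function(r) identical(r$sample_column, label_b) &&
                         !is.na(r$l_max), corpus$schema)
  without_sat <- NULL
  n_saturated <- 0L
  if (length(match_rule)) {
    l_max <- match_rule[[1]]$l_max
    sat <- keep & abs(b - l_max) < 1e-9
    n_saturated <- sum(sat)
    keep2 <- keep & !sat
    if (sum(keep2) >= 3) {
      without_sat <- spearman_rho(a[keep2], b[keep2])
    }
  }
  structure(
    list(label_a = label_a, label_b = label_b,
         with_saturated = with_sat, without_saturated = without_sat,
         n_saturated = n_saturated),
    class = "label_cross_correlation"
  )
}

#' Default parameters of the corpus-design linter
#'
#' @return Named list of rule parameters; pass a modified copy to
#'   [lint_design()] or disable a rule by setting its entry to `NULL`.
#' @export
lint_rules <- function() {
  list(
    MIN_SAMPLE_LENGTH = list(min_s = 20),
    MAX_SAMPLE_LENGTH = list(max_s = 120),
    UNEQUAL_SAMPLES_PER_SPEAKER = list(),
    MISSING_METADATA = list(fields = c("sex", "age")),
    KSS_REPEAT_SPACING = list(min_interval_min = 10,
                              timestamp_column = "timestamp_min"),
    RAW_LABELS_ABSENT = list()
  )
}

#' Lint a corpus against design guidelines
#'
#' Checks the quantifiable corpus-design recommendations: samples at least
#' 20 s (features need that long to stabilize) and at most 2 min (fatigue
#' and boredom), the same number of samples for every speaker, sex and age
#' recorded for every speaker, KSS measurements spaced at least 10 min apart
#' (the scale's validity window) when timestamps exist, and the presence of
#' raw pre-binarized label values. Lint never raises: violations are data.
#'
#' @param corpus a [corpus()].
#' @param config rule parameters, as from [lint_rules()]; omit an entry to
#'   disable the rule.
#' @return A list of class `lint_report` with a `violations` tibble
#'   (`rule`, `severity`, `scope`, `entity`, `message`); empty iff the corpus
#'   passes all enabled rules.
#' @export
lint_design <- function(corpus, config = lint_rules()) {
  v <- list()
  add <- function(rule, severity, scope, entity, message) {
    v[[length(v) + 1]] <<- tibble::tibble(
      rule = rule, severity = severity, scope = scope,
      entity = as.character(entity), message = message
    )
  }
  sa <- corpus$samples
  sp <- corpus$speakers

  if (!is.null(config$MIN_SAMPLE_LENGTH)) {
    min_s <- config$MIN_SAMPLE_LENGTH$min_s
    short <- sa$sample_id[!is.na(sa$duration_s) & sa$duration_s < min_s]
    for (id in short) {
      add("MIN_SAMPLE_LENGTH", "warning", "sample", id,
          sprintf("duration %.1f s below the %g s minimum for feature convergence",
                  sa$duration_s[sa$sample_id == id][1], min_s))
    }
  }
  if (!is.null(config$MAX_SAMPLE_LENGTH)) {
    max_s <- config$MAX_SAMPLE_LENGTH$max_s
    long <- sa$sample_id[!is.na(sa$duration_s) & sa$duration_s > max_s]
    for (id in long) {
      add("MAX_SAMPLE_LENGTH", "info", "sample", id,
          sprintf("duration %.1f s above the %g s maximum (fatigue/boredom risk)",
                  sa$duration_s[sa$sample_id == id][1], max_s))
    }
  }
  if (!is.null(config$UNEQUAL_SAMPLES_PER_SPEAKER)) {
    counts <- table(sa$speaker_id)
    if (length(counts) > 1 && length(unique(as.integer(counts))) > 1) {
      add("UNEQUAL_SAMPLES_PER_SPEAKER", "warning", "corpus", NA,
          sprintf("samples per speaker range from %d to %d; equal counts recommended",
                  min(counts), max(counts)))
    }
  }
  if (!is.null(config$MISSING_METADATA)) {
    for (field in config$MISSING_METADATA$fields) {
      if (!field %in% names(sp) || any(is.na(sp[[field]]))) {
        n_missing <- if (field %in% names(sp)) sum(is.na(sp[[field]])) else nrow(sp)
        add("MISSING_METADATA", "warning", "corpus", field,
            sprintf("speaker metadata '%s' missing for %d of %d speakers",
                    field, n_missing, nrow(sp)))
      }
    }
  }
  if (!is.null(config$KSS_REPEAT_SPACING)) {
    ts_col <- config$KSS_REPEAT_SPACING$timestamp_column
    min_gap <- config$KSS_REPEAT_SPACING$min_interval_min
    if (ts_col %in% names(sa) && any(!is.na(sa[[ts_col]]))) {
      with_kss <- sa[!is.na(sa$kss) & !is.na(sa[[ts_col]]), ]
      for (spk in unique(with_kss$speaker_id)) {
        ts <- sort(with_kss[[ts_col]][with_kss$speaker_id == spk])
        if (length(ts) > 1 && any(diff(ts) < min_gap)) {
          add("KSS_REPEAT_SPACING", "warning", "speaker", spk,
              sprintf("KSS refilled after %.1f min (validity window %g min)",
                      min(diff(ts)), min_gap))
        }
      }
    }
  }
  if (!is.null(config$RAW_LABELS_ABSENT)) {
    raw_cols <- vapply(corpus$schema, `[[`, character(1), "sample_column")
    raw_cols <- raw_cols[!is.na(raw_cols)]
    has_raw <- any(vapply(raw_cols, function(col) {
      col %in% names(sa) && any(!is.na(sa[[col]]))
    }, logical(1)))
    has_class <- "state_class" %in% names(sa) && any(!is.na(sa$state_class))
    if (!has_raw && has_class) {
      add("RAW_LABELS_ABSENT", "warning", "corpus", NA,
          "only binarized classes present; raw label values should be distributed")
    }
  }

  violations <- if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(rule = character(), severity = character(),
                   scope = character(), entity = character(),
                   message = character())
  structure(list(violations = violations,
                 fingerprint = .corpus_fingerprint(corpus)),
            class = "lint_report")
}

#' @export
print.lint_report <- function(x, ...) {
  if (nrow(x$violations) == 0) {
    cat("<lint_report> clean: no guideline violations\n")
  } else {
    cat(sprintf("<lint_report> %d violation(s)\n", nrow(x$violations)))
    print(x$violations, n = Inf)
  }
  invisible(x)
}

#' Serialize an audit report to a JSON-ready list
#'
#' @param report an [audit_covariates()] result.
#' @return A plain list suitable for `jsonlite::write_json()`.
#' @export
audit_report_to_list <- function(report) {
  list(
    rule = report$rule, level = report$level, alpha = report$alpha,
    n_tests = report$n_tests, fingerprint = report$fingerprint,
    rows = report$rows, saturation = report$saturation,
    outliers = report$outliers
  )
}

#' Render an audit report as Markdown
#'
#' @param report an [audit_covariates()] result.
#' @return Character vector of Markdown lines.
#' @export
format_audit_markdown <- function(report) {
  r <- report$rows
  fmt_p <- function(p) ifelse(is.na(p), "-", formatC(p, digits = 2, format = "g"))
  lines <- c(
    sprintf("### Covariate audit (rule %s, %s level, alpha = %g)",
            report$rule, report$level, report$alpha),
    sprintf("%d tests, uncorrected; corpus fingerprint %s", report$n_tests,
            report$fingerprint),
    "",
    "| covariate | method | statistic | p | SL mean (sd) | NSL mean (sd) | flag |",
    "| --- | --- | ---: | ---: | ---: | ---: | --- |",
    sprintf("| %s | %s | %s | %s | %s | %s | %s |",
            r$covariate, ifelse(is.na(r$method), "-", r$method),
            ifelse(is.na(r$statistic), "-",
                   formatC(r$statistic, digits = 4, format = "g")),
            fmt_p(r$p_value),
            ifelse(is.na(r$sl_mean), sprintf("n=%d", r$sl_n),
                   sprintf("%.2f (%.2f)", r$sl_mean, r$sl_sd)),
            ifelse(is.na(r$nsl_mean), sprintf("n=%d", r$nsl_n),
                   sprintf("%.2f (%.2f)", r$nsl_mean, r$nsl_sd)),
            r$flag)
  )
  if (nrow(report$saturation)) {
    lines <- c(lines, "", "| label rule | level | saturation | n |",
               "| --- | --- | ---: | ---: |",
               sprintf("| %s | %s | %.1f%% | %d |", report$saturation$rule,
                       report$saturation$level,
                       100 * report$saturation$fraction, report$saturation$n))
  }
  if (nrow(report$outliers)) {
    lines <- c(lines, "",
               sprintf("Samples-per-speaker outliers (fence %.1f): %s",
                       report$outliers$fence[1],
                       paste(sprintf("%s (%d)", report$outliers$speaker_id,
                                     report$outliers$n_samples),
                             collapse = ", ")))
  }
  lines
}
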