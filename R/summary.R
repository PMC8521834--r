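#' Per-class summary table of a corpus
#'
#' Mirrors the layout of the per-class "global statistics" tables that
#' clinical speech corpora report: per class (SL / NSL / total) the speaker
#' and sample counts, total and mean/sd recording length, sex counts, and
#' mean/sd of every numeric label and covariate available at the chosen
#' level. Entities whose label is missing are excluded from the classes and
#' counted separately in `$missing`.
#'
#' @param corpus a [corpus()].
#' @param rule a [binarization_rule()] or name; defines the SL/NSL split.
#' @param level `"sample"` (classes from per-sample labels) or `"speaker"`.
#' @return A list of class `corpus_summary` with elements `level`, `rule`,
#'   `table` (tibble: `metric`, `SL`, `NSL`, `total`), and `missing`.
#' @export
summarize_corpus <- function(corpus, rule, level = c("sample", "speaker")) {
  level <- match.arg(level)
  rule <- resolve_rule(rule, corpus)
  cls <- derive_classes(corpus, rule, level)
  if (all(is.na(cls$class))) {
    abort(sprintf("label of rule '%s' is absent everywhere at the %s level",
                  rule$name, level),
          class = "somnaudit_empty_summary_error")
  }

  sa <- corpus$samples
  sp <- corpus$speakers
  if (level == "sample") {
    sa$._class <- cls$class[match(sa$sample_id, cls$id)]
    ent <- sa
    sex <- sp$sex[match(sa$speaker_id, sp$speaker_id)]
    numeric_cols <- intersect(c("duration_s", "kss", "kss_mixed", "latency_min"),
                              names(sa))
  } else {
    sp$._class <- cls$class[match(sp$speaker_id, cls$id)]
    ent <- sp
    sex <- sp$sex
    numeric_cols <- intersect(c("age", "bmi", "ess", "avg_latency_min", "avg_kss"),
                              names(sp))
  }
  ent$._sex <- sex

  groups <- list(SL = ent[!is.na(ent$._class) & ent$._class == "SL", ],
                 NSL = ent[!is.na(ent$._class) & ent$._class == "NSL", ],
                 total = ent[!is.na(ent$._class), ])

  one_metric <- function(fn) vapply(groups, fn, numeric(1))
  rows <- list()
  push <- function(metric, values) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      metric = metric, SL = values[["SL"]], NSL = values[["NSL"]],
      total = values[["total"]]
    )
  }

  if (level == "sample") {
    push("speakers", one_metric(function(g) length(unique(g$speaker_id))))
    push("samples", one_metric(nrow))
    push("total_length_s", one_metric(function(g) sum(g$duration_s, na.rm = TRUE)))
    push("mean_length_s", one_metric(function(g) mean(g$duration_s, na.rm = TRUE)))
    push("sd_length_s", one_metric(function(g) sd(g$duration_s, na.rm = TRUE)))
  } else {
    push("speakers", one_metric(nrow))
  }
  push("men", one_metric(function(g) sum(g$._sex == "M", na.rm = TRUE)))
  push("women", one_metric(function(g) sum(g$._sex == "F", na.rm = TRUE)))
  for (col in setdiff(numeric_cols, "duration_s")) {
    if (all(is.na(ent[[col]]))) next
    push(paste0("mean_", col), one_metric(function(g) mean(g[[col]], na.rm = TRUE)))
    push(paste0("sd_", col), one_metric(function(g) sd(g[[col]], na.rm = TRUE)))
  }

  structure(
    list(level = level, rule = rule$name,
         table = dplyr::bind_rows(rows),
         missing = sum(is.na(cls$class))),
    class = "corpus_summary"
  )
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat(sprintf("<corpus_summary> %s level, rule %s (%d unlabeled excluded)\n",
              x$level, x$rule, x$missing))
  print(x$table, n = Inf)
  invisible(x)
}

#' Render a corpus summary as Markdown
#'
#' @param summary a [summarize_corpus()] result.
#' @return Character vector of Markdown lines.
#' @export
format_summary_markdown <- function(summary) {
  tab <- summary$table
  fmt <- function(v) ifelse(abs(v - round(v)) < 1e-9, format(round(v)),
                            formatC(v, digits = 2, format = "f"))
  c(sprintf("### Corpus summary (%s level, rule %s)", summary$level, summary$rule),
    "",
    "| metric | SL | NSL | total |",
    "| --- | ---: | ---: | ---: |",
    sprintf("| %s | %s | %s | %s |", tab$metric, fmt(tab$SL), fmt(tab$NSL),
            fmt(tab$total)),
    "",
    sprintf("Entities with missing label: %d", summary$missing))
}
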