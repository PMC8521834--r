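#' @keywords internal
"_PACKAGE"

## usethis namespace: start
#' @importFrom rlang .data %||% abort warn
#' @importFrom stats fft mvfft rnorm rgamma rbinom runif sd quantile median
#'   wilcox.test chisq.test pchisq pt cor cov approx plogis qnorm coef lm setNames
#' @importFrom utils head tail modifyList
## usethis namespace: end
NULL

# Canonical column sets for the two manifest tables. Extra columns are carried
# through untouched (they often hold study-specific metadata such as
# timestamps or questionnaire subscores).
.speaker_columns <- c(
  "speaker_id", "sex", "age", "bmi", "comorbidities", "ess",
  "avg_latency_min", "avg_kss", "trait_class"
)

.sample_columns <- c(
  "sample_id", "speaker_id", "session_index", "task", "duration_s",
  "kss", "kss_mixed", "latency_min", "audio_ref", "state_class"
)

#' Assemble a speech-health corpus
#'
#' A corpus bundles a speaker table, a sample (recording) table, a label
#' schema (a list of [binarization_rule()] objects describing each clinical
#' label), and free-form provenance metadata. Speakers carry trait-level
#' information (sex, age, BMI, comorbidities, Epworth score, averaged sleep
#' latency); samples carry state-level information (session index, task,
#' duration, KSS score, per-iteration sleep latency, audio reference).
#'
#' Missing values are explicit `NA`s: a speaker without a BMI measurement or a
#' sample without a KSS simply has an `NA` cell, and every downstream audit
#' excludes (and counts) such entities rather than imputing.
#'
#' @param speakers data frame with at least a `speaker_id` column; recognised
#'   columns are `sex` (`"M"`/`"F"`), `age` (years), `bmi` (kg/m^2),
#'   `comorbidities` (`;`-separated tags), `ess` (0-24), `avg_latency_min`
#'   (minutes), `avg_kss`, `trait_class` (`"SL"`/`"NSL"`).
#' @param samples data frame with at least `sample_id`, `speaker_id` and
#'   `duration_s`; recognised columns are `session_index`, `task`, `kss`
#'   (integer scale score), `kss_mixed` (rater-averaged real-valued KSS, kept
#'   separate from self-report `kss`), `latency_min`, `audio_ref`,
#'   `state_class`.
#' @param schema list of [binarization_rule()] objects (defaults to the three
#'   built-in clinical rules, see [builtin_rules()]).
#' @param provenance named list of free-text metadata.
#' @param validate if `TRUE` (default), abort when [validate_corpus()] finds
#'   violations.
#' @return An object of class `corpus`.
#' @export
#' @examples
#' sp <- tibble::tibble(speaker_id = c("a", "b"), sex = c("M", "F"))
#' sa <- tibble::tibble(
#'   sample_id = c("a1", "a2", "b1"), speaker_id = c("a", "a", "b"),
#'   duration_s = c(30, 25, 40), kss = c(8L, 6L, 3L)
#' )
#' corp <- corpus(sp, sa)
#' corp
corpus <- function(speakers, samples, schema = builtin_rules(),
                   provenance = list(), validate = TRUE) {
  speakers <- .coerce_speakers(speakers)
  samples <- .coerce_samples(samples)
  if (!is.null(names(schema)) || length(schema) == 0) {
    schema <- unname(schema)
  }
  for (r in schema) {
    if (!inherits(r, "binarization_rule")) {
      abort("every schema entry must be a binarization_rule")
    }
  }
  names(schema) <- vapply(schema, `[[`, character(1), "name")
  obj <- structure(
    list(speakers = speakers, samples = samples, schema = schema,
         provenance = provenance),
    class = "corpus"
  )
  if (validate) {
    v <- validate_corpus(obj)
    if (nrow(v) > 0) {
      abort(c("invalid corpus", .format_violations(v)))
    }
  }
  obj
}

.coerce_speakers <- function(speakers) {
  speakers <- tibble::as_tibble(speakers)
  if (!"speaker_id" %in% names(speakers)) {
    abort("speakers table must have a speaker_id column", class = "somnaudit_schema_error")
  }
  defaults <- list(
    sex = NA_character_, age = NA_real_, bmi = NA_real_,
    comorbidities = NA_character_, ess = NA_integer_,
    avg_latency_min = NA_real_, avg_kss = NA_real_, trait_class = NA_character_
  )
  for (col in names(defaults)) {
    if (!col %in% names(speakers)) speakers[[col]] <- defaults[[col]]
  }
  speakers$speaker_id <- as.character(speakers$speaker_id)
  speakers$sex <- as.character(speakers$sex)
  speakers$comorbidities <- as.character(speakers$comorbidities)
  speakers$age <- as.numeric(speakers$age)
  speakers$bmi <- as.numeric(speakers$bmi)
  speakers$ess <- as.integer(speakers$ess)
  speakers$avg_latency_min <- as.numeric(speakers$avg_latency_min)
  speakers$avg_kss <- as.numeric(speakers$avg_kss)
  speakers$trait_class <- as.character(speakers$trait_class)
  dplyr::relocate(speakers, dplyr::any_of(.speaker_columns))
}

.coerce_samples <- function(samples) {
  samples <- tibble::as_tibble(samples)
  for (col in c("sample_id", "speaker_id", "duration_s")) {
    if (!col %in% names(samples)) {
      abort(paste0("samples table must have a ", col, " column"),
            class = "somnaudit_schema_error")
    }
  }
  defaults <- list(
    session_index = NA_integer_, task = NA_character_, kss = NA_integer_,
    kss_mixed = NA_real_, latency_min = NA_real_, audio_ref = NA_character_,
    state_class = NA_character_
  )
  for (col in names(defaults)) {
    if (!col %in% names(samples)) samples[[col]] <- defaults[[col]]
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$speaker_id <- as.character(samples$speaker_id)
  samples$session_index <- as.integer(samples$session_index)
  samples$task <- as.character(samples$task)
  samples$duration_s <- as.numeric(samples$duration_s)
  samples$kss <- as.integer(samples$kss)
  samples$kss_mixed <- as.numeric(samples$kss_mixed)
  samples$latency_min <- as.numeric(samples$latency_min)
  samples$audio_ref <- as.character(samples$audio_ref)
  samples$state_class <- as.character(samples$state_class)
  dplyr::relocate(samples, dplyr::any_of(.sample_columns))
}

.format_violations <- function(v) {
  msgs <- paste0(v$entity, " ", v$id, ": ", v$message)
  utils::head(msgs, 10)
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf(
    "<corpus> %d speakers, %d samples, %d label rule(s)\n",
    nrow(x$speakers), nrow(x$samples), length(x$schema)
  ))
  if (length(x$schema)) {
    cat("  rules:", paste(names(x$schema), collapse = ", "), "\n")
  }
  dur <- sum(x$samples$duration_s, na.rm = TRUE)
  cat(sprintf("  total audio: %.1f s (%.2f h)\n", dur, dur / 3600))
  invisible(x)
}

#' Check a corpus against its type invariants
#'
#' Runs every structural rule (unique identifiers, resolvable speaker
#' references, field ranges, schema bounds on label columns) and returns the
#' violations as data rather than raising: an internally inconsistent corpus
#' is a finding to report, not a crash. An empty result means all invariants
#' hold.
#'
#' @param corpus a [corpus()] object (or a bare list with `speakers`,
#'   `samples`, `schema` elements, so that invalid objects can be examined).
#' @return A tibble with columns `entity` (`"speaker"`/`"sample"`/`"corpus"`),
#'   `id`, `field`, `rule` and `message`; zero rows iff the corpus is valid.
#' @export
validate_corpus <- function(corpus) {
  sp <- corpus$speakers
  sa <- corpus$samples
  out <- list()
  add <- function(entity, id, field, rule, message) {
    out[[length(out) + 1]] <<- tibble::tibble(
      entity = entity, id = as.character(id), field = field,
      rule = rule, message = message
    )
  }

  dup <- unique(sp$speaker_id[duplicated(sp$speaker_id)])
  for (d in dup) add("speaker", d, "speaker_id", "unique_id",
                     sprintf("duplicate speaker_id '%s'", d))
  dup <- unique(sa$sample_id[duplicated(sa$sample_id)])
  for (d in dup) add("sample", d, "sample_id", "unique_id",
                     sprintf("duplicate sample_id '%s'", d))

  dangling <- setdiff(sa$speaker_id, sp$speaker_id)
  for (d in dangling) add("sample", d, "speaker_id", "referential",
                          sprintf("speaker_id '%s' not in speakers table", d))

  bad <- sp$speaker_id[!is.na(sp$ess) & (sp$ess < 0 | sp$ess > 24)]
  for (d in bad) add("speaker", d, "ess", "range", "ess outside [0, 24]")
  bad <- sp$speaker_id[!is.na(sp$bmi) & sp$bmi <= 0]
  for (d in bad) add("speaker", d, "bmi", "range", "bmi must be positive")
  bad <- sp$speaker_id[!is.na(sp$age) & sp$age < 0]
  for (d in bad) add("speaker", d, "age", "range", "age must be nonnegative")
  bad <- sp$speaker_id[!is.na(sp$sex) & !sp$sex %in% c("M", "F")]
  for (d in bad) add("speaker", d, "sex", "category", "sex must be M or F")
  bad <- sp$speaker_id[!is.na(sp$trait_class) & !sp$trait_class %in% c("SL", "NSL")]
  for (d in bad) add("speaker", d, "trait_class", "category",
                     "trait_class must be SL or NSL")

  bad <- sa$sample_id[!is.na(sa$duration_s) & sa$duration_s <= 0]
  for (d in bad) add("sample", d, "duration_s", "range", "duration_s must be > 0")
  bad <- sa$sample_id[is.na(sa$duration_s)]
  for (d in bad) add("sample", d, "duration_s", "required", "duration_s is missing")
  bad <- sa$sample_id[!is.na(sa$session_index) & sa$session_index < 1]
  for (d in bad) add("sample", d, "session_index", "range", "session_index must be >= 1")
  bad <- sa$sample_id[!is.na(sa$state_class) & !sa$state_class %in% c("SL", "NSL")]
  for (d in bad) add("sample", d, "state_class", "category",
                     "state_class must be SL or NSL")

  # label columns checked against the schema rule that declares them; when
  # several rules share a column (e.g. both latency tests), the widest scale
  # applies so a value is not double-flagged
  widest_per_column <- function(get_col) {
    rules <- Filter(function(r) !is.na(get_col(r)), corpus$schema)
    if (!length(rules)) return(list())
    cols <- vapply(rules, get_col, character(1))
    lapply(split(rules, cols), function(group) {
      group[[which.max(vapply(group, function(r) r$scale[2], numeric(1)))]]
    })
  }
  checks <- c(
    lapply(widest_per_column(function(r) r$sample_column), function(r) {
      list(df = sa, col = r$sample_column, entity = "sample",
           idcol = "sample_id", rule = r)
    }),
    lapply(widest_per_column(function(r) r$speaker_column), function(r) {
      list(df = sp, col = r$speaker_column, entity = "speaker",
           idcol = "speaker_id", rule = r)
    })
  )
  for (tab in checks) {
    {
      r <- tab$rule
      col <- tab$col
      if (is.na(col) || !col %in% names(tab$df)) next
      v <- tab$df[[col]]
      ids <- tab$df[[tab$idcol]]
      bad <- ids[!is.na(v) & (v < r$scale[1] | v > r$scale[2])]
      for (d in bad) {
        add(tab$entity, d, col, "scale_bounds",
            sprintf("%s = %s outside scale [%g, %g] of rule '%s'",
                    col, format(v[ids == d][1]), r$scale[1], r$scale[2], r$name))
      }
      if (!is.na(r$l_max)) {
        bad <- ids[!is.na(v) & v > r$l_max + 1e-9]
        for (d in setdiff(bad, ids[!is.na(v) & (v < r$scale[1] | v > r$scale[2])])) {
          add(tab$entity, d, col, "saturation_bound",
              sprintf("%s exceeds L_max = %g of rule '%s'", col, r$l_max, r$name))
        }
      }
    }
  }

  if (length(out) == 0) {
    return(tibble::tibble(entity = character(), id = character(),
                          field = character(), rule = character(),
                          message = character()))
  }
  dplyr::bind_rows(out)
}
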