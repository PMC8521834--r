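#' Read a corpus manifest from disk
#'
#' A manifest is a directory holding `speakers.csv` and `samples.csv`
#' (UTF-8, comma-separated, header row, empty cell = missing) plus an
#' optional `schema.json` sidecar describing the label rules. Unknown columns
#' are preserved. When a sample has an `audio_ref` but no `duration_s`, the
#' duration is filled in from the WAV header.
#'
#' @param path manifest directory.
#' @param audio_root directory against which relative `audio_ref` paths are
#'   resolved; defaults to `path`.
#' @return A validated [corpus()].
#' @export
load_manifest <- function(path, audio_root = NULL) {
  if (!dir.exists(path)) {
    abort(sprintf("manifest directory '%s' does not exist", path),
          class = "somnaudit_io_error")
  }
  audio_root <- audio_root %||% path
  sp_path <- file.path(path, "speakers.csv")
  sa_path <- file.path(path, "samples.csv")
  for (p in c(sp_path, sa_path)) {
    if (!file.exists(p)) {
      abort(sprintf("manifest file '%s' is missing", p),
            class = "somnaudit_io_error")
    }
  }
  speakers <- readr::read_csv(sp_path, show_col_types = FALSE,
                              na = c("", "NA"), progress = FALSE)
  samples <- readr::read_csv(sa_path, show_col_types = FALSE,
                             na = c("", "NA"), progress = FALSE)
  if (!"speaker_id" %in% names(speakers)) {
    abort("speakers.csv lacks required column 'speaker_id'",
          class = "somnaudit_schema_error")
  }
  for (col in c("sample_id", "speaker_id")) {
    if (!col %in% names(samples)) {
      abort(sprintf("samples.csv lacks required column '%s'", col),
            class = "somnaudit_schema_error")
    }
  }
  if (!"duration_s" %in% names(samples)) samples$duration_s <- NA_real_

  schema_path <- file.path(path, "schema.json")
  schema <- if (file.exists(schema_path)) {
    .schema_from_json(schema_path)
  } else {
    builtin_rules()
  }
  prov_path <- file.path(path, "provenance.json")
  provenance <- if (file.exists(prov_path)) {
    jsonlite::read_json(prov_path, simplifyVector = TRUE)
  } else {
    list()
  }

  # fill missing durations from WAV headers
  need <- which(is.na(samples$duration_s) & !is.na(samples$audio_ref %||% NA))
  if ("audio_ref" %in% names(samples) && length(need)) {
    for (i in need) {
      wav <- samples$audio_ref[i]
      if (!file.exists(wav)) wav <- file.path(audio_root, samples$audio_ref[i])
      samples$duration_s[i] <- wav_duration(wav)
    }
  }

  corpus(speakers, samples, schema = schema, provenance = provenance)
}

#' Write a corpus manifest to disk
#'
#' Inverse of [load_manifest()]: emits `speakers.csv`, `samples.csv`,
#' `schema.json` and `provenance.json` into `path` (created if needed).
#' Missing values become empty cells, so the round trip is the identity on
#' every field including missing markers.
#'
#' @param corpus a [corpus()].
#' @param path target directory.
#' @return `path`, invisibly.
#' @export
save_manifest <- function(corpus, path) {
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(path, mode = 2) != 0) {
    abort(sprintf("cannot write to '%s'", path), class = "somnaudit_io_error")
  }
  readr::write_csv(corpus$speakers, file.path(path, "speakers.csv"), na = "")
  readr::write_csv(corpus$samples, file.path(path, "samples.csv"), na = "")
  jsonlite::write_json(.schema_to_list(corpus$schema),
                       file.path(path, "schema.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(corpus$provenance, file.path(path, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.schema_to_list <- function(schema) {
  lapply(unname(schema), function(r) {
    out <- list(name = r$name, label_name = r$label_name,
                threshold = r$threshold, direction = r$direction,
                scale = r$scale, l_max = r$l_max,
                sample_column = r$sample_column,
                speaker_column = r$speaker_column)
    Filter(function(v) !(length(v) == 1 && is.na(v)), out)
  })
}

.schema_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- lapply(raw, function(r) {
    binarization_rule(
      name = r$name, label_name = r$label_name, threshold = r$threshold,
      direction = r$direction, scale = unlist(r$scale),
      l_max = r$l_max %||% NA_real_,
      sample_column = r$sample_column %||% NA_character_,
      speaker_column = r$speaker_column %||% NA_character_
    )
  })
  names(rules) <- vapply(rules, `[[`, character(1), "name")
  rules
}
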