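# On-disk cohort schema: patient table CSV, long-format code CSV, one UTF-8
# text file per note with the day offset encoded in the filename, plus a
# manifest CSV. User-supplied real cohorts can be ingested from the same
# layout.

#' Write / read a cohort in the on-disk schema
#'
#' Layout under `dir`: `patients.csv` (patient_id, A, time_days, event,
#' researcher covariates), `codes.csv` (patient_id, code, domain),
#' `notes/<note_id>__day<offset>.txt` with `notes_manifest.csv`
#' (patient_id, note_id, day_offset, file), and `sim_config.json` when the
#' cohort was generated. Simulation truth is not serialized.
#'
#' @param cohort A `noteps_cohort`.
#' @param dir Output directory (created if missing).
#' @return `read_cohort()` returns a `noteps_cohort` (with `truth = NULL`);
#'   the writer returns `dir` invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "noteps_cohort"))
  dir.create(file.path(dir, "notes"), recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$patients, file.path(dir, "patients.csv"), row.names = FALSE)
  write.csv(cohort$codes, file.path(dir, "codes.csv"), row.names = FALSE)
  manifest <- cohort$notes
  manifest$file <- sprintf("notes/%s__day%d.txt", manifest$note_id,
                           manifest$day_offset)
  for (i in seq_len(nrow(manifest))) {
    writeLines(manifest$text[i], file.path(dir, manifest$file[i]),
               useBytes = TRUE)
  }
  write.csv(manifest[c("patient_id", "note_id", "day_offset", "file")],
            file.path(dir, "notes_manifest.csv"), row.names = FALSE)
  if (!is.null(cohort$config)) {
    cfg <- cohort$config
    cfg$code_loadings <- NULL
    cfg$note_topic_loadings <- NULL
    jsonlite::write_json(unclass(cfg), file.path(dir, "sim_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  patients <- as_tibble(read.csv(file.path(dir, "patients.csv"),
                                 stringsAsFactors = FALSE))
  patients$patient_id <- as.character(patients$patient_id)
  codes <- as_tibble(read.csv(file.path(dir, "codes.csv"),
                              stringsAsFactors = FALSE))
  codes$patient_id <- as.character(codes$patient_id)
  manifest_path <- file.path(dir, "notes_manifest.csv")
  if (file.exists(manifest_path)) {
    manifest <- as_tibble(read.csv(manifest_path, stringsAsFactors = FALSE))
    manifest$patient_id <- as.character(manifest$patient_id)
    manifest$text <- vapply(manifest$file, function(f) {
      paste(readLines(file.path(dir, f), warn = FALSE), collapse = "\n")
    }, "", USE.NAMES = FALSE)
    notes <- manifest[c("patient_id", "note_id", "day_offset", "text")]
  } else {
    notes <- tibble(patient_id = character(), note_id = character(),
                    day_offset = integer(), text = character())
  }
  if (any(notes$day_offset >= 0)) {
    abort("Note day offsets must be strictly negative (pre-index only).")
  }
  cfg_path <- file.path(dir, "sim_config.json")
  config <- if (file.exists(cfg_path)) {
    jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  }
  structure(
    list(patients = patients, codes = codes, notes = notes,
         truth = NULL, config = config),
    class = "noteps_cohort"
  )
}
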