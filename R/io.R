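# Session-log readers/writers and analysis reports.
#
# CSV dialect: comma-separated, mandatory header, UTF-8, one row per trial
# with columns subject_id, group, mapping_label, mapping_image (nine digits,
# row-major), trial_index, stimulus, action, correct (0/1). A JSON-lines
# mirror uses identical field names.

sessions_to_frame <- function(sessions) {
  do.call(rbind, lapply(sessions, function(s) {
    data.frame(subject_id = s$subject_id,
               group = s$group,
               mapping_label = s$mapping$label,
               mapping_image = paste(s$mapping$image, collapse = ""),
               trial_index = s$trials$index,
               stimulus = s$trials$stimulus,
               action = s$trials$action,
               correct = as.integer(s$trials$correct))
  }))
}

#' Write session logs
#'
#' @param sessions List of `sl_session` objects.
#' @param path Output file.
#' @param format `"csv"` (default) or `"jsonl"` (one JSON object per trial).
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  df <- sessions_to_frame(sessions)
  if (format == "csv") {
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(df)))
      writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read and validate session logs
#'
#' Reconstructs sessions from a CSV or JSON-lines log, applying the schema
#' and consistency checks: stimulus/action in 1..9, `mapping_image` a
#' permutation, and the stored correctness flag equal to
#' `action == image[stimulus]`. Violations are rejected with the offending
#' row number.
#'
#' @param path Input file.
#' @param format `"csv"` or `"jsonl"`; guessed from the extension by default.
#' @return List of `sl_session` objects (class `sl_cohort`).
#' @export
read_sessions <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  df <- if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(readLines(path), function(l)
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
  }
  need <- c("subject_id", "group", "mapping_label", "mapping_image",
            "trial_index", "stimulus", "action", "correct")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  bad <- which(!(df$stimulus %in% 1:9) | !(df$action %in% 1:9) |
                 !(df$correct %in% 0:1))
  if (length(bad))
    stop("invalid stimulus/action/correct at row ", bad[1L], call. = FALSE)
  key <- paste(df$subject_id, df$mapping_label, df$mapping_image)
  sessions <- lapply(split(seq_len(nrow(df)), factor(key, unique(key))),
                     function(rows) {
    rows <- rows[order(df$trial_index[rows])]
    d <- df[rows, ]
    image <- as.integer(strsplit(as.character(d$mapping_image[1L]), "")[[1L]])
    if (length(image) != 9L || !identical(sort(image), 1:9))
      stop("invalid mapping_image at row ", rows[1L], call. = FALSE)
    expect <- as.integer(d$action == image[d$stimulus])
    mism <- which(expect != d$correct)
    if (length(mism))
      stop("correctness flag inconsistent with mapping_image at row ",
           rows[mism[1L]], call. = FALSE)
    trials <- data.frame(index = seq_len(nrow(d)), stimulus = d$stimulus,
                         action = d$action, correct = d$correct == 1L)
    learned <- is_learned(trials)
    structure(list(subject_id = d$subject_id[1L],
                   group = as.integer(d$group[1L]),
                   mapping = sl_mapping(image, d$mapping_label[1L]),
                   trials = trials, learned = learned,
                   trials_to_criterion = if (learned) nrow(trials)
                                         else NA_integer_),
              class = "sl_session")
  })
  names(sessions) <- NULL
  structure(sessions, class = "sl_cohort")
}

#' Write analysis reports with a reproducibility manifest
#'
#' Writes each element of `results` (data frames or coercible) as a CSV named
#' after it, plus a JSON manifest recording the file list, the configuration,
#' its MD5 hash, and the seed, so a run can be reproduced from the manifest.
#'
#' @param results Named list of data frames (may be empty - then only the
#'   manifest is written, with a warning).
#' @param path Output directory (created if needed).
#' @param config Optional list describing the run (model, parameters).
#' @param seed Optional seed to record.
#' @return Paths of the written files, invisibly.
#' @export
report_results <- function(results, path, config = list(), seed = NULL) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  if (!length(results)) warning("empty results; writing manifest only")
  files <- character(0)
  for (nm in names(results)) {
    f <- file.path(path, paste0(nm, ".csv"))
    write.csv(as.data.frame(results[[nm]]), f, row.names = FALSE)
    files <- c(files, f)
  }
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(files = basename(files),
                   config = config,
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   seed = seed)
  mf <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  unlink(cfg_file)
  invisible(c(files, mf))
}
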