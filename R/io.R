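#' Read a landmark annotation file
#'
#' CSV files have header `name,x,y` with the 11 canonical landmark names;
#' JSON files carry the same records under `landmarks` plus an
#' `anterior_direction` field.  Every canonical name must appear exactly
#' once; offending names are reported.
#'
#' @param path File path (`.csv` or `.json`).
#' @param anterior Frame convention for CSV files, which do not carry one
#'   (ignored for JSON).
#' @return List with `landmarks` (a [landmark_set()]) and `frame`.
#' @export
read_landmarks <- function(path, anterior = "+x") {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$anterior_direction)) {
      abort("JSON annotation lacks `anterior_direction`")
    }
    frame <- frame_convention(obj$anterior_direction)
    df <- tibble::as_tibble(obj$landmarks)
  } else if (ext == "csv") {
    frame <- frame_convention(anterior)
    df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  } else {
    abort(paste0("unsupported annotation format: .", ext))
  }
  list(landmarks = landmark_set(df), frame = frame)
}

#' Write a landmark annotation file
#'
#' @param landmarks A [landmark_set()].
#' @param path Output path (`.csv` or `.json`).
#' @param frame A [frame_convention()]; stored in JSON output only.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path, frame = frame_convention()) {
  landmarks <- as_landmarks(landmarks)
  frame <- as_frame(frame)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(
      list(anterior_direction = frame$anterior,
           landmarks = as.data.frame(landmarks[, c("name", "x", "y")])),
      path, auto_unbox = TRUE, digits = NA
    )
  } else if (ext == "csv") {
    write.csv(as.data.frame(landmarks[, c("name", "x", "y")]), path,
              row.names = FALSE)
  } else {
    abort(paste0("unsupported annotation format: .", ext))
  }
  invisible(path)
}

#' Write a sagittal measurement report
#'
#' JSON output keeps full floating precision (machine-facing); CSV output
#' rounds angles to 2 decimals (human-facing, the precision clinical
#' reports print).
#'
#' @param report A [sagittal_report()] tibble.
#' @param path Output path (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  df <- as.data.frame(report)
  if (ext == "json") {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else if (ext == "csv") {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], round, digits = 2)
    write.csv(df, path, row.names = FALSE)
  } else {
    abort(paste0("unsupported report format: .", ext))
  }
  invisible(path)
}

#' Read a sagittal measurement report written by [write_report()]
#'
#' @param path Report path (`.csv` or `.json`).
#' @return Tibble with the report columns.
#' @export
read_report <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  }
  for (col in c("direct", "derived", "discrepancy")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  class(df) <- c("sagittal_report", class(df))
  df
}

run_config_keys <- function() {
  c("seed", "anterior", "output_dir", "log_level",
    "phantom", "cohort_n", "cascade", "training", "stats")
}

#' Read a run configuration file
#'
#' YAML configuration binding a full pipeline run: global seed, frame
#' convention, phantom/cohort parameters, cascade and training parameters,
#' statistics options and output directory.  Unknown keys are rejected;
#' the file round-trips losslessly through [write_run_config()].
#'
#' @param path YAML file path.
#' @return Named list of class `run_config` with defaults filled in.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), run_config_keys())
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  defaults <- list(seed = 1L, anterior = "+x", output_dir = ".",
                   log_level = "info", phantom = list(), cohort_n = 10L,
                   cascade = list(), training = list(), stats = list())
  cfg <- modifyList(defaults, raw)
  frame_convention(cfg$anterior)  # validates
  structure(cfg, class = "run_config")
}

#' Write a run configuration file
#'
#' @param config A `run_config` (or plain named list with valid keys).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  unknown <- setdiff(names(cfg), run_config_keys())
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

log_levels <- c(debug = 1, info = 2, warn = 3, error = 4)

#' Log a message to stderr
#'
#' Messages below the active level (`options(spinesag.log_level = ...)`,
#' default `"info"`) are suppressed.
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @param ... Message parts, pasted together.
#' @return Invisibly, whether the message was emitted.
#' @export
log_msg <- function(level, ...) {
  level <- match.arg(level, names(log_levels))
  active <- getOption("spinesag.log_level", "info")
  emitted <- log_levels[[level]] >= log_levels[[active]]
  if (emitted) {
    cat(sprintf("[%s] %s %s\n", toupper(level),
                format(Sys.time(), "%H:%M:%S"), paste0(..., collapse = " ")),
        file = stderr())
  }
  invisible(emitted)
}
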