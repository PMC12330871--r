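# File formats: cohort CSV (with a column-mapping layer for externally
# deposited exports), block JSONL, session-log CSV, and config round-trip.

COHORT_COLUMNS <- c("participant_id", "session", "time_of_day", "std_ms",
                    "n_blocks", "sleep_hours", "n_wakeups",
                    "sleep_quality", "kss", "vasf")
COHORT_REQUIRED <- c("participant_id", "session", "std_ms")

#' Write a cohort table as CSV
#'
#' One row per participant x session. A `# schema_version: <v>` comment
#' line precedes the header.
#'
#' @param cohort A `tload_cohort` (or compatible data.frame).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_cohort_csv <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# schema_version: %d",
                     attr(cohort, "schema_version") %||%
                       COHORT_SCHEMA_VERSION), con)
  utils::write.csv(as.data.frame(cohort), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Accepts the package's own schema directly; externally produced exports
#' with different column names are handled through `mapping`, a named
#' character vector `c(our_name = "their_name", ...)`. Rows violating the
#' table invariants (STD off the staircase grid or non-numeric, session
#' outside 1-3, KSS outside 1-9) are dropped with a message and counted in
#' the `dropped_rows` attribute.
#'
#' @param path CSV file path; lines starting with `#` are ignored.
#' @param mapping Optional named character vector renaming source columns.
#' @param config A [task_config()] supplying the STD grid for validation.
#' @return A `tload_cohort` data.frame.
#' @export
read_cohort_csv <- function(path, mapping = NULL, config = task_config()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (ours in names(mapping)) {
      theirs <- mapping[[ours]]
      if (theirs %in% names(raw)) {
        names(raw)[names(raw) == theirs] <- ours
      }
    }
  }
  missing <- setdiff(COHORT_REQUIRED, names(raw))
  if (length(missing)) {
    stop("cohort CSV lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- raw[intersect(COHORT_COLUMNS, names(raw))]

  std <- suppressWarnings(as.numeric(raw$std_ms))
  sess <- suppressWarnings(as.integer(raw$session))
  bad <- is.na(std) | !on_grid(std, config$std_step_ms) |
    is.na(sess) | !sess %in% 1:3
  if ("kss" %in% names(raw)) {
    kss <- suppressWarnings(as.numeric(raw$kss))
    bad <- bad | (!is.na(kss) & (kss < 1 | kss > 9))
  }
  if (any(bad)) {
    message(sum(bad), " row(s) dropped for invariant violations")
    raw <- raw[!bad, , drop = FALSE]
    std <- std[!bad]; sess <- sess[!bad]
  }
  raw$std_ms <- as.integer(std)
  raw$session <- sess
  for (col in c("n_blocks", "n_wakeups", "sleep_quality", "kss")) {
    if (col %in% names(raw)) raw[[col]] <- as.integer(raw[[col]])
  }
  rownames(raw) <- NULL
  attr(raw, "dropped_rows") <- sum(bad)
  attr(raw, "schema_version") <- COHORT_SCHEMA_VERSION
  class(raw) <- c("tload_cohort", "data.frame")
  raw
}

#' Serialize a block as JSON lines
#'
#' One item per line with fields index, kind, symbol, is_repeat_target,
#' parity; a first header line carries std_ms, phase and the schema
#' version.
#'
#' @param block A `tload_block`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_block_jsonl <- function(block, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(
    list(schema_version = COHORT_SCHEMA_VERSION, std_ms = block$std_ms,
         phase = block$phase), auto_unbox = TRUE), con)
  for (i in seq_along(block$index)) {
    writeLines(jsonlite::toJSON(
      list(index = block$index[i], kind = block$kind[i],
           symbol = block$symbol[i],
           is_repeat_target = block$is_repeat_target[i],
           parity = block$parity[i]),
      auto_unbox = TRUE, null = "null", na = "null"), con)
  }
  invisible(path)
}

#' Read a block from JSON lines
#'
#' @param path A file written by [write_block_jsonl()].
#' @return A `tload_block`.
#' @export
read_block_jsonl <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  items <- lapply(lines[-1], jsonlite::fromJSON)
  get_chr <- function(f) vapply(items, function(x)
    if (is.null(x[[f]]) || is.na(x[[f]] %||% NA)) NA_character_ else
      as.character(x[[f]]), "")
  kind <- get_chr("kind")
  is_target <- vapply(items, function(x) {
    v <- x$is_repeat_target
    if (is.null(v)) NA else as.logical(v)
  }, NA)
  new_block(kind, get_chr("symbol"), is_target, get_chr("parity"),
            as.numeric(header$std_ms), header$phase)
}

#' Export a calibration trajectory as a session-log data.frame
#'
#' @param result A `tload_calib_result`.
#' @return The trajectory data.frame (block_no, std_ms, letter/number
#'   accuracies, composite, passed, phase).
#' @export
session_log <- function(result) {
  stopifnot(inherits(result, "tload_calib_result"))
  result$trajectory
}

#' Save / load a run configuration
#'
#' A [task_config()] plus optional [cohort_design()] overrides serialized
#' as JSON; `load(save(config)) == config`.
#'
#' @param config A `tload_config`.
#' @param path File path.
#' @return `write_config`: invisibly the path; `read_config`: the
#'   `tload_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "tload_config"))
  jsonlite::write_json(
    c(list(schema_version = COHORT_SCHEMA_VERSION), unclass(config)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- jsonlite::fromJSON(path)
  vals$schema_version <- NULL
  do.call(task_config, vals)
}
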