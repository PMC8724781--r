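# Text formats: recordings as self-describing TSV (a '#'-prefixed key=value
# header block followed by one row per sample), feature tables and truth
# tables as plain CSV. All round-trips are lossless at double precision.

required_header_keys <- c("sampling_rate_hz", "infusion_rate_ml_min",
                          "channels", "units")

#' Write a recording to a self-describing TSV file
#'
#' The file starts with a `#`-prefixed `key=value` header block
#' (`sampling_rate_hz`, `infusion_rate_ml_min`, `channels`, `units`,
#' `animal_id`, `session_id`), then a column-name line and one row per
#' sample. Sample times are implicit (`(i-1)/rate`, zero-based).
#'
#' @param rec a [stuc_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "stuc_recording"))
  hdr <- c(
    sprintf("#sampling_rate_hz=%.15g", rec$sampling_rate),
    sprintf("#infusion_rate_ml_min=%.15g", rec$metadata$infusion_rate),
    sprintf("#animal_id=%s", rec$metadata$animal_id),
    sprintf("#session_id=%s", rec$metadata$session_id),
    "#channels=pressure,emg",
    "#units=mmHg,mV",
    "pressure\temg"
  )
  writeLines(hdr, path)
  data.table::fwrite(data.table::data.table(p = rec$pressure, e = rec$emg),
                     path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' Parses the header block and both channels at full precision. Unknown
#' header keys are preserved in the metadata notes. Malformed files (missing
#' required keys, non-numeric samples, ragged rows) raise errors naming the
#' offending key or line.
#'
#' @param path file to read.
#' @return A [stuc_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- character(0)
  nskip <- 0L
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) break
    if (!startsWith(line, "#")) break
    hdr <- c(hdr, sub("^#", "", line))
    nskip <- nskip + 1L
  }
  kv <- strsplit(hdr, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  missing_keys <- setdiff(required_header_keys, keys)
  if (length(missing_keys) > 0) {
    stop("missing required header key(s): ", paste(missing_keys, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  get <- function(k, default = NA) if (k %in% keys) vals[match(k, keys)] else default
  rate <- as.numeric(get("sampling_rate_hz"))
  infusion <- as.numeric(get("infusion_rate_ml_min"))
  if (!is.finite(rate) || !is.finite(infusion)) {
    stop("non-numeric sampling_rate_hz or infusion_rate_ml_min header in ",
         path, call. = FALSE)
  }
  channels <- strsplit(get("channels"), ",", fixed = TRUE)[[1]]
  extra <- setdiff(keys, c(required_header_keys, "animal_id", "session_id"))
  notes <- if (length(extra) > 0) {
    paste(sprintf("%s=%s", extra, vals[match(extra, keys)]), collapse = "; ")
  } else ""

  dt <- data.table::fread(path, sep = "\t", skip = nskip, header = TRUE,
                          colClasses = "character", data.table = FALSE,
                          fill = TRUE)
  if (!identical(names(dt), channels)) {
    stop("column names ", paste(names(dt), collapse = ","),
         " do not match declared channels ", paste(channels, collapse = ","),
         " in ", path, call. = FALSE)
  }
  parse_channel <- function(col, name) {
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop("non-numeric or missing '", name, "' sample at data line ",
           bad[1], " (file line ", bad[1] + nskip + 1L, ") in ", path,
           call. = FALSE)
    }
    v
  }
  pressure <- parse_channel(dt[[1]], channels[1])
  emg <- parse_channel(dt[[2]], channels[2])
  stuc_recording(pressure, emg, rate,
                 animal_id = get("animal_id", "unknown"),
                 session_id = get("session_id", NA),
                 infusion_rate = infusion, notes = notes)
}

#' Write / read a long-format session feature table
#'
#' The table has one row per (animal, session, event, feature) with a fixed
#' column order `animal_id, session_id, event_index, feature, value`.
#' Round-trips are lossless; duplicate keys on read raise an integrity
#' error.
#'
#' @param table data.frame with the five columns above.
#' @param path CSV file.
#' @return `write_feature_table()`: `path` invisibly;
#'   `read_feature_table()`: the data.frame.
#' @export
write_feature_table <- function(table, path) {
  cols <- c("animal_id", "session_id", "event_index", "feature", "value")
  if (!all(cols %in% names(table))) {
    stop("feature table must have columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  table <- table[cols]
  if (nrow(table) > 0) validate_feature_table(table)
  data.table::fwrite(table, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- data.table::fread(path, data.table = FALSE)
  cols <- c("animal_id", "session_id", "event_index", "feature", "value")
  if (!identical(names(df), cols)) {
    stop("unexpected feature-table columns in ", path, ": ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  if (nrow(df) > 0) {
    df$animal_id <- as.character(df$animal_id)
    validate_feature_table(df)
  }
  df
}

validate_feature_table <- function(df) {
  key <- paste(df$animal_id, df$session_id, df$event_index, df$feature)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicate (animal, session, event, feature) key: ", key[dup[1]],
         call. = FALSE)
  }
  if (any(!is.finite(df$value))) {
    stop("non-finite feature values in table", call. = FALSE)
  }
  invisible(df)
}
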