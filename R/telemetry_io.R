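#' @title Tabular input/output for the telemetry pipeline
#' @description Readers and writers for the pipeline's CSV formats:
#'   raw detections, tag deployments, and any of the derived result tables.
#'   All timestamps are ISO-8601 UTC; the dialect is fixed (comma separator,
#'   header required, `.` decimal) so that stage outputs round-trip
#'   losslessly and runs are reproducible.
#' @name telemetry_io
NULL

TIME_FORMAT <- "%Y-%m-%dT%H:%M:%SZ"

parse_utc <- function(x) {
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"))
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  out
}

format_utc <- function(x) format(x, TIME_FORMAT, tz = "UTC")

SPECIES_LEVELS <- c("sockeye", "steelhead")
ORIGIN_LEVELS <- c("H", "W", "H/W")
TAG_MODELS <- c("V7", "V9")

#' Read raw detection records
#'
#' Expects a comma-separated file with header columns `timestamp`
#' (ISO-8601 UTC), `tag_id`, `array`, and `receiver` (1-based index).
#' Each receiver index is validated against the geometry of the named
#' array. Rows are returned sorted by `(tag_id, timestamp)`.
#'
#' @param path Path to the CSV file.
#' @param geometries Named list of [receiver_array_geometry()] objects,
#'   one per array label appearing in the file. Defaults to
#'   [default_array_set()].
#' @param strict If `TRUE` (default) any malformed row aborts with a
#'   row-numbered error; if `FALSE` malformed rows are dropped and reported
#'   in the `"row_errors"` attribute (a data.frame of `row`, `message`), so
#'   that `n(input rows) == n(parsed) + n(reported errors)`.
#' @return A data.frame with columns `tag_id`, `array`, `receiver_index`,
#'   `timestamp` (POSIXct, UTC).
#' @export
read_detections <- function(path, geometries = default_array_set(),
                            strict = TRUE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("timestamp", "tag_id", "array", "receiver")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("detections file missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  n <- nrow(raw)
  if (n == 0) {
    out <- data.frame(tag_id = character(0), array = character(0),
                      receiver_index = integer(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"))
    attr(out, "row_errors") <- data.frame(row = integer(0),
                                          message = character(0))
    return(out)
  }
  ts <- suppressWarnings(parse_utc(raw$timestamp))
  rec <- suppressWarnings(as.integer(raw$receiver))
  err <- character(n)
  bad_ts <- is.na(ts)
  err[bad_ts] <- paste0("unparseable timestamp '", raw$timestamp[bad_ts], "'")
  bad_arr <- !(raw$array %in% names(geometries))
  err[bad_arr & err == ""] <- paste0("unknown array '", raw$array[bad_arr & err == ""], "'")
  nrec <- vapply(geometries, function(g) g$n_receivers, integer(1))
  limit <- nrec[raw$array]
  bad_rec <- is.na(rec) | rec < 1L | (!is.na(limit) & rec > limit)
  err[bad_rec & err == ""] <-
    paste0("receiver '", raw$receiver[bad_rec & err == ""],
           "' invalid for array '", raw$array[bad_rec & err == ""], "'")
  bad <- err != ""
  if (any(bad)) {
    msgs <- paste0("row ", which(bad), ": ", err[bad])
    if (strict) {
      shown <- utils::head(msgs, 10L)
      stop("malformed detection rows:\n  ",
           paste(shown, collapse = "\n  "),
           if (length(msgs) > 10L) sprintf("\n  ... and %d more", length(msgs) - 10L),
           call. = FALSE)
    }
    warning(sum(bad), " malformed detection row(s) dropped", call. = FALSE)
  }
  keep <- !bad
  out <- data.frame(tag_id = raw$tag_id[keep], array = raw$array[keep],
                    receiver_index = rec[keep], timestamp = ts[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$tag_id, out$timestamp, out$receiver_index), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "row_errors") <- data.frame(row = which(bad), message = err[bad],
                                        stringsAsFactors = FALSE)
  out
}

#' Read tag-deployment metadata
#'
#' One row per tagged smolt: `tag_id`, `species` (`sockeye`/`steelhead`),
#' `population`, `origin` (`H`, `W`, `H/W`), `fork_length_mm`,
#' `release_date` (ISO date), `release_year`, `tag_model` (`V7`/`V9`).
#'
#' @param path Path to the CSV file.
#' @return A data.frame, one record per unique `tag_id`.
#' @export
read_deployments <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("tag_id", "species", "population", "origin",
                "fork_length_mm", "release_date", "release_year", "tag_model")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("deployments file missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  dup <- d$tag_id[duplicated(d$tag_id)]
  if (length(dup))
    stop("duplicate tag_id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad_sp <- !(d$species %in% SPECIES_LEVELS)
  if (any(bad_sp))
    stop("unknown species token(s): ",
         paste(unique(d$species[bad_sp]), collapse = ", "), call. = FALSE)
  bad_tm <- !(d$tag_model %in% TAG_MODELS)
  if (any(bad_tm))
    stop("unknown tag_model token(s): ",
         paste(unique(d$tag_model[bad_tm]), collapse = ", "), call. = FALSE)
  bad_or <- !(d$origin %in% ORIGIN_LEVELS)
  if (any(bad_or))
    stop("unknown origin token(s): ",
         paste(unique(d$origin[bad_or]), collapse = ", "), call. = FALSE)
  d$fork_length_mm <- as.numeric(d$fork_length_mm)
  if (anyNA(d$fork_length_mm) || any(d$fork_length_mm <= 0))
    stop("fork_length_mm must be positive for every record", call. = FALSE)
  d$release_date <- as.Date(d$release_date)
  if (anyNA(d$release_date))
    stop("unparseable release_date", call. = FALSE)
  d$release_year <- as.integer(d$release_year)
  d
}

#' Write a pipeline result table to CSV
#'
#' Serialises POSIXct columns as ISO-8601 UTC and Dates as ISO dates so
#' that [read_pipeline_table()] round-trips losslessly; numeric values keep
#' R's full `as.character()` precision (>= 15 significant digits).
#'
#' @param records A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  out <- records
  for (nm in names(out)) {
    if (inherits(out[[nm]], "POSIXct")) out[[nm]] <- format_utc(out[[nm]])
    else if (inherits(out[[nm]], "Date")) out[[nm]] <- format(out[[nm]], "%Y-%m-%d")
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("cannot write table to '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  invisible(path)
}

#' Read back a pipeline result table
#'
#' Columns named `timestamp` or ending in `_time` are parsed as POSIXct
#' (UTC); columns named or ending in `date` are parsed as Dates.
#'
#' @param path Path to a CSV written by [write_table()].
#' @return A data.frame.
#' @export
read_pipeline_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in names(d)) {
    if (nm == "timestamp" || grepl("_time$", nm)) {
      d[[nm]] <- parse_utc(d[[nm]])
    } else if (grepl("(^|_)date$", nm)) {
      d[[nm]] <- as.Date(d[[nm]])
    }
  }
  d
}

#' Default array set for the study region
#'
#' The NSOG curtain plus gap-free downstream (QCS) and westward-exit (JDF)
#' lines used only for presence/absence.
#'
#' @param gap_mode Passed to [nsog_geometry()].
#' @return Named list of geometries.
#' @export
default_array_set <- function(gap_mode = "add") {
  list(
    NSOG = nsog_geometry(gap_mode = gap_mode),
    QCS = simple_line_geometry("QCS", n_receivers = 20L, spacing_km = 1.0),
    JDF = simple_line_geometry("JDF", n_receivers = 10L, spacing_km = 1.0)
  )
}
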