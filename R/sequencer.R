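#' Collapse one tag's detections at one array into detection sequences
#'
#' A detection sequence is a maximal run of consecutive detections of a
#' single tag at a single array in which (1) consecutive detections are
#' less than `max_gap_hours` apart and (2) consecutive detections lie
#' within `max_step_km` of each other along the curtain (chainage
#' distance). A new sequence therefore starts whenever the time gap is
#' `>= max_gap_hours` (a gap of exactly one hour breaks) or the step
#' exceeds `max_step_km` (a step of exactly 1.6 km retains). Because the
#' step rule is measured in km, receivers on opposite sides of the
#' oversized island gap always break a sequence even though their index
#' difference is 1; `step_mode = "index"` offers the index-difference
#' alternative (<= 2 indices retains).
#'
#' @param detections Data.frame with columns `tag_id`, `array`,
#'   `receiver_index`, `timestamp` (POSIXct), already sorted by time, all
#'   rows one tag at one array.
#' @param geom The array's [receiver_array_geometry()].
#' @param max_gap_hours Time rule threshold (default 1 hour).
#' @param max_step_km Distance rule threshold (default 1.6 km, two
#'   receiver spacings).
#' @param step_mode `"km"` (default; chainage distance) or `"index"`
#'   (absolute index difference <= 2 retains).
#' @return Data.frame of sequences: `tag_id`, `array`, `ordinal`,
#'   `first_time`, `first_receiver`, `last_time`, `last_receiver`,
#'   `n_detections`.
#' @export
build_sequences <- function(detections, geom, max_gap_hours = 1.0,
                            max_step_km = 1.6,
                            step_mode = c("km", "index")) {
  step_mode <- match.arg(step_mode)
  if (nrow(detections) == 0) return(empty_sequences())
  if (length(unique(detections$tag_id)) > 1L)
    stop("build_sequences: detections mix multiple tags", call. = FALSE)
  if (length(unique(detections$array)) > 1L)
    stop("build_sequences: detections mix multiple arrays", call. = FALSE)
  if (is.unsorted(detections$timestamp))
    stop("build_sequences: detections must be sorted by time", call. = FALSE)
  breaks <- sequence_breaks(detections$timestamp, detections$receiver_index,
                            geom, max_gap_hours, max_step_km, step_mode)
  seq_id <- cumsum(c(TRUE, breaks))
  first <- which(c(TRUE, breaks))
  last <- c(first[-1] - 1L, nrow(detections))
  data.frame(
    tag_id = detections$tag_id[first],
    array = detections$array[first],
    ordinal = seq_along(first),
    first_time = detections$timestamp[first],
    first_receiver = detections$receiver_index[first],
    last_time = detections$timestamp[last],
    last_receiver = detections$receiver_index[last],
    n_detections = as.integer(tabulate(seq_id)),
    stringsAsFactors = FALSE
  )
}

empty_sequences <- function() {
  data.frame(tag_id = character(0), array = character(0),
             ordinal = integer(0),
             first_time = as.POSIXct(character(0), tz = "UTC"),
             first_receiver = integer(0),
             last_time = as.POSIXct(character(0), tz = "UTC"),
             last_receiver = integer(0), n_detections = integer(0),
             stringsAsFactors = FALSE)
}

# TRUE at position i (of n-1) when detections i and i+1 must be split.
sequence_breaks <- function(times, receivers, geom, max_gap_hours,
                            max_step_km, step_mode) {
  n <- length(times)
  if (n < 2L) return(logical(0))
  gap_h <- as.numeric(difftime(times[-1], times[-n], units = "hours"))
  if (step_mode == "km") {
    ch <- receiver_chainage(geom, receivers)
    step_ok <- abs(diff(ch)) <= max_step_km
  } else {
    step_ok <- abs(diff(receivers)) <= 2L
  }
  (gap_h >= max_gap_hours) | !step_ok
}

#' Build detection sequences for every tag and array in a detection table
#'
#' Orders detections by `(tag_id, array, timestamp)` — ties in timestamp
#' are broken by ascending receiver index for deterministic output — then
#' applies [build_sequences()] within each tag/array group. Ordinals rank a
#' tag's sequences at each array by start time.
#'
#' @param detections Data.frame as returned by [read_detections()]
#'   (any mix of tags and arrays).
#' @param geometries Named list of geometries ([default_array_set()]).
#' @inheritParams build_sequences
#' @return Combined sequence data.frame (see [build_sequences()]).
#' @export
sequence_detections <- function(detections, geometries = default_array_set(),
                                max_gap_hours = 1.0, max_step_km = 1.6,
                                step_mode = c("km", "index")) {
  step_mode <- match.arg(step_mode)
  if (nrow(detections) == 0) return(empty_sequences())
  unknown <- setdiff(unique(detections$array), names(geometries))
  if (length(unknown))
    stop("no geometry supplied for array(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  o <- order(detections$tag_id, detections$array, detections$timestamp,
             detections$receiver_index)
  d <- detections[o, , drop = FALSE]
  key <- paste(d$tag_id, d$array, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(d)), key), function(idx) {
    g <- d[idx, , drop = FALSE]
    build_sequences(g, geometries[[g$array[1]]], max_gap_hours,
                    max_step_km, step_mode)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$tag_id, out$array, out$ordinal), , drop = FALSE]
}

#' Within-sequence east-west drift
#'
#' Signed displacement (km, east positive) between the first and last
#' detection of each sequence: [delta_x()] from the first to the last
#' receiver, so a fish ending its sequence further west scores negative.
#' Applied to the initial sequence this measures whether a smolt crossed
#' the curtain perpendicularly or at an east/west angle.
#'
#' @param sequences Sequence data.frame from [build_sequences()].
#' @param geom The array's geometry.
#' @return Numeric vector of signed km, one per sequence.
#' @export
within_sequence_drift <- function(sequences, geom) {
  if (nrow(sequences) == 0) return(numeric(0))
  delta_x(geom, sequences$first_receiver, sequences$last_receiver)
}
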