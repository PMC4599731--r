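#' Receiver-curtain geometry
#'
#' Describes a line ("curtain") of acoustic receivers spanning a strait.
#' Receiver indices are 1-based and increase from the easternmost receiver
#' (index 1, mainland / Malaspina side) to the westernmost receiver
#' (index `n_receivers`). Consecutive receivers are `spacing_km` apart
#' except for one oversized gap of `gap_km` (an island blocking the line;
#' Texada Island in the default layout) between `gap_after_index` and
#' `gap_after_index + 1`. Receivers whose index falls in
#' `malaspina_indices` lie in the eastern channel (Malaspina Strait); the
#' remainder lie in the Strait of Georgia proper.
#'
#' Arrays without an internal gap (e.g. a downstream exit curtain used only
#' for presence/absence) are described with `gap_after_index = NA`.
#'
#' @param array_name Label for the array (e.g. `"NSOG"`).
#' @param n_receivers Number of receivers in the line.
#' @param spacing_km Distance in km between consecutive receivers.
#' @param gap_after_index Index of the receiver immediately east of the
#'   oversized gap, or `NA` for a gap-free line.
#' @param gap_km Width in km of the oversized gap.
#' @param malaspina_indices Integer vector of indices lying in the eastern
#'   channel (may be empty).
#' @param gap_mode How the oversized gap enters signed displacements
#'   ([delta_x()]): `"add"` (default) adds `gap_km` to the
#'   `spacing_km * |index difference|` magnitude for gap-spanning pairs;
#'   `"replace"` instead substitutes `gap_km` for the single inter-receiver
#'   step at the gap (matching physical chainage).
#' @return An object of class `receiver_array_geometry`.
#' @seealso [nsog_geometry()], [receiver_chainage()], [strait_of()], [delta_x()]
#' @export
receiver_array_geometry <- function(array_name,
                                    n_receivers,
                                    spacing_km = 0.8,
                                    gap_after_index = NA,
                                    gap_km = 8.0,
                                    malaspina_indices = integer(0),
                                    gap_mode = c("add", "replace")) {
  gap_mode <- match.arg(gap_mode)
  n_receivers <- as.integer(n_receivers)
  if (is.na(n_receivers) || n_receivers < 1)
    stop("n_receivers must be a positive integer", call. = FALSE)
  if (!is.numeric(spacing_km) || spacing_km <= 0)
    stop("spacing_km must be positive", call. = FALSE)
  if (!is.na(gap_after_index)) {
    gap_after_index <- as.integer(gap_after_index)
    if (gap_after_index < 1 || gap_after_index >= n_receivers)
      stop("gap_after_index must lie strictly inside the array", call. = FALSE)
    if (!is.numeric(gap_km) || gap_km <= spacing_km)
      stop("gap_km must exceed spacing_km (the gap is oversized)", call. = FALSE)
  }
  malaspina_indices <- as.integer(malaspina_indices)
  if (length(malaspina_indices) &&
      (any(malaspina_indices < 1) || any(malaspina_indices > n_receivers)))
    stop("malaspina_indices out of receiver range", call. = FALSE)
  structure(
    list(
      array_name = as.character(array_name),
      n_receivers = n_receivers,
      spacing_km = spacing_km,
      gap_after_index = if (is.na(gap_after_index)) NA_integer_ else gap_after_index,
      gap_km = gap_km,
      malaspina_indices = sort(unique(malaspina_indices)),
      gap_mode = gap_mode
    ),
    class = "receiver_array_geometry"
  )
}

#' @export
print.receiver_array_geometry <- function(x, ...) {
  cat("Receiver array geometry: ", x$array_name, "\n", sep = "")
  cat("  receivers: 1..", x$n_receivers,
      " (east -> west), spacing ", x$spacing_km, " km\n", sep = "")
  if (!is.na(x$gap_after_index))
    cat("  oversized gap: ", x$gap_km, " km between receivers ",
        x$gap_after_index, " and ", x$gap_after_index + 1L,
        " (delta-x gap mode: ", x$gap_mode, ")\n", sep = "")
  if (length(x$malaspina_indices))
    cat("  eastern channel (Malaspina) indices: ",
        paste(range(x$malaspina_indices), collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Default northern Strait of Georgia (NSOG) receiver curtain
#'
#' 27 receivers at 0.8 km spacing with the ~8 km Texada Island gap between
#' receivers 7 and 8; receivers 1-7 span Malaspina Strait.
#'
#' @inheritParams receiver_array_geometry
#' @return A `receiver_array_geometry`.
#' @export
nsog_geometry <- function(gap_mode = c("add", "replace")) {
  receiver_array_geometry(
    array_name = "NSOG", n_receivers = 27L, spacing_km = 0.8,
    gap_after_index = 7L, gap_km = 8.0, malaspina_indices = 1:7,
    gap_mode = match.arg(gap_mode)
  )
}

#' Simple gap-free receiver line
#'
#' Convenience constructor for auxiliary arrays (downstream exit curtain,
#' westward-exit curtain) where only presence/absence is analysed.
#'
#' @inheritParams receiver_array_geometry
#' @return A `receiver_array_geometry` without an internal gap.
#' @export
simple_line_geometry <- function(array_name, n_receivers = 10L, spacing_km = 1.0) {
  receiver_array_geometry(array_name, n_receivers, spacing_km)
}

#' Read a receiver geometry from a YAML config file
#'
#' Keys: `array_name`, `n_receivers`, `spacing_km`, `gap_after_index`,
#' `gap_km`, `malaspina_indices` (vector or `first-last` string), and
#' optionally `gap_mode`. A bundled default reproducing the NSOG layout
#' ships as `system.file("extdata", "nsog_geometry.yaml", package = "smoltroutes")`.
#'
#' @param path Path to the YAML file.
#' @return A `receiver_array_geometry`.
#' @export
read_geometry <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("array_name", "n_receivers", "spacing_km")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("geometry config missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  mal <- cfg$malaspina_indices
  if (is.character(mal) && length(mal) == 1 && grepl("-", mal, fixed = TRUE)) {
    parts <- as.integer(strsplit(mal, "-", fixed = TRUE)[[1]])
    mal <- seq.int(parts[1], parts[2])
  }
  receiver_array_geometry(
    array_name = cfg$array_name,
    n_receivers = cfg$n_receivers,
    spacing_km = cfg$spacing_km,
    gap_after_index = if (is.null(cfg$gap_after_index)) NA else cfg$gap_after_index,
    gap_km = if (is.null(cfg$gap_km)) 8.0 else cfg$gap_km,
    malaspina_indices = if (is.null(mal)) integer(0) else mal,
    gap_mode = if (is.null(cfg$gap_mode)) "add" else cfg$gap_mode
  )
}

check_receiver_index <- function(geom, index, what = "receiver index") {
  if (length(index) == 0 || anyNA(index) ||
      any(index != as.integer(index)) ||
      any(index < 1L) || any(index > geom$n_receivers))
    stop(what, " out of range 1..", geom$n_receivers, call. = FALSE)
  as.integer(index)
}

#' Distance along the curtain from receiver 1
#'
#' Chainage increases westward: receiver 1 is at 0 km and consecutive
#' receivers differ by `spacing_km`, except across the oversized gap where
#' they differ by `gap_km`. Used by the sequencer's inter-receiver distance
#' rule and by the simulator; signed analytical displacement between
#' sequences uses [delta_x()] instead.
#'
#' @param geom A [receiver_array_geometry()].
#' @param index Receiver index (vectorised).
#' @return Distance(s) in km from receiver 1.
#' @export
receiver_chainage <- function(geom, index) {
  index <- check_receiver_index(geom, index)
  out <- (index - 1L) * geom$spacing_km
  if (!is.na(geom$gap_after_index)) {
    beyond <- index > geom$gap_after_index
    out[beyond] <- out[beyond] + (geom$gap_km - geom$spacing_km)
  }
  out
}

#' Strait membership of a receiver
#'
#' @inheritParams receiver_chainage
#' @return Character vector, `"MALASPINA"` for indices in the eastern
#'   channel, `"SOG"` otherwise.
#' @export
strait_of <- function(geom, index) {
  index <- check_receiver_index(geom, index)
  ifelse(index %in% geom$malaspina_indices, "MALASPINA", "SOG")
}

#' Signed east-west displacement between two receivers
#'
#' East is positive and west negative; since indices increase westward,
#' movement towards a larger index is westward (negative). The magnitude is
#' `spacing_km * |index difference|`; for pairs spanning the oversized gap
#' the gap width enters according to the geometry's `gap_mode`: `"add"`
#' (default) adds `gap_km` to the magnitude, `"replace"` substitutes
#' `gap_km` for the single step across the gap.
#'
#' @param geom A [receiver_array_geometry()].
#' @param from_index,to_index Receiver indices (vectorised, recycled).
#' @return Signed displacement(s) in km, east positive.
#' @export
delta_x <- function(geom, from_index, to_index) {
  from_index <- check_receiver_index(geom, from_index, "from_index")
  to_index <- check_receiver_index(geom, to_index, "to_index")
  di <- abs(from_index - to_index)
  mag <- geom$spacing_km * di
  if (!is.na(geom$gap_after_index)) {
    spans <- (pmin(from_index, to_index) <= geom$gap_after_index) &
      (pmax(from_index, to_index) > geom$gap_after_index)
    if (geom$gap_mode == "add") {
      mag <- mag + geom$gap_km * spans
    } else {
      mag <- mag + (geom$gap_km - geom$spacing_km) * spans
    }
  }
  sign(from_index - to_index) * mag
}

#' Does a receiver pair span the oversized (Texada) gap?
#'
#' @inheritParams delta_x
#' @return Logical vector.
#' @export
spans_gap <- function(geom, from_index, to_index) {
  from_index <- check_receiver_index(geom, from_index, "from_index")
  to_index <- check_receiver_index(geom, to_index, "to_index")
  if (is.na(geom$gap_after_index)) return(rep(FALSE, length(from_index)))
  (pmin(from_index, to_index) <= geom$gap_after_index) &
    (pmax(from_index, to_index) > geom$gap_after_index)
}
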