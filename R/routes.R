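ROUTE_LEVELS <- c("LINEAR", "COUNTERCLOCKWISE", "CLOCKWISE",
                  "UNCLASSIFIED", "JUAN_DE_FUCA")

#' Classify one smolt's migration route
#'
#' With two or more detection sequences at the entry curtain, the last
#' receiver of the first sequence is compared with the first receiver of
#' the second: a second sequence beginning west of where the first ended is
#' a counterclockwise route, east a clockwise route, and the same receiver
#' a linear route. With exactly one sequence, a smolt later detected at the
#' downstream exit curtain is classified linear (no detectable east-west
#' movement at the entry curtain); one never seen again is unclassifiable.
#'
#' @param nsog_sequences Sequence data.frame (one tag, entry array),
#'   ordered by `ordinal`.
#' @param has_qcs Logical: was the tag detected at the downstream array?
#' @return One of `"LINEAR"`, `"COUNTERCLOCKWISE"`, `"CLOCKWISE"`,
#'   `"UNCLASSIFIED"`.
#' @export
classify_route <- function(nsog_sequences, has_qcs) {
  n <- nrow(nsog_sequences)
  if (n == 0)
    stop("classify_route requires at least one entry-array sequence",
         call. = FALSE)
  if (n == 1L) return(if (isTRUE(has_qcs)) "LINEAR" else "UNCLASSIFIED")
  end1 <- nsog_sequences$last_receiver[1]
  start2 <- nsog_sequences$first_receiver[2]
  if (start2 > end1) "COUNTERCLOCKWISE"        # larger index = further west
  else if (start2 < end1) "CLOCKWISE"
  else "LINEAR"
}

#' Lateral displacement metrics between consecutive sequences
#'
#' `dx12_km` is the signed east-west displacement ([delta_x()]) from the
#' end of the first sequence to the beginning of the second; `dx23_km`
#' analogously between the second and third. A second sequence starting at
#' the receiver where the first ended scores exactly zero. `duration12_h`
#' is the time in hours from the end of the first sequence to the start of
#' the second. Fields are `NA` when the corresponding sequences are absent.
#'
#' @inheritParams classify_route
#' @param geom The entry array's geometry.
#' @return A one-row data.frame: `dx12_km`, `dx23_km`, `duration12_h`,
#'   `dx12_spans_texada`.
#' @export
lateral_metrics <- function(nsog_sequences, geom) {
  n <- nrow(nsog_sequences)
  dx12 <- dx23 <- dur12 <- NA_real_
  spans12 <- NA
  if (n >= 2L) {
    dx12 <- delta_x(geom, nsog_sequences$last_receiver[1],
                    nsog_sequences$first_receiver[2])
    spans12 <- spans_gap(geom, nsog_sequences$last_receiver[1],
                         nsog_sequences$first_receiver[2])
    dur12 <- as.numeric(difftime(nsog_sequences$first_time[2],
                                 nsog_sequences$last_time[1],
                                 units = "hours"))
  }
  if (n >= 3L) {
    dx23 <- delta_x(geom, nsog_sequences$last_receiver[2],
                    nsog_sequences$first_receiver[3])
  }
  data.frame(dx12_km = dx12, dx23_km = dx23, duration12_h = dur12,
             dx12_spans_texada = spans12)
}

#' Apparent survival and transit durations for one smolt
#'
#' A smolt with any detection at the downstream exit curtain is a
#' survivor; all others are assumed mortalities (apparent survival:
#' non-detection and death are confounded). Durations are in days.
#'
#' @param first_nsog_time POSIXct of the first entry-array detection.
#' @param first_qcs_time POSIXct of the first downstream detection, or `NA`.
#' @param release_date Release date (`Date` or POSIXct), or `NA`.
#' @return One-row data.frame: `survived_qcs`, `nsog_to_qcs_days`,
#'   `entry_to_nsog_days`.
#' @export
assign_survival <- function(first_nsog_time, first_qcs_time,
                            release_date = NA) {
  survived <- !is.na(first_qcs_time)
  nsog_to_qcs <- NA_real_
  if (survived) {
    nsog_to_qcs <- as.numeric(difftime(first_qcs_time, first_nsog_time,
                                       units = "days"))
    if (nsog_to_qcs < 0)
      warning("downstream detection precedes first entry-array detection; ",
              "survivor status retained", call. = FALSE)
  }
  entry_days <- NA_real_
  if (!is.na(release_date)) {
    rel <- if (inherits(release_date, "Date"))
      as.POSIXct(format(release_date), tz = "UTC") else release_date
    entry_days <- as.numeric(difftime(first_nsog_time, rel, units = "days"))
  }
  data.frame(survived_qcs = survived, nsog_to_qcs_days = nsog_to_qcs,
             entry_to_nsog_days = entry_days)
}

#' Per-smolt route records from detections and deployments
#'
#' The central derived table of the pipeline: for every tag detected at
#' the entry curtain (or at the westward-exit curtain), one row with its
#' route class, entry position and timing, lateral displacement metrics,
#' and apparent survival. Tags with any westward-exit (JDF) detection are
#' tallied as the westward route (`JUAN_DE_FUCA`) and excluded from
#' entry-curtain analyses.
#'
#' @param detections Detection data.frame (all arrays).
#' @param deployments Deployment data.frame ([read_deployments()]).
#' @param geometries Named list of geometries; the entry curtain is
#'   `nsog_array`, downstream `qcs_array`, westward exit `jdf_array`.
#' @param nsog_array,qcs_array,jdf_array Array labels.
#' @inheritParams build_sequences
#' @return A data.frame of route records, one row per analysed tag.
#' @export
build_route_records <- function(detections, deployments,
                                geometries = default_array_set(),
                                nsog_array = "NSOG", qcs_array = "QCS",
                                jdf_array = "JDF",
                                max_gap_hours = 1.0, max_step_km = 1.6,
                                step_mode = "km") {
  geom <- geometries[[nsog_array]]
  if (is.null(geom))
    stop("no geometry for entry array '", nsog_array, "'", call. = FALSE)
  nsog <- detections[detections$array == nsog_array, , drop = FALSE]
  seqs <- sequence_detections(nsog, geometries, max_gap_hours,
                              max_step_km, step_mode)
  s1 <- seqs[seqs$ordinal == 1L, , drop = FALSE]
  s2 <- seqs[seqs$ordinal == 2L, , drop = FALSE]
  s3 <- seqs[seqs$ordinal == 3L, , drop = FALSE]
  tags <- s1$tag_id
  nseq <- as.integer(table(factor(seqs$tag_id, levels = tags)))

  qcs <- detections[detections$array == qcs_array, , drop = FALSE]
  qcs_first <- if (nrow(qcs)) {
    tapply(qcs$timestamp, qcs$tag_id, min)
  } else NULL
  jdf_tags <- unique(detections$tag_id[detections$array == jdf_array])

  m2 <- match(tags, s2$tag_id)
  m3 <- match(tags, s3$tag_id)
  end1 <- s1$last_receiver
  start2 <- s2$first_receiver[m2]

  route <- rep(NA_character_, length(tags))
  multi <- !is.na(start2)
  route[multi & start2 > end1] <- "COUNTERCLOCKWISE"
  route[multi & start2 < end1] <- "CLOCKWISE"
  route[multi & start2 == end1] <- "LINEAR"

  first_qcs <- rep(as.POSIXct(NA, tz = "UTC"), length(tags))
  if (!is.null(qcs_first)) {
    mq <- match(tags, names(qcs_first))
    first_qcs[!is.na(mq)] <-
      as.POSIXct(unname(qcs_first[mq[!is.na(mq)]]), tz = "UTC",
                 origin = "1970-01-01")
  }
  survived <- !is.na(first_qcs)
  route[!multi] <- ifelse(survived[!multi], "LINEAR", "UNCLASSIFIED")
  in_jdf <- tags %in% jdf_tags
  if (any(in_jdf)) {
    warning(sum(in_jdf), " tag(s) detected at both entry and westward-exit ",
            "arrays; tallied as JUAN_DE_FUCA and excluded from entry analyses",
            call. = FALSE)
    route[in_jdf] <- "JUAN_DE_FUCA"
  }

  dx12 <- ifelse(multi, delta_x_safe(geom, end1, start2), NA_real_)
  spans12 <- ifelse(multi, spans_gap_safe(geom, end1, start2), NA)
  dur12 <- as.numeric(difftime(s2$first_time[m2], s1$last_time,
                               units = "hours"))
  end2 <- s2$last_receiver[m2]
  start3 <- s3$first_receiver[m3]
  triple <- !is.na(start3)
  dx23 <- ifelse(triple, delta_x_safe(geom, end2, start3), NA_real_)

  if (any(survived & first_qcs < s1$first_time, na.rm = TRUE))
    warning("downstream detection precedes first entry-array detection for ",
            sum(survived & first_qcs < s1$first_time, na.rm = TRUE),
            " tag(s); survivor status retained", call. = FALSE)
  nsog_to_qcs <- ifelse(survived,
                        as.numeric(difftime(first_qcs, s1$first_time,
                                            units = "days")),
                        NA_real_)

  md <- match(tags, deployments$tag_id)
  release_date <- deployments$release_date[md]
  entry_days <- as.numeric(difftime(
    s1$first_time,
    as.POSIXct(format(release_date), tz = "UTC"),
    units = "days"))

  records <- data.frame(
    tag_id = tags,
    species = deployments$species[md],
    population = deployments$population[md],
    release_year = deployments$release_year[md],
    fork_length_mm = deployments$fork_length_mm[md],
    tag_model = deployments$tag_model[md],
    route = route,
    n_sequences = nseq,
    p_initial = s1$first_receiver,
    arrival_date = as.Date(s1$first_time),
    arrival_julian = as.integer(strftime(s1$first_time, "%j", tz = "UTC")),
    initial_strait = strait_of(geom, s1$first_receiver),
    drift1_km = delta_x(geom, s1$first_receiver, s1$last_receiver),
    dx12_km = dx12,
    dx23_km = dx23,
    dx12_spans_texada = spans12,
    duration12_h = dur12,
    survived_qcs = survived,
    nsog_to_qcs_days = nsog_to_qcs,
    entry_to_nsog_days = entry_days,
    stringsAsFactors = FALSE
  )

  # Tags seen only at the westward exit: counted as the westward route.
  jdf_only <- setdiff(jdf_tags, tags)
  if (length(jdf_only)) {
    mj <- match(jdf_only, deployments$tag_id)
    extra <- data.frame(
      tag_id = jdf_only,
      species = deployments$species[mj],
      population = deployments$population[mj],
      release_year = deployments$release_year[mj],
      fork_length_mm = deployments$fork_length_mm[mj],
      tag_model = deployments$tag_model[mj],
      route = "JUAN_DE_FUCA",
      n_sequences = 0L,
      p_initial = NA_integer_, arrival_date = as.Date(NA),
      arrival_julian = NA_integer_, initial_strait = NA_character_,
      drift1_km = NA_real_, dx12_km = NA_real_, dx23_km = NA_real_,
      dx12_spans_texada = NA, duration12_h = NA_real_,
      survived_qcs = jdf_only %in% names(qcs_first),
      nsog_to_qcs_days = NA_real_, entry_to_nsog_days = NA_real_,
      stringsAsFactors = FALSE
    )
    records <- rbind(records, extra)
  }
  rownames(records) <- NULL
  records
}

# delta_x / spans_gap on vectors that may contain NA pairs
delta_x_safe <- function(geom, from, to) {
  out <- rep(NA_real_, length(from))
  ok <- !is.na(from) & !is.na(to)
  if (any(ok)) out[ok] <- delta_x(geom, from[ok], to[ok])
  out
}

spans_gap_safe <- function(geom, from, to) {
  out <- rep(NA, length(from))
  ok <- !is.na(from) & !is.na(to)
  if (any(ok)) out[ok] <- spans_gap(geom, from[ok], to[ok])
  out
}

#' Route counts and proportions per release group
#'
#' Groups records by `(species, population, release_year)` and counts each
#' route class. Proportions use the classified fish
#' (linear + counterclockwise + clockwise) as denominator; unclassifiable
#' and westward-exit fish are excluded from it. Groups with zero
#' classified fish get `NA` proportions.
#'
#' @param records Route records from [build_route_records()].
#' @return Data.frame with counts `n_linear`, `n_counter`, `n_clockwise`,
#'   `n_unclassified`, `n_jdf`, `n_classified` and proportions
#'   `p_linear`, `p_counter`, `p_clockwise`.
#' @export
route_tallies <- function(records) {
  key <- interaction(records$species, records$population,
                     records$release_year, drop = TRUE, sep = "\r")
  groups <- split(records, key)
  rows <- lapply(groups, function(g) {
    data.frame(
      species = g$species[1], population = g$population[1],
      release_year = g$release_year[1],
      n_linear = sum(g$route == "LINEAR"),
      n_counter = sum(g$route == "COUNTERCLOCKWISE"),
      n_clockwise = sum(g$route == "CLOCKWISE"),
      n_unclassified = sum(g$route == "UNCLASSIFIED"),
      n_jdf = sum(g$route == "JUAN_DE_FUCA"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$species, out$release_year, out$population), ,
             drop = FALSE]
  group_route_proportions(out)
}

#' Add route proportions to a table of per-group route counts
#'
#' @param counts Data.frame with columns `n_linear`, `n_counter`,
#'   `n_clockwise` (one row per release group).
#' @return `counts` with `n_classified`, `p_linear`, `p_counter`,
#'   `p_clockwise` appended; proportions are `NA` where no fish were
#'   classified.
#' @export
group_route_proportions <- function(counts) {
  stopifnot(all(c("n_linear", "n_counter", "n_clockwise") %in% names(counts)))
  denom <- counts$n_linear + counts$n_counter + counts$n_clockwise
  counts$n_classified <- denom
  safe <- function(x) ifelse(denom > 0, x / denom, NA_real_)
  counts$p_linear <- safe(counts$n_linear)
  counts$p_counter <- safe(counts$n_counter)
  counts$p_clockwise <- safe(counts$n_clockwise)
  counts
}
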