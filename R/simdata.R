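#' Release-group summary table of the tracked study cohorts
#'
#' The published per-release-group summary used as the worked-example
#' input and as the default cohort structure of the simulator: one row
#' per (year, species, population) with fork-length moments, the number
#' of smolts released, detected at the entry (NSOG) and downstream (QCS)
#' curtains, and the counts classified to each migration route. Tag model
#' follows the study design: the small wild Chilko sockeye carried V7
#' tags, all other groups V9.
#'
#' @return A data.frame with 21 rows.
#' @export
table1_release_groups <- function() {
  d <- utils::read.csv(text = trimws("
release_year,species,population,origin,fl_mean_mm,fl_sd_mm,n_released,n_nsog,n_qcs,n_linear,n_counter,n_clockwise
2004,sockeye,Cultus,H,178,13,100,34,13,13,1,0
2004,sockeye,Sakinaw,H,193,15,97,38,16,16,4,1
2005,sockeye,Cultus,H,177,14,378,44,22,17,8,4
2005,sockeye,Sakinaw,W,191,12,47,13,3,2,3,3
2006,sockeye,Cultus,H,178,9,200,54,30,26,6,3
2006,sockeye,Sakinaw,H/W,206,14,136,40,15,12,7,6
2007,sockeye,Cultus,H,182,11,319,107,64,58,12,4
2010,sockeye,Chilko,W,130,4,199,25,4,3,4,1
2011,sockeye,Chilko,W,133,7,443,54,24,23,2,0
2012,sockeye,Chilko,W,123,4,386,60,18,19,7,3
2013,sockeye,Chilko,W,123,2,432,184,48,42,32,13
2004,steelhead,Cheakamus,W,184,17,51,26,10,7,7,2
2004,steelhead,Englishman,W,174,17,67,41,10,8,9,3
2005,steelhead,Cheakamus,W,178,14,49,26,13,10,5,1
2005,steelhead,Englishman,W,159,15,43,20,5,4,2,2
2006,steelhead,Englishman,W,169,12,50,34,12,9,10,2
2006,steelhead,Seymour,H,207,16,50,5,1,0,3,0
2007,steelhead,Cheakamus,H,183,11,100,12,3,3,1,0
2007,steelhead,Seymour,H,186,13,60,6,1,1,1,0
2008,steelhead,Cheakamus,H/W,180,12,198,55,20,17,14,1
2008,steelhead,Seymour,H,184,14,60,9,4,4,2,0
"), stringsAsFactors = FALSE)
  d$tag_model <- ifelse(d$population == "Chilko", "V7", "V9")
  d
}

#' Simulation configuration
#'
#' Assembles and validates the parameter set of the synthetic telemetry
#' generator. Components (each a list merged over defaults):
#'
#' * `release_groups`: data.frame with `species`, `population`, `origin`,
#'   `n`, `fl_mean_mm`, `fl_sd_mm`, `release_year`, `tag_model`, and
#'   optionally `release_start` / `release_window_days`. Defaults to the
#'   published cohort structure ([table1_release_groups()], `n` = number
#'   released) with a 45-day release window opening April 25 (arrival at
#'   the entry curtain then centres on late May with an SD near the
#'   reported 11-16 days).
#' * `movement`: `speed_bl_s` (body lengths per second over ground, 1.0),
#'   `speed_min_km_day` / `speed_max_km_day` clamp (13-17),
#'   `p_linear`/`p_ccw`/`p_cw` behavior-class probabilities
#'   (0.65/0.25/0.10), loop amplitude distribution
#'   (`loop_amplitude_mean_km` 7, `loop_amplitude_sd_km` 4,
#'   `loop_amplitude_min_km` 0.8), dwell-time distribution between
#'   crossings (`dwell_mean_h` 70, `dwell_min_h` 2), third-crossing
#'   closure (`third_crossing_prob` 0.6, `third_amplitude_mean_km` 2),
#'   westward in-crossing drift `p_drift_west` 0.4, and `p_jdf` 0.014
#'   (fraction exiting via the westward strait).
#' * `arrival`: `malaspina_fraction` (0.66) of arrivals spread uniformly
#'   over the eastern-channel receivers, remainder uniform over the rest;
#'   or an explicit `probs` vector over all receivers.
#' * `detection`: per-crossing detection `efficiency` by tag model
#'   (V7 0.675, V9 0.90), `ping_interval_s` 120, within-crossing
#'   residence `residence_min_min`/`residence_max_min` (5/20), and
#'   `qcs_efficiency` (1.0: the downstream curtain treated as perfectly
#'   efficient so simulated apparent survival equals true survival).
#' * `mortality`: `baseline_daily_hazard` (0.05) driving an exponential
#'   death clock, plus an optional logistic stage on the entry-to-exit
#'   leg: `logit_intercept` and log-odds coefficients `beta_p_initial`,
#'   `beta_julian`, `beta_duration` applied to 2-SD standardized true
#'   covariates and `beta_malaspina` to the eastern-channel indicator.
#' * `geometry` (entry curtain), `arrays` (full array set),
#'   `entry_distance_km` (150, release point to entry curtain),
#'   `qcs_distance_km` (250, entry to downstream curtain).
#'
#' @param release_groups,movement,arrival,detection,mortality See above.
#' @param geometry,arrays,entry_distance_km,qcs_distance_km See above.
#' @return An object of class `smolt_sim_config`.
#' @export
sim_config <- function(release_groups = NULL, movement = list(),
                       arrival = list(), detection = list(),
                       mortality = list(), geometry = nsog_geometry(),
                       arrays = default_array_set(),
                       entry_distance_km = 150, qcs_distance_km = 250) {
  if (is.null(release_groups)) {
    t1 <- table1_release_groups()
    release_groups <- data.frame(
      species = t1$species, population = t1$population, origin = t1$origin,
      n = t1$n_released, fl_mean_mm = t1$fl_mean_mm, fl_sd_mm = t1$fl_sd_mm,
      release_year = t1$release_year, tag_model = t1$tag_model,
      stringsAsFactors = FALSE)
  }
  if (is.null(release_groups$release_start))
    release_groups$release_start <-
      as.Date(paste0(release_groups$release_year, "-04-25"))
  if (is.null(release_groups$release_window_days))
    release_groups$release_window_days <- 45
  movement <- utils::modifyList(list(
    speed_bl_s = 1.0, speed_min_km_day = 13, speed_max_km_day = 17,
    p_linear = 0.65, p_ccw = 0.25, p_cw = 0.10,
    loop_amplitude_mean_km = 7, loop_amplitude_sd_km = 4,
    loop_amplitude_min_km = 0.8,
    dwell_mean_h = 70, dwell_min_h = 2,
    couple_amplitude_to_dwell = TRUE,
    third_crossing_prob = 0.6, third_amplitude_mean_km = 2,
    p_drift_west = 0.4, p_jdf = 0.014), movement)
  arrival <- utils::modifyList(list(malaspina_fraction = 0.66,
                                    probs = NULL), arrival)
  detection <- utils::modifyList(list(
    efficiency = c(V7 = 0.675, V9 = 0.90), ping_interval_s = 120,
    residence_min_min = 5, residence_max_min = 20,
    qcs_efficiency = 1.0), detection)
  mortality <- utils::modifyList(list(
    baseline_daily_hazard = 0.05, logit_intercept = NULL,
    beta_p_initial = 0, beta_julian = 0, beta_duration = 0,
    beta_malaspina = 0), mortality)
  cfg <- structure(
    list(release_groups = release_groups, movement = movement,
         arrival = arrival, detection = detection, mortality = mortality,
         geometry = geometry, arrays = arrays,
         entry_distance_km = entry_distance_km,
         qcs_distance_km = qcs_distance_km),
    class = "smolt_sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  rg <- cfg$release_groups
  if (nrow(rg) == 0 || any(rg$n <= 0))
    stop("sim config: every release group needs n > 0", call. = FALSE)
  if (!all(rg$tag_model %in% TAG_MODELS))
    stop("sim config: unknown tag model", call. = FALSE)
  m <- cfg$movement
  probs <- c(m$p_linear, m$p_ccw, m$p_cw)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    stop("sim config: behavior-class probabilities must be nonnegative ",
         "and sum to 1", call. = FALSE)
  if (m$p_jdf < 0 || m$p_jdf >= 1)
    stop("sim config: p_jdf must be in [0, 1)", call. = FALSE)
  d <- cfg$detection
  if (any(d$efficiency < 0) || any(d$efficiency > 1) ||
      d$qcs_efficiency < 0 || d$qcs_efficiency > 1)
    stop("sim config: efficiencies must lie in [0, 1]", call. = FALSE)
  if (m$dwell_min_h <= 1)
    warning("sim config: dwell_min_h <= 1 h can merge crossings into one ",
            "detection sequence", call. = FALSE)
  if (cfg$mortality$baseline_daily_hazard < 0)
    stop("sim config: baseline_daily_hazard must be >= 0", call. = FALSE)
  invisible(cfg)
}

expand_release_groups <- function(rg) {
  idx <- rep(seq_len(nrow(rg)), rg$n)
  d <- rg[idx, , drop = FALSE]
  within_group <- stats::ave(seq_along(idx), idx, FUN = seq_along)
  d$tag_id <- sprintf("%s%d-%04d", d$population, d$release_year,
                      within_group)
  rownames(d) <- NULL
  d
}

# 2-SD standardization that tolerates constant vectors (returns zeros)
z2 <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / (2 * s)
}

nearest_receiver <- function(chain, target) {
  max.col(-abs(outer(target, chain, "-")), ties.method = "first")
}

#' Simulate deployments, detections and ground truth
#'
#' Agent-based generator for the whole study: each smolt draws a fork
#' length, release date and behavior class; travels at ~1 BL/s over
#' ground (clamped to 13-17 km/day) to the entry curtain; crosses at a
#' receiver drawn from the arrival distribution (eastern-channel skewed
#' by default); loopers (counterclockwise/clockwise) re-cross displaced
#' west/east by a draw from the loop-amplitude distribution after a dwell
#' time, optionally closing the loop with a third, oppositely displaced
#' crossing; each crossing is detected with the tag model's per-crossing
#' efficiency, emitting pings at fixed intervals while the fish is within
#' range. Mortality combines an exponential death clock (baseline daily
#' hazard) with an optional logistic stage on the entry-to-exit leg (see
#' [sim_config()]); survivors are detected at the downstream curtain. A
#' small configurable fraction instead exits via the westward strait and
#' is detected only there. Movement is one-dimensional along-migration
#' plus east-west receiver displacement; rotation is imposed as a
#' behavior class, not emergent hydrodynamics.
#'
#' Identical `(config, seed)` give byte-identical output.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for all randomness.
#' @return A list of class `smolt_simulation`: `deployments`,
#'   `detections`, `truth` (per-smolt behavior class, true survival and
#'   crossing schedule).
#' @export
simulate_smolts <- function(config, seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(as.integer(seed))
  geom <- config$geometry
  mv <- config$movement
  det <- config$detection
  mort <- config$mortality
  nrec <- geom$n_receivers
  chain <- receiver_chainage(geom, seq_len(nrec))

  fish <- expand_release_groups(config$release_groups)
  n <- nrow(fish)
  fl <- pmax(60, stats::rnorm(n, fish$fl_mean_mm, fish$fl_sd_mm))
  release_date <- fish$release_start +
    floor(stats::runif(n, 0, fish$release_window_days))
  release_ts <- as.POSIXct(format(release_date), tz = "UTC")

  # over-ground speed from body length, clamped to the observed range
  speed_km_day <- pmin(pmax(mv$speed_bl_s * fl / 1000 * 86.4,
                            mv$speed_min_km_day), mv$speed_max_km_day)

  is_jdf <- stats::runif(n) < mv$p_jdf
  behavior <- sample(c("linear", "ccw", "cw"), n, replace = TRUE,
                     prob = c(mv$p_linear, mv$p_ccw, mv$p_cw))
  behavior[is_jdf] <- "jdf"

  # arrival distribution across the curtain (eastern-channel skewed);
  # loopers draw from the sub-range leaving room for their loop direction
  probs <- config$arrival$probs
  if (is.null(probs)) {
    probs <- rep(0, nrec)
    mal <- geom$malaspina_indices
    if (length(mal)) probs[mal] <- config$arrival$malaspina_fraction / length(mal)
    rest <- setdiff(seq_len(nrec), mal)
    probs[rest] <- (1 - sum(probs)) / length(rest)
  }
  probs <- probs / sum(probs)
  r1 <- integer(n)
  idx_lin <- which(!is_jdf & behavior == "linear")
  idx_ccw <- which(behavior == "ccw")
  idx_cw <- which(behavior == "cw")
  if (length(idx_lin))
    r1[idx_lin] <- sample.int(nrec, length(idx_lin), replace = TRUE,
                              prob = probs)
  if (length(idx_ccw))
    r1[idx_ccw] <- sample.int(nrec - 1L, length(idx_ccw), replace = TRUE,
                              prob = probs[-nrec])
  if (length(idx_cw))
    r1[idx_cw] <- 1L + sample.int(nrec - 1L, length(idx_cw),
                                  replace = TRUE, prob = probs[-1])
  r1[is_jdf] <- 1L  # placeholder; westward-exit fish never cross the curtain

  t1_start <- as.numeric(release_ts) +
    config$entry_distance_km / speed_km_day * 86400 +
    stats::runif(n, 0, 43200)
  res_s <- function(k) round(stats::runif(
    k, det$residence_min_min, det$residence_max_min) * 60)
  res1 <- res_s(n)
  # westward drift within the first crossing, where geometrically safe
  drift_ok <- r1 < nrec & (is.na(geom$gap_after_index) |
                             r1 != geom$gap_after_index) &
    !(behavior == "ccw" & r1 == nrec - 1L)
  drift <- as.integer(stats::runif(n) < mv$p_drift_west & drift_ok)
  r1_end <- r1 + drift
  t1_end <- t1_start + res1

  looper <- behavior %in% c("ccw", "cw")
  amp_mean <- mv$loop_amplitude_mean_km; amp_sd <- mv$loop_amplitude_sd_km
  shape <- (amp_mean / amp_sd)^2
  dwell1 <- mv$dwell_min_h +
    stats::rexp(n, 1 / max(mv$dwell_mean_h - mv$dwell_min_h, 1e-6))
  # longer milling drifts fish further: amplitude scales with sqrt(dwell)
  amp <- stats::rgamma(n, shape = shape, rate = shape / amp_mean)
  if (isTRUE(mv$couple_amplitude_to_dwell))
    amp <- amp * sqrt(dwell1 / mv$dwell_mean_h)
  amp <- pmax(amp, mv$loop_amplitude_min_km)
  target2 <- ifelse(behavior == "ccw", chain[r1_end] + amp,
                    chain[r1_end] - amp)
  r2 <- nearest_receiver(chain, target2)
  r2 <- ifelse(behavior == "ccw", pmin(pmax(r2, r1_end + 1L), nrec),
               pmax(pmin(r2, r1_end - 1L), 1L))
  r2[!looper] <- NA_integer_
  t2_start <- ifelse(looper, t1_end + dwell1 * 3600, NA_real_)
  res2 <- res_s(n)
  t2_end <- t2_start + res2

  amp3 <- pmax(stats::rexp(n, 1 / mv$third_amplitude_mean_km),
               mv$loop_amplitude_min_km)
  can3 <- looper & ifelse(behavior == "ccw", r2 > 1L, r2 < nrec)
  has3 <- can3 & stats::runif(n) < mv$third_crossing_prob
  target3 <- ifelse(behavior == "ccw", chain[ifelse(looper, r2, 1L)] - amp3,
                    chain[ifelse(looper, r2, 1L)] + amp3)
  r3 <- nearest_receiver(chain, target3)
  r3 <- ifelse(behavior == "ccw", pmax(pmin(r3, r2 - 1L), 1L),
               pmin(pmax(r3, r2 + 1L), nrec))
  r3[!has3] <- NA_integer_
  dwell2 <- mv$dwell_min_h +
    stats::rexp(n, 1 / max(mv$dwell_mean_h / 2 - mv$dwell_min_h, 1e-6))
  t3_start <- ifelse(has3, t2_end + dwell2 * 3600, NA_real_)
  res3 <- res_s(n)
  t3_end <- t3_start + res3

  t_last_end <- ifelse(has3, t3_end, ifelse(looper, t2_end, t1_end))
  t_qcs <- t_last_end + config$qcs_distance_km / speed_km_day * 86400

  hazard <- mort$baseline_daily_hazard
  t_death <- if (hazard > 0)
    as.numeric(release_ts) + stats::rexp(n, hazard) * 86400
  else rep(Inf, n)

  julian <- as.integer(strftime(
    as.POSIXct(t1_start, origin = "1970-01-01", tz = "UTC"), "%j",
    tz = "UTC"))
  duration12_true <- ifelse(looper, dwell1, 0)
  malaspina <- as.integer(r1 %in% geom$malaspina_indices)

  logistic_on <- !is.null(mort$logit_intercept) ||
    mort$beta_p_initial != 0 || mort$beta_julian != 0 ||
    mort$beta_duration != 0 || mort$beta_malaspina != 0
  extra_survive <- rep(TRUE, n)
  if (logistic_on) {
    eligible <- !is_jdf & t_death > t_last_end
    b0 <- if (is.null(mort$logit_intercept)) 0 else mort$logit_intercept
    lp <- b0 +
      mort$beta_p_initial * z2(r1[eligible]) +
      mort$beta_julian * z2(julian[eligible]) +
      mort$beta_duration * z2(duration12_true[eligible]) +
      mort$beta_malaspina * malaspina[eligible]
    extra_survive[eligible] <- stats::runif(sum(eligible)) < stats::plogis(lp)
  }
  survived <- !is_jdf & t_death > t_qcs & extra_survive

  made1 <- !is_jdf & t_death > t1_start
  made2 <- looper & t_death > t2_start & made1
  made3 <- has3 & t_death > t3_start & made2
  eff <- det$efficiency[fish$tag_model]
  det1 <- made1 & stats::runif(n) < eff
  det2 <- made2 & stats::runif(n) < eff
  det3 <- made3 & stats::runif(n) < eff

  pings <- function(which_fish, r_start, r_end, t_start, res) {
    idx <- which(which_fish)
    if (!length(idx)) return(NULL)
    np <- pmax(2L, as.integer(res[idx] %/% det$ping_interval_s) + 1L)
    fi <- rep(idx, np)
    off <- sequence(np) - 1L
    n_start <- ceiling(rep(np, np) * 0.6)
    data.frame(
      tag_id = fish$tag_id[fi], array = geom$array_name,
      receiver_index = ifelse(off < n_start, r_start[fi], r_end[fi]),
      timestamp_s = round(t_start[fi]) + off * det$ping_interval_s,
      stringsAsFactors = FALSE)
  }
  d1 <- pings(det1, r1, r1_end, t1_start, res1)
  d2 <- pings(det2, r2, r2, t2_start, res2)
  d3 <- pings(det3, r3, r3, t3_start, res3)

  qcs_geom <- config$arrays$QCS
  qcs_det <- survived & stats::runif(n) < det$qcs_efficiency
  dq <- NULL
  if (any(qcs_det)) {
    idx <- which(qcs_det)
    rq <- sample.int(qcs_geom$n_receivers, length(idx), replace = TRUE)
    dq <- data.frame(
      tag_id = rep(fish$tag_id[idx], each = 2), array = "QCS",
      receiver_index = rep(rq, each = 2),
      timestamp_s = round(rep(t_qcs[idx], each = 2)) +
        rep(c(0, det$ping_interval_s), length(idx)),
      stringsAsFactors = FALSE)
  }
  jdf_geom <- config$arrays$JDF
  t_jdf <- as.numeric(release_ts) +
    config$entry_distance_km / speed_km_day * 86400
  jdf_det <- is_jdf & t_death > t_jdf & stats::runif(n) < eff
  dj <- NULL
  if (any(jdf_det)) {
    idx <- which(jdf_det)
    rj <- sample.int(jdf_geom$n_receivers, length(idx), replace = TRUE)
    dj <- data.frame(
      tag_id = rep(fish$tag_id[idx], each = 2), array = "JDF",
      receiver_index = rep(rj, each = 2),
      timestamp_s = round(rep(t_jdf[idx], each = 2)) +
        rep(c(0, det$ping_interval_s), length(idx)),
      stringsAsFactors = FALSE)
  }

  detections <- do.call(rbind, Filter(Negate(is.null), list(d1, d2, d3, dq, dj)))
  if (is.null(detections))
    detections <- data.frame(tag_id = character(0), array = character(0),
                             receiver_index = integer(0),
                             timestamp_s = numeric(0))
  detections$timestamp <- as.POSIXct(detections$timestamp_s,
                                     origin = "1970-01-01", tz = "UTC")
  detections$timestamp_s <- NULL
  detections <- detections[order(detections$tag_id, detections$timestamp,
                                 detections$receiver_index), , drop = FALSE]
  rownames(detections) <- NULL

  deployments <- data.frame(
    tag_id = fish$tag_id, species = fish$species,
    population = fish$population, origin = fish$origin,
    fork_length_mm = round(fl, 1), release_date = release_date,
    release_year = fish$release_year, tag_model = fish$tag_model,
    stringsAsFactors = FALSE)

  to_ts <- function(x) as.POSIXct(round(x), origin = "1970-01-01", tz = "UTC")
  truth <- data.frame(
    tag_id = fish$tag_id, behavior = behavior, survived_qcs = survived,
    n_crossings = made1 + made2 + made3,
    r1 = ifelse(made1, r1, NA_integer_),
    r1_end = ifelse(made1, r1_end, NA_integer_),
    r2 = ifelse(made2, r2, NA_integer_),
    r3 = ifelse(made3, r3, NA_integer_),
    t1_start_time = to_ts(ifelse(made1, t1_start, NA_real_)),
    t2_start_time = to_ts(ifelse(made2, t2_start, NA_real_)),
    t3_start_time = to_ts(ifelse(made3, t3_start, NA_real_)),
    p_initial_true = ifelse(is_jdf, NA_integer_, r1),
    julian_true = ifelse(is_jdf, NA_integer_, julian),
    duration12_true_h = ifelse(is_jdf, NA_real_, duration12_true),
    malaspina_true = ifelse(is_jdf, NA, malaspina == 1L),
    qcs_time = to_ts(ifelse(survived, t_qcs, NA_real_)),
    qcs_sched_time = to_ts(ifelse(is_jdf, NA_real_, t_qcs)),
    stringsAsFactors = FALSE)

  structure(list(deployments = deployments, detections = detections,
                 truth = truth, config = config, seed = seed),
            class = "smolt_simulation")
}

#' @export
print.smolt_simulation <- function(x, ...) {
  cat("Synthetic smolt telemetry simulation\n")
  cat("  smolts: ", nrow(x$deployments), "  detections: ",
      nrow(x$detections), "\n", sep = "")
  cat("  true routes: ",
      paste(names(table(x$truth$behavior)),
            table(x$truth$behavior), sep = "=", collapse = ", "),
      "\n", sep = "")
  cat("  true survival to exit curtain: ",
      sum(x$truth$survived_qcs), " (",
      round(100 * mean(x$truth$survived_qcs), 1), "%)\n", sep = "")
  invisible(x)
}

#' Deployments matching the published release-group structure
#'
#' Expands the printed per-group table into one deployment record per
#' smolt, with fork lengths drawn at the printed group mean and SD.
#'
#' @param seed Integer seed.
#' @return A deployments data.frame (one row per released smolt).
#' @export
make_table1_deployments <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  t1 <- table1_release_groups()
  rg <- data.frame(
    species = t1$species, population = t1$population, origin = t1$origin,
    n = t1$n_released, fl_mean_mm = t1$fl_mean_mm, fl_sd_mm = t1$fl_sd_mm,
    release_year = t1$release_year, tag_model = t1$tag_model,
    release_start = as.Date(paste0(t1$release_year, "-04-25")),
    release_window_days = 45, stringsAsFactors = FALSE)
  fish <- expand_release_groups(rg)
  data.frame(
    tag_id = fish$tag_id, species = fish$species,
    population = fish$population, origin = fish$origin,
    fork_length_mm = round(pmax(60, stats::rnorm(
      nrow(fish), fish$fl_mean_mm, fish$fl_sd_mm)), 1),
    release_date = fish$release_start +
      floor(stats::runif(nrow(fish), 0, fish$release_window_days)),
    release_year = fish$release_year, tag_model = fish$tag_model,
    stringsAsFactors = FALSE)
}
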