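#' Construct a telemetry test result
#'
#' Light container used by every test in the descriptive battery so that
#' results can be collected into one table (`as.data.frame` method).
#'
#' @param test_name Short label of the test.
#' @param statistic Named or unnamed test statistic.
#' @param p_value P-value in `[0, 1]`.
#' @param n Sample size(s) used.
#' @param estimates Named numeric vector of estimates (proportions, tau,
#'   means, odds ratio, ...).
#' @param groups Optional character vector of group labels.
#' @param extra Optional object (e.g. a Tukey pairwise table) kept as an
#'   attribute.
#' @return An object of class `telemetry_test`.
#' @export
telemetry_test <- function(test_name, statistic, p_value, n,
                           estimates = numeric(0), groups = NULL,
                           extra = NULL) {
  stopifnot(is.numeric(p_value), p_value >= 0, p_value <= 1)
  structure(
    list(test_name = test_name, statistic = statistic, p_value = p_value,
         n = n, estimates = estimates, groups = groups, extra = extra),
    class = "telemetry_test"
  )
}

#' @export
print.telemetry_test <- function(x, ...) {
  cat(x$test_name, "\n", sep = "")
  if (length(x$statistic))
    cat("  statistic: ", paste(signif(x$statistic, 5), collapse = ", "),
        "\n", sep = "")
  cat("  p-value: ", format.pval(x$p_value), "   n: ",
      paste(x$n, collapse = ", "), "\n", sep = "")
  if (length(x$estimates)) {
    cat("  estimates:\n")
    for (nm in names(x$estimates))
      cat("    ", nm, " = ", signif(x$estimates[[nm]], 5), "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.telemetry_test <- function(x, ...) {
  data.frame(
    test_name = x$test_name,
    statistic = if (length(x$statistic)) unname(x$statistic[1]) else NA_real_,
    p_value = x$p_value,
    n = sum(x$n),
    estimates = paste(sprintf("%s=%.6g", names(x$estimates),
                              unlist(x$estimates)), collapse = "; "),
    groups = paste(x$groups, collapse = "; "),
    stringsAsFactors = FALSE
  )
}

#' Test for disproportionate use of the eastern channel
#'
#' Exact binomial test of the number of smolts whose first detection
#' sequence began in Malaspina Strait against the expectation proportional
#' to the strait's relative width (number of receivers: 7/27 in the
#' default layout).
#'
#' @param p_initial Integer vector of first-detection receiver indices.
#' @param geom Entry-array geometry.
#' @return A [telemetry_test()].
#' @export
strait_use_test <- function(p_initial, geom) {
  p_initial <- p_initial[!is.na(p_initial)]
  n <- length(p_initial)
  if (n == 0) stop("strait_use_test: no initial positions", call. = FALSE)
  expected <- length(geom$malaspina_indices) / geom$n_receivers
  k <- sum(strait_of(geom, p_initial) == "MALASPINA")
  bt <- stats::binom.test(k, n, p = expected, alternative = "two.sided")
  telemetry_test(
    "strait_use_binomial", statistic = c(count_malaspina = k),
    p_value = bt$p.value, n = n,
    estimates = c(observed_prop = k / n, expected_prop = expected)
  )
}

#' Chi-square test of uniform distribution across receivers
#'
#' Goodness-of-fit of the per-receiver counts of a detection-sequence
#' cohort against a uniform expectation across all receivers of the array.
#'
#' @param receiver_indices Integer vector of receiver indices.
#' @param geom Entry-array geometry.
#' @return A [telemetry_test()].
#' @export
uniformity_test <- function(receiver_indices, geom) {
  receiver_indices <- check_receiver_index(geom, receiver_indices)
  counts <- tabulate(receiver_indices, nbins = geom$n_receivers)
  ct <- suppressWarnings(stats::chisq.test(counts))
  telemetry_test(
    "uniformity_chisq", statistic = c(X_squared = unname(ct$statistic)),
    p_value = ct$p.value, n = length(receiver_indices)
  )
}

# exact only when feasible: n <= 25 and no ties among |values|
use_exact <- function(values) {
  length(values) <= 25L && !any(duplicated(abs(values)))
}

#' One-sample Wilcoxon signed-rank test of zero median displacement
#'
#' Used for the within-sequence drift and the between-sequence
#' displacements: are signed east-west displacements centred on zero?
#' Exact null distribution when n <= 25 with no ties, else the normal
#' approximation with continuity correction. Exact zeros are dropped from
#' the statistic (classical Wilcoxon zero-handling), reducing n.
#'
#' @param values Numeric vector of signed displacements (km).
#' @return A [telemetry_test()].
#' @export
signed_rank_zero_test <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0)
    stop("signed_rank_zero_test: no values", call. = FALSE)
  nz <- values[values != 0]
  if (length(nz) == 0) {
    warning("all displacements are exactly zero; degenerate test (p = 1)",
            call. = FALSE)
    return(telemetry_test("wilcoxon_signed_rank", c(V = NA_real_), 1,
                          n = 0, estimates = c(mean = 0, median = 0)))
  }
  dropped <- length(values) - length(nz)
  if (dropped > 0)
    warning(dropped, " exact zero(s) dropped from signed-rank statistic",
            call. = FALSE)
  wt <- suppressWarnings(
    stats::wilcox.test(nz, mu = 0, exact = use_exact(nz), correct = TRUE)
  )
  telemetry_test(
    "wilcoxon_signed_rank", statistic = c(V = unname(wt$statistic)),
    p_value = wt$p.value, n = length(nz),
    estimates = c(mean = mean(values), median = stats::median(values))
  )
}

#' Mann-Whitney rank-sum test between two displacement samples
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum). The reported statistic is
#' the smaller of the two equivalent U values. Exact when both samples are
#' small and untied, else normal approximation with continuity correction.
#'
#' @param values_a,values_b Numeric samples (e.g. one species each).
#' @param labels Optional group labels (length 2).
#' @return A [telemetry_test()].
#' @export
ranksum_test <- function(values_a, values_b, labels = c("a", "b")) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) == 0 || length(values_b) == 0)
    stop("ranksum_test: both samples must be nonempty", call. = FALSE)
  exact <- (length(values_a) + length(values_b)) <= 25L &&
    !any(duplicated(c(values_a, values_b)))
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = exact, correct = TRUE)
  )
  u <- unname(wt$statistic)
  u_min <- min(u, length(values_a) * length(values_b) - u)
  telemetry_test(
    "mann_whitney_u", statistic = c(U = u_min),
    p_value = wt$p.value, n = c(length(values_a), length(values_b)),
    estimates = c(mean_a = mean(values_a), mean_b = mean(values_b)),
    groups = labels
  )
}

#' Kendall rank correlation between milling duration and displacement
#'
#' Tie-corrected Kendall's tau-b with the p-value from [stats::cor.test()]
#' (exact for small untied samples, normal approximation otherwise).
#'
#' @param x,y Paired numeric vectors (e.g. duration between sequences in
#'   hours and the displacement in km).
#' @return A [telemetry_test()].
#' @export
kendall_tau <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) stop("kendall_tau: need n >= 2 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("kendall_tau: zero variance; tau undefined", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  telemetry_test(
    "kendall_tau", statistic = c(T = unname(ct$statistic)),
    p_value = ct$p.value, n = length(x),
    estimates = c(tau = unname(ct$estimate))
  )
}

# F and p from a one-way ANOVA table; a between-group sum of squares of
# zero is a true null result (F = 0, p = 1) even when the residual
# variance is also zero (0/0 at floating-point noise level in the table).
anova_f_p <- function(tab) {
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  ssb <- tab[["Sum Sq"]][1]
  ssw <- tab[["Sum Sq"]][2]
  if (ssb <= 1e-10) {
    f <- 0
    p <- 1
  } else if (!is.finite(f) && ssw <= 1e-10) {
    f <- Inf
    p <- 0
  }
  c(f, p)
}

#' Weighted ANOVA of route proportions across route classes
#'
#' Compares the per-release-group proportions of the three route classes,
#' weighting each release group by its number of route-classified fish
#' (case weights in the linear model), followed by Tukey HSD pairwise
#' comparisons using the weighted model.
#'
#' @param proportions Data.frame with columns `route` (3 classes),
#'   `proportion`, `weight` (classified-fish count), `group` (release
#'   group label).
#' @return A [telemetry_test()] whose `extra` holds the Tukey HSD table.
#' @export
route_proportion_anova <- function(proportions) {
  proportions <- proportions[!is.na(proportions$proportion), , drop = FALSE]
  proportions$route <- factor(proportions$route)
  reps <- table(proportions$route)
  if (any(reps < 2))
    stop("route_proportion_anova: every route class needs >= 2 release ",
         "groups (got ", paste(reps, collapse = ", "), ")", call. = FALSE)
  fit <- stats::aov(proportion ~ route, data = proportions,
                    weights = proportions$weight)
  tab <- summary(fit)[[1]]
  tukey <- stats::TukeyHSD(fit)$route
  f_p <- anova_f_p(tab)
  telemetry_test(
    "route_proportion_anova_weighted",
    statistic = c(F = f_p[1]),
    p_value = f_p[2],
    n = nrow(proportions),
    estimates = stats::setNames(
      tapply(proportions$proportion, proportions$route, mean),
      paste0("mean_", levels(proportions$route))),
    groups = levels(proportions$route),
    extra = tukey
  )
}

#' Welch t-test of a route's proportion between the two species
#'
#' Compares per-release-group proportions of one route class between
#' species (each release group one observation).
#'
#' @param props_a,props_b Numeric vectors of per-group proportions.
#' @param labels Species labels.
#' @return A [telemetry_test()].
#' @export
species_proportion_ttest <- function(props_a, props_b,
                                     labels = c("a", "b")) {
  props_a <- props_a[!is.na(props_a)]
  props_b <- props_b[!is.na(props_b)]
  if (length(props_a) < 2 || length(props_b) < 2)
    stop("species_proportion_ttest: need >= 2 groups per species",
         call. = FALSE)
  if (stats::sd(props_a) == 0 && stats::sd(props_b) == 0 &&
      mean(props_a) == mean(props_b)) {
    return(telemetry_test("welch_t", c(t = 0), 1,
                          n = c(length(props_a), length(props_b)),
                          estimates = c(mean_a = mean(props_a),
                                        mean_b = mean(props_b)),
                          groups = labels))
  }
  tt <- stats::t.test(props_a, props_b)
  telemetry_test(
    "welch_t", statistic = c(t = unname(tt$statistic)),
    p_value = tt$p.value, n = c(length(props_a), length(props_b)),
    estimates = c(mean_a = mean(props_a), mean_b = mean(props_b)),
    groups = labels
  )
}

#' Fisher's exact test on a 2x2 survival-by-strait table
#'
#' Conditional odds-ratio estimate and exact two-sided p-value. A table
#' with a zero margin has an undefined odds ratio; p = 1 is returned with
#' a warning.
#'
#' @param counts 2x2 matrix of nonnegative integers (rows: strait, cols:
#'   survived / not).
#' @return A [telemetry_test()].
#' @export
fisher_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0),
            all(counts == round(counts)))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    warning("fisher_2x2: zero margin; odds ratio undefined, p = 1",
            call. = FALSE)
    return(telemetry_test("fisher_exact", c(odds_ratio = NA_real_), 1,
                          n = sum(counts)))
  }
  ft <- stats::fisher.test(counts)
  telemetry_test(
    "fisher_exact", statistic = c(odds_ratio = unname(ft$estimate)),
    p_value = ft$p.value, n = sum(counts),
    estimates = c(odds_ratio = unname(ft$estimate))
  )
}

#' Pearson correlations guarding the survival models against
#' migration-rate confounding
#'
#' For each candidate survival covariate (entry position, arrival
#' day-of-year, duration between the first two sequences) reports the
#' Pearson correlation with (a) the time from release to the entry
#' curtain, all fish, and (b) the time from the entry curtain to the
#' downstream curtain, survivors only.
#'
#' @param records Route records ([build_route_records()]).
#' @return Data.frame with columns `variable`, `against`, `r`, `p`, `n`.
#' @export
confound_correlations <- function(records) {
  vars <- c(p_initial = "p_initial", arrival_julian = "arrival_julian",
            duration12_h = "duration12_h")
  against <- list(
    entry_to_nsog_days = records$entry_to_nsog_days,
    nsog_to_qcs_days = ifelse(records$survived_qcs,
                              records$nsog_to_qcs_days, NA_real_)
  )
  rows <- list()
  for (v in names(vars)) {
    for (a in names(against)) {
      x <- records[[vars[[v]]]]
      y <- against[[a]]
      keep <- !is.na(x) & !is.na(y)
      if (sum(keep) < 3) {
        warning("confound_correlations: fewer than 3 pairs for ", v,
                " vs ", a, "; skipped", call. = FALSE)
        next
      }
      if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) {
        warning("confound_correlations: zero variance for ", v, " vs ", a,
                "; skipped", call. = FALSE)
        next
      }
      ct <- stats::cor.test(x[keep], y[keep], method = "pearson")
      rows[[paste(v, a)]] <- data.frame(
        variable = v, against = a, r = unname(ct$estimate),
        p = ct$p.value, n = sum(keep), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(variable = character(0),
                                      against = character(0), r = numeric(0),
                                      p = numeric(0), n = integer(0))
  rownames(out) <- NULL
  out
}

#' Tally large westward displacements between the first two sequences
#'
#' Counts, per species, the multi-sequence smolts whose first-to-second
#' displacement was westward and either spanned the island gap or reached
#' at least `threshold_km`.
#'
#' @param records Route records.
#' @param threshold_km Displacement threshold (default 8 km, ten receiver
#'   spacings).
#' @return Data.frame per species: `n_multi`, `n_big_westward`, `fraction`.
#' @export
big_westward_tally <- function(records, threshold_km = 8.0) {
  multi <- records[!is.na(records$dx12_km), , drop = FALSE]
  groups <- split(multi, multi$species)
  rows <- lapply(names(groups), function(sp) {
    g <- groups[[sp]]
    west <- g$dx12_km < 0
    big <- west & (abs(g$dx12_km) >= threshold_km |
                     g$dx12_spans_texada %in% TRUE)
    data.frame(species = sp, n_multi = nrow(g), n_big_westward = sum(big),
               fraction = if (nrow(g)) sum(big) / nrow(g) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(species = character(0), n_multi = integer(0),
                      n_big_westward = integer(0), fraction = numeric(0))
  rownames(out) <- NULL
  out
}

#' ANOVA of transit duration to the downstream curtain across routes
#'
#' One-way ANOVA of survivors' entry-to-exit transit time (days) across
#' the three route classes, with Tukey HSD pairwise comparisons and
#' per-route means and SDs. Routes with fewer than 2 survivors are dropped
#' with a warning; at least two routes must remain.
#'
#' @param records Route records.
#' @return A [telemetry_test()] whose `extra` holds the Tukey table and a
#'   per-route summary data.frame.
#' @export
duration_by_route <- function(records) {
  d <- records[records$survived_qcs &
                 records$route %in% c("LINEAR", "COUNTERCLOCKWISE",
                                      "CLOCKWISE") &
                 !is.na(records$nsog_to_qcs_days), , drop = FALSE]
  counts <- table(d$route)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("duration_by_route: dropping route(s) with < 2 survivors: ",
            paste(small, collapse = ", "), call. = FALSE)
    d <- d[!(d$route %in% small), , drop = FALSE]
  }
  if (length(unique(d$route)) < 2)
    stop("duration_by_route: need >= 2 route classes with >= 2 survivors",
         call. = FALSE)
  d$route <- factor(d$route)
  fit <- stats::aov(nsog_to_qcs_days ~ route, data = d)
  tab <- summary(fit)[[1]]
  f_p <- anova_f_p(tab)
  per_route <- do.call(rbind, lapply(split(d, d$route), function(g)
    data.frame(route = as.character(g$route[1]), n = nrow(g),
               mean_days = mean(g$nsog_to_qcs_days),
               sd_days = stats::sd(g$nsog_to_qcs_days),
               stringsAsFactors = FALSE)))
  rownames(per_route) <- NULL
  telemetry_test(
    "duration_by_route_anova", statistic = c(F = f_p[1]),
    p_value = f_p[2], n = nrow(d),
    estimates = stats::setNames(per_route$mean_days,
                                paste0("mean_", per_route$route)),
    groups = levels(d$route),
    extra = list(tukey = stats::TukeyHSD(fit)$route, summary = per_route)
  )
}

#' Run the full descriptive test battery on a set of route records
#'
#' Convenience wrapper applying each test of the battery per species where
#' applicable; failures on degenerate inputs are recorded, not fatal.
#'
#' @param records Route records ([build_route_records()]).
#' @param geom Entry-array geometry.
#' @return A list with `results` (one data.frame row per test) and
#'   `tallies` (per-group route proportions).
#' @export
run_route_stats <- function(records, geom) {
  tallies <- route_tallies(records)
  results <- list()
  add <- function(label, expr) {
    r <- tryCatch(suppressWarnings(expr), error = function(e) e)
    if (inherits(r, "error")) {
      results[[label]] <<- data.frame(
        test_name = label, statistic = NA_real_, p_value = NA_real_,
        n = NA_integer_, estimates = paste("error:", conditionMessage(r)),
        groups = "", stringsAsFactors = FALSE)
    } else {
      row <- as.data.frame(r)
      row$test_name <- label
      results[[label]] <<- row
    }
  }
  species <- intersect(SPECIES_LEVELS, unique(records$species))
  for (sp in species) {
    rs <- records[records$species == sp & records$route != "JUAN_DE_FUCA" &
                    !is.na(records$p_initial), , drop = FALSE]
    add(paste0(sp, ".strait_use"), strait_use_test(rs$p_initial, geom))
    add(paste0(sp, ".drift1_zero"), signed_rank_zero_test(rs$drift1_km))
    add(paste0(sp, ".dx12_zero"), signed_rank_zero_test(rs$dx12_km))
    add(paste0(sp, ".dx23_zero"), signed_rank_zero_test(rs$dx23_km))
    add(paste0(sp, ".dx12_vs_duration_kendall"),
        kendall_tau(rs$duration12_h, abs(rs$dx12_km)))
    tl <- tallies[tallies$species == sp & !is.na(tallies$p_linear), ,
                  drop = FALSE]
    long <- data.frame(
      route = rep(c("LINEAR", "COUNTERCLOCKWISE", "CLOCKWISE"),
                  each = nrow(tl)),
      proportion = c(tl$p_linear, tl$p_counter, tl$p_clockwise),
      weight = rep(tl$n_classified, 3),
      group = rep(paste(tl$population, tl$release_year), 3),
      stringsAsFactors = FALSE)
    add(paste0(sp, ".route_proportion_anova"), route_proportion_anova(long))
    surv_strait <- table(factor(rs$initial_strait,
                                levels = c("MALASPINA", "SOG")),
                         factor(rs$survived_qcs, levels = c(TRUE, FALSE)))
    add(paste0(sp, ".survival_by_strait_fisher"), fisher_2x2(surv_strait))
    add(paste0(sp, ".duration_by_route"), duration_by_route(rs))
  }
  if (length(species) == 2) {
    a <- records[records$species == species[1] & !is.na(records$dx12_km), ]
    b <- records[records$species == species[2] & !is.na(records$dx12_km), ]
    if (nrow(a) && nrow(b)) {
      add("dx12_between_species", ranksum_test(a$dx12_km, b$dx12_km, species))
      ta <- tallies[tallies$species == species[1], "p_counter"]
      tb <- tallies[tallies$species == species[2], "p_counter"]
      add("counter_prop_between_species",
          species_proportion_ttest(ta, tb, species))
    }
  }
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  list(results = out, tallies = tallies,
       big_westward = big_westward_tally(records),
       confounds = confound_correlations(records))
}
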