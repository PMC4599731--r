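geom <- nsog_geometry()

test_that("strait-use binomial test against the width-weighted null", {
  near_null <- strait_use_test(c(rep(3, 26), rep(15, 74)), geom)
  expect_equal(unname(near_null$estimates["expected_prop"]), 7 / 27)
  expect_gt(near_null$p_value, 0.5)
  skew <- strait_use_test(c(rep(3, 66), rep(15, 34)), geom)
  expect_equal(unname(skew$estimates["observed_prop"]), 0.66)
  expect_lt(skew$p_value, 1e-6)
  none <- strait_use_test(rep(20, 10), geom)
  expect_equal(unname(none$estimates["observed_prop"]), 0)
  expect_error(strait_use_test(integer(0), geom), "no initial positions")
  # oracle agreement on small cohorts
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    pos <- sample(1:27, n, replace = TRUE)
    got <- strait_use_test(pos, geom)
    k <- sum(pos <= 7)
    expect_equal(got$p_value, oracle_binom_p(k, n, 7 / 27), tolerance = 1e-12)
  }
})

test_that("uniformity chi-square across receivers", {
  flat <- uniformity_test(1:27, geom)
  expect_equal(unname(flat$statistic), 0)
  expect_equal(flat$p_value, 1)
  point <- uniformity_test(rep(13, 54), geom)
  expect_lt(point$p_value, 1e-10)
})

test_that("signed-rank zero test matches enumeration and handles zeros", {
  all_neg <- signed_rank_zero_test(-(1:5))
  expect_equal(unname(all_neg$statistic), 0)
  expect_equal(all_neg$p_value, oracle_signed_rank_p(-(1:5)))
  expect_equal(all_neg$p_value, 2 / 32)
  sym <- signed_rank_zero_test(c(-1, 1))
  expect_equal(sym$p_value, 1)
  expect_warning(deg <- signed_rank_zero_test(c(0, 0, 0)), "zero")
  expect_equal(deg$p_value, 1)
  set.seed(2)
  for (rep in 1:20) {
    v <- round(stats::rnorm(sample(3:8, 1)), 3)
    v <- v[v != 0]
    if (length(v) < 2 || any(duplicated(abs(v)))) next
    got <- signed_rank_zero_test(v)
    expect_equal(got$p_value, oracle_signed_rank_p(v), tolerance = 1e-12)
  }
})

test_that("rank-sum test matches enumeration", {
  sep <- ranksum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(sep$statistic), 0)
  expect_equal(sep$p_value, 0.1)
  expect_equal(sep$p_value, oracle_ranksum_p(c(1, 2, 3), c(4, 5, 6)))
  ident <- ranksum_test(c(1, 2, 3), c(1, 2, 3))
  expect_gt(ident$p_value, 0.99)
  tiny <- ranksum_test(1, 2)
  expect_equal(tiny$p_value, 1)
  expect_error(ranksum_test(numeric(0), 1), "nonempty")
  set.seed(3)
  for (rep in 1:20) {
    a <- round(stats::rnorm(sample(2:5, 1)), 3)
    b <- round(stats::rnorm(sample(2:5, 1)) + 0.5, 3)
    if (any(duplicated(c(a, b)))) next
    got <- ranksum_test(a, b)
    expect_equal(got$p_value, oracle_ranksum_p(a, b), tolerance = 1e-12)
  }
})

test_that("Kendall tau matches brute-force pair counting", {
  conc <- kendall_tau(1:5, c(2, 4, 6, 8, 10))
  expect_equal(unname(conc$estimates["tau"]), 1)
  mid <- kendall_tau(1:4, c(1, 3, 2, 4))
  expect_equal(unname(mid$estimates["tau"]), 4 / 6, tolerance = 1e-12)
  rev <- kendall_tau(1:4, 4:1)
  expect_equal(unname(rev$estimates["tau"]), -1)
  expect_error(kendall_tau(rep(1, 4), 1:4), "zero variance")
  set.seed(4)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    x <- sample(100, n); y <- sample(100, n)
    got <- kendall_tau(x, y)
    orc <- oracle_kendall(x, y, exact_p = n <= 6)
    expect_equal(unname(got$estimates["tau"]), orc$tau, tolerance = 1e-12)
    if (n <= 6) expect_equal(got$p_value, orc$p, tolerance = 1e-12)
  }
})

test_that("weighted route-proportion ANOVA and Tukey HSD", {
  ident <- data.frame(
    route = rep(c("LINEAR", "COUNTERCLOCKWISE", "CLOCKWISE"), each = 3),
    proportion = rep(c(0.3, 0.4, 0.3), 3),
    weight = 10, group = rep(paste0("g", 1:3), 3))
  r <- route_proportion_anova(ident)
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 1)

  set.seed(5)
  sep <- data.frame(
    route = rep(c("LINEAR", "COUNTERCLOCKWISE", "CLOCKWISE"), each = 11),
    proportion = c(stats::rnorm(11, 0.65, 0.03),
                   stats::rnorm(11, 0.24, 0.03),
                   stats::rnorm(11, 0.11, 0.03)),
    weight = sample(10:100, 33, replace = TRUE),
    group = rep(paste0("g", 1:11), 3))
  r2 <- route_proportion_anova(sep)
  expect_lt(r2$p_value, 0.001)
  tukey <- r2$extra
  expect_lt(tukey["LINEAR-COUNTERCLOCKWISE", "p adj"], 0.001)
  expect_lt(tukey["LINEAR-CLOCKWISE", "p adj"], 0.001)

  two <- ident[ident$route != "CLOCKWISE", ]
  r3 <- route_proportion_anova(two)
  expect_equal(nrow(r3$extra), 1)       # one pairwise row
  expect_error(route_proportion_anova(ident[c(1, 4, 7), ]), ">= 2")
})

test_that("between-species Welch t-test on group proportions", {
  ident <- species_proportion_ttest(c(0.2, 0.3, 0.4), c(0.2, 0.3, 0.4))
  expect_equal(ident$p_value, 1)
  expect_equal(unname(ident$statistic), 0)
  # vectors constructed at stated moments; compare to closed-form Welch t
  a <- as.numeric(scale(1:11)) * 0.14 + 0.25
  b <- as.numeric(scale(1:10)) * 0.10 + 0.41
  got <- species_proportion_ttest(a, b)
  t_closed <- (mean(a) - mean(b)) /
    sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  expect_equal(unname(got$statistic), t_closed, tolerance = 1e-12)
  expect_lt(got$p_value, 0.02)
  const <- species_proportion_ttest(rep(0.3, 3), c(0.1, 0.5, 0.4))
  expect_true(is.finite(const$p_value))
  expect_error(species_proportion_ttest(0.5, c(0.1, 0.2)), ">= 2 groups")
})

test_that("Fisher exact test matches hypergeometric enumeration", {
  even <- fisher_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(unname(even$statistic), 1, tolerance = 1e-6)
  expect_equal(even$p_value, 1)
  diag <- fisher_2x2(matrix(c(0, 5, 5, 0), 2))
  expect_equal(diag$p_value, 2 / 252, tolerance = 1e-9)
  expect_warning(zero <- fisher_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_equal(zero$p_value, 1)
  set.seed(6)
  for (rep in 1:20) {
    m <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    got <- fisher_2x2(m)
    expect_equal(got$p_value, oracle_fisher_p(m), tolerance = 1e-9)
  }
})

test_that("confounding correlations report Pearson r per covariate", {
  rec <- data.frame(
    p_initial = 1:10, arrival_julian = c(2, 4, 6, 8, 10, 12, 14, 16, 18, 20),
    duration12_h = NA_real_,
    entry_to_nsog_days = 2 * (1:10),
    survived_qcs = rep(c(TRUE, FALSE), 5),
    nsog_to_qcs_days = 11:20)
  out <- suppressWarnings(confound_correlations(rec))
  r1 <- out[out$variable == "p_initial" &
              out$against == "entry_to_nsog_days", ]
  expect_equal(r1$r, 1)
  expect_false(any(out$variable == "duration12_h"))   # all missing: skipped
  x <- c(1, 2, 3, 4); y <- c(1, 2, 4, 3)
  r_closed <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  rec2 <- data.frame(p_initial = x, arrival_julian = NA_integer_,
                     duration12_h = NA_real_, entry_to_nsog_days = y,
                     survived_qcs = FALSE, nsog_to_qcs_days = NA_real_)
  out2 <- suppressWarnings(confound_correlations(rec2))
  expect_equal(out2$r[1], r_closed, tolerance = 1e-12)
  expect_equal(out2$r[1], 0.8, tolerance = 1e-12)
})

test_that("big westward displacements are tallied per species", {
  rec <- data.frame(
    species = c("sockeye", "sockeye", "sockeye", "steelhead"),
    dx12_km = c(-0.8, -11.2, 9.6, -8.0),
    dx12_spans_texada = c(FALSE, TRUE, FALSE, FALSE))
  out <- big_westward_tally(rec)
  so <- out[out$species == "sockeye", ]
  expect_equal(so$n_multi, 3)
  expect_equal(so$n_big_westward, 1)    # spanning counts, eastward excluded
  st <- out[out$species == "steelhead", ]
  expect_equal(st$n_big_westward, 1)    # exactly at the 8 km threshold
  small <- big_westward_tally(data.frame(
    species = "sockeye", dx12_km = c(-0.8, -0.8),
    dx12_spans_texada = FALSE))
  expect_equal(small$n_big_westward, 0)
})

test_that("transit-duration ANOVA across routes", {
  base <- data.frame(
    survived_qcs = TRUE,
    route = rep(c("LINEAR", "COUNTERCLOCKWISE"), each = 30),
    nsog_to_qcs_days = 12)
  flat <- duration_by_route(base)
  expect_equal(unname(flat$statistic), 0)
  expect_equal(flat$p_value, 1)

  set.seed(8)
  base$nsog_to_qcs_days <- c(stats::rnorm(30, 11.2, 3.4),
                             stats::rnorm(30, 15.5, 4.1))
  r <- duration_by_route(base)
  expect_lt(r$p_value, 0.001)
  diffs <- r$extra$summary
  gap <- diffs$mean_days[diffs$route == "COUNTERCLOCKWISE"] -
    diffs$mean_days[diffs$route == "LINEAR"]
  expect_equal(gap, 4.3, tolerance = 1.5)
  single <- base[base$route == "LINEAR", ]
  expect_error(suppressWarnings(duration_by_route(single)), ">= 2 route")
})
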