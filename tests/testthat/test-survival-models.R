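fake_records <- function(n = 120, species = "sockeye",
                         populations = c("Chilko", "Cultus"),
                         years = c(2012L, 2013L), seed = 99) {
  set.seed(seed)
  data.frame(
    tag_id = sprintf("T%03d", 1:n), species = species,
    population = sample(populations, n, replace = TRUE),
    release_year = sample(years, n, replace = TRUE),
    fork_length_mm = stats::rnorm(n, 150, 15),
    route = sample(c("LINEAR", "COUNTERCLOCKWISE", "CLOCKWISE",
                     "UNCLASSIFIED"), n, replace = TRUE),
    p_initial = sample(1:27, n, replace = TRUE),
    arrival_julian = sample(120:170, n, replace = TRUE),
    dx12_km = c(stats::rnorm(n - 10, -5, 5), rep(NA, 10)),
    duration12_h = c(stats::rexp(n - 10, 1 / 70), rep(NA, 10)),
    survived_qcs = stats::runif(n) < 0.4,
    stringsAsFactors = FALSE)
}

test_that("2-SD standardization centres and halves the scale", {
  expect_equal(standardize(c(1, 2, 3)), c(-0.5, 0, 0.5))
  z <- standardize(stats::rnorm(50, 10, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 0.5, tolerance = 1e-12)
  expect_error(standardize(rep(2, 5), name = "flat"), "flat")
  expect_error(standardize(1), "at least 2")
})

test_that("AICc formula and its guard", {
  expect_equal(aicc(-10, 2, 100), 24 + 12 / 97)
  expect_equal(aicc(-10, 2, 1e9), 24, tolerance = 1e-6)
  expect_error(aicc(-10, 2, 3), "n > k")
})

test_that("logistic fits match closed forms and the Newton oracle", {
  y <- rep(c(1, 0), c(30, 70))
  f <- fit_logistic(character(0), data.frame(survived = y))
  expect_equal(unname(f$coef), stats::qlogis(0.3), tolerance = 1e-8)
  expect_equal(f$loglik, 100 * (0.3 * log(0.3) + 0.7 * log(0.7)),
               tolerance = 1e-8)
  expect_equal(f$k, 1)

  # 2x2 closed-form log-odds: x=1 group has 4x the odds
  d <- data.frame(survived = rep(c(1, 0, 1, 0), c(10, 20, 20, 10)),
                  x = rep(c(0, 0, 1, 1), c(10, 20, 20, 10)))
  f2 <- fit_logistic("x", d)
  expect_equal(unname(f2$coef["x"]), log(4), tolerance = 1e-6)

  set.seed(13)
  d3 <- data.frame(x = stats::rnorm(40))
  d3$survived <- as.integer(stats::runif(40) < stats::plogis(0.5 * d3$x))
  f3 <- fit_logistic("x", d3)
  orc <- oracle_logistic_mle(d3$survived, d3$x)
  expect_equal(unname(f3$coef), orc$coef, tolerance = 1e-6)
  expect_equal(f3$loglik, orc$loglik, tolerance = 1e-8)

  const <- fit_logistic(character(0), data.frame(survived = rep(1, 20)))
  expect_true(const$separation)
  sep <- data.frame(survived = rep(c(0, 1), each = 10),
                    x = rep(c(-1, 1), each = 10))
  expect_true(fit_logistic("x", sep)$separation)
})

test_that("McFadden pseudo-R2 and its adjustment", {
  fake <- list(loglik = -50, k = 2)
  r <- pseudo_r2(fake, -100)
  expect_equal(unname(r["r2"]), 0.5)
  expect_equal(unname(r["adj_r2"]), 0.48)
  expect_lte(r["adj_r2"], r["r2"])
  expect_error(pseudo_r2(fake, 0), "zero")
})

test_that("all-subsets enumeration respects marginality", {
  expect_length(all_subsets(c("A", "B", "C")), 8)
  withint <- all_subsets(c("A", "B"), "A:B")
  expect_length(withint, 5)
  expect_equal(withint[[1]], character(0))
  expect_true(list(c("A", "B", "A:B")) %in% withint ||
                any(vapply(withint, function(s)
                  setequal(s, c("A", "B", "A:B")), logical(1))))
  expect_false(any(vapply(withint, function(s)
    "A:B" %in% s && !all(c("A", "B") %in% s), logical(1))))
  expect_length(all_subsets(character(0)), 1)
  expect_error(all_subsets("A", "A:B"), "missing from mains")

  # brute-force validation at the largest term-set size used
  mains <- c("a", "b", "c", "d", "e")
  ints <- c("a:b", "c:d")
  got <- all_subsets(mains, ints)
  all_terms <- c(mains, ints)
  count <- 0
  for (mask in 0:(2^7 - 1)) {
    s <- all_terms[as.logical(bitwAnd(mask, 2^(0:6)))]
    if (subset_respects_marginality(s, ints)) count <- count + 1
  }
  expect_length(got, count)
  expect_false(any(duplicated(vapply(got, function(s)
    paste(sort(s), collapse = "+"), character(1)))))
})

fake_fit <- function(terms, aicc, coef = NULL, se = NULL) {
  structure(list(terms = terms, coef = coef, se = se, aicc = aicc,
                 loglik = -aicc / 2, k = length(coef), n = 100,
                 converged = TRUE, separation = FALSE),
            class = "route_glm")
}

test_that("AICc ranking produces deltas and normalized weights", {
  fits <- rank_models(list(fake_fit("A", 100), fake_fit("B", 101)))
  expect_equal(vapply(fits, function(f) f$delta_aicc, numeric(1)), c(0, 1))
  w <- vapply(fits, function(f) f$weight, numeric(1))
  expect_equal(w, c(1, exp(-0.5)) / (1 + exp(-0.5)), tolerance = 1e-12)
  expect_equal(sum(w), 1)
  single <- rank_models(list(fake_fit("A", 50)))
  expect_equal(single[[1]]$weight, 1)
  tied <- rank_models(list(fake_fit("A", 10), fake_fit("B", 10)))
  expect_equal(vapply(tied, function(f) f$weight, numeric(1)), c(0.5, 0.5))
  expect_error(rank_models(list()), "empty")
})

test_that("model averaging: zero substitution and unconditional SE", {
  f1 <- fake_fit("A", 100, coef = c("(Intercept)" = 0.2, A = 1.0),
                 se = c("(Intercept)" = 0.1, A = 0.3))
  f2 <- fake_fit(character(0), 101, coef = c("(Intercept)" = 0.1),
                 se = c("(Intercept)" = 0.1))
  avg <- model_average(rank_models(list(f1, f2)))
  w1 <- 1 / (1 + exp(-0.5))
  a_row <- avg$coefficients[avg$coefficients$coefficient == "A", ]
  expect_equal(a_row$estimate, w1 * 1.0, tolerance = 1e-12)
  expect_equal(a_row$n_models, 1)
  # unconditional SE: present model contributes sampling + shrinkage,
  # absent model contributes |0 - estimate|
  est <- w1 * 1.0
  se_exp <- w1 * sqrt(0.3^2 + (1 - est)^2) + (1 - w1) * abs(0 - est)
  expect_equal(a_row$se, se_exp, tolerance = 1e-12)
  expect_equal(a_row$ci_lower, est - 1.96 * se_exp, tolerance = 1e-12)
  expect_equal(a_row$estimate_conditional, 1.0, tolerance = 1e-12)

  only <- model_average(rank_models(list(f1)))
  expect_equal(only$coefficients$estimate,
               unname(f1$coef[only$coefficients$coefficient]))

  f3 <- fake_fit("A", 100.5, coef = c("(Intercept)" = 0.2, A = 1.0),
                 se = c("(Intercept)" = 0.1, A = 0.3))
  same <- model_average(rank_models(list(f1, f3)))
  a2 <- same$coefficients[same$coefficients$coefficient == "A", ]
  expect_equal(a2$estimate, 1.0, tolerance = 1e-12)
  expect_equal(a2$se, 0.3, tolerance = 1e-12)   # no between-model variance
})

test_that("entry model set: term lists differ by species", {
  rec <- fake_records()
  so <- build_entry_set(rec, "sockeye")
  expect_setequal(so$mains, c("p_initial", "julian", "population"))
  expect_setequal(so$interactions,
                  c("population:julian", "population:p_initial"))
  expect_false(any(c("fl", "year") %in% so$mains))

  rec_st <- fake_records(species = "steelhead",
                         populations = c("Cheakamus", "Englishman"))
  st <- build_entry_set(rec_st, "steelhead")
  expect_setequal(st$mains,
                  c("p_initial", "julian", "fl", "population", "year"))
  # 16 subsets without the population term + 36 with it (each interaction
  # needs population and its continuous parent): 52 candidate models
  expect_length(all_subsets(st$mains, st$interactions), 52)

  one_pop <- fake_records(populations = "Chilko")
  expect_warning(single <- build_entry_set(one_pop, "sockeye"),
                 "single population")
  expect_false("population" %in% single$mains)
  expect_length(single$interactions, 0)
  # standardized continuous predictors
  expect_equal(mean(so$data$p_initial), 0, tolerance = 1e-12)
  expect_equal(stats::sd(so$data$p_initial), 0.5, tolerance = 1e-12)
})

test_that("lateral model set: multi-sequence fish only, Seymour excluded", {
  rec_st <- fake_records(species = "steelhead",
                         populations = c("Cheakamus", "Seymour"))
  expect_warning(st <- build_lateral_set(rec_st, "steelhead"),
                 "single population")
  expect_false("Seymour" %in% levels(st$data$population))
  expect_equal(nrow(st$data),
               sum(rec_st$population == "Cheakamus" & !is.na(rec_st$dx12_km)))
  so <- build_lateral_set(fake_records(), "sockeye")
  expect_setequal(so$mains, c("dx12", "duration", "population"))
  expect_setequal(so$interactions,
                  c("population:dx12", "population:duration"))
  expect_equal(nrow(so$data), sum(!is.na(fake_records()$dx12_km)))
})

test_that("candidate-set fitting ranks, averages and predicts", {
  rec <- fake_records(n = 200)
  fitted <- suppressWarnings(fit_candidate_set(build_entry_set(rec, "sockeye")))
  rk <- fitted$ranking
  expect_equal(nrow(rk), length(all_subsets(
    fitted$model_set$mains, fitted$model_set$interactions)))
  expect_equal(rk$delta_aicc[1], 0)
  expect_equal(sum(rk$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(rk$aicc) >= 0))
  expect_true(all(rk$adj_r2 <= rk$r2))
  cf <- fitted$averaged$coefficients
  expect_true(all(cf$ci_lower <= cf$estimate & cf$estimate <= cf$ci_upper))

  pred <- predict_survival(fitted, "julian")
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))
  expect_equal(sort(unique(pred$population)),
               levels(fitted$model_set$data$population))
  sc <- fitted$model_set$scaling$julian
  expect_equal(pred$x_natural, pred$x * 2 * sc["sd"] + sc["mean"],
               ignore_attr = TRUE)
  w <- testthat::capture_warnings(
    predict_survival(fitted, "julian", grid = c(-99, 0)))
  expect_true(any(grepl("truncated", w)))
})

test_that("flat and monotone prediction curves from known coefficients", {
  d <- data.frame(survived = rep(0:1, 50))
  ms <- structure(list(
    species = "sockeye", set = "entry",
    data = cbind(d, x = standardize(stats::rnorm(100, 5, 2))),
    mains = "x", interactions = character(0),
    scaling = list(x = c(mean = 5, sd = 2))), class = "survival_model_set")
  fitted <- fit_candidate_set(ms)
  # overwrite averaged coefficients with a pure intercept of known value
  fitted$averaged$coefficients <- data.frame(
    coefficient = c("(Intercept)", "x"), estimate = c(stats::qlogis(0.3), 0))
  flat <- predict_survival(fitted, "x")
  expect_equal(flat$prob, rep(0.3, nrow(flat)), tolerance = 1e-12)
  fitted$averaged$coefficients$estimate <- c(0, 2)
  up <- predict_survival(fitted, "x")
  expect_true(all(diff(up$prob) > 0))
  fitted$averaged$coefficients$estimate <- c(0, 0)
  half <- predict_survival(fitted, "x")
  expect_equal(half$prob, rep(0.5, nrow(half)))
})
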