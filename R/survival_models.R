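#' Standardize a predictor by twice its standard deviation
#'
#' Centres by the mean and divides by two sample standard deviations
#' (n - 1 denominator), so that a one-unit change corresponds to a move of
#' 2 SD and binary and continuous predictors are on comparable scales.
#' The result has mean 0 and SD 0.5.
#'
#' @param x Numeric vector, n >= 2, non-constant.
#' @param name Variable name used in error messages.
#' @return Standardized numeric vector.
#' @export
standardize <- function(x, name = deparse(substitute(x))) {
  x <- as.numeric(x)
  if (sum(!is.na(x)) < 2)
    stop("standardize: need at least 2 non-missing values in ", name,
         call. = FALSE)
  s <- stats::sd(x, na.rm = TRUE)
  if (s == 0)
    stop("standardize: variable '", name, "' is constant (SD = 0)",
         call. = FALSE)
  (x - mean(x, na.rm = TRUE)) / (2 * s)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters (including the intercept).
#' @param n Number of observations.
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0)
    stop("aicc: requires n > k + 1 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit one candidate binomial survival model
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares (deviance convergence tolerance 1e-8). Non-convergence and
#' quasi-complete separation (fitted probabilities within 1e-8 of 0 or 1)
#' are flagged; flagged fits are excluded from model averaging.
#'
#' @param terms Character vector of model terms (empty for intercept-only);
#'   interactions as `"a:b"`.
#' @param data Data.frame containing the response and all term variables.
#' @param response Name of the 0/1 response column.
#' @return An object of class `route_glm`: the fitted model plus AICc
#'   bookkeeping (`loglik`, `k`, `n`, `aicc`, `converged`, `separation`).
#' @export
fit_logistic <- function(terms, data, response = "survived") {
  formula <- if (length(terms))
    stats::reformulate(terms, response = response)
  else stats::reformulate("1", response = response)
  fit <- suppressWarnings(stats::glm(
    formula, family = stats::binomial(), data = data,
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  mu <- stats::fitted(fit)
  separation <- any(mu < 1e-8 | mu > 1 - 1e-8)
  ll <- as.numeric(stats::logLik(fit))
  k <- length(stats::coef(fit))
  n <- stats::nobs(fit)
  structure(
    list(terms = terms, formula = formula, fit = fit,
         coef = stats::coef(fit),
         se = sqrt(diag(stats::vcov(fit))),
         loglik = ll, k = k, n = n,
         aicc = if (n - k - 1 > 0) aicc(ll, k, n) else NA_real_,
         converged = fit$converged, separation = separation),
    class = "route_glm"
  )
}

#' @export
print.route_glm <- function(x, ...) {
  cat("Binomial survival model: ",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "(intercept only)",
      "\n", sep = "")
  cat("  logLik ", round(x$loglik, 3), "  k ", x$k, "  n ", x$n,
      "  AICc ", round(x$aicc, 3), "\n", sep = "")
  if (x$separation) cat("  [flagged: separation]\n")
  if (!x$converged) cat("  [flagged: non-convergence]\n")
  invisible(x)
}

#' McFadden pseudo-R-squared
#'
#' `R2 = 1 - logLik/logLik_null`; adjusted version penalises by the
#' parameter count: `1 - (logLik - k)/logLik_null`.
#'
#' @param fit A `route_glm`.
#' @param null_loglik Log-likelihood of the intercept-only model on the
#'   same data.
#' @return Named vector `c(r2, adj_r2)`.
#' @export
pseudo_r2 <- function(fit, null_loglik) {
  if (null_loglik == 0)
    stop("pseudo_r2: null log-likelihood is zero", call. = FALSE)
  c(r2 = 1 - fit$loglik / null_loglik,
    adj_r2 = 1 - (fit$loglik - fit$k) / null_loglik)
}

#' Enumerate all candidate term subsets respecting marginality
#'
#' Every subset of the supplied main effects and interactions (including
#' the intercept-only model) in which each interaction's parent main
#' effects are present. Deterministic ordering: by term count, then
#' lexicographically on the collapsed term string.
#'
#' @param mains Character vector of main-effect names.
#' @param interactions Character vector of interactions (`"a:b"`), each
#'   parent listed in `mains`.
#' @return List of character vectors of terms (first element:
#'   `character(0)`, the intercept-only model).
#' @export
all_subsets <- function(mains, interactions = character(0)) {
  terms <- c(mains, interactions)
  parents <- lapply(interactions, function(i)
    strsplit(i, ":", fixed = TRUE)[[1]])
  if (length(interactions)) {
    bad <- !vapply(parents, function(p) all(p %in% mains), logical(1))
    if (any(bad))
      stop("all_subsets: interaction parent(s) missing from mains: ",
           paste(interactions[bad], collapse = ", "), call. = FALSE)
  }
  nt <- length(terms)
  subsets <- list(character(0))
  if (nt > 0) {
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), nt))
    keep <- apply(grid, 1, function(inc) {
      present <- terms[unlist(inc)]
      for (j in seq_along(interactions)) {
        if (interactions[j] %in% present &&
            !all(parents[[j]] %in% present)) return(FALSE)
      }
      TRUE
    })
    subsets <- apply(grid[keep, , drop = FALSE], 1,
                     function(inc) terms[unlist(inc)], simplify = FALSE)
  }
  key <- vapply(subsets, function(s) paste(sort(s), collapse = "+"),
                character(1))
  ord <- order(lengths(subsets), key)
  unname(subsets[ord])
}

#' Rank fitted candidate models by AICc
#'
#' Adds `delta_aicc` (difference from the best model) and Akaike weights
#' `w = exp(-delta/2) / sum(exp(-delta/2))` to a list of fits.
#'
#' @param fits List of `route_glm` fits (all on the same data).
#' @return The list, sorted by AICc, each element gaining `delta_aicc` and
#'   `weight`.
#' @export
rank_models <- function(fits) {
  if (length(fits) == 0) stop("rank_models: empty candidate set",
                              call. = FALSE)
  aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
  delta <- aiccs - min(aiccs)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  for (i in seq_along(fits)) {
    fits[[i]]$delta_aicc <- delta[i]
    fits[[i]]$weight <- w[i]
  }
  fits[order(aiccs)]
}

#' Average coefficients across the near-best candidate models
#'
#' Over all models with `delta_aicc <= delta_max` (weights renormalized
#' within the set), computes for every coefficient the full
#' (zero-substitution) average `sum(w_i b_i)` with `b_i = 0` where the
#' term is absent, the unconditional standard error including
#' between-model variance
#' (`sum(w_i * sqrt(se_i^2 + (b_i - bbar)^2))`), and the Wald 95%
#' confidence interval. Conditional (subset) averages over only the
#' models containing each term are emitted alongside.
#'
#' @param ranked_fits Output of [rank_models()].
#' @param delta_max Inclusion threshold on `delta_aicc` (default 2).
#' @return An object of class `averaged_model`: a data.frame of averaged
#'   coefficients plus the candidate subset used.
#' @export
model_average <- function(ranked_fits, delta_max = 2) {
  set <- Filter(function(f) f$delta_aicc <= delta_max, ranked_fits)
  if (length(set) == 0)
    stop("model_average: no models within delta AICc <= ", delta_max,
         call. = FALSE)
  w <- vapply(set, function(f) f$weight, numeric(1))
  w <- w / sum(w)
  coef_names <- unique(unlist(lapply(set, function(f) names(f$coef))))
  rows <- lapply(coef_names, function(cn) {
    b <- vapply(set, function(f)
      if (cn %in% names(f$coef)) unname(f$coef[cn]) else 0, numeric(1))
    se <- vapply(set, function(f)
      if (cn %in% names(f$coef)) unname(f$se[cn]) else 0, numeric(1))
    present <- vapply(set, function(f) cn %in% names(f$coef), logical(1))
    est <- sum(w * b)
    use <- sum(w * sqrt(se^2 + (b - est)^2))
    wc <- w[present] / sum(w[present])
    est_c <- sum(wc * b[present])
    use_c <- sum(wc * sqrt(se[present]^2 + (b[present] - est_c)^2))
    data.frame(
      coefficient = cn, estimate = est, se = use,
      ci_lower = est - 1.96 * use, ci_upper = est + 1.96 * use,
      estimate_conditional = est_c, se_conditional = use_c,
      n_models = sum(present), stringsAsFactors = FALSE)
  })
  structure(
    list(coefficients = do.call(rbind, rows), weights = w,
         models = lapply(set, function(f) f$terms),
         delta_max = delta_max),
    class = "averaged_model"
  )
}

#' @export
print.averaged_model <- function(x, ...) {
  cat("Model-averaged coefficients (", length(x$models),
      " model(s) with delta AICc <= ", x$delta_max, ")\n", sep = "")
  print(x$coefficients, digits = 4, row.names = FALSE)
  invisible(x)
}

# shared subset/standardization logic for the two model sets
prepare_model_data <- function(records, species, vars, drop_populations = NULL) {
  d <- records[records$species == species &
                 records$route != "JUAN_DE_FUCA", , drop = FALSE]
  if (length(drop_populations))
    d <- d[!(d$population %in% drop_populations), , drop = FALSE]
  for (v in vars) d <- d[!is.na(d[[v]]), , drop = FALSE]
  pop_n <- table(d$population)
  small <- names(pop_n)[pop_n < 2]
  if (length(small)) {
    warning("dropping population(s) with < 2 records: ",
            paste(small, collapse = ", "), call. = FALSE)
    d <- d[!(d$population %in% small), , drop = FALSE]
  }
  d
}

finish_model_set <- function(d, species, set, continuous, source_cols) {
  data <- data.frame(survived = as.integer(d$survived_qcs))
  scaling <- list()
  for (i in seq_along(continuous)) {
    v <- continuous[i]; src <- source_cols[i]
    x <- d[[src]]
    scaling[[v]] <- c(mean = mean(x), sd = stats::sd(x))
    data[[v]] <- standardize(x, name = v)
  }
  data$population <- factor(d$population)
  data$year <- factor(d$release_year)
  mains <- continuous
  interactions <- character(0)
  if (nlevels(data$population) >= 2) {
    mains <- c(mains, "population")
    int_with <- intersect(c("julian", "p_initial", "dx12", "duration"),
                          continuous)
    interactions <- paste0("population:", int_with)
  } else {
    warning("single population; population terms and interactions dropped",
            call. = FALSE)
  }
  if (species == "steelhead") {
    if (nlevels(data$year) >= 2) mains <- c(mains, "year")
    else warning("single release year; year term dropped", call. = FALSE)
  }
  structure(
    list(species = species, set = set, data = data, mains = mains,
         interactions = interactions, scaling = scaling,
         tag_id = d$tag_id),
    class = "survival_model_set"
  )
}

#' Build the entry-metrics candidate model set
#'
#' Survival to the downstream curtain modelled from metrics of a smolt's
#' arrival at the entry curtain, using every smolt detected there: entry
#' receiver position, day-of-year of arrival, and (steelhead only) fork
#' length and release year, plus natal population and its interactions
#' with day-of-year and entry position. Fork length and release year are
#' excluded for sockeye (collinear with population). Continuous
#' predictors are 2-SD standardized.
#'
#' @param records Route records ([build_route_records()]).
#' @param species `"sockeye"` or `"steelhead"`.
#' @return A `survival_model_set`: data plus full term lists.
#' @export
build_entry_set <- function(records, species = c("sockeye", "steelhead")) {
  species <- match.arg(species)
  vars <- c("p_initial", "arrival_julian",
            if (species == "steelhead") "fork_length_mm")
  d <- prepare_model_data(records, species, vars)
  continuous <- c("p_initial", "julian",
                  if (species == "steelhead") "fl")
  source_cols <- c("p_initial", "arrival_julian",
                   if (species == "steelhead") "fork_length_mm")
  finish_model_set(d, species, "entry", continuous, source_cols)
}

#' Build the lateral-movement candidate model set
#'
#' Survival modelled from east-west movement after first arrival, using
#' smolts with at least two detection sequences at the entry curtain:
#' the first-to-second displacement, the duration between the first two
#' sequences, and (steelhead only) fork length and release year, plus
#' population and its interactions with displacement and duration.
#' Steelhead from the Seymour population (too few multi-sequence fish)
#' are excluded.
#'
#' @inheritParams build_entry_set
#' @return A `survival_model_set`.
#' @export
build_lateral_set <- function(records, species = c("sockeye", "steelhead")) {
  species <- match.arg(species)
  vars <- c("dx12_km", "duration12_h",
            if (species == "steelhead") "fork_length_mm")
  drop_pop <- if (species == "steelhead") "Seymour" else NULL
  d <- prepare_model_data(records, species, vars, drop_populations = drop_pop)
  continuous <- c("dx12", "duration",
                  if (species == "steelhead") "fl")
  source_cols <- c("dx12_km", "duration12_h",
                   if (species == "steelhead") "fork_length_mm")
  finish_model_set(d, species, "lateral", continuous, source_cols)
}

#' Fit, rank and average a candidate model set
#'
#' Enumerates every marginality-respecting subset of the set's terms
#' ([all_subsets()]), fits each by [fit_logistic()], ranks converged
#' unseparated fits by AICc and averages coefficients over the
#' `delta AICc <= delta_max` subset ([model_average()]).
#'
#' @param model_set A `survival_model_set` from [build_entry_set()] or
#'   [build_lateral_set()].
#' @param delta_max Averaging threshold (default 2).
#' @return A list: `ranking` (data.frame with terms, r2, adj_r2, logLik,
#'   k, AICc, delta_aicc, weight per model), `fits`, `averaged`
#'   (an `averaged_model`), `model_set`.
#' @export
fit_candidate_set <- function(model_set, delta_max = 2) {
  specs <- all_subsets(model_set$mains, model_set$interactions)
  fits <- lapply(specs, fit_logistic, data = model_set$data)
  ok <- vapply(fits, function(f)
    f$converged && !f$separation && !is.na(f$aicc), logical(1))
  if (any(!ok))
    warning(sum(!ok), " candidate model(s) flagged (separation or ",
            "non-convergence) and excluded from ranking", call. = FALSE)
  if (!any(ok)) stop("no usable candidate models", call. = FALSE)
  ranked <- rank_models(fits[ok])
  null_ll <- fit_logistic(character(0), model_set$data)$loglik
  ranking <- do.call(rbind, lapply(ranked, function(f) {
    r2 <- pseudo_r2(f, null_ll)
    data.frame(
      model = if (length(f$terms)) paste(f$terms, collapse = " + ")
      else "(intercept)",
      r2 = unname(r2["r2"]), adj_r2 = unname(r2["adj_r2"]),
      loglik = f$loglik, k = f$k, n = f$n, aicc = f$aicc,
      delta_aicc = f$delta_aicc, weight = f$weight,
      stringsAsFactors = FALSE)
  }))
  rownames(ranking) <- NULL
  list(ranking = ranking, fits = ranked,
       averaged = model_average(ranked, delta_max),
       model_set = model_set)
}

#' Predicted survival probability along one model-averaged effect
#'
#' Inverse-logit of the averaged linear predictor along a grid of one
#' continuous variable, other continuous covariates held at their means
#' (standardized 0). When the set contains a population term, one curve
#' per population is produced, each restricted to that population's
#' observed range of the variable; a user grid extending beyond the
#' observed range is truncated with a warning.
#'
#' @param fitted_set Output of [fit_candidate_set()].
#' @param variable Name of the standardized continuous variable (e.g.
#'   `"julian"`, `"p_initial"`, `"duration"`).
#' @param grid Optional numeric grid on the standardized scale; default
#'   51 points over the observed range.
#' @param length.out Grid resolution when `grid` is `NULL`.
#' @return Data.frame `population`, `x` (standardized), `x_natural`
#'   (original units), `prob`.
#' @export
predict_survival <- function(fitted_set, variable, grid = NULL,
                             length.out = 51) {
  ms <- fitted_set$model_set
  data <- ms$data
  if (!variable %in% names(data) || !is.numeric(data[[variable]]))
    stop("predict_survival: unknown continuous variable '", variable, "'",
         call. = FALSE)
  avg <- fitted_set$averaged$coefficients
  beta <- stats::setNames(avg$estimate, avg$coefficient)
  has_pop <- "population" %in% ms$mains
  pops <- if (has_pop) levels(data$population) else NA_character_
  full_terms <- c(ms$mains, ms$interactions)
  rhs <- stats::reformulate(if (length(full_terms)) full_terms else "1")
  out <- list()
  for (pop in pops) {
    obs <- if (has_pop) data[data$population == pop, variable]
    else data[[variable]]
    rng <- range(obs)
    g <- if (is.null(grid)) seq(rng[1], rng[2], length.out = length.out)
    else grid
    if (any(g < rng[1] | g > rng[2])) {
      warning("grid truncated to the observed range of ", variable,
              if (has_pop) paste0(" for population ", pop), call. = FALSE)
      g <- g[g >= rng[1] & g <= rng[2]]
    }
    nd <- data.frame(row.names = seq_along(g))
    for (v in intersect(ms$mains, names(data)))
      if (is.numeric(data[[v]])) nd[[v]] <- 0
    nd[[variable]] <- g
    if (has_pop)
      nd$population <- factor(pop, levels = levels(data$population))
    if ("year" %in% ms$mains)
      nd$year <- factor(levels(data$year)[1], levels = levels(data$year))
    mm <- stats::model.matrix(rhs, nd)
    b <- stats::setNames(rep(0, ncol(mm)), colnames(mm))
    common <- intersect(names(b), names(beta))
    b[common] <- beta[common]
    lp <- drop(mm %*% b)
    sc <- ms$scaling[[variable]]
    out[[length(out) + 1]] <- data.frame(
      population = pop, x = g,
      x_natural = g * 2 * sc["sd"] + sc["mean"],
      prob = stats::plogis(lp), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
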