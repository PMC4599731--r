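# Hand-built fixtures and brute-force oracles, independent of the package
# code paths they check.

UTC0 <- as.POSIXct("2013-05-01 00:00:00", tz = "UTC")

det_frame <- function(receivers, gap_hours, tag = "T1", array = "NSOG",
                      start = UTC0) {
  stopifnot(length(gap_hours) == length(receivers) - 1)
  times <- start + cumsum(c(0, gap_hours)) * 3600
  data.frame(tag_id = tag, array = array,
             receiver_index = as.integer(receivers), timestamp = times,
             stringsAsFactors = FALSE)
}

# --- sequencer oracles ------------------------------------------------------

# rule check for one adjacent pair, straight from the definitions
pair_ok <- function(t1, t2, r1, r2, geom, max_gap_hours = 1.0,
                    max_step_km = 1.6) {
  gap <- as.numeric(difftime(t2, t1, units = "hours"))
  step <- abs(receiver_chainage(geom, r2) - receiver_chainage(geom, r1))
  (gap < max_gap_hours) && (step <= max_step_km)
}

# segmentation implied by checking every adjacent pair independently
oracle_pairwise_segments <- function(det, geom, ...) {
  n <- nrow(det)
  if (n == 1) return(rep(1L, 1))
  ok <- vapply(seq_len(n - 1), function(i)
    pair_ok(det$timestamp[i], det$timestamp[i + 1],
            det$receiver_index[i], det$receiver_index[i + 1], geom, ...),
    logical(1))
  cumsum(c(TRUE, !ok))
}

# coarsest valid partition found by full enumeration of boundary placements
oracle_enum_segments <- function(det, geom, ...) {
  n <- nrow(det)
  if (n == 1) return(rep(1L, 1))
  best <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    breaks <- as.logical(bitwAnd(mask, 2^(0:(n - 2))))
    seg <- cumsum(c(TRUE, breaks))
    valid <- TRUE
    for (i in seq_len(n - 1)) {
      if (seg[i] == seg[i + 1] &&
          !pair_ok(det$timestamp[i], det$timestamp[i + 1],
                   det$receiver_index[i], det$receiver_index[i + 1],
                   geom, ...)) {
        valid <- FALSE
        break
      }
    }
    if (valid && (is.null(best) || max(seg) < max(best))) best <- seg
  }
  best
}

random_detection_string <- function(n, geom, tag = "T1") {
  gaps <- stats::runif(n - 1, 0, 2)                  # hours, straddles 1 h
  steps <- sample(-3:3, n, replace = TRUE)
  recs <- pmin(pmax(cumsum(c(sample(1:27, 1), steps[-1])), 1), 27)
  det_frame(recs, gaps, tag = tag)
}

# --- exact-test enumeration oracles ----------------------------------------

oracle_binom_p <- function(k, n, p0) {
  d <- stats::dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# exact signed-rank two-sided p by enumerating all sign patterns
oracle_signed_rank_p <- function(v) {
  stopifnot(all(v != 0), !any(duplicated(abs(v))))
  n <- length(v)
  r <- rank(abs(v))
  V_obs <- sum(r[v > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Vs <- apply(signs, 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(Vs <= V_obs), mean(Vs >= V_obs)))
}

# exact Mann-Whitney two-sided p by enumerating rank assignments
oracle_ranksum_p <- function(a, b) {
  stopifnot(!any(duplicated(c(a, b))))
  na <- length(a); nb <- length(b)
  u_of <- function(x, y) sum(outer(x, y, ">"))
  U_obs <- u_of(a, b)
  pool <- c(a, b)
  sets <- utils::combn(na + nb, na)
  Us <- apply(sets, 2, function(ix) u_of(pool[ix], pool[-ix]))
  min(1, 2 * min(mean(Us <= U_obs), mean(Us >= U_obs)))
}

# Fisher exact two-sided p by hypergeometric enumeration over fixed margins
oracle_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  probs <- stats::dhyper(lo:hi, r1, r2, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Kendall tau-b and (untied) exact p by brute-force pair counting
oracle_kendall <- function(x, y, exact_p = FALSE) {
  n <- length(x)
  conc <- disc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) conc <- conc + 1
    if (s < 0) disc <- disc + 1
  }
  tie_x <- sum(vapply(table(x), function(t) t * (t - 1) / 2, numeric(1)))
  tie_y <- sum(vapply(table(y), function(t) t * (t - 1) / 2, numeric(1)))
  n0 <- n * (n - 1) / 2
  tau <- (conc - disc) / sqrt((n0 - tie_x) * (n0 - tie_y))
  out <- list(tau = tau, T = conc)
  if (exact_p) {
    stopifnot(!any(duplicated(x)), !any(duplicated(y)))
    perms <- perms_of(n)
    ys <- y[order(y)]
    Ts <- apply(perms, 1, function(p) {
      cc <- 0
      yy <- ys[p]
      xx <- sort(x)
      for (i in 1:(n - 1)) for (j in (i + 1):n)
        if (sign(xx[j] - xx[i]) * sign(yy[j] - yy[i]) > 0) cc <- cc + 1
      cc
    })
    out$p <- min(1, 2 * min(mean(Ts <= conc), mean(Ts >= conc)))
  }
  out
}

perms_of <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- perms_of(n - 1)
  do.call(rbind, lapply(1:n, function(k)
    cbind(k, sub + (sub >= k))))
}

# Newton maximisation of the logistic log-likelihood, <= 2 parameters
oracle_logistic_mle <- function(y, x = NULL, tol = 1e-12, maxit = 200) {
  X <- if (is.null(x)) matrix(1, length(y), 1) else cbind(1, x)
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(X, y - mu))
    H <- crossprod(X * (mu * (1 - mu)), X)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  loglik <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  list(coef = as.numeric(beta), loglik = loglik)
}

# marginality checker used to validate all_subsets by brute force
subset_respects_marginality <- function(subset, interactions) {
  for (i in interactions) {
    if (i %in% subset &&
        !all(strsplit(i, ":", fixed = TRUE)[[1]] %in% subset)) return(FALSE)
  }
  TRUE
}

# --- small simulation configs ----------------------------------------------

tiny_groups <- function(n = 100, species = "sockeye", population = "Chilko",
                        tag_model = "V9", year = 2013) {
  data.frame(species = species, population = population, origin = "W",
             n = n, fl_mean_mm = 150, fl_sd_mm = 10, release_year = year,
             tag_model = tag_model, stringsAsFactors = FALSE)
}
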