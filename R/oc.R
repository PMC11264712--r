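# Operating-characteristics engines: bootstrap resampling of a cohort's
# pairwise INMB values, and Monte-Carlo simulation studies over a grid of
# maximum sample sizes.

#' Resample observation paths from a cohort
#'
#' Builds bootstrap observation paths from a cohort's pairwise INMB
#' values. Each path draws two resamples (with replacement) of the whole
#' cohort, concatenates them, and randomly orders the result into
#' sequential blocks; a path of length `t_max = 2 * n` uses all of it,
#' and a path of length `t_max = n` uses the first half of the same
#' randomly sorted data set, so the shorter path is a prefix of the
#' longer one for a given draw.
#'
#' @param x Numeric vector of cohort pairwise INMB values (one per pair).
#' @param t_max Path length: the cohort size or twice the cohort size
#'   (other lengths require `allow_any = TRUE`).
#' @param n_paths Number of paths (default 5000).
#' @param seed Optional integer seed.
#' @param allow_any Permit path lengths other than `n` and `2n`.
#' @return Matrix with `n_paths` rows and `t_max` columns.
#' @export
resample_paths <- function(x, t_max, n_paths = 5000, seed = NULL,
                           allow_any = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  if (!allow_any && !t_max %in% c(n, 2L * n))
    stop("'t_max' must equal the cohort size (", n, ") or twice it; ",
         "set allow_any = TRUE to override", call. = FALSE)
  full <- 2L * n
  paths <- matrix(NA_real_, n_paths, full)
  for (i in seq_len(n_paths)) {
    draw <- c(x[sample.int(n, n, replace = TRUE)],
              x[sample.int(n, n, replace = TRUE)])
    paths[i, ] <- draw[sample.int(full)]
  }
  paths[, seq_len(min(t_max, full)), drop = FALSE]
}

# Vectorised sequential monitoring of many paths at once. Returns per-path
# stopping epoch (NA if never), total pairs, and final posterior mean.
# Equivalent to looping run_trial over the rows (tested against it).
.monitor_paths <- function(paths, design, schedule) {
  params <- design$params; prior <- design$prior
  b <- design$boundary
  cs <- t(apply(paths, 1, cumsum))
  mun <- sweep(cs[, schedule, drop = FALSE] + prior$n0 * prior$mu0, 2,
               prior$n0 + schedule, "/")
  up <- b$upper[schedule]; lo <- b$lower[schedule]
  out <- sweep(mun, 2, up, ">=") | sweep(mun, 2, lo, "<=")
  out[is.na(out)] <- TRUE      # no continuation region at that epoch
  first <- apply(out, 1, function(r) { i <- which(r)[1]
                                       if (is.na(i)) NA_integer_ else i })
  n_stop <- schedule[first]
  total <- ifelse(is.na(n_stop), params$t_max,
                  pmin(n_stop + params$tau, params$t_max))
  idx <- cbind(seq_len(nrow(paths)), total)
  mu_final <- (prior$n0 * prior$mu0 + cs[idx]) / (prior$n0 + total)
  data.frame(n_stop = n_stop, total_pairs = total, mu_final = mu_final)
}

#' Operating characteristics of sequential versus fixed designs
#'
#' Runs the value-based sequential design and a fixed sample-size design
#' over a set of observation paths and summarises the distribution of the
#' final posterior mean, the sample size, the adoption decision and the
#' variable-cost saving of the sequential design.
#'
#' @param paths Matrix of pairwise INMB paths (one row per path), e.g.
#'   from [resample_paths()] or Gaussian streams.
#' @param design A [vb_design()] object.
#' @param schedule Decision epochs, from [interim_schedule()].
#' @param fixed_n Sample size of the fixed comparator (defaults to
#'   `t_max`).
#' @return An object of class `"vb_oc"`: a list of two summary data
#'   frames (`fixed`, `sequential`) and the per-path results.
#' @export
run_oc <- function(paths, design,
                   schedule = interim_schedule(design$params$t_max,
                                               design$params$tau),
                   fixed_n = design$params$t_max) {
  params <- design$params; prior <- design$prior
  seq_res <- .monitor_paths(paths, design, schedule)
  csf <- if (fixed_n > 0) rowSums(paths[, seq_len(fixed_n), drop = FALSE]) else 0
  mu_fixed <- (prior$n0 * prior$mu0 + csf) / (prior$n0 + fixed_n)
  smr <- function(mu, n) {
    data.frame(
      mu_final_mean = mean(mu), mu_final_sd = stats::sd(mu),
      mu_final_min = min(mu), mu_final_max = max(mu),
      pairs_mean = mean(n), pairs_sd = stats::sd(n),
      pairs_min = min(n), pairs_max = max(n),
      prop_adopt_N = mean(params$P * mu > params$I))
  }
  out <- list(fixed = smr(mu_fixed, rep(fixed_n, nrow(paths))),
              sequential = smr(seq_res$mu_final, seq_res$total_pairs),
              saving_variable = (fixed_n - mean(seq_res$total_pairs)) *
                params$c_pair,
              prop_stop_early = mean(!is.na(seq_res$n_stop)),
              paths = seq_res, fixed_mu = mu_fixed, fixed_n = fixed_n)
  class(out) <- "vb_oc"
  out
}

#' @export
print.vb_oc <- function(x, ...) {
  cat("Operating characteristics over", nrow(x$paths), "paths\n")
  cat(sprintf("  fixed design (n = %d):  E[mu_final] = %.1f (sd %.1f), P(adopt N) = %.3f\n",
              x$fixed_n, x$fixed$mu_final_mean, x$fixed$mu_final_sd,
              x$fixed$prop_adopt_N))
  cat(sprintf("  sequential:  E[mu_final] = %.1f (sd %.1f), P(adopt N) = %.3f\n",
              x$sequential$mu_final_mean, x$sequential$mu_final_sd,
              x$sequential$prop_adopt_N))
  cat(sprintf("  sequential sample size: mean %.1f (sd %.1f, range %d-%d)\n",
              x$sequential$pairs_mean, x$sequential$pairs_sd,
              x$sequential$pairs_min, x$sequential$pairs_max))
  cat(sprintf("  early stopping in %.1f%% of paths; expected variable-cost saving GBP %s\n",
              100 * x$prop_stop_early,
              format(round(x$saving_variable), big.mark = ",")))
  invisible(x)
}

#' Simulation study over a grid of maximum sample sizes
#'
#' For each maximum sample size, solves the stopping boundary, simulates
#' `reps` trials with pairwise INMB drawn i.i.d. from
#' `Normal(mean, sd^2)`, monitors them on the standard interim schedule,
#' and summarises the expected sample size and the proportion of trials
#' recruiting to the maximum.
#'
#' @param t_max_values Vector of maximum pairwise allocations.
#' @param reps Simulated trials per value (default 5000).
#' @param mean,sd Gaussian INMB model for the simulated streams.
#' @param params A [vb_params()] object (its `t_max` is overridden).
#' @param prior A [vb_prior()] object.
#' @param dp A [dp_config()]; large horizons need a fine grid step.
#' @param seed Optional integer seed.
#' @param batch Paths simulated per memory batch.
#' @return Data frame with one row per `t_max`: `t_max`, `pairs_mean`,
#'   `ratio` (mean over `t_max`), `prop_reach_max`, `pairs_sd`,
#'   `mu_final_mean`, `prop_adopt_N`, plus Monte-Carlo standard errors
#'   `se_pairs` and `se_reach`.
#' @export
tmax_grid_study <- function(t_max_values, reps = 5000, mean = -45, sd = 7615,
                            params = vb_params(), prior = vb_prior(),
                            dp = dp_config(mu_grid_step = 10), seed = NULL,
                            batch = 1000) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(t_max_values, function(tm) {
    p <- params; p$t_max <- as.integer(tm)
    des <- vb_design(p, prior, dp, thresholds = FALSE)
    schedule <- interim_schedule(tm, p$tau)
    need <- tm
    tot <- mu <- numeric(0); nst <- integer(0)
    left <- reps
    while (left > 0) {
      nb <- min(batch, left)
      paths <- matrix(stats::rnorm(nb * need, mean, sd), nb, need)
      res <- .monitor_paths(paths, des, schedule)
      tot <- c(tot, res$total_pairs); mu <- c(mu, res$mu_final)
      nst <- c(nst, res$n_stop)
      left <- left - nb
    }
    reach <- tot == tm
    data.frame(t_max = tm, pairs_mean = base::mean(tot),
               ratio = base::mean(tot) / tm,
               prop_reach_max = base::mean(reach),
               pairs_sd = stats::sd(tot),
               mu_final_mean = base::mean(mu),
               prop_adopt_N = base::mean(params$P * mu > params$I),
               se_pairs = stats::sd(tot) / sqrt(reps),
               se_reach = sqrt(base::mean(reach) * (1 - base::mean(reach)) / reps))
  })
  do.call(rbind, rows)
}

#' Simulate trials from a solved design
#'
#' [simulate()] method for [vb_design()] objects: draws `nsim` Gaussian
#' INMB trials under the design's own model and returns their operating
#' characteristics.
#'
#' @param object A [vb_design()] object.
#' @param nsim Number of simulated trials.
#' @param seed Optional integer seed.
#' @param mean,sd Gaussian INMB model (defaults: the prior mean and the
#'   sampling SD of the design's prior specification).
#' @param ... Unused.
#' @return A `"vb_oc"` object.
#' @export
simulate.vb_design <- function(object, nsim = 1000, seed = NULL,
                               mean = object$prior$mu0,
                               sd = object$prior$sigma_x, ...) {
  if (!is.null(seed)) set.seed(seed)
  tm <- object$params$t_max
  paths <- matrix(stats::rnorm(nsim * tm, mean, sd), nsim, tm)
  run_oc(paths, object)
}

#' Six-month follow-up variant
#'
#' Re-derives the design for a halved follow-up delay (six months rather
#' than twelve): the pipeline shrinks to `tau = round(recruit_rate / 2)`
#' pairs, the boundary is re-solved, and the operating characteristics
#' are re-evaluated on simulated streams from the same INMB model.
#'
#' @param params A [vb_params()] object (the 12-month design).
#' @param prior A [vb_prior()] object.
#' @param reps Simulated trials.
#' @param mean,sd Gaussian INMB model.
#' @param dp A [dp_config()].
#' @param seed Optional integer seed.
#' @return A list with the re-derived `params`, the `design`, and the
#'   operating characteristics `oc`.
#' @export
six_month_variant <- function(params = vb_params(), prior = vb_prior(),
                              reps = 1000, mean = -45, sd = prior$sigma_x,
                              dp = dp_config(), seed = NULL) {
  p2 <- vb_params(lambda_wtp = params$lambda_wtp,
                  annual_incidence = params$annual_incidence,
                  horizon_years = params$horizon_years,
                  P = params$P, I = params$I, c_pair = params$c_pair,
                  fixed_cost_pre = params$fixed_cost_pre,
                  fixed_cost_during = params$fixed_cost_during,
                  fixed_cost_post = params$fixed_cost_post,
                  delta_years = params$delta_years / 2,
                  recruit_rate = params$recruit_rate,
                  t_max = params$t_max, trial_days = params$trial_days)
  des <- vb_design(p2, prior, dp, thresholds = FALSE)
  oc <- simulate(des, nsim = reps, seed = seed, mean = mean, sd = sd)
  list(params = p2, design = des, oc = oc)
}
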