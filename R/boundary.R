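# Optimal-stopping boundary for the value-based sequential design, by
# backward induction on a posterior-mean grid, plus the design-selection
# thresholds (points A-D) and one-stage ENBS comparators.

#' Preposterior standard deviation of the posterior mean
#'
#' Standard deviation of the posterior mean of E\[INMB\] after `m`
#' further pairwise observations, given that `n` have been observed:
#' `sigma_x * sqrt(m / ((n0 + n) * (n0 + n + m)))`. This is the spread of
#' the predictive distribution of the future posterior mean around the
#' current one.
#'
#' @param n Pairs observed so far (may be a vector).
#' @param m Further pairs to be observed (may be a vector).
#' @param prior A [vb_prior()] object.
#' @return Standard deviation in GBP.
#' @export
preposterior_sd <- function(n, m, prior = vb_prior()) {
  t0 <- prior$n0 + n
  prior$sigma_x * sqrt(m / (t0 * (t0 + m)))
}

#' Expected value of stopping recruitment
#'
#' Expected reward of halting recruitment with `n` pairs observed and `m`
#' still in the pipeline: the pipeline outcomes will move the posterior
#' mean to `mu' ~ Normal(mu, s^2)` with `s = preposterior_sd(n, m)`, after
#' which the better technology is adopted, for an expected reward of
#' `E[max(P * mu' - I, 0)]`. Evaluated in closed form as
#' `P * ((mu - I/P) * pnorm(z) + s * dnorm(z))` with
#' `z = (mu - I/P) / s`.
#'
#' @param mu Current posterior mean of E\[INMB\] (GBP); vectorised.
#' @param n Pairs observed.
#' @param m Pairs remaining in the pipeline.
#' @param params A [vb_params()] object (uses `P` and `I`).
#' @param prior A [vb_prior()] object.
#' @return Expected reward in GBP.
#' @export
expected_stop_value <- function(mu, n, m, params = vb_params(),
                                prior = vb_prior()) {
  s <- preposterior_sd(n, m, prior)
  .stop_value(mu, s, params$P, params$I)
}

# closed-form E[max(P*mu' - I, 0)], mu' ~ N(mu, s^2); vectorised in mu and s
.stop_value <- function(mu, s, P, I) {
  len <- max(length(mu), length(s))
  d <- rep_len(mu - I / P, len)
  s <- rep_len(s, len)
  pos <- s > 0
  out <- P * pmax(d, 0)
  if (any(pos)) {
    z <- d[pos] / s[pos]
    out[pos] <- P * (d[pos] * stats::pnorm(z) + s[pos] * stats::dnorm(z))
  }
  out
}

#' Numerical configuration for the boundary solver
#'
#' The dynamic program is solved on a uniform grid of posterior means.
#' `mu_grid_step` controls accuracy: the default GBP 50 resolves the
#' boundary to a few tens of pounds for short designs, while long
#' horizons (hundreds to thousands of decision epochs) need a finer step
#' because discretisation error accumulates across backward-induction
#' sweeps once the one-step spread of the posterior mean falls below the
#' grid step (see the package vignette for the convergence study; GBP 10
#' is used for the shipped large-horizon analyses).
#'
#' @param mu_grid_half_width Half-width of the posterior-mean grid (GBP).
#'   Must comfortably cover the design-selection thresholds.
#' @param mu_grid_step Grid step (GBP); must be at most 100.
#' @param kernel_support Half-width of the Gaussian transition kernel in
#'   one-step standard deviations.
#' @param store_value Keep the full value surface (memory-heavy for long
#'   horizons; needed only for diagnostics such as Bellman residuals).
#' @return An object of class `"vb_dp_config"`.
#' @export
dp_config <- function(mu_grid_half_width = 60000, mu_grid_step = 50,
                      kernel_support = 6, store_value = FALSE) {
  if (mu_grid_step > 100) stop("'mu_grid_step' must be at most 100", call. = FALSE)
  if (mu_grid_half_width < 60 * mu_grid_step)
    stop("'mu_grid_half_width' must span at least 60 grid steps", call. = FALSE)
  structure(list(mu_grid_half_width = mu_grid_half_width,
                 mu_grid_step = mu_grid_step,
                 kernel_support = kernel_support,
                 store_value = store_value),
            class = "vb_dp_config")
}

# Transition weights for E[f(mu + v*Z)] on a uniform grid of step h, where
# f is the piecewise-linear interpolant of the grid values. The weight on
# offset k*h is the expectation of the triangular hat function centred
# there; the rule is exact for the interpolant at every v, including
# sub-grid v where the kernel degenerates towards the identity.
.transition_kernel <- function(v, h, support = 6) {
  K <- ceiling(support * v / h) + 1L
  t <- (-K:K) * h
  a <- (t - h) / v; b <- t / v; cc <- (t + h) / v
  w <- (v * (stats::dnorm(a) - stats::dnorm(b)) +
          (h - t) * (stats::pnorm(b) - stats::pnorm(a))) / h +
       ((t + h) * (stats::pnorm(cc) - stats::pnorm(b)) -
          v * (stats::dnorm(b) - stats::dnorm(cc))) / h
  w / sum(w)
}

# Backward induction over observed-pair epochs n = N-1, ..., 0 with
# N = t_max - tau. Terminal value at N is the stopping reward; interior
# value is max(stop, -c + E[V(n+1, mu')]). Returns the boundary (sign
# change of continue - stop), the epoch-0 value function, and optionally
# the full surface.
.solve_dp <- function(params, prior, dp) {
  N <- params$t_max - params$tau
  h <- dp$mu_grid_step
  mu <- seq(-dp$mu_grid_half_width, dp$mu_grid_half_width, by = h)
  G <- function(n, x) .stop_value(x, preposterior_sd(n, params$tau, prior),
                                  params$P, params$I)
  V <- G(N, mu)
  upper <- rep(NA_real_, N)
  lower <- rep(NA_real_, N)
  surface <- if (dp$store_value) vector("list", N + 1L) else NULL
  if (dp$store_value) surface[[N + 1L]] <- V
  for (n in (N - 1L):0L) {
    v1 <- preposterior_sd(n, 1, prior)
    w <- .transition_kernel(v1, h, dp$kernel_support)
    K <- (length(w) - 1L) %/% 2L
    ext <- c(G(n + 1L, mu[1L] - (K:1) * h), V,
             G(n + 1L, mu[length(mu)] + (1:K) * h))
    cont <- -params$c_pair +
      as.numeric(stats::filter(ext, w, sides = 2))[(K + 1L):(K + length(mu))]
    stp <- G(n, mu)
    V <- pmax(stp, cont)
    if (dp$store_value) surface[[n + 1L]] <- V
    if (n >= 1L) {
      d <- cont - stp
      inreg <- d > 0
      if (any(inreg)) {
        idx <- range(which(inreg))
        if (idx[1L] == 1L || idx[2L] == length(mu))
          stop("stopping boundary touches the grid edge at n = ", n,
               "; increase 'mu_grid_half_width'", call. = FALSE)
        i <- idx[2L]
        upper[n] <- mu[i] + h * d[i] / (d[i] - d[i + 1L])
        i <- idx[1L]
        lower[n] <- mu[i] - h * d[i] / (d[i] - d[i - 1L])
      } else {
        # stopping optimal everywhere at this epoch: no continuation region
        upper[n] <- NA_real_
        lower[n] <- NA_real_
      }
    }
  }
  list(mu_grid = mu, value0 = V, upper = upper, lower = lower, n_max = N,
       surface = surface)
}

#' One-stage expected net benefit of sampling
#'
#' Expected net benefit of running a fixed trial of `n_fixed` pairwise
#' allocations relative to deciding immediately on the prior: the value of
#' the information the trial will deliver, minus its variable cost
#' `c_pair * n_fixed` and any fixed costs charged to the design choice.
#'
#' @param n_fixed Fixed sample size in pairwise allocations (vectorised).
#' @param mu0 Prior mean of E\[INMB\] (GBP).
#' @param params A [vb_params()] object.
#' @param prior A [vb_prior()] object.
#' @param fixed_cost Fixed cost charged to the design comparison (GBP).
#'   The package compares designs on variable sampling costs by default;
#'   see the vignette for the rationale.
#' @return ENBS in GBP (vectorised over `n_fixed`).
#' @export
one_stage_enbs <- function(n_fixed, mu0, params = vb_params(),
                           prior = vb_prior(), fixed_cost = 0) {
  base <- pmax(params$P * mu0 - params$I, 0)
  ifelse(n_fixed == 0,
         -fixed_cost,
         expected_stop_value(mu0, 0, n_fixed, params, prior) - base -
           params$c_pair * n_fixed - fixed_cost)
}

# Best one-stage ENBS over a sample-size grid; returns net gain and argmax
.one_stage_best <- function(mu0, params, prior, n_search, fixed_cost = 0) {
  s <- preposterior_sd(0, n_search, prior)
  vapply(mu0, function(m) {
    gain <- .stop_value(m, s, params$P, params$I) -
      pmax(params$P * m - params$I, 0) - params$c_pair * n_search - fixed_cost
    i <- which.max(gain)
    c(enbs = gain[i], n_opt = n_search[i])
  }, numeric(2))
}

# Locate the design-selection thresholds A-D from the epoch-0 value
# function of the sequential design and the one-stage ENBS curve.
#   A/B: outermost prior means at which the best trial still beats
#        immediate adoption (one-stage ENBS crosses zero).
#   C/D: prior means at which the sequential design's net gain drops to
#        the one-stage optimum.
.design_thresholds <- function(sol, params, prior, n_search = 1:1000,
                               fixed_cost = 0) {
  mu <- sol$mu_grid
  one <- .one_stage_best(mu, params, prior, n_search, fixed_cost)
  one_net <- one["enbs", ]
  seq_net <- sol$value0 - params$c_pair * params$tau - fixed_cost -
    pmax(params$P * mu - params$I, 0)
  zero_at <- function(x, y, from_above) {
    # root of y(x) on the side where y falls through 0 moving outwards
    pos <- which(y > 0)
    if (!length(pos)) return(NA_real_)
    if (from_above) {             # outer positive root on the right
      i <- max(pos)
      if (i == length(x)) return(Inf)
      x[i] + (x[i + 1] - x[i]) * y[i] / (y[i] - y[i + 1])
    } else {
      i <- min(pos)
      if (i == 1L) return(-Inf)
      x[i] - (x[i] - x[i - 1]) * y[i] / (y[i] - y[i - 1])
    }
  }
  A <- zero_at(mu, one_net, TRUE)
  B <- zero_at(mu, one_net, FALSE)
  d <- seq_net - pmax(one_net, 0)
  C <- zero_at(mu, d, TRUE)
  D <- zero_at(mu, d, FALSE)
  list(A = A, B = B, C = C, D = D,
       one_stage = data.frame(mu0 = mu, enbs = one_net,
                              n_opt = one["n_opt", ],
                              seq_net = seq_net))
}

#' Solve a value-based sequential trial design
#'
#' Computes the Stage II stopping boundary by backward induction and the
#' prior-mean thresholds (points A--D) that separate the no-trial,
#' one-stage and sequential designs.
#'
#' At each decision epoch `n` (pairs observed; `n` runs from 1 to
#' `t_max - tau`), recruitment stops if the posterior mean of E\[INMB\]
#' lies on or outside the boundary. The value of stopping accounts for
#' the `tau` pipeline pairs still to be observed; the value of continuing
#' pays the variable cost of one more pairwise allocation and takes the
#' expectation of the next epoch's value over the one-observation
#' predictive distribution of the posterior mean.
#'
#' @param params A [vb_params()] object.
#' @param prior A [vb_prior()] object.
#' @param dp A [dp_config()] object controlling grid resolution.
#' @param thresholds Compute the design-selection thresholds (adds the
#'   one-stage ENBS sweep; disable for speed in pure simulation studies).
#' @param n_search Sample sizes searched for the one-stage optimum.
#' @return An object of class `"vb_design"` with components
#'   \describe{
#'     \item{boundary}{data frame `n`, `lower`, `upper` over decision
#'       epochs `1 .. t_max - tau` (`NA` where stopping is optimal for
#'       every posterior mean).}
#'     \item{thresholds}{list with `A`, `B`, `C`, `D` (GBP) and the
#'       one-stage ENBS sweep.}
#'     \item{value0}{expected-value function at epoch 0 over `mu_grid`.}
#'     \item{params, prior, dp}{the inputs.}
#'   }
#' @examples
#' \donttest{
#' des <- vb_design(vb_params(), vb_prior())
#' des
#' }
#' @export
vb_design <- function(params = vb_params(), prior = vb_prior(),
                      dp = dp_config(), thresholds = TRUE,
                      n_search = 1:1000) {
  sol <- .solve_dp(params, prior, dp)
  thr <- if (thresholds) .design_thresholds(sol, params, prior, n_search)
         else NULL
  structure(list(boundary = data.frame(n = seq_len(sol$n_max),
                                       lower = sol$lower,
                                       upper = sol$upper),
                 thresholds = thr,
                 value0 = sol$value0,
                 mu_grid = sol$mu_grid,
                 surface = sol$surface,
                 params = params, prior = prior, dp = dp),
            class = "vb_design")
}

#' Classify a prior mean against the design-selection thresholds
#'
#' @param design A [vb_design()] object (with thresholds).
#' @param mu0 Prior mean of E\[INMB\] (GBP).
#' @return One of `"no_trial_adopt_N"`, `"no_trial_keep_S"`,
#'   `"one_stage"`, `"sequential"`.
#' @export
classify_prior <- function(design, mu0) {
  thr <- design$thresholds
  if (is.null(thr)) stop("design was solved with thresholds = FALSE", call. = FALSE)
  if (mu0 > thr$A) "no_trial_adopt_N"
  else if (mu0 < thr$B) "no_trial_keep_S"
  else if (mu0 >= thr$C || mu0 <= thr$D) "one_stage"
  else "sequential"
}

#' @export
print.vb_design <- function(x, ...) {
  p <- x$params
  cat("Value-based sequential trial design\n")
  cat(sprintf("  maximum pairwise allocations: %d (pipeline tau = %d)\n",
              p$t_max, p$tau))
  cat(sprintf("  decision epochs: n = 1 .. %d observed pairs\n", p$t_max - p$tau))
  b <- x$boundary
  shown <- b[b$n %in% unique(pmin(c(20, 30, 40, p$t_max - p$tau), p$t_max - p$tau)), ]
  cat("  stopping boundary (GBP):\n")
  for (i in seq_len(nrow(shown)))
    cat(sprintf("    n = %3d: [%8.0f, %8.0f]\n", shown$n[i], shown$lower[i],
                shown$upper[i]))
  if (!is.null(x$thresholds))
    cat(sprintf("  design selection: sequential for mu0 in (%.0f, %.0f); no trial beyond (%.0f, %.0f)\n",
                x$thresholds$D, x$thresholds$C, x$thresholds$B, x$thresholds$A))
  invisible(x)
}

#' @export
summary.vb_design <- function(object, ...) {
  b <- object$boundary
  out <- list(t_max = object$params$t_max, tau = object$params$tau,
              n_epochs = nrow(b),
              boundary_range = range(b$upper, na.rm = TRUE),
              thresholds = object$thresholds[c("A", "B", "C", "D")])
  class(out) <- "summary.vb_design"
  out
}

#' @export
print.summary.vb_design <- function(x, ...) {
  cat("Value-based sequential design summary\n")
  cat(sprintf("  t_max %d, tau %d, %d decision epochs\n", x$t_max, x$tau, x$n_epochs))
  cat(sprintf("  upper boundary from GBP %.0f down to GBP %.0f\n",
              x$boundary_range[2], x$boundary_range[1]))
  if (!is.null(x$thresholds$A))
    cat(sprintf("  A = %.0f, B = %.0f, C = %.0f, D = %.0f\n",
                x$thresholds$A, x$thresholds$B, x$thresholds$C, x$thresholds$D))
  invisible(x)
}

#' Plot a stopping boundary
#'
#' Draws the Stage II stopping boundary over observed-pair epochs, with
#' the continuation region between the curves. A monitored trial path can
#' be overlaid with [lines()] on the returned coordinates or via
#' `plot(trial)` methods.
#'
#' @param x A [vb_design()] object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.vb_design <- function(x, ...) {
  b <- x$boundary
  ylim <- range(b$lower, b$upper, na.rm = TRUE)
  graphics::plot(b$n, b$upper, type = "l", ylim = ylim,
                 xlab = "pairs observed (n)",
                 ylab = "posterior mean of E[INMB] (GBP)",
                 main = "Value-based sequential stopping boundary", ...)
  graphics::lines(b$n, b$lower)
  graphics::abline(h = 0, lty = 3, col = "grey50")
  invisible(x)
}

#' Export and import a stopping boundary
#'
#' The boundary is written as CSV (`n, lower, upper`) with a JSON sidecar
#' carrying the design-selection thresholds and a hash of the generating
#' parameters, so a boundary file can be traced to its configuration.
#'
#' @param design A [vb_design()] object.
#' @param csv_path Path of the boundary CSV.
#' @param json_path Path of the JSON metadata file (defaults to
#'   `csv_path` with extension `.json`).
#' @return `write_boundary()` returns `csv_path` invisibly;
#'   `read_boundary()` returns a list with `boundary` (data frame) and
#'   `meta`.
#' @export
write_boundary <- function(design, csv_path,
                           json_path = sub("\\.csv$", ".json", csv_path)) {
  utils::write.csv(design$boundary, csv_path, row.names = FALSE)
  meta <- list(A = design$thresholds$A, B = design$thresholds$B,
               C = design$thresholds$C, D = design$thresholds$D,
               t_max = design$params$t_max, tau = design$params$tau,
               params_hash = config_hash(design$params),
               mu_grid_step = design$dp$mu_grid_step)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(csv_path)
}

#' @rdname write_boundary
#' @export
read_boundary <- function(csv_path,
                          json_path = sub("\\.csv$", ".json", csv_path)) {
  boundary <- utils::read.csv(csv_path)
  meta <- if (file.exists(json_path)) jsonlite::read_json(json_path) else NULL
  list(boundary = boundary, meta = meta)
}
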