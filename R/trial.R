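# Monitoring engine: run one value-based sequential trial against a
# solved boundary (Stage II interim analyses, Stage III pipeline
# follow-up, final adoption decision), and the fixed-design comparator.

#' Interim analysis schedule
#'
#' Decision epochs at which the posterior mean is compared with the
#' stopping boundary: the first after `first_interim` observed pairs
#' (data sparsity rules out an earlier multiply-imputed estimate), then
#' every `block` pairs, keeping only epochs at which recruitment is still
#' ongoing (`n + tau < t_max`).
#'
#' @param t_max Maximum pairwise allocations.
#' @param tau Pipeline delay in pairwise allocations.
#' @param first_interim Observed pairs at the first interim analysis.
#' @param block Pairs between successive interims.
#' @return Integer vector of decision epochs (observed-pair counts).
#' @examples
#' interim_schedule(124, 74)  # 20 30 40: three interim analyses
#' interim_schedule(248, 74)  # 16 interim analyses
#' @export
interim_schedule <- function(t_max, tau, first_interim = 20, block = 10) {
  if (first_interim < 1 || block < 1) stop("invalid schedule", call. = FALSE)
  n <- seq(first_interim, max(first_interim, t_max), by = block)
  n <- n[n + tau < t_max]
  if (!length(n))
    stop("no feasible interim analyses: t_max too close to tau", call. = FALSE)
  as.integer(n)
}

# posterior means at the requested epochs for a stream of pairwise INMB
.posterior_path <- function(x, epochs, prior) {
  cs <- cumsum(x)
  (prior$n0 * prior$mu0 + cs[epochs]) / (prior$n0 + epochs)
}

#' Run one value-based sequential trial
#'
#' Monitors a stream of pairwise INMB observations against the design's
#' stopping boundary. At each scheduled interim the posterior mean is
#' computed from all pairs observed so far; recruitment stops at the first
#' interim at which it lies on or outside the boundary. The `tau` pairs in
#' the pipeline are then followed up (entering the posterior in blocks of
#' 10 with a final partial block), and the technology is adopted if the
#' final posterior mean satisfies `P * mu > I`.
#'
#' @param x Numeric vector of pairwise INMB observations in arrival
#'   order, or a data frame of by-block estimates with columns `n_end`
#'   (cumulative pairs) and `estimate` (block mean), e.g. from
#'   [by_block_estimates()]. A vector must be long enough to cover the
#'   pipeline of any reachable stopping point.
#' @param design A [vb_design()] object.
#' @param schedule Decision epochs, from [interim_schedule()].
#' @return An object of class `"vb_trial"`: a list with the interim
#'   `trace` (data frame `n`, `mu`, `stopped`), `n_stop` (pairs observed
#'   at stopping; `NA` if the boundary was never crossed), `total_pairs`,
#'   `mu_final`, `decision` and `variable_cost`.
#' @examples
#' \donttest{
#' des <- vb_design(vb_params(), vb_prior())
#' set.seed(1)
#' x <- generate_inmb_stream(124, mean = -45, sd = 7615)
#' run_trial(x, des)
#' }
#' @export
run_trial <- function(x, design,
                      schedule = interim_schedule(design$params$t_max,
                                                  design$params$tau)) {
  params <- design$params; prior <- design$prior
  b <- design$boundary
  if (is.data.frame(x)) return(.run_trial_blocks(x, design, schedule))
  N <- params$t_max - params$tau
  if (any(schedule > N)) stop("schedule extends beyond t_max - tau", call. = FALSE)
  if (length(x) < min(max(schedule) + params$tau, params$t_max))
    stop("observation source exhausted before the schedule completes", call. = FALSE)
  mu_path <- .posterior_path(x, schedule, prior)
  up <- b$upper[schedule]; lo <- b$lower[schedule]
  out <- is.na(up) | mu_path >= up | mu_path <= lo
  k <- which(out)[1]
  n_stop <- if (is.na(k)) NA_integer_ else schedule[k]
  total <- if (is.na(k)) params$t_max else min(n_stop + params$tau, params$t_max)
  if (length(x) < total)
    stop("observation source exhausted before pipeline follow-up completes",
         call. = FALSE)
  trace_n <- if (is.na(k)) schedule else schedule[seq_len(k)]
  trace <- data.frame(n = trace_n, mu = mu_path[seq_along(trace_n)],
                      stopped = FALSE)
  if (!is.na(k)) trace$stopped[k] <- TRUE
  mu_final <- (prior$n0 * prior$mu0 + sum(x[seq_len(total)])) / (prior$n0 + total)
  structure(list(trace = trace, n_stop = n_stop, total_pairs = total,
                 mu_final = mu_final,
                 decision = adoption_decision(mu_final, params$P, params$I),
                 variable_cost = total * params$c_pair,
                 design = "sequential"),
            class = "vb_trial")
}

# monitoring driven by multiply-imputed by-block estimates
.run_trial_blocks <- function(blocks, design, schedule) {
  stopifnot(all(c("n_end", "estimate") %in% names(blocks)))
  params <- design$params; prior <- design$prior
  b <- design$boundary
  blocks <- blocks[order(blocks$n_end), ]
  n_end <- blocks$n_end
  sizes <- diff(c(0, n_end))
  cs <- cumsum(blocks$estimate * sizes)
  mu_at <- function(n) {
    i <- match(n, n_end)
    if (any(is.na(i)))
      stop("no block estimate ending at pair ", n[which(is.na(i))[1]], call. = FALSE)
    (prior$n0 * prior$mu0 + cs[i]) / (prior$n0 + n)
  }
  schedule <- schedule[schedule <= max(n_end)]
  if (!length(schedule))
    stop("observation source exhausted before the schedule completes", call. = FALSE)
  mu_path <- mu_at(schedule)
  up <- b$upper[schedule]; lo <- b$lower[schedule]
  out <- is.na(up) | mu_path >= up | mu_path <= lo
  k <- which(out)[1]
  n_stop <- if (is.na(k)) NA_integer_ else schedule[k]
  total <- if (is.na(k)) params$t_max else min(n_stop + params$tau, params$t_max)
  if (max(n_end) < total)
    stop("block estimates do not cover the pipeline follow-up", call. = FALSE)
  # final posterior from all blocks up to 'total' (exact cover required)
  mu_final <- mu_at(total)
  trace_n <- if (is.na(k)) schedule else schedule[seq_len(k)]
  trace <- data.frame(n = trace_n, mu = mu_path[seq_along(trace_n)],
                      stopped = FALSE)
  if (!is.na(k)) trace$stopped[k] <- TRUE
  structure(list(trace = trace, n_stop = n_stop, total_pairs = total,
                 mu_final = mu_final,
                 decision = adoption_decision(mu_final, params$P, params$I),
                 variable_cost = total * params$c_pair,
                 design = "sequential"),
            class = "vb_trial")
}

#' Run a fixed sample-size comparator trial
#'
#' No interim stopping: all `n_fixed` pairs are observed and the adoption
#' decision is taken from the resulting posterior mean.
#'
#' @param x Numeric vector of pairwise INMB observations.
#' @param n_fixed Fixed number of pairwise allocations.
#' @param params A [vb_params()] object.
#' @param prior A [vb_prior()] object.
#' @return A `"vb_trial"` object (with `n_stop = NA` and
#'   `total_pairs = n_fixed`).
#' @export
fixed_design <- function(x, n_fixed, params = vb_params(), prior = vb_prior()) {
  if (n_fixed > length(x))
    stop("observation source exhausted: need ", n_fixed, " pairs", call. = FALSE)
  mu_final <- if (n_fixed == 0) prior$mu0 else
    (prior$n0 * prior$mu0 + sum(x[seq_len(n_fixed)])) / (prior$n0 + n_fixed)
  structure(list(trace = data.frame(n = integer(), mu = numeric(),
                                    stopped = logical()),
                 n_stop = NA_integer_, total_pairs = as.integer(n_fixed),
                 mu_final = mu_final,
                 decision = adoption_decision(mu_final, params$P, params$I),
                 variable_cost = n_fixed * params$c_pair,
                 design = "fixed"),
            class = "vb_trial")
}

#' @export
print.vb_trial <- function(x, ...) {
  cat(sprintf("%s design trial\n",
              if (x$design == "fixed") "Fixed sample-size" else "Value-based sequential"))
  if (x$design != "fixed") {
    if (is.na(x$n_stop))
      cat("  boundary never crossed; recruited to the maximum\n")
    else
      cat(sprintf("  stopped at the interim with %d pairs observed\n", x$n_stop))
  }
  cat(sprintf("  total pairwise allocations: %d (%d patients)\n",
              x$total_pairs, 2L * x$total_pairs))
  cat(sprintf("  final posterior mean E[INMB]: GBP %.2f -> %s\n",
              x$mu_final, x$decision))
  cat(sprintf("  variable research cost: GBP %s\n",
              format(x$variable_cost, big.mark = ",")))
  invisible(x)
}

#' @export
as.data.frame.vb_trial <- function(x, ...) {
  data.frame(design = x$design,
             n_stop = x$n_stop,
             total_pairs = x$total_pairs,
             mu_final = x$mu_final,
             decision = x$decision,
             variable_cost = x$variable_cost)
}
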