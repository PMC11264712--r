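# Sequential multiple imputation of missing cost and utility fields at
# interim analyses, with by-block INMB estimates pooled by Rubin's rules.
#
# The imputer is a compact chained-equations scheme with the linear-normal
# ("norm") method: each incomplete variable is regressed on the other
# variables, regression parameters are drawn from their approximate
# posterior, and missing cells are replaced by draws from the resulting
# predictive distribution. Imputed utilities are censored to the EQ-5D
# range.

#' Multiple imputation configuration
#'
#' @param m Number of imputed data sets (default 5).
#' @param cycles Chained-equation sweeps per imputation (at least 5).
#' @param min_pairs Minimum pairs required before an interim estimate is
#'   attempted; chained equations are numerically unstable on fewer (an
#'   interim on 10 pairs fails for data sparsity).
#' @return An object of class `"vb_mi_config"`.
#' @export
mi_config <- function(m = 5, cycles = 10, min_pairs = 20) {
  if (m < 1) stop("'m' must be at least 1", call. = FALSE)
  if (cycles < 5) stop("'cycles' must be at least 5", call. = FALSE)
  structure(list(m = as.integer(m), cycles = as.integer(cycles),
                 min_pairs = as.integer(min_pairs)),
            class = "vb_mi_config")
}

# one posterior-draw linear-normal imputation pass for variable `v`
.impute_norm_draw <- function(df, v, predictors) {
  obs <- !is.na(df[[paste0(".orig_", v)]])
  form <- stats::reformulate(predictors, response = v)
  X <- stats::model.matrix(form, df)
  y <- df[[v]]
  fit <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
  keep <- !is.na(fit$coefficients)
  Xk <- X[, keep, drop = FALSE]
  qrk <- qr(Xk[obs, , drop = FALSE])
  beta <- qr.coef(qrk, y[obs])
  res <- y[obs] - Xk[obs, , drop = FALSE] %*% beta
  df_res <- max(sum(obs) - sum(keep), 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df_res)
  R <- qr.R(qrk)
  beta_star <- beta + backsolve(R, stats::rnorm(ncol(Xk))) * sqrt(sigma2)
  pred <- Xk[!obs, , drop = FALSE] %*% beta_star +
    stats::rnorm(sum(!obs), 0, sqrt(sigma2))
  df[[v]][!obs] <- pred
  df
}

#' Multiply impute missing fields in the records available at an interim
#'
#' Fills missing utilities and cost components by chained equations,
#' conditioning on arm, baseline covariates and the other observed
#' outcome fields. Observed cells are never altered; the `m` completed
#' data sets differ only in imputed cells. With no missing data the input
#' is returned unchanged `m` times.
#'
#' @param records Patient records available at the interim (data frame in
#'   the [read_patient_csv()] dialect).
#' @param cfg A [mi_config()] object.
#' @param seed Optional integer seed.
#' @return A list of `m` completed data frames.
#' @export
impute_interim <- function(records, cfg = mi_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fields <- intersect(c("u0", "u6", "u12", "cost_1", "cost_2",
                        grep("^cost_", names(records), value = TRUE)),
                      names(records))
  fields <- unique(fields)
  n_pairs <- min(sum(records$arm == "N"), sum(records$arm == "S"))
  has_miss <- fields[vapply(fields, function(f) anyNA(records[[f]]), logical(1))]
  if (!length(has_miss)) return(replicate(cfg$m, records, simplify = FALSE))
  if (n_pairs < cfg$min_pairs)
    stop("data sparsity: only ", n_pairs, " pairs available; at least ",
         cfg$min_pairs, " are required for a stable interim imputation",
         call. = FALSE)
  for (f in fields) {
    if (all(is.na(records[[f]])))
      stop("all values of '", f, "' are missing; cannot impute", call. = FALSE)
  }
  covs <- grep("^cov_", names(records), value = TRUE)
  work0 <- records
  work0$.arm_n <- as.numeric(records$arm == "N")
  lapply(seq_len(cfg$m), function(im) {
    work <- work0
    for (v in fields) work[[paste0(".orig_", v)]] <- records[[v]]
    # initialise missing cells with draws from the observed values
    for (v in has_miss) {
      mis <- is.na(work[[v]])
      work[[v]][mis] <- sample(work[[v]][!mis], sum(mis), replace = TRUE)
    }
    for (cy in seq_len(cfg$cycles)) {
      for (v in has_miss) {
        # arm, covariates, arm-by-covariate interactions (treatment effects
        # may vary with baseline state), and the other outcome fields
        predictors <- c(".arm_n", covs,
                        if (length(covs)) paste0(".arm_n:", covs),
                        setdiff(fields, v))
        work <- .impute_norm_draw(work, v, predictors)
      }
    }
    for (v in intersect(has_miss, c("u0", "u6", "u12")))
      work[[v]] <- pmin(pmax(work[[v]], -0.594), 1)
    work[, names(records)]
  })
}

#' By-block INMB estimate from multiply imputed data
#'
#' For a block of pairwise allocations, computes the mean pairwise INMB
#' within each completed data set and pools the per-imputation block
#' means by Rubin's rules. With complete data the estimate equals the
#' complete-data block mean exactly.
#'
#' @param imputations List of completed data frames from
#'   [impute_interim()].
#' @param block_start,block_end First and last pair index of the block.
#' @param lambda_wtp Willingness to pay per QALY.
#' @param delta_years Follow-up window in years.
#' @return A block-estimate list: `block_start`, `block_end`, `estimate`,
#'   `within_var`, `between_var`, `total_var`, `m_imputations`.
#' @export
by_block_estimates <- function(imputations, block_start, block_end,
                               lambda_wtp = 30000, delta_years = 1) {
  if (block_end < block_start) stop("empty block", call. = FALSE)
  per <- vapply(imputations, function(df) {
    x <- cohort_inmb(df, lambda_wtp, delta_years)
    if (block_end > length(x))
      stop("block extends beyond the available ", length(x), " pairs",
           call. = FALSE)
    xb <- x[block_start:block_end]
    c(mean(xb), stats::var(xb) / length(xb))
  }, numeric(2))
  pooled <- rubins_pool(per[1, ], per[2, ])
  c(list(block_start = block_start, block_end = block_end), pooled)
}

#' Monitor a cohort with sequential multiple imputation
#'
#' Runs the full interim pipeline on patient-level records: at each
#' scheduled interim, the records of the pairs followed up so far are
#' multiply imputed, the most recent block's INMB estimate is pooled by
#' Rubin's rules, the posterior over E\[INMB\] is updated blockwise, and
#' recruitment stops at the first boundary crossing. Pipeline pairs are
#' then imputed and appended the same way before the adoption decision.
#'
#' Imputation at an interim uses only records of pairs already followed
#' up at that interim (no future data enter any estimate).
#'
#' @param records Full cohort of patient records (in arrival order after
#'   pairing).
#' @param design A [vb_design()] object.
#' @param mi A [mi_config()] object.
#' @param schedule Decision epochs, from [interim_schedule()].
#' @param seed Optional integer seed (re-seeded per interim for
#'   reproducibility of each imputation step).
#' @return A `"vb_trial"` object; its `blocks` component holds the pooled
#'   by-block estimates.
#' @export
run_trial_mi <- function(records, design, mi = mi_config(),
                         schedule = interim_schedule(design$params$t_max,
                                                     design$params$tau),
                         seed = NULL) {
  params <- design$params; prior <- design$prior
  pairs <- pair_patients(records)
  n_avail <- nrow(pairs)
  if (max(schedule) > n_avail)
    stop("observation source exhausted before the schedule completes",
         call. = FALSE)
  blocks <- list()
  state <- posterior_init(prior)

  step_to <- function(n_end, k) {
    cut_rows <- sort(c(pairs$row_N[seq_len(n_end)],
                       pairs$row_S[seq_len(n_end)]))
    avail <- records[cut_rows, , drop = FALSE]
    imp <- impute_interim(avail, mi,
                          seed = if (is.null(seed)) NULL else seed + k)
    be <- by_block_estimates(imp, state$n + 1L, n_end,
                             params$lambda_wtp, params$delta_years)
    blocks[[length(blocks) + 1L]] <<- be
    state <<- update_posterior(state, be$estimate, prior,
                               size = n_end - state$n,
                               block_start = state$n + 1L)
  }

  # Stage II: interim monitoring with first-crossing stopping
  b <- design$boundary
  trace <- data.frame(n = integer(), mu = numeric(), stopped = logical())
  n_stop <- NA_integer_
  for (k in seq_along(schedule)) {
    step_to(schedule[k], k)
    up <- b$upper[state$n]; lo <- b$lower[state$n]
    crossed <- is.na(up) || state$mu >= up || state$mu <= lo
    trace <- rbind(trace, data.frame(n = state$n, mu = state$mu,
                                     stopped = crossed))
    if (crossed) { n_stop <- state$n; break }
  }
  total <- if (is.na(n_stop)) params$t_max else
    min(n_stop + params$tau, params$t_max)
  if (total > n_avail)
    stop("records do not cover the pipeline follow-up (need ", total,
         " pairs)", call. = FALSE)
  # Stage III: pipeline outcomes enter in blocks of 10, final partial block
  k <- length(schedule)
  while (state$n < total) {
    k <- k + 1L
    step_to(min(state$n + 10L, total), k)
  }
  structure(list(trace = trace, n_stop = n_stop,
                 total_pairs = as.integer(total),
                 mu_final = state$mu,
                 decision = adoption_decision(state$mu, params$P, params$I),
                 variable_cost = total * params$c_pair,
                 design = "sequential", blocks = blocks),
            class = "vb_trial")
}
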