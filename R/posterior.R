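# Conjugate-normal posterior updating of E[INMB] from blockwise estimates,
# and Rubin's-rules pooling across multiple imputations.

#' Initial posterior state
#'
#' The state of knowledge about E\[INMB\] after `n` observed pairwise
#' allocations: the posterior is Normal with mean
#' `(n0*mu0 + n*xbar) / (n0 + n)` and variance `sigma_x^2 / (n0 + n)`.
#' `posterior_init()` returns the state at `n = 0` (the prior).
#'
#' @param prior A [vb_prior()] object.
#' @return An object of class `"vb_posterior"`: a list with fields `n`,
#'   `mu`, `var`, and the running data sum `sum_x` used for updating.
#' @export
posterior_init <- function(prior = vb_prior()) {
  structure(list(n = 0L, mu = prior$mu0, var = prior$sigma_x^2 / prior$n0,
                 sum_x = 0),
            class = "vb_posterior")
}

#' Update the posterior with a block of observations
#'
#' Advances the posterior over E\[INMB\] by one block of pairwise INMB
#' observations, supplied either as raw values or as a block mean with its
#' size (e.g. a multiply-imputed by-block estimate). Blocks must be
#' contiguous: the block is assumed to cover pairs
#' `state$n + 1, ..., state$n + size`.
#'
#' Updating is algebraically identical to recomputing the conjugate
#' posterior from the pooled sample, so any split of the data into blocks
#' gives the same final state.
#'
#' @param state A `"vb_posterior"` state.
#' @param x Numeric vector of pairwise INMB values for the block, or a
#'   single block mean if `size` is given.
#' @param prior The [vb_prior()] used to initialise the state.
#' @param size Block size when `x` is a block mean; ignored otherwise.
#' @param block_start Optional index of the first pair in the block; if
#'   supplied it must equal `state$n + 1` (guards against overlapping or
#'   duplicated blocks).
#' @return The updated `"vb_posterior"` state.
#' @examples
#' st <- posterior_init(vb_prior(mu0 = 0, sigma_x = 7615, n0 = 2))
#' st <- update_posterior(st, x = -1000, size = 10)
#' st$mu  # 10 * (-1000) / 12
#' @export
update_posterior <- function(state, x, prior = vb_prior(), size = NULL,
                             block_start = NULL) {
  stopifnot(inherits(state, "vb_posterior"))
  if (!is.null(block_start) && block_start != state$n + 1L)
    stop("non-contiguous block: expected block starting at pair ",
         state$n + 1L, ", got ", block_start, call. = FALSE)
  if (is.null(size)) {
    size <- length(x)
    block_sum <- sum(x)
  } else {
    if (length(x) != 1L) stop("'x' must be a single block mean when 'size' is given", call. = FALSE)
    block_sum <- x * size
  }
  if (size < 1L) stop("empty block", call. = FALSE)
  n <- state$n + size
  sum_x <- state$sum_x + block_sum
  structure(list(n = n,
                 mu = (prior$n0 * prior$mu0 + sum_x) / (prior$n0 + n),
                 var = prior$sigma_x^2 / (prior$n0 + n),
                 sum_x = sum_x),
            class = "vb_posterior")
}

#' @export
print.vb_posterior <- function(x, ...) {
  cat(sprintf("Posterior for E[INMB] after %d pairs: mean GBP %.2f, sd GBP %.1f\n",
              x$n, x$mu, sqrt(x$var)))
  invisible(x)
}

#' Pool estimates across multiple imputations by Rubin's rules
#'
#' Combines per-imputation point estimates and within-imputation variances
#' into a single estimate with variance decomposed into within, between
#' and total components, `total = within + (1 + 1/m) * between`.
#'
#' A single imputation (`m = 1`, the complete-data case) passes through
#' with between-variance zero and is flagged in the result.
#'
#' @param estimates Numeric vector of per-imputation estimates.
#' @param variances Numeric vector of per-imputation (within) variances;
#'   may be omitted when only the pooled point estimate is needed.
#' @return A list with `estimate`, `within_var`, `between_var`,
#'   `total_var`, `m_imputations` and `single_imputation` (logical).
#' @examples
#' rubins_pool(c(1, 2, 3), c(0.5, 0.5, 0.5))
#' @export
rubins_pool <- function(estimates, variances = rep(0, length(estimates))) {
  m <- length(estimates)
  if (m == 0L) stop("empty estimate list", call. = FALSE)
  if (length(variances) != m)
    stop("'variances' must match 'estimates' in length", call. = FALSE)
  est <- mean(estimates)
  within <- mean(variances)
  between <- if (m > 1L) stats::var(estimates) else 0
  list(estimate = est,
       within_var = within,
       between_var = between,
       total_var = within + (1 + 1 / m) * between,
       m_imputations = m,
       single_imputation = m == 1L)
}

#' Sampling standard deviation of pairwise INMB
#'
#' Estimates the sampling standard deviation `sigma_x` of pairwise INMB.
#' When a matrix is supplied (pairs in rows, imputations in columns) the
#' per-imputation sample standard deviations are averaged, matching the
#' pooled estimate used to parameterise the stopping-boundary model.
#'
#' @param x Numeric vector of pairwise INMB values, or a matrix with one
#'   column per imputation.
#' @return Estimated standard deviation (GBP).
#' @export
sample_sd_inmb <- function(x) {
  if (is.matrix(x)) mean(apply(x, 2, stats::sd)) else stats::sd(x)
}
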