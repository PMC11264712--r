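# Stopping-boundary solver: preposterior moments, stopping values,
# backward induction, design-selection thresholds.

test_that("preposterior SD matches a Monte-Carlo oracle and its limits", {
  pr <- vb_prior(mu0 = 0, sigma_x = 7615, n0 = 2)
  expect_equal(preposterior_sd(20, 0, pr), 0)
  expect_lt(preposterior_sd(1e8, 74, pr), 1e-3)

  # oracle: simulate the posterior mean after m further observations
  n <- 20; m <- 74
  set.seed(31)
  reps <- 2e5
  mu_n <- 0; t0 <- pr$n0 + n
  mu_true <- rnorm(reps, mu_n, pr$sigma_x / sqrt(t0))
  xbar_new <- rnorm(reps, mu_true, pr$sigma_x / sqrt(m))
  mu_next <- (t0 * mu_n + m * xbar_new) / (t0 + m)
  mc <- sd(mu_next)
  expect_lt(abs(mc - preposterior_sd(n, m, pr)) / mc, 0.01)
})

test_that("expected stopping value matches its closed form and a Monte-Carlo oracle", {
  p <- vb_params(); pr <- vb_prior()
  # degenerate predictive: no pipeline information left
  expect_equal(expected_stop_value(2, 1e9, 74, p, pr), p$P * 2, tolerance = 1e-6)
  expect_equal(expected_stop_value(1000, 10, 0, p, pr), p$P * 1000)
  expect_equal(expected_stop_value(-1000, 10, 0, p, pr), 0)
  # symmetric case mu = I/P: value is P * s * dnorm(0)
  s <- preposterior_sd(20, 74, pr)
  expect_equal(expected_stop_value(0, 20, 74, p, pr), p$P * s * dnorm(0))

  set.seed(32)
  mu_prime <- rnorm(4e5, 0, s)
  mc <- mean(pmax(p$P * mu_prime - p$I, 0))
  se <- sd(pmax(p$P * mu_prime - p$I, 0)) / sqrt(4e5)
  expect_lt(abs(mc - expected_stop_value(0, 20, 74, p, pr)), 3 * se)
})

test_that("the boundary is mirror-symmetric when the switching cost is zero", {
  des <- design_124()
  b <- des$boundary
  ok <- !is.na(b$upper)
  expect_true(any(ok))
  expect_lt(max(abs(b$upper[ok] + b$lower[ok])), des$dp$mu_grid_step)
  expect_true(all(b$upper[ok] >= b$lower[ok]))
  # boundary narrows as information accumulates over the scheduled epochs
  expect_true(all(diff(b$upper[c(20, 30, 40)]) < 0))
})

test_that("Bellman consistency holds at interior nodes (independent quadrature)", {
  p <- vb_params()
  pr <- vb_prior()
  des <- cached_design("d124_surface", function()
    vb_design(p, pr, dp_config(store_value = TRUE), thresholds = FALSE))
  surf <- des$surface
  mu <- des$mu_grid
  n <- 25
  Vn <- surf[[n + 1]]; Vn1 <- surf[[n + 2]]
  v1 <- preposterior_sd(n, 1, pr)
  fV <- approxfun(mu, Vn1, rule = 2)
  for (mu0 in c(-8000, -2000, 0, 3000, 9000)) {
    # fine fixed-grid quadrature (independent of the solver's kernel)
    z <- seq(-8, 8, length.out = 8001)
    fz <- fV(mu0 + v1 * z) * dnorm(z)
    cont <- -p$c_pair + sum((fz[-1] + fz[-length(fz)]) / 2) * diff(z[1:2])
    stp <- expected_stop_value(mu0, n, p$tau, p, pr)
    i <- which.min(abs(mu - mu0))
    # residual bounded by the interpolation error of the scheme
    expect_lt(abs(Vn[i] - max(stp, cont)), 15)
    expect_gte(Vn[i] + 1e-6, stp)
  }
})

test_that("a prohibitive sampling cost empties the continuation region", {
  p <- vb_params(c_pair = 1e9)
  des <- vb_design(p, vb_prior(), dp_config(mu_grid_step = 100),
                   thresholds = FALSE)
  expect_true(all(is.na(des$boundary$upper)))
})

test_that("a too-narrow grid raises the widening error", {
  expect_error(vb_design(vb_params(), vb_prior(),
                         dp_config(mu_grid_half_width = 6000,
                                   mu_grid_step = 100),
                         thresholds = FALSE),
               "mu_grid_half_width")
})

test_that("halving the grid step moves the boundary by less than GBP 100", {
  b1 <- design_124()$boundary
  b2 <- design_124_fine()$boundary
  ok <- !is.na(b1$upper) & !is.na(b2$upper)
  expect_gt(mean(ok), 0.9)
  expect_lt(max(abs(b1$upper[ok] - b2$upper[ok])), 100)
  expect_lt(max(abs(b1$lower[ok] - b2$lower[ok])), 100)
})

test_that("value responds monotonically to sampling cost and population size", {
  pr <- vb_prior()
  dp <- dp_config(mu_grid_step = 100)
  base <- vb_design(vb_params(t_max = 100, tau = 50), pr, dp, thresholds = FALSE)
  dearer <- vb_design(vb_params(t_max = 100, tau = 50, c_pair = 5000), pr, dp,
                      thresholds = FALSE)
  bigger <- vb_design(vb_params(t_max = 100, tau = 50,
                                annual_incidence = 4900), pr, dp,
                      thresholds = FALSE)
  expect_true(all(dearer$value0 <= base$value0 + 1e-6))
  expect_true(all(bigger$value0 >= base$value0 - 1e-6))
})

test_that("one-stage ENBS is unimodal and negative beyond the no-trial threshold", {
  p <- vb_params(); pr <- vb_prior()
  expect_equal(one_stage_enbs(0, 5000, p, pr, fixed_cost = 200), -200)
  n <- 1:500
  enbs <- one_stage_enbs(n, 4000, p, pr)
  k <- which.max(enbs)
  expect_true(all(diff(enbs[1:k]) > 0))
  expect_true(all(diff(enbs[k:length(n)]) < 0))
  # beyond point A no fixed trial has positive expected net benefit
  A <- design_124()$thresholds$A
  expect_true(all(one_stage_enbs(n, A + 2000, p, pr) < 0))
})

test_that("design-selection thresholds bracket the sequential and one-stage regions", {
  des <- design_124()
  thr <- des$thresholds
  expect_true(thr$A > thr$C && thr$C > 0)
  expect_true(thr$B < thr$D && thr$D < 0)
  # switching cost zero: symmetric thresholds
  expect_lt(abs(thr$A + thr$B), 300)
  expect_lt(abs(thr$C + thr$D), 300)

  expect_equal(classify_prior(des, 0), "sequential")
  expect_equal(classify_prior(des, 20000), "no_trial_adopt_N")
  expect_equal(classify_prior(des, -20000), "no_trial_keep_S")
  expect_equal(classify_prior(des, (thr$C + thr$A) / 2), "one_stage")
  expect_equal(classify_prior(des, (thr$D + thr$B) / 2), "one_stage")
})

test_that("boundary export and import round-trip with metadata", {
  des <- design_124()
  csv <- tempfile(fileext = ".csv")
  write_boundary(des, csv)
  back <- read_boundary(csv)
  expect_equal(back$boundary$upper, des$boundary$upper, tolerance = 1e-8)
  expect_equal(back$meta$t_max, 124)
  expect_equal(back$meta$A, des$thresholds$A, tolerance = 1e-6)
  unlink(c(csv, sub("\\.csv$", ".json", csv)))
})
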