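# Economic primitives: QALY derivation, INMB, adoption rule, costs and
# parameter derivation.

test_that("QALYs are the trapezoidal area under the utility curve", {
  r <- list(u0 = 1, u6 = 1, u12 = 1, cost_1 = 0)
  expect_equal(derive_costs_and_qalys(r)$qaly, 1)

  r <- list(u0 = 0.5, u6 = 0.5, u12 = 0.5, cost_1 = 100, cost_2 = 50)
  out <- derive_costs_and_qalys(r)
  expect_equal(out$qaly, 0.5)
  expect_equal(out$total_cost, 150)

  # hand-computed trapezoid: 0.25*0.8 + 0.5*0.6 + 0.25*0.4 = 0.6
  r <- list(u0 = 0.8, u6 = 0.6, u12 = 0.4, cost_1 = 0)
  expect_equal(derive_costs_and_qalys(r)$qaly, 0.6)

  # six-month window uses baseline and 6 months only
  r <- list(u0 = 0.8, u6 = 0.4, cost_1 = 0)
  expect_equal(derive_costs_and_qalys(r, delta_years = 0.5)$qaly,
               0.5 * (0.8 + 0.4) / 2)
})

test_that("missing or out-of-range fields are rejected by name", {
  expect_error(derive_costs_and_qalys(list(u0 = 0.5, u6 = NA, u12 = 0.5,
                                           cost_1 = 1)),
               "u6")
  expect_error(derive_costs_and_qalys(list(u0 = 0.5, u6 = 0.5, u12 = 0.5,
                                           cost_1 = 1, cost_2 = NA)),
               "cost_2")
  expect_error(derive_costs_and_qalys(list(u0 = 1.2, u6 = 0.5, u12 = 0.5,
                                           cost_1 = 1)),
               "outside")
})

test_that("pairwise INMB follows the net-benefit definition and sign convention", {
  rn <- list(arm = "N", u0 = 0.7, u6 = 0.7, u12 = 0.7, cost_1 = 100)
  rs <- list(arm = "S", u0 = 0.7, u6 = 0.7, u12 = 0.7, cost_1 = 100)
  expect_equal(compute_inmb(rn, rs), 0)

  # dQALY = 0.01, dcost = 100 at lambda 30,000 -> 200
  rn2 <- list(arm = "N", u0 = 0.71, u6 = 0.71, u12 = 0.71, cost_1 = 200)
  expect_equal(compute_inmb(rn2, rs, lambda_wtp = 30000), 30000 * 0.01 - 100)

  # equal effects, new technology GBP 39 cheaper -> +39 (favours N)
  rn3 <- list(arm = "N", u0 = 0.7, u6 = 0.7, u12 = 0.7, cost_1 = 61)
  expect_equal(compute_inmb(rn3, rs), 39)

  expect_error(compute_inmb(rs, rn), "arms")
})

test_that("INMB is antisymmetric under swapping the arm labels", {
  set.seed(11)
  for (i in 1:20) {
    u <- runif(6, 0.2, 0.95); cc <- runif(2, 0, 2000)
    a <- list(arm = "N", u0 = u[1], u6 = u[2], u12 = u[3], cost_1 = cc[1])
    b <- list(arm = "S", u0 = u[4], u6 = u[5], u12 = u[6], cost_1 = cc[2])
    a2 <- a; a2$arm <- "S"; b2 <- b; b2$arm <- "N"
    expect_equal(compute_inmb(a, b), -compute_inmb(b2, a2))
  }
})

test_that("adoption requires the population reward to strictly exceed the switching cost", {
  expect_equal(adoption_decision(-30, P = 24500, I = 0), "keep_S")
  expect_equal(adoption_decision(0, P = 24500, I = 0), "keep_S")
  expect_equal(adoption_decision(1, P = 24500, I = 0), "adopt_N")
  expect_equal(adoption_decision(10, P = 100, I = 1000), "keep_S")  # tie
  for (mu in c(-2, 0.5, 3)) {
    expect_equal(adoption_decision(mu, P = 12345, I = 0),
                 if (mu > 0) "adopt_N" else "keep_S")
  }
})

test_that("cost accounting matches the budget arithmetic", {
  p <- vb_params(t_max = 248)
  expect_equal((248 - 237) * p$c_pair, 18150)
  expect_equal(cost_accounting(0, p)$variable, 0)
  expect_equal(cost_accounting(124, p)$variable, 204600)
  # variable spend agrees with the accounts figure to rounding of c
  expect_lt(abs(cost_accounting(124, p)$variable - 204581), 124 / 2)
  expect_error(cost_accounting(-1, p), "non-negative")
  expect_error(cost_accounting(300, p), "t_max")
})

test_that("design parameters derive from accounts, accrual and incidence", {
  p <- derive_design_params(pairs = 124, trial_days = 611, delta_years = 1,
                            variable_spend = 204581,
                            annual_incidence = 2450, horizon_years = 10)
  expect_equal(p$tau, 74L)
  expect_equal(p$c_pair, 1650)
  expect_equal(p$P, 24500)
  # halving the follow-up delay halves the pipeline
  p6 <- derive_design_params(pairs = 124, trial_days = 611, delta_years = 0.5,
                             variable_spend = 204581,
                             annual_incidence = 2450, horizon_years = 10)
  expect_equal(p6$tau, 37L)
  expect_error(derive_design_params(pairs = 124, trial_days = 0,
                                    variable_spend = 1, annual_incidence = 1,
                                    horizon_years = 1),
               "trial_days")
})

test_that("patients pair by within-arm arrival rank; surplus is dropped with a warning", {
  rec <- data.frame(id = c("a", "b", "c", "d", "e"),
                    arm = c("N", "S", "N", "S", "N"),
                    rand_date = c(5, 1, 2, 9, 3))
  expect_warning(pr <- pair_patients(rec), "unpaired")
  expect_equal(nrow(pr), 2)
  # first N by date is "c" (2), first S is "b" (1)
  expect_equal(pr$id_N, c("c", "e"))
  expect_equal(pr$id_S, c("b", "d"))
})

test_that("parameter and record invariants are enforced", {
  expect_error(vb_params(tau = 0), "tau")
  expect_error(vb_params(t_max = 74, tau = 74), "t_max")
  expect_error(vb_params(c_pair = -1), "c_pair")
  expect_error(vb_prior(sigma_x = 0), "sigma_x")
  pr <- vb_prior(sigma_x = 7615, n0 = 2)
  expect_equal(pr$sigma0_sq * pr$n0, pr$sigma_x^2)
})
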