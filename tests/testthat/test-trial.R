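# Trial monitoring: schedules, stopping, totals, and the fixed-design
# comparator.

test_that("interim schedules match the delayed-design arithmetic", {
  expect_equal(interim_schedule(124, 74), c(20L, 30L, 40L))       # 3 interims
  expect_length(interim_schedule(248, 74), 16L)                   # 16 interims
  expect_equal(max(interim_schedule(248, 74)), 170L)
  # halving the delay strictly increases the number of decision epochs
  expect_gt(length(interim_schedule(124, 37)), length(interim_schedule(124, 74)))
  expect_error(interim_schedule(90, 74), "feasible")
})

test_that("total sample size is observed pairs at stopping plus the pipeline", {
  des <- design_124()
  sched <- interim_schedule(124, 74)
  # craft a stream that crosses at the third interim (n = 40) only
  up <- des$boundary$upper
  x <- rep(0, 124)
  x[31:40] <- (up[40] + 1) * (2 + 40) / 10   # lifts mu_40 just over the boundary
  tr <- run_trial(x, des)
  expect_equal(tr$n_stop, 40L)
  expect_equal(tr$total_pairs, 114L)          # 40 observed + 74 pipeline

  # crossing at the first interim: 20 + 74 = 94 pairs
  x2 <- rep(0, 124); x2[1:20] <- (up[20] + 1) * (2 + 20) / 20
  tr2 <- run_trial(x2, des)
  expect_equal(tr2$n_stop, 20L)
  expect_equal(tr2$total_pairs, 94L)

  # a stop at 30 observed pairs means 104 pairs, 208 patients
  x3 <- rep(0, 124); x3[21:30] <- (des$boundary$lower[30] - 1) * (2 + 30) / 10
  tr3 <- run_trial(x3, des)
  expect_equal(tr3$n_stop, 30L)
  expect_equal(tr3$total_pairs, 104L)
  expect_equal(2L * tr3$total_pairs, 208L)
})

test_that("stopping is first-crossing and inclusive at the boundary", {
  des <- design_124()
  up <- des$boundary$upper
  x <- rep(0, 124); x[1:20] <- up[20] * (2 + 20) / 20  # exactly on the boundary
  tr <- run_trial(x, des)
  expect_equal(tr$n_stop, 20L)
  expect_equal(sum(tr$trace$stopped), 1L)
  expect_equal(max(tr$trace$n), 20L)  # no entries after the stop
})

test_that("a never-crossing path equals the fixed design at t_max", {
  des <- design_124()
  set.seed(41)
  repeat {
    x <- generate_inmb_stream(124, -45, 7615)
    tr <- run_trial(x, des)
    if (is.na(tr$n_stop)) break
  }
  fx <- fixed_design(x, 124, des$params, des$prior)
  expect_equal(tr$total_pairs, 124L)
  expect_equal(tr$mu_final, fx$mu_final)
  expect_equal(tr$decision, fx$decision)
})

test_that("the sequential design never samples more than the fixed design", {
  des <- design_124()
  set.seed(42)
  for (i in 1:100) {
    x <- generate_inmb_stream(124, -45, 7615)
    tr <- run_trial(x, des)
    expect_lte(tr$total_pairs, 124L)
    expect_gte(tr$total_pairs, 20L + 74L)
  }
})

test_that("interim posterior means agree with batch conjugate updating", {
  des <- design_124()
  pr <- des$prior
  set.seed(43)
  x <- generate_inmb_stream(124, -45, 7615)
  tr <- run_trial(x, des)
  for (k in seq_len(nrow(tr$trace))) {
    n <- tr$trace$n[k]
    st <- update_posterior(posterior_init(pr), x[1:n], pr)
    expect_equal(tr$trace$mu[k], st$mu)
  }
})

test_that("fixed design with no data decides on the prior alone", {
  p <- vb_params(); pr <- vb_prior(mu0 = -10)
  fx <- fixed_design(numeric(0), 0, p, pr)
  expect_equal(fx$mu_final, -10)
  expect_equal(fx$decision, "keep_S")
  expect_error(fixed_design(rnorm(5), 10, p, pr), "exhausted")
  expect_error(run_trial(rnorm(10), design_124()), "exhausted")
})

test_that("vectorised path monitoring agrees with run_trial path by path", {
  des <- design_124()
  set.seed(44)
  paths <- matrix(rnorm(30 * 124, -45, 7615), 30, 124)
  sched <- interim_schedule(124, 74)
  fast <- vbseq:::.monitor_paths(paths, des, sched)
  for (i in 1:30) {
    tr <- run_trial(paths[i, ], des, sched)
    expect_equal(fast$total_pairs[i], tr$total_pairs)
    expect_equal(fast$mu_final[i], tr$mu_final)
    expect_equal(fast$n_stop[i], if (is.na(tr$n_stop)) NA_integer_ else tr$n_stop)
  }
})

test_that("block-estimate sources reproduce raw-stream monitoring", {
  des <- design_124()
  block_means <- function(x, edges) {
    data.frame(n_end = edges,
               estimate = vapply(seq_along(edges), function(k) {
                 lo <- if (k == 1) 1 else edges[k - 1] + 1
                 mean(x[lo:edges[k]])
               }, numeric(1)))
  }
  # a path that never crosses: totals and final posterior match the raw run
  set.seed(45)
  repeat {
    x <- generate_inmb_stream(124, -45, 7615)
    tr_raw <- run_trial(x, des)
    if (is.na(tr_raw$n_stop)) break
  }
  est <- block_means(x, c(seq(20, 120, by = 10), 124))
  tr_blk <- run_trial(est, des)
  expect_equal(tr_blk$total_pairs, tr_raw$total_pairs)
  expect_equal(tr_blk$mu_final, tr_raw$mu_final, tolerance = 1e-10)

  # a crafted crossing at n = 20: pipeline blocks carry the posterior to 94
  up <- des$boundary$upper
  x2 <- rep(100, 124); x2[1:20] <- (up[20] + 1) * (2 + 20) / 20
  est2 <- block_means(x2, c(seq(20, 90, by = 10), 94))
  tr2_raw <- run_trial(x2, des)
  tr2_blk <- run_trial(est2, des)
  expect_equal(tr2_blk$n_stop, 20L)
  expect_equal(tr2_blk$total_pairs, tr2_raw$total_pairs)
  expect_equal(tr2_blk$mu_final, tr2_raw$mu_final, tolerance = 1e-10)
})
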