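no_ramp <- function(...) sequencer_model(..., ramp_start = 1)

test_that("sequencing_time is the rate-product inverse without a ramp", {
  # 100 useful calls per minute -> 250 calls in 150 s
  m <- no_ramp(active_pores = 100, per_pore_read_rate = 1 / 60)
  expect_equal(sequencing_time(m, 1, 250), 150)
  # proportionality: doubling the target fraction halves the time
  expect_equal(sequencing_time(m, 0.2, 250),
               2 * sequencing_time(m, 0.4, 250))
  expect_identical(sequencing_time(m, 0), Inf)
  # every loss factor enters multiplicatively
  m2 <- no_ramp(100, 1 / 60, participation = 0.5, call_yield = 0.8,
                barcode_loss = 0.1)
  expect_equal(sequencing_time(m2, 1, 250),
               150 / (0.5 * 0.8 * 0.9))
})

test_that("the participation ramp integrates piecewise correctly", {
  m <- sequencer_model(10, 0.1, participation = 0.8, ramp_start = 0.3,
                       ramp_duration = 120)
  # numeric oracle: integrate the instantaneous call rate on a fine grid
  oracle <- function(model, tf, support) {
    dt <- 0.001
    t <- seq(dt, 4000, by = dt)
    base <- model$active_pores * model$per_pore_read_rate *
      (1 - model$barcode_loss) * tf * model$call_yield * model$participation
    ramp <- ifelse(t < model$ramp_duration,
                   model$ramp_start + (1 - model$ramp_start) *
                     t / model$ramp_duration, 1)
    cum <- cumsum(base * ramp * dt)
    t[which(cum >= support)[1]]
  }
  for (support in c(20, 100, 900)) # in-ramp and post-ramp crossings
    expect_equal(sequencing_time(m, 1, support), oracle(m, 1, support),
                 tolerance = 1e-3)
})

test_that("sequencing_time is strictly decreasing in its rate factors", {
  tf <- seq(0.1, 0.9, by = 0.2)
  m <- sequencer_model(500, 0.02, 0.7)
  t_tf <- vapply(tf, function(f) sequencing_time(m, f), numeric(1))
  expect_true(all(diff(t_tf) < 0))
  t_pores <- vapply(c(100, 400, 1600), function(p)
    sequencing_time(sequencer_model(p, 0.02, 0.7), 0.3), numeric(1))
  expect_true(all(diff(t_pores) < 0))
  t_rate <- vapply(c(0.01, 0.04, 0.16), function(r)
    sequencing_time(sequencer_model(500, r, 0.7), 0.3), numeric(1))
  expect_true(all(diff(t_rate) < 0))
})

test_that("optimal_amplification equals a dense grid-search oracle", {
  m <- no_ramp(1200, 0.05, participation = 0.6, call_yield = 0.9)
  # logistic fraction curve sampled at 1-minute steps
  amt <- seq(4, 20, by = 1)
  curves <- list(
    logistic = 0.5 / (1 + exp(-(amt - 10))),
    concave = pmin(0.6, 0.08 * sqrt(pmax(amt - 4, 0))),
    constant = rep(0.25, length(amt)))
  for (nm in names(curves)) {
    cv <- amplification_curve(amt, curves[[nm]])
    res <- optimal_amplification(cv, m, per_unit_amp_time = 60,
                                 fixed_overhead = 300, support = 250)
    # independent argmin on an even denser grid
    dense <- seq(min(amt), max(amt), length.out = 20001)
    fr <- approx(cv$amount, cv$target_fraction, dense, rule = 2)$y
    tot <- dense * 60 + 300 +
      vapply(fr, function(f) sequencing_time(m, f, 250), numeric(1))
    expect_equal(res$optimum_amount, dense[which.min(tot)], tolerance = 0.02,
                 label = nm)
    expect_equal(res$optimum_total_time, min(tot), tolerance = 0.5)
  }
  # constant fraction: no reason to amplify longer
  cv <- amplification_curve(amt, curves$constant)
  expect_equal(optimal_amplification(cv, m, 60, 0, 250)$optimum_amount,
               min(amt))
  expect_error(optimal_amplification(
    amplification_curve(1:3, c(0, 0, 0)), m), "no feasible")
})

test_that("over-amplification is cheaper than under-amplification", {
  # increasing-concave fraction curve around the optimum
  m <- no_ramp(1200, 0.05, participation = 0.6)
  amt <- seq(4, 30, by = 0.5)
  cv <- amplification_curve(amt, pmin(0.55, 0.12 * sqrt(pmax(amt - 4, 0))))
  res <- optimal_amplification(cv, m, per_unit_amp_time = 60,
                               fixed_overhead = 0, support = 250)
  tab <- res$table
  opt <- res$optimum_amount
  delta <- 4
  t_over <- tab$total_time[which.min(abs(tab$amount - (opt + delta)))]
  t_under <- tab$total_time[which.min(abs(tab$amount - (opt - delta)))]
  expect_lt(t_over - res$optimum_total_time,
            t_under - res$optimum_total_time)
})

test_that("cycles-mode and seconds-mode agree when units convert", {
  m <- no_ramp(800, 0.04, 0.5)
  cyc <- amplification_curve(20:30, seq(0.1, 0.5, length.out = 11))
  sec <- amplification_curve((20:30) * 30, seq(0.1, 0.5, length.out = 11))
  r1 <- optimal_amplification(cyc, m, per_unit_amp_time = 30,
                              fixed_overhead = 100)
  r2 <- optimal_amplification(sec, m, per_unit_amp_time = 1,
                              fixed_overhead = 100)
  expect_equal(r1$optimum_total_time, r2$optimum_total_time, tolerance = 1e-6)
  expect_equal(r1$optimum_amount * 30, r2$optimum_amount, tolerance = 1e-6)
})

test_that("a fitted model predicts simulated time-to-support within 20%", {
  lambda <- 8; f <- 0.4; support <- 250
  m <- no_ramp(active_pores = lambda, per_pore_read_rate = 1,
               participation = 1)
  pred <- sequencing_time(m, f, support)
  set.seed(31)
  ratio <- replicate(20, {
    arrivals <- cumsum(rexp(3000, lambda))
    useful <- arrivals[runif(3000) < f]
    useful[support]
  }) / pred
  expect_true(all(abs(ratio - 1) < 0.2))
})
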