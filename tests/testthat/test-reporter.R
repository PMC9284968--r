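test_that("proportion_ci matches the closed form and clamps", {
  ci <- proportion_ci(50, 100, 0.95)
  # 0.5 +/- 1.959964 * sqrt(0.25/100)
  expect_equal(unname(ci), c(0.4020018, 0.5979982), tolerance = 1e-6)
  expect_identical(unname(proportion_ci(0, 100)[1]), 0)
  expect_identical(unname(proportion_ci(100, 100)[2]), 1)
  w <- proportion_ci(0, 100, method = "wilson")
  expect_gt(unname(w[2]), 0)  # Wilson does not degenerate at k = 0
  expect_error(proportion_ci(5, 0), "n must be")
  expect_error(proportion_ci(5, 4), "k must be")
})

test_that("Wald CI coverage is nominal at p = 0.3, n = 250", {
  set.seed(99)
  p <- 0.3; n <- 250L
  k <- rbinom(2000, n, p)
  covered <- vapply(k, function(ki) {
    ci <- proportion_ci(ki, n)
    ci[1] <= p && p <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("accumulate counts supporting calls and builds the timeline", {
  a <- fixture_assay()
  diags <- c(lapply(1:3, function(i) stub_diag("TARGET", "T", i)),
             list(stub_diag("TARGET", "A", 4)))
  acc <- accumulate(diags, a)
  expect_identical(acc$vaf_report$support, 4L)
  expect_equal(acc$vaf_report$vaf, 0.75)
  expect_identical(acc$timeline$cumulative_support, 1:4)
  expect_true(!is.unsorted(acc$timeline$start_time))

  # non-supporting calls are tallied separately
  diags2 <- c(diags, list(stub_diag("TARGET", "C", 5),
                          stub_diag("TARGET", "DEL", 6),
                          stub_diag("FRAGMENT", start_time = 7)))
  acc2 <- accumulate(diags2, a)
  expect_identical(acc2$vaf_report$support, 4L)
  expect_identical(acc2$vaf_report$n_other, 1L)
  expect_identical(acc2$vaf_report$n_del, 1L)

  # zero reads: NOCALL
  acc0 <- accumulate(list(), a)
  expect_identical(acc0$vaf_report$support, 0L)
  expect_identical(acc0$vaf_report$call, "NOCALL")
  expect_true(is.na(acc0$vaf_report$vaf))

  # missing start_time: excluded from timeline with a warning, counted in vaf
  diags3 <- c(diags, list(stub_diag("TARGET", "T", NA_real_)))
  expect_warning(acc3 <- accumulate(diags3, a), "start_time")
  expect_identical(acc3$vaf_report$support, 5L)
  expect_identical(nrow(acc3$timeline), 4L)

  # vaf is scale-free; duplication narrows the CI
  acc_dup <- accumulate(c(diags, diags), a)
  expect_equal(acc_dup$vaf_report$vaf, acc$vaf_report$vaf)
  expect_lt(diff(acc_dup$vaf_report$ci), diff(acc$vaf_report$ci))
})

test_that("time_to_support finds the threshold crossing and is monotone", {
  tl <- data.frame(start_time = c(1, 2, 5, 9), cumulative_support = 1:4)
  expect_equal(time_to_support(tl, 3), 5)
  expect_equal(time_to_support(tl, 1), 1)
  expect_true(is.na(time_to_support(tl, 250)))
  tts <- vapply(1:4, function(th) time_to_support(tl, th), numeric(1))
  expect_true(!is.unsorted(tts))
})

test_that("detection_power matches exact summation and Monte-Carlo", {
  # the 250x / VAF 10% / 1% error operating point
  dp <- detection_power(250, 0.10, 0.01, 0.05)
  expect_gte(dp[["sensitivity"]], 0.99)
  expect_gte(dp[["specificity"]], 0.99)

  # independent oracle: direct density summation
  kmin <- ceiling(0.05 * 250)
  sens_oracle <- sum(dbinom(kmin:250, 250, 0.10))
  spec_oracle <- sum(dbinom(0:(kmin - 1), 250, 0.01))
  expect_equal(dp[["sensitivity"]], sens_oracle, tolerance = 1e-12)
  expect_equal(dp[["specificity"]], spec_oracle, tolerance = 1e-12)

  # Monte-Carlo oracle within 3 standard errors
  set.seed(123)
  mc <- mean(rbinom(1e5, 250, 0.10) >= kmin)
  se <- sqrt(mc * (1 - mc) / 1e5)
  expect_lt(abs(dp[["sensitivity"]] - mc), 3 * se + 1e-9)

  # single-trial case
  dp1 <- detection_power(1, 0.3, 0.02, 0.5)
  expect_equal(dp1[["sensitivity"]], 0.3)
  expect_equal(dp1[["specificity"]], 0.98)

  # boundary bookkeeping when true_vaf equals the error rate
  dpe <- detection_power(100, 0.05, 0.05, 0.05)
  expect_equal(dpe[["sensitivity"]], 1 - dpe[["specificity"]],
               tolerance = 1e-12)

  expect_error(detection_power(250, 0.1, 0.01, 0), "degenerate")
  expect_error(detection_power(250, 0, 0.01, 0.5), "fractions")
})

test_that("hotspot VCF is written with 1-based coordinates", {
  a <- fixture_assay()
  acc <- accumulate(lapply(1:3, function(i) stub_diag("TARGET", "T", i)), a)
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_hotspot_vcf(acc$vaf_report, a, tmp)
  rec <- readLines(tmp)
  body <- rec[!startsWith(rec, "#")]
  fields <- strsplit(body, "\t")[[1]]
  expect_identical(as.integer(fields[2]), a$hotspot_pos + 1L)
  expect_identical(fields[4], a$wildtype_allele)
  expect_match(fields[8], "DP=3")
})
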