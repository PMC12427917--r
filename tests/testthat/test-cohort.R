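# Synthetic cohorts: calibration of the serial-multiplication framework.

test_that("chained posteriors equal exhaustive Bayes enumeration (<= 3 findings)", {
  # independent oracle: enumerate all findings-pattern x disease combinations
  findings <- three_findings()
  for (prev in c(0.014, 0.071, 0.25)) {
    oracle <- enumerate_posteriors(prev, findings)
    for (r in seq_len(nrow(oracle))) {
      pattern <- as.logical(oracle[r, 1:3])
      ev <- lapply(seq_along(findings), function(j) {
        f <- findings[[j]]
        lr <- if (pattern[j]) f$lr_positive else f$lr_negative
        evidence_item(f$id, lr)
      })
      expect_equal(chain_update(prev, ev)$posterior, oracle$posterior[r],
                   tolerance = 1e-12)
    }
    expect_equal(sum(oracle$pattern_prob), 1, tolerance = 1e-12)
  }
})

test_that("cohorts are exactly reproducible for a fixed config and seed", {
  cfg <- simulation_config(500, 0.071, three_findings(), rho = 0.3, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$summary, b$summary)
  c <- simulate_cohort(simulation_config(500, 0.071, three_findings(),
                                         rho = 0.3, seed = 100))
  expect_false(identical(a$patients$posterior, c$patients$posterior))
})

test_that("a near-perfect test polarizes posteriors and the tier is near-perfect", {
  f <- sim_finding("near_perfect", sensitivity = 0.999, specificity = 0.999)
  cohort <- simulate_cohort(simulation_config(20000, 0.5, list(f), seed = 4))
  p <- cohort$patients$posterior
  expect_true(all(p < 0.01 | p > 0.99))
  act <- cohort$patients$tier != "surveillance"
  expect_gt(mean(act == cohort$patients$disease), 0.99)
})

test_that("empirical P(disease | positive test) matches the closed form", {
  # prevalence 4%, the millimetric ST-elevation tier: P(D | T+) = 0.3417
  f <- sim_finding("ste", sensitivity = 0.436, specificity = 0.965)
  cohort <- simulate_cohort(simulation_config(200000, 0.04, list(f), seed = 7))
  pos <- cohort$patients$ste
  p_hat <- mean(cohort$patients$disease[pos])
  p_true <- 0.341692789968652
  se <- sqrt(p_true * (1 - p_true) / sum(pos))
  expect_lt(abs(p_hat - p_true), 3 * se)
  # and the chained posterior of test-positive patients is exactly that value
  u <- unique(cohort$patients$posterior[pos])
  expect_length(u, 1L)
  expect_equal(u, p_true, tolerance = 1e-10)
})

test_that("posteriors from the vectorized chain match chain_update row by row", {
  findings <- three_findings()
  cohort <- simulate_cohort(simulation_config(50, 0.1, findings, seed = 12))
  for (r in c(1, 17, 50)) {
    ev <- lapply(findings, function(f) {
      pos <- cohort$patients[[f$id]][r]
      evidence_item(f$id, if (pos) f$lr_positive else f$lr_negative)
    })
    expect_equal(cohort$patients$posterior[r], chain_update(0.1, ev)$posterior,
                 tolerance = 1e-12)
  }
})

test_that("independent findings give calibrated posteriors (slope ~ 1)", {
  cohort <- simulate_cohort(simulation_config(100000, 0.071, three_findings(),
                                              rho = 0, seed = 21))
  cal <- calibration_report(cohort, n_bins = 10)
  expect_true(cal$slope_ci[1] <= 1 && 1 <= cal$slope_ci[2])
  expect_true(cal$intercept_ci[1] <= 0 && 0 <= cal$intercept_ci[2])
  # every populated bin's observed fraction within 3 binomial SEs of predicted
  b <- cal$bins[cal$bins$count > 0, ]
  se <- sqrt(b$mean_posterior * (1 - b$mean_posterior) / b$count)
  expect_true(all(abs(b$observed - b$mean_posterior) <= 3 * se + 1e-9))
  expect_equal(sum(cal$bins$count), 100000L)
})

test_that("correlated findings break calibration detectably at rho = 0.8", {
  # duplicated evidence: three copies of the same finding, strongly coupled --
  # serial multiplication now triple-counts what is nearly one observation
  dup <- replicate(3, sim_finding("ecg", sensitivity = 0.781, specificity = 0.944),
                   simplify = FALSE)
  for (i in seq_along(dup)) dup[[i]]$id <- paste0("ecg", i)
  cohort <- simulate_cohort(simulation_config(100000, 0.071, dup, rho = 0.8, seed = 22))
  cal <- calibration_report(cohort)
  expect_true(cal$slope_ci[2] < 1 || cal$slope_ci[1] > 1)
})

test_that("mis-calibration is already detectable at rho = 0.5", {
  dup <- replicate(3, sim_finding("ecg", sensitivity = 0.781, specificity = 0.944),
                   simplify = FALSE)
  for (i in seq_along(dup)) dup[[i]]$id <- paste0("ecg", i)
  cohort <- simulate_cohort(simulation_config(100000, 0.071, dup, rho = 0.5, seed = 23))
  cal <- calibration_report(cohort)
  expect_true(cal$slope_ci[2] < 1 || cal$slope_ci[1] > 1)
})

test_that("self-calibrated predictions pass their own report", {
  # posteriors equal to the generating probabilities are calibrated by
  # construction; the regression must not reject them
  set.seed(31)
  p <- runif(50000, 0.01, 0.9)
  y <- runif(50000) < p
  cohort <- structure(list(patients = data.frame(disease = y, posterior = p)),
                      class = "omi_cohort")
  cal <- calibration_report(cohort, n_bins = 10)
  expect_true(cal$slope_ci[1] <= 1 && 1 <= cal$slope_ci[2])
})

test_that("a single-bin calibration recovers the prevalence", {
  cohort <- simulate_cohort(simulation_config(5000, 0.2, list(ecg_finding()), seed = 9))
  cal <- calibration_report(cohort, n_bins = 1)
  expect_equal(cal$bins$observed, mean(cohort$patients$disease))
  expect_equal(cal$bins$count, 5000L)
})

test_that("empty bins are reported, not dropped", {
  f <- sim_finding("weak", sensitivity = 0.55, specificity = 0.55)
  cohort <- simulate_cohort(simulation_config(2000, 0.05, list(f), seed = 10))
  cal <- calibration_report(cohort, n_bins = 20)
  expect_equal(nrow(cal$bins), 20L)
  expect_true(any(cal$bins$count == 0L))
  expect_true(all(is.na(cal$bins$observed[cal$bins$count == 0L])))
})

test_that("policy sweep operating characteristics are monotone", {
  cohort <- simulate_cohort(simulation_config(20000, 0.071, three_findings(), seed = 13))
  sweep <- policy_sweep(cohort, c(0.05, 0.10, 0.25, 0.5, 0.9))
  expect_true(all(diff(sweep$activation_rate) <= 0))
  expect_true(all(diff(sweep$sensitivity) <= 0))
  expect_lt(sweep$activation_rate[nrow(sweep)], sweep$activation_rate[1])
  # boundary behavior
  tiny <- policy_sweep(cohort, 1e-12)
  expect_equal(tiny$activation_rate, 1.0)
  huge <- policy_sweep(cohort, 1 - 1e-12)
  expect_equal(huge$activation_rate, 0.0)
  expect_error(policy_sweep(cohort, c(0, 0.5)), "strictly inside")
})

test_that("findings can be specified by LR pairs, with Sn/Sp solved exactly", {
  # initial troponin entry: LR+ 1.4 / LR- 0.28 solve to Sn 0.9, Sp ~0.357
  expect_message(f <- sim_finding("trop", lr_positive = 1.4, lr_negative = 0.28),
                 "solved Sn = 0.9000")
  expect_equal(f$sensitivity, 0.9, tolerance = 1e-12)
  expect_equal(f$specificity, 1 - 0.72 / 1.12, tolerance = 1e-12)
  expect_equal(f$lr_positive, 1.4, tolerance = 1e-12)
  expect_equal(f$lr_negative, 0.28, tolerance = 1e-12)
  # LR+-only form fixes the false-positive rate and logs the solved Sn
  expect_message(g <- sim_finding("qoh", lr_positive = 2.6, fpr = 0.1),
                 "solved Sn = 0.2600")
  expect_equal(g$sensitivity, 0.26, tolerance = 1e-12)
  expect_error(sim_finding("bad"), "needs sensitivity")
  expect_error(sim_finding("bad", lr_positive = 0.9, lr_negative = 0.5), "requires")
})

test_that("simulation configs are validated", {
  expect_error(simulation_config(0, 0.1, list(ecg_finding())), "at least 1")
  expect_error(simulation_config(10, 1.5, list(ecg_finding())), "strictly inside")
  expect_error(simulation_config(10, 0.1, list()), "at least one finding")
  expect_error(simulation_config(10, 0.1, list(ecg_finding()), rho = 1), "rho")
  expect_error(simulation_config(10, 0.1, list("not a finding")), "sim_finding")
})
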