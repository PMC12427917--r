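# Odds/probability conversions and sequential likelihood-ratio updating.

test_that("probability/odds conversions match hand-evaluated values", {
  expect_identical(prob_to_odds(0.5), 1)
  expect_equal(prob_to_odds(0.16), 0.19047619047619, tolerance = 1e-12)
  expect_equal(prob_to_odds(0.196), 0.243781094527363, tolerance = 1e-12)
  expect_identical(odds_to_prob(1), 0.5)
  expect_equal(odds_to_prob(0.19047619047619), 0.16, tolerance = 1e-12)
  expect_equal(odds_to_prob(3.0473), 0.752921700887011, tolerance = 1e-12)
})

test_that("conversions reject out-of-domain input with the offending value", {
  expect_error(prob_to_odds(0), "strictly inside \\(0, 1\\).*0")
  expect_error(prob_to_odds(1), "strictly inside")
  expect_error(prob_to_odds(1.2), "1.2")
  expect_error(prob_to_odds(NA_real_), "non-missing")
  expect_error(odds_to_prob(0), "positive")
  expect_error(odds_to_prob(-2), "-2")
})

test_that("round trip probability -> odds -> probability is exact to 1e-12", {
  for (p in seq(0.0001, 0.9999, length.out = 201)) {
    expect_equal(odds_to_prob(prob_to_odds(p)), p, tolerance = 1e-12)
  }
})

test_that("apply_lr reproduces published single-step updates", {
  # low-prior patient, millimetric ST-elevation LR+ 12.5 -> just above 9%
  expect_equal(apply_lr(0.008, 12.5), 0.0915750915750916, tolerance = 1e-12)
  # intermediate probability knocked down by a negative initial troponin
  expect_equal(apply_lr(0.27, 0.28), 0.0938430983118173, tolerance = 1e-12)
  # pre-ECG 19.6% through LR+ 12.5 -> ~75%
  expect_equal(apply_lr(0.196, 12.5), 0.752919483712354, tolerance = 1e-12)
})

test_that("neutral evidence leaves the probability unchanged exactly", {
  for (p in c(0.001, 0.2, 0.5, 0.87, 0.999)) {
    expect_identical(apply_lr(p, 1), p)
  }
})

test_that("apply_lr is strictly monotone in both arguments", {
  lrs <- c(0.1, 0.5, 0.9, 1.3, 2, 10)
  ps <- c(0.01, 0.1, 0.4, 0.8)
  for (p in ps) {
    post <- vapply(lrs, function(l) apply_lr(p, l), numeric(1))
    expect_true(all(diff(post) > 0))
  }
  for (l in lrs) {
    post <- vapply(ps, function(p) apply_lr(p, l), numeric(1))
    expect_true(all(diff(post) > 0))
  }
})

test_that("complement symmetry: apply_lr(p, lr) + apply_lr(1-p, 1/lr) == 1", {
  set.seed(42)
  for (k in 1:50) {
    p <- runif(1, 0.001, 0.999)
    lr <- exp(runif(1, log(0.01), log(100)))
    expect_equal(apply_lr(p, lr) + apply_lr(1 - p, 1 / lr), 1, tolerance = 1e-12)
  }
})

test_that("chain_update reproduces published chains at full precision", {
  # youngest-band male with typical pain changing within 24 h -> pre-ECG 0.8%
  tr <- chain_update(0.0017, list(1.3, 1.9, 2.0))
  expect_equal(tr$posterior, 0.00834212445043101, tolerance = 1e-12)
  expect_equal(nrow(tr$steps), 3L)
  expect_equal(tr$steps$p_pre[1], 0.0017)
  expect_equal(tr$steps$p_post[3], tr$posterior)
  # 9% anchor through typical character and left-arm radiation -> 19.6%
  expect_equal(chain_update(0.09, list(1.9, 1.3))$posterior,
               0.196326061997704, tolerance = 1e-12)
  # reciprocal LRs cancel exactly
  expect_equal(chain_update(0.5, list(2.0, 0.5))$posterior, 0.5, tolerance = 1e-15)
})

test_that("empty evidence returns the prior, not an error", {
  tr <- chain_update(0.37, list())
  expect_identical(tr$posterior, 0.37)
  expect_equal(nrow(tr$steps), 0L)
})

test_that("full-precision chaining is order-invariant and collapsible", {
  set.seed(7)
  for (k in 1:20) {
    prior <- runif(1, 0.001, 0.99)
    lrs <- exp(runif(sample(2:6, 1), log(0.2), log(15)))
    post <- chain_update(prior, as.list(lrs))$posterior
    post_perm <- chain_update(prior, as.list(sample(lrs)))$posterior
    expect_equal(post, post_perm, tolerance = 1e-12)
    expect_equal(post, apply_lr(prior, prod(lrs)), tolerance = 1e-12)
  }
})

test_that("printed_checkpoint policy rounds each step half-up on the percent scale", {
  pol <- printed_checkpoint(c(2L, 1L, 1L))
  tr <- chain_update(0.0017, list(1.3, 1.9, 2.0), pol)
  expect_equal(tr$steps$p_post[1], 0.0022)   # 0.2209% -> 0.22%
  expect_equal(tr$steps$p_post[2], 0.004)    # 0.4183% -> 0.4%
  expect_equal(tr$posterior, 0.008)          # 0.797% -> 0.8%
  # half-up, not banker's: 12.5% at zero decimals goes to 13%, not 12%
  tr2 <- chain_update(0.125, list(1.0), printed_checkpoint(0L))
  expect_equal(tr2$posterior, 0.13)
})

test_that("evidence direction is inferred and inconsistencies rejected", {
  expect_identical(evidence_item("a", 2.0)$direction, "supports")
  expect_identical(evidence_item("b", 0.5)$direction, "refutes")
  expect_identical(evidence_item("c", 1.0)$direction, "neutral")
  expect_identical(evidence_item("c", 1.0, "supports")$direction, "supports")
  expect_error(evidence_item("d", 2.0, "refutes"), "inconsistent")
})

test_that("likelihood_ratio validates its value and interval", {
  expect_error(likelihood_ratio(0), "positive")
  expect_error(likelihood_ratio(-1), "positive")
  expect_error(likelihood_ratio(2, 2.5, 3), "ci_low <= value")
  expect_error(likelihood_ratio(2, 1.5, 1.8), "value <= ci_high")
  lr <- likelihood_ratio(2.6, 1.8, 3.7, label = "radiation to both arms")
  expect_equal(lr$ci_low, 1.8)
})

test_that("interval propagation collapses to the point for degenerate CIs", {
  ev <- list(
    evidence_item("a", likelihood_ratio(2.6, 2.6, 2.6)),
    evidence_item("b", likelihood_ratio(1.9, 1.9, 1.9))
  )
  iv <- propagate_interval(0.014, ev, n_draws = 2000, seed = 3)
  expect_equal(unname(iv["lower"]), unname(iv["point"]), tolerance = 1e-12)
  expect_equal(unname(iv["upper"]), unname(iv["point"]), tolerance = 1e-12)
  expect_equal(unname(iv["point"]), 0.0655445619621669, tolerance = 1e-12)
})

test_that("interval propagation brackets the published pre-ECG value", {
  # anchor 1.4% with both-arm radiation 2.6 [1.8, 3.7] and typical pain
  # 1.9 [0.94, 2.9]; point estimate ~6.6% must lie inside the MC interval
  ev <- list(
    evidence_item("radiation to both arms", likelihood_ratio(2.6, 1.8, 3.7)),
    evidence_item("typical chest pain", likelihood_ratio(1.9, 0.94, 2.9))
  )
  iv <- propagate_interval(0.014, ev, n_draws = 100000, seed = 1)
  expect_lt(iv["lower"], 0.066)
  expect_gt(iv["upper"], 0.066)
  expect_lt(iv["lower"], iv["point"])
  expect_gt(iv["upper"], iv["point"])
  # deterministic for a fixed seed
  iv2 <- propagate_interval(0.014, ev, n_draws = 100000, seed = 1)
  expect_identical(iv, iv2)
})

test_that("a single log-symmetric CI spanning 1 gives an interval spanning the prior", {
  # draws are centered on the point value with spread from the CI width, so a
  # CI that straddles 1 symmetrically on the log scale straddles the prior
  ev <- list(evidence_item("equivocal finding", likelihood_ratio(1.1, 0.55, 2.2)))
  iv <- propagate_interval(0.1, ev, n_draws = 50000, seed = 2)
  expect_lt(iv["lower"], 0.1)
  expect_gt(iv["upper"], 0.1)
})

test_that("interval propagation refuses items without a CI, naming them", {
  ev <- list(evidence_item("no-CI step", 2.0))
  expect_error(propagate_interval(0.1, ev, n_draws = 1000), "no-CI step")
  expect_error(propagate_interval(0.1, list(), n_draws = 10), "at least 1000")
})
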