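#' Define a synthetic-finding for cohort simulation
#'
#' A finding is simulated from its sensitivity (positivity rate in diseased
#' patients) and specificity (negativity rate in non-diseased). Three ways to
#' specify one:
#'
#' * `sensitivity` + `specificity` directly;
#' * `lr_positive` + `lr_negative`: the unique (Sn, Sp) pair consistent with
#'   both is solved exactly from `1 - Sp = (1 - LR-) / (LR+ - LR-)`,
#'   `Sn = LR+ * (1 - Sp)`;
#' * `lr_positive` only, plus `fpr` (the marginal positivity rate among
#'   non-diseased, default 0.2): `Sn = LR+ * fpr`. The solved values are
#'   reported via `message()` so nothing is assumed silently.
#'
#' @param id Finding identifier.
#' @param sensitivity,specificity Fractions in (0, 1).
#' @param lr_positive,lr_negative Positive/negative likelihood ratios.
#' @param fpr False-positive rate used only in the LR+-only form.
#' @return A list of class `omi_finding` with `id`, `sensitivity`,
#'   `specificity`, `lr_positive`, `lr_negative`.
#' @export
sim_finding <- function(id, sensitivity = NULL, specificity = NULL,
                        lr_positive = NULL, lr_negative = NULL, fpr = 0.2) {
  if (!is.null(sensitivity) && !is.null(specificity)) {
    sn <- sensitivity; sp <- specificity
  } else if (!is.null(lr_positive) && !is.null(lr_negative)) {
    if (lr_positive <= 1 || lr_negative >= 1 || lr_negative <= 0) {
      stop("solving Sn/Sp requires LR+ > 1 and 0 < LR- < 1 for finding '", id, "'",
           call. = FALSE)
    }
    one_minus_sp <- (1 - lr_negative) / (lr_positive - lr_negative)
    sp <- 1 - one_minus_sp
    sn <- lr_positive * one_minus_sp
    message(sprintf("finding '%s': solved Sn = %.4f, Sp = %.4f from LR+ %.3g / LR- %.3g",
                    id, sn, sp, lr_positive, lr_negative))
  } else if (!is.null(lr_positive)) {
    sn <- lr_positive * fpr
    sp <- 1 - fpr
    if (sn >= 1) {
      stop("LR+ ", lr_positive, " with fpr ", fpr, " implies sensitivity >= 1 for '",
           id, "'; lower fpr", call. = FALSE)
    }
    message(sprintf("finding '%s': fixed fpr = %.3g, solved Sn = %.4f", id, fpr, sn))
  } else {
    stop("finding '", id, "' needs sensitivity+specificity, or lr_positive (+ lr_negative)",
         call. = FALSE)
  }
  for (v in list(sn = sn, sp = sp)) {
    if (v <= 0 || v >= 1) {
      stop("finding '", id, "' has degenerate Sn/Sp (", sn, ", ", sp,
           "); simulation needs both strictly inside (0, 1)", call. = FALSE)
    }
  }
  structure(list(id = id, sensitivity = sn, specificity = sp,
                 lr_positive = sn / (1 - sp), lr_negative = (1 - sn) / sp),
            class = "omi_finding")
}

#' Configuration for a synthetic cohort
#'
#' @param n Number of patients.
#' @param prevalence True disease prevalence in (0, 1) — the prior every
#'   patient's chain starts from.
#' @param findings List of [sim_finding()]s (catalog tests can be converted
#'   with [sim_finding()] using their Sn/Sp).
#' @param rho Inter-finding correlation in \[0, 1): 0 reproduces the
#'   framework's independence assumption; larger values couple findings
#'   through a Gaussian copula (equicorrelated latent normals within each
#'   disease class) to stress the serial-multiplication arithmetic.
#' @param seed Integer seed; a config fully determines its cohort.
#' @param thresholds A [threshold_policy()] for tier assignment.
#' @return A list of class `omi_sim_config`.
#' @export
simulation_config <- function(n, prevalence, findings, rho = 0, seed = 1L,
                              thresholds = threshold_policy()) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be at least 1", call. = FALSE)
  assert_probability(prevalence, "prevalence")
  if (!length(findings)) stop("at least one finding is required", call. = FALSE)
  findings <- lapply(findings, function(f) {
    if (!inherits(f, "omi_finding")) stop("findings must be sim_finding objects", call. = FALSE)
    f
  })
  if (!is.numeric(rho) || rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  structure(list(n = n, prevalence = prevalence, findings = findings,
                 rho = rho, seed = as.integer(seed), thresholds = thresholds),
            class = "omi_sim_config")
}

#' Simulate a synthetic chest-pain cohort
#'
#' Generates disease status as Bernoulli(prevalence) and each finding
#' conditional on status with its sensitivity/specificity. With `rho > 0`
#' the findings share an equicorrelated Gaussian copula within each patient
#' (`Z_j = sqrt(rho) * Z0 + sqrt(1 - rho) * e_j`), so their marginal rates are
#' unchanged but they co-occur more than independence predicts — the exact
#' situation in which multiplying their LRs in sequence double-counts
#' evidence. Each patient's posterior is then computed by the same odds-scale
#' LR chain the bedside engine uses (accumulated on the log-odds scale, which
#' is algebraically identical to repeated [apply_lr()] by collapsibility),
#' and an action tier is assigned.
#'
#' @param config An [simulation_config()].
#' @return An object of class `omi_cohort`: `patients` (data frame with
#'   `disease`, one logical column per finding, `posterior`, `tier`) plus the
#'   config and a `summary` list (activation rate, tier sensitivity and
#'   specificity, missed-occlusion rate).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "omi_sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  n <- config$n
  k <- length(config$findings)
  disease <- stats::runif(n) < config$prevalence

  sn <- vapply(config$findings, `[[`, numeric(1), "sensitivity")
  sp <- vapply(config$findings, `[[`, numeric(1), "specificity")
  # P(finding positive | status), per patient x finding
  p_pos <- matrix(1 - sp, n, k, byrow = TRUE)
  if (any(disease)) {
    p_pos[disease, ] <- matrix(sn, sum(disease), k, byrow = TRUE)
  }

  if (config$rho > 0) {
    z0 <- stats::rnorm(n)
    eps <- matrix(stats::rnorm(n * k), n, k)
    z <- sqrt(config$rho) * z0 + sqrt(1 - config$rho) * eps
    u <- stats::pnorm(z)
  } else {
    u <- matrix(stats::runif(n * k), n, k)
  }
  positive <- u < p_pos

  log_lr_pos <- log(sn / (1 - sp))
  log_lr_neg <- log((1 - sn) / sp)
  log_odds <- log(prob_to_odds(config$prevalence)) +
    positive %*% log_lr_pos + (!positive) %*% log_lr_neg
  posterior <- as.vector(odds_to_prob(exp(log_odds)))

  tier <- ifelse(posterior > config$thresholds$lysis_threshold,
                 "activate_cath_and_lysis_eligible",
                 ifelse(posterior > config$thresholds$cath_threshold,
                        "activate_cath", "surveillance"))

  patients <- data.frame(disease = disease, positive, posterior = posterior,
                         tier = tier, stringsAsFactors = FALSE)
  names(patients)[1 + seq_len(k)] <- vapply(config$findings, `[[`, character(1), "id")

  activated <- tier != "surveillance"
  summary <- list(
    n = n,
    prevalence_true = mean(disease),
    activation_rate = mean(activated),
    tier_sensitivity = if (any(disease)) mean(activated[disease]) else NA_real_,
    tier_specificity = if (any(!disease)) mean(!activated[!disease]) else NA_real_,
    false_activation_fraction = if (any(activated)) mean(!disease[activated]) else NA_real_,
    missed_occlusion_rate = if (any(disease)) mean(!activated[disease]) else NA_real_
  )
  structure(list(patients = patients, config = config, summary = summary),
            class = "omi_cohort")
}

#' @export
print.omi_cohort <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cohort> n = %d, prevalence %.3g (drawn %.3g), rho = %.2g\n",
              s$n, x$config$prevalence, s$prevalence_true, x$config$rho))
  cat(sprintf("  activation rate %.3f; tier Sn %.3f, Sp %.3f; missed occlusions %.3f\n",
              s$activation_rate, s$tier_sensitivity, s$tier_specificity,
              s$missed_occlusion_rate))
  invisible(x)
}

#' Calibration of chained posteriors against observed disease
#'
#' Bins patients by their chained posterior on an equal-width partition of
#' \[0, 1\] and compares each bin's mean predicted probability with its
#' observed disease fraction; also fits the standard logistic calibration
#' regression of outcome on logit(posterior), whose slope and intercept are
#' (1, 0) for a perfectly calibrated predictor. Under independent findings
#' generated from the same Sn/Sp the chain uses, the posteriors are exactly
#' the Bayes-correct conditional probabilities, so slope 1 is a property of
#' the arithmetic; under correlated findings the slope pulls away from 1 —
#' the quantitative face of the independence caveat.
#'
#' @param cohort An `omi_cohort`.
#' @param n_bins Number of equal-width bins of \[0, 1\].
#' @return A list of class `omi_calibration`: `bins` (data frame `bin`,
#'   `lower`, `upper`, `mean_posterior`, `observed`, `count`; empty bins kept
#'   with count 0), `slope`, `intercept`, `slope_ci`, `intercept_ci` (95%
#'   Wald intervals).
#' @export
calibration_report <- function(cohort, n_bins = 10L) {
  stopifnot(inherits(cohort, "omi_cohort"))
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) stop("n_bins must be at least 1", call. = FALSE)
  p <- cohort$patients$posterior
  y <- cohort$patients$disease
  if (!length(p)) stop("cohort is empty", call. = FALSE)

  edges <- seq(0, 1, length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(p, edges, rightmost.closed = TRUE), 1L), n_bins)
  bins <- data.frame(
    bin = seq_len(n_bins),
    lower = edges[-(n_bins + 1L)],
    upper = edges[-1L],
    mean_posterior = vapply(seq_len(n_bins), function(b) {
      if (any(idx == b)) mean(p[idx == b]) else NA_real_
    }, numeric(1)),
    observed = vapply(seq_len(n_bins), function(b) {
      if (any(idx == b)) mean(y[idx == b]) else NA_real_
    }, numeric(1)),
    count = vapply(seq_len(n_bins), function(b) sum(idx == b), integer(1))
  )

  # logit-scale calibration regression; degenerate one-sided cohorts get NA
  slope <- intercept <- NA_real_
  slope_ci <- intercept_ci <- c(NA_real_, NA_real_)
  if (length(unique(y)) == 2L && length(unique(p)) > 1L) {
    fit <- stats::glm(y ~ stats::qlogis(p), family = stats::binomial())
    est <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    intercept <- unname(est[1]); slope <- unname(est[2])
    zc <- stats::qnorm(0.975)
    intercept_ci <- intercept + c(-1, 1) * zc * se[1]
    slope_ci <- slope + c(-1, 1) * zc * se[2]
  }
  structure(list(bins = bins, slope = slope, intercept = intercept,
                 slope_ci = slope_ci, intercept_ci = intercept_ci),
            class = "omi_calibration")
}

#' @export
print.omi_calibration <- function(x, ...) {
  cat(sprintf("<calibration> slope %.3f [%.3f, %.3f], intercept %.3f [%.3f, %.3f]\n",
              x$slope, x$slope_ci[1], x$slope_ci[2],
              x$intercept, x$intercept_ci[1], x$intercept_ci[2]))
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' Operating characteristics across a threshold grid
#'
#' For each candidate activation threshold, computes the activation rate,
#' the sensitivity for occlusion (fraction of diseased patients activated),
#' and the false-activation fraction (non-diseased among activations).
#' Activation uses the same strict-inequality convention as [recommend()].
#' Both the activation rate and the sensitivity are non-increasing in the
#' threshold — an individual-level threshold says nothing about service-line
#' rates until it is pushed through a cohort like this.
#'
#' @param cohort An `omi_cohort`.
#' @param thresholds Numeric vector of thresholds inside (0, 1).
#' @return Data frame: `threshold`, `activation_rate`, `sensitivity`,
#'   `false_activation_fraction`.
#' @export
policy_sweep <- function(cohort, thresholds) {
  stopifnot(inherits(cohort, "omi_cohort"))
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie strictly inside (0, 1)", call. = FALSE)
  }
  p <- cohort$patients$posterior
  y <- cohort$patients$disease
  rows <- lapply(sort(thresholds), function(t) {
    act <- p > t
    data.frame(
      threshold = t,
      activation_rate = mean(act),
      sensitivity = if (any(y)) mean(act[y]) else NA_real_,
      false_activation_fraction = if (any(act)) mean(!y[act]) else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Exact posterior by exhaustive enumeration
#'
#' Independent oracle for the chained arithmetic: for a small set of binary
#' findings, enumerate every findings-pattern x disease-status combination
#' and compute `P(disease | pattern)` directly from the generative model
#' (prevalence, per-finding Sn/Sp, independence within class). Used in tests
#' to show the LR chain is exactly Bayes' rule under independence.
#'
#' @param prevalence Disease prevalence.
#' @param findings List of [sim_finding()]s (at most a handful; the table has
#'   `2^k` rows).
#' @return Data frame with one row per pattern: the finding columns, the
#'   pattern probability, and `posterior`.
#' @export
enumerate_posteriors <- function(prevalence, findings) {
  assert_probability(prevalence, "prevalence")
  k <- length(findings)
  if (k > 12) stop("enumeration is intended for small k", call. = FALSE)
  sn <- vapply(findings, `[[`, numeric(1), "sensitivity")
  sp <- vapply(findings, `[[`, numeric(1), "specificity")
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
  colnames(grid) <- vapply(findings, `[[`, character(1), "id")
  lik_d <- apply(grid, 1, function(g) prod(ifelse(g, sn, 1 - sn)))
  lik_h <- apply(grid, 1, function(g) prod(ifelse(g, 1 - sp, sp)))
  joint_d <- prevalence * lik_d
  joint_h <- (1 - prevalence) * lik_h
  out <- as.data.frame(grid)
  out$pattern_prob <- joint_d + joint_h
  out$posterior <- joint_d / (joint_d + joint_h)
  out
}
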