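#' Action-threshold policy
#'
#' The two pragmatic decision lines of the framework: a posterior probability
#' strictly above `cath_threshold` mobilizes the catheterization laboratory
#' (angiography both confirms and treats, at low procedural risk), and a
#' posterior strictly above `lysis_threshold` additionally justifies systemic
#' thrombolysis when angiography is unavailable (an irreversible therapy with
#' real hemorrhagic risk, so the bar is far higher). Comparisons are strictly
#' greater-than: a posterior sitting exactly on a threshold stays in the
#' lower tier. These cut-points are didactic landmarks, not universal
#' constants; systems with longer transfer delays or higher bleeding risk
#' should move them.
#'
#' @param cath_threshold Catheterization-activation threshold, default 0.10.
#' @param lysis_threshold Fibrinolysis threshold, default 0.75.
#' @return An object of class `omi_policy_thresholds`.
#' @export
threshold_policy <- function(cath_threshold = 0.10, lysis_threshold = 0.75) {
  assert_probability(cath_threshold, "cath_threshold")
  assert_probability(lysis_threshold, "lysis_threshold")
  if (cath_threshold >= lysis_threshold) {
    stop("cath_threshold must be below lysis_threshold", call. = FALSE)
  }
  structure(list(cath_threshold = cath_threshold, lysis_threshold = lysis_threshold),
            class = "omi_policy_thresholds")
}

#' Map a posterior probability to an action tier
#'
#' @param posterior Posterior probability fraction in (0, 1).
#' @param policy A [threshold_policy()].
#' @return Character scalar: `"surveillance"`, `"activate_cath"`, or
#'   `"activate_cath_and_lysis_eligible"`. The tier names describe which
#'   threshold was crossed; they are decision support, not orders.
#' @examples
#' recommend(0.17)    # above the 10% catheterization trigger
#' recommend(0.10)    # exactly at threshold: stays surveillance
#' recommend(0.7529)  # above both thresholds
#' @export
recommend <- function(posterior, policy = threshold_policy()) {
  assert_probability(posterior, "posterior")
  stopifnot(inherits(policy, "omi_policy_thresholds"))
  if (posterior > policy$lysis_threshold) {
    "activate_cath_and_lysis_eligible"
  } else if (posterior > policy$cath_threshold) {
    "activate_cath"
  } else {
    "surveillance"
  }
}

#' Classical test/treatment thresholds
#'
#' Computes the decision-analytic thresholds that the pragmatic 10%/75%
#' targets approximate, reconstructed in their standard textbook form. With
#' `Brx` the net benefit of treating a diseased patient, `Rrx` the net harm
#' of treating a non-diseased patient, `Rt` the intrinsic risk of the
#' confirmatory test, and the test's sensitivity and specificity, the three
#' pivot probabilities are:
#'
#' * no-test treatment threshold: `Rrx / (Rrx + Brx)` — where treating and
#'   not treating break even without any test;
#' * testing threshold:
#'   `((1 - Sp) * Rrx + Rt) / ((1 - Sp) * Rrx + Sn * Brx)` — below it,
#'   neither testing nor treating is worthwhile;
#' * test-treatment threshold:
#'   `(Sp * Rrx - Rt) / (Sp * Rrx + (1 - Sn) * Brx)` — above it, treat
#'   without waiting for the test.
#'
#' All utilities are on a common scale, so the thresholds are invariant to
#' rescaling `(Brx, Rrx, Rt)` by a common positive factor. If the test's risk
#' exceeds what a positive result could ever gain (a negative numerator), the
#' test is never useful and the function says so.
#'
#' @param Brx Net benefit of treating a diseased patient (> 0).
#' @param Rrx Net harm of treating a non-diseased patient (>= 0).
#' @param Rt Intrinsic risk of the confirmatory test (>= 0).
#' @param Sn,Sp Sensitivity and specificity of the confirmatory test.
#' @return List with `testing_threshold`, `test_treatment_threshold`,
#'   `no_test_treatment_threshold` (all clamped to \[0, 1\]) and
#'   `test_useful` (logical).
#' @examples
#' pauker_kassirer_thresholds(Brx = 9, Rrx = 1, Rt = 0, Sn = 0.781, Sp = 0.944)
#' @export
pauker_kassirer_thresholds <- function(Brx, Rrx, Rt = 0, Sn, Sp) {
  for (v in list(Brx = Brx, Rrx = Rrx, Rt = Rt)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("Brx, Rrx and Rt must be non-negative numbers", call. = FALSE)
    }
  }
  if (Brx <= 0) stop("Brx must be strictly positive", call. = FALSE)
  for (v in list(Sn = Sn, Sp = Sp)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v > 1) {
      stop("Sn and Sp must be fractions in (0, 1]", call. = FALSE)
    }
  }
  no_test <- Rrx / (Rrx + Brx)
  t_test <- ((1 - Sp) * Rrx + Rt) / ((1 - Sp) * Rrx + Sn * Brx)
  num_tt <- Sp * Rrx - Rt
  den_tt <- Sp * Rrx + (1 - Sn) * Brx
  test_useful <- TRUE
  if (num_tt < 0) {
    # test risk exceeds any possible gain from a negative result
    test_useful <- FALSE
  }
  t_treat <- if (den_tt > 0) num_tt / den_tt else 1
  clamp01 <- function(x) min(max(x, 0), 1)
  list(
    testing_threshold = clamp01(t_test),
    test_treatment_threshold = clamp01(t_treat),
    no_test_treatment_threshold = clamp01(no_test),
    test_useful = test_useful
  )
}
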