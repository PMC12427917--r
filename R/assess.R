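# Patient assessment: the front-door operation that ties the modules
# together. Reads a structured patient record, resolves every finding and
# test against the catalog, chains the LRs onto the demographic anchor, and
# emits an auditable report.

REPORT_SCHEMA_VERSION <- "1"

DISCLAIMER <- paste(
  "Didactic decision support: this probability chain illustrates Bayesian",
  "reasoning with published likelihood ratios. It is not a medical device and",
  "does not replace clinical judgment; thresholds are system-specific."
)

#' Read and validate a patient input file
#'
#' Patient records are YAML or JSON (auto-detected; JSON is a subset of YAML)
#' with fields `age` (years), `sex` (`"female"`/`"male"`), and any of
#' `findings` (list of `{feature, present}` referencing the catalog's
#' clinical features), `tests` (ordered list of `{test, result}`), and
#' `custom_evidence` (list of `{label, lr}` for explicit multipliers).
#' Ordering is preserved — the sequence matters under per-step rounding and
#' in the nomogram ladder. Violations raise a classed condition
#' (`omi_schema_error`) listing every offending line.
#'
#' @param path Path to the record.
#' @return A validated list of class `omi_patient`.
#' @export
read_patient_input <- function(path) {
  if (!file.exists(path)) {
    schema_error(paste0("input file not found: ", path))
  }
  rec <- tryCatch(yaml::read_yaml(path),
                  error = function(e) schema_error(paste0("cannot parse ", path, ": ",
                                                          conditionMessage(e))))
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  allowed <- c("age", "sex", "findings", "tests", "custom_evidence")
  extra <- setdiff(names(rec), allowed)
  if (length(extra)) note(paste0("unknown keys: ", paste(extra, collapse = ", ")))
  if (is.null(rec$age) || !is.numeric(rec$age) || rec$age < 0) {
    note("'age' must be a non-negative number")
  }
  if (is.null(rec$sex) || !rec$sex %in% c("female", "male")) {
    note("'sex' must be \"female\" or \"male\"")
  }
  for (f in rec$findings) {
    if (is.null(f$feature)) note("findings entries need a 'feature' id")
    if (is.null(f$present) || !is.logical(f$present)) {
      note(paste0("finding '", f$feature, "' needs logical 'present'"))
    }
  }
  for (t in rec$tests) {
    if (is.null(t$test)) note("tests entries need a 'test' id")
    if (is.null(t$result) || !t$result %in% c("positive", "negative")) {
      note(paste0("test '", t$test, "' needs result \"positive\" or \"negative\""))
    }
  }
  for (ce in rec$custom_evidence) {
    if (is.null(ce$lr) || !is.numeric(ce$lr) || ce$lr <= 0) {
      note(paste0("custom evidence '", ce$label, "' needs a positive 'lr'"))
    }
  }
  if (length(problems)) {
    schema_error(paste0("invalid patient input ", path, ":\n  - ",
                        paste(problems, collapse = "\n  - ")))
  }
  structure(rec, class = "omi_patient")
}

schema_error <- function(msg) {
  stop(structure(class = c("omi_schema_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Assess a patient record
#'
#' Runs the full pipeline: demographic anchor, sequential likelihood-ratio
#' updates for every finding and test in order, action tier, and a
#' serializable report with the complete audit trail. With the default
#' `"printed"` policy each step's output is rounded to one decimal on the
#' percent scale before the next step, matching bedside nomogram practice
#' and published walkthroughs; `"full"` carries machine precision.
#'
#' @param input Path to a patient record, or an already-validated
#'   `omi_patient` / plain list with the same fields.
#' @param policy `"printed"` (one-decimal per-step rounding, default) or
#'   `"full"`.
#' @param thresholds A [threshold_policy()].
#' @param catalog An `omi_catalog`.
#' @param interval If `TRUE`, adds a Monte-Carlo 95% posterior interval via
#'   [propagate_interval()] (requires every applied LR to carry a CI).
#' @param nomogram Optional file path; if given, the update ladder is
#'   rendered there as SVG.
#' @return An `omi_report`: patient echo, anchor, per-step trail, posterior,
#'   tier, thresholds, catalog version, schema version, and disclaimer.
#' @examples
#' \donttest{
#' rec <- list(age = 40, sex = "female",
#'             findings = list(list(feature = "typical_chest_pain", present = TRUE)),
#'             tests = list(list(test = "ecg_omi_comprehensive", result = "positive")))
#' assess(rec)
#' }
#' @export
assess <- function(input, policy = c("printed", "full"),
                   thresholds = threshold_policy(), catalog = load_catalog(),
                   interval = FALSE, nomogram = NULL) {
  policy <- match.arg(policy)
  rec <- if (is.character(input)) read_patient_input(input) else input

  evidence <- list()
  if (identical(rec$sex, "male")) {
    evidence[[1L]] <- evidence_item(
      "male sex (odds multiplier)",
      likelihood_ratio(catalog$anchors$male_odds_multiplier,
                       source = "anchor table footnote"))
  }
  for (f in rec$findings) {
    evidence[[length(evidence) + 1L]] <-
      evidence_item(paste0(f$feature, if (isTRUE(f$present)) ", present" else ", absent"),
                    lookup_clinical_lr(f$feature, isTRUE(f$present), catalog))
  }
  for (t in rec$tests) {
    evidence[[length(evidence) + 1L]] <-
      evidence_item(paste0(t$test, ", ", t$result),
                    lookup_test_lr(t$test, t$result, catalog))
  }
  for (ce in rec$custom_evidence) {
    lbl <- if (is.null(ce$label)) sprintf("custom LR %.4g", ce$lr) else ce$label
    evidence[[length(evidence) + 1L]] <-
      evidence_item(lbl, likelihood_ratio(ce$lr, source = "user-supplied"))
  }

  anchor <- anchor_probability(rec$age, "female", catalog)
  chain_policy <- if (policy == "printed") printed_checkpoint(1L) else full_precision()
  trace <- chain_update(anchor, evidence, chain_policy)

  ival <- NULL
  if (isTRUE(interval) && length(evidence)) {
    with_ci <- lapply(evidence, function(it) {
      if (is.na(it$lr$ci_low)) {
        # point evidence: degenerate interval so propagation still runs
        evidence_item(it$label, likelihood_ratio(it$lr$value, it$lr$value,
                                                 it$lr$value, it$label))
      } else it
    })
    ival <- propagate_interval(anchor, with_ci, n_draws = 20000L, seed = 20000L)
  }

  report <- structure(list(
    schema_version = REPORT_SCHEMA_VERSION,
    patient = list(age = rec$age, sex = rec$sex),
    policy = policy,
    anchor_percent = round_half_up(100 * anchor, 2L),
    steps = data.frame(
      label = trace$steps$label,
      lr = trace$steps$lr,
      pre_percent = round_half_up(100 * trace$steps$p_pre, 1L),
      post_percent = round_half_up(100 * trace$steps$p_post, 1L),
      stringsAsFactors = FALSE
    ),
    posterior_percent = round_half_up(100 * trace$posterior, 1L),
    interval_percent = if (is.null(ival)) NULL else round_half_up(100 * ival, 1L),
    tier = recommend(trace$posterior, thresholds),
    thresholds = list(cath_percent = 100 * thresholds$cath_threshold,
                      lysis_percent = 100 * thresholds$lysis_threshold),
    catalog_version = if (is.null(catalog$version)) "unversioned" else catalog$version,
    disclaimer = DISCLAIMER
  ), class = "omi_report", trace = trace)

  if (!is.null(nomogram)) {
    render_nomogram(NULL, nomogram, trace = trace)
  }
  report
}

#' Serialize an assessment report
#'
#' `report_json()` gives the stable machine-readable form (deterministic:
#' identical inputs give identical bytes); `print()` gives the human table.
#'
#' @param report An `omi_report`.
#' @param path Optional file to write to.
#' @return The JSON string, invisibly if written to a file.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "omi_report"))
  x <- unclass(report)
  attr(x, "trace") <- NULL
  x$steps <- lapply(seq_len(nrow(report$steps)), function(k) as.list(report$steps[k, ]))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path, useBytes = TRUE)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' @export
print.omi_report <- function(x, ...) {
  cat(sprintf("OMI assessment (schema %s, catalog %s, %s policy)\n",
              x$schema_version, x$catalog_version, x$policy))
  cat(sprintf("  patient: %s, age %s\n", x$patient$sex, format(x$patient$age)))
  cat(sprintf("  anchor: %.2f%%\n", x$anchor_percent))
  if (nrow(x$steps)) {
    for (k in seq_len(nrow(x$steps))) {
      cat(sprintf("  %2d. %-52s LR %7.4g  %6.1f%% -> %6.1f%%\n",
                  k, substr(x$steps$label[k], 1, 52), x$steps$lr[k],
                  x$steps$pre_percent[k], x$steps$post_percent[k]))
    }
  }
  cat(sprintf("  posterior: %.1f%%", x$posterior_percent))
  if (!is.null(x$interval_percent)) {
    cat(sprintf("  (95%% MC interval %.1f-%.1f%%)",
                x$interval_percent[["lower"]], x$interval_percent[["upper"]]))
  }
  cat(sprintf("\n  tier: %s (cath > %g%%, lysis > %g%%)\n", x$tier,
              x$thresholds$cath_percent, x$thresholds$lysis_percent))
  cat("  ", x$disclaimer, "\n", sep = "")
  invisible(x)
}
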