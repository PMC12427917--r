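#' Load an evidence catalog
#'
#' Reads the structured-text catalog holding the three sections of the
#' evidence base: `anchors` (age/sex baseline prevalences of acute coronary
#' occlusion among ED chest-pain patients, with the derivation constants),
#' `clinical_features` (pre-ECG likelihood ratios for chest-pain descriptors),
#' and `tests` (ECG tiers and troponin assays, as sensitivity/specificity or
#' direct LRs). The file is schema-checked on load; unknown sections or entry
#' keys are rejected so a typo cannot silently drop evidence.
#'
#' @param path Path to a YAML catalog. Defaults to the catalog shipped with
#'   the package.
#' @return An object of class `omi_catalog`.
#' @examples
#' cat <- load_catalog()
#' names(cat)
#' @export
load_catalog <- function(path = default_catalog_path()) {
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  validate_catalog_schema(raw, path)
  structure(raw, class = "omi_catalog", path = path)
}

#' @rdname load_catalog
#' @export
default_catalog_path <- function() {
  system.file("extdata", "catalog.yaml", package = "omibayes", mustWork = TRUE)
}

#' Write a catalog back to disk
#'
#' @param catalog An `omi_catalog`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
save_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "omi_catalog"))
  x <- unclass(catalog)
  attr(x, "path") <- NULL
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

validate_catalog_schema <- function(raw, path) {
  fail <- function(...) stop("catalog schema error in ", path, ": ", ..., call. = FALSE)
  allowed_top <- c("version", "anchors", "clinical_features", "tests")
  if (!is.list(raw)) fail("top level must be a mapping")
  extra <- setdiff(names(raw), allowed_top)
  if (length(extra)) fail("unknown top-level keys: ", paste(extra, collapse = ", "))
  missing <- setdiff(c("anchors", "clinical_features", "tests"), names(raw))
  if (length(missing)) fail("missing sections: ", paste(missing, collapse = ", "))

  a <- raw$anchors
  allowed_a <- c("chest_pain_share", "omi_multiplier", "male_odds_multiplier",
                 "cap_percent", "source", "bands")
  extra <- setdiff(names(a), allowed_a)
  if (length(extra)) fail("unknown anchor keys: ", paste(extra, collapse = ", "))
  if (!is.numeric(a$chest_pain_share) || a$chest_pain_share <= 0 || a$chest_pain_share >= 1) {
    fail("chest_pain_share must be a fraction in (0,1)")
  }
  if (!is.numeric(a$omi_multiplier) || a$omi_multiplier <= 0) fail("omi_multiplier must be positive")
  if (!is.numeric(a$male_odds_multiplier) || a$male_odds_multiplier <= 0) {
    fail("male_odds_multiplier must be positive")
  }
  if (!length(a$bands)) fail("anchors$bands is empty")
  allowed_band <- c("band", "age_min", "age_max", "stemi_rate_per_10k",
                    "stemi_prevalence_pct", "p_omi_pct", "derivation_whitelisted", "capped")
  prev_p <- -Inf
  prev_max <- -Inf
  for (b in a$bands) {
    extra <- setdiff(names(b), allowed_band)
    if (length(extra)) fail("unknown band keys: ", paste(extra, collapse = ", "))
    need <- setdiff(c("band", "age_min", "age_max", "stemi_rate_per_10k", "p_omi_pct"), names(b))
    if (length(need)) fail("band ", b$band, " missing keys: ", paste(need, collapse = ", "))
    if (b$age_min <= prev_max) fail("bands must be ordered by age and non-overlapping")
    if (b$p_omi_pct < prev_p) fail("anchor probability must be non-decreasing with age")
    if (b$p_omi_pct <= 0 || b$p_omi_pct >= 100) fail("p_omi_pct out of range in band ", b$band)
    prev_p <- b$p_omi_pct
    prev_max <- b$age_max
  }

  allowed_feat <- c("id", "description", "lr_positive", "lr_negative")
  ids <- character(0)
  for (f in raw$clinical_features) {
    extra <- setdiff(names(f), allowed_feat)
    if (length(extra)) fail("unknown feature keys in ", f$id, ": ", paste(extra, collapse = ", "))
    if (is.null(f$id) || is.null(f$lr_positive) || is.null(f$lr_negative)) {
      fail("feature entries need id, lr_positive, lr_negative")
    }
    for (side in c("lr_positive", "lr_negative")) check_lr_node(f[[side]], f$id, fail)
    ids <- c(ids, f$id)
  }
  if (anyDuplicated(ids)) fail("duplicate feature ids")

  allowed_test <- c("id", "description", "sensitivity", "specificity",
                    "lr_positive", "lr_negative", "source")
  tids <- character(0)
  for (t in raw$tests) {
    extra <- setdiff(names(t), allowed_test)
    if (length(extra)) fail("unknown test keys in ", t$id, ": ", paste(extra, collapse = ", "))
    has_acc <- !is.null(t$sensitivity) && !is.null(t$specificity)
    has_lr <- !is.null(t$lr_positive) && !is.null(t$lr_negative)
    if (!has_acc && !has_lr) {
      fail("test ", t$id, " needs sensitivity+specificity or lr_positive+lr_negative")
    }
    if (has_acc) {
      if (t$sensitivity <= 0 || t$sensitivity > 1) fail("sensitivity out of (0,1] in ", t$id)
      if (t$specificity <= 0 || t$specificity > 1) fail("specificity out of (0,1] in ", t$id)
    }
    tids <- c(tids, t$id)
  }
  if (anyDuplicated(tids)) fail("duplicate test ids")
  invisible(TRUE)
}

check_lr_node <- function(node, id, fail) {
  allowed <- c("value", "ci_low", "ci_high", "range")
  extra <- setdiff(names(node), allowed)
  if (length(extra)) fail("unknown LR keys in ", id, ": ", paste(extra, collapse = ", "))
  if (is.null(node$value) || node$value <= 0) fail("LR value missing or non-positive in ", id)
  if (!is.null(node$ci_low) && (node$ci_low > node$value || node$ci_high < node$value)) {
    fail("LR interval does not bracket the value in ", id)
  }
}

lr_from_node <- function(node, label = "", source = "") {
  likelihood_ratio(node$value,
                   ci_low = if (is.null(node$ci_low)) NA_real_ else node$ci_low,
                   ci_high = if (is.null(node$ci_high)) NA_real_ else node$ci_high,
                   label = label, source = source)
}

#' Age- and sex-specific anchor probability of occlusion MI
#'
#' Looks up the baseline probability of an acute culprit coronary occlusion
#' for an ED chest-pain patient, before any symptom, biomarker or ECG
#' evidence. Anchors are tabulated for women by age band (closed-open integer
#' bands: 18-34, 35-44, ..., 85+); for men the female anchor's odds are
#' multiplied by the catalog's male multiplier (default 1.3). Patients under
#' 18 are mapped to the youngest band with a warning — pediatric chest pain
#' is outside the surveillance data the anchors come from, but the framework
#' still needs a starting point for them.
#'
#' @param age Age in years, non-negative.
#' @param sex `"female"` or `"male"`.
#' @param catalog An `omi_catalog`; defaults to the shipped catalog.
#' @return Probability fraction in (0, 1).
#' @examples
#' anchor_probability(70, "female")  # 0.106
#' anchor_probability(70, "male")    # ~0.134 (odds-scale x1.3)
#' @export
anchor_probability <- function(age, sex = c("female", "male"),
                               catalog = load_catalog()) {
  sex <- match.arg(sex)
  if (!is.numeric(age) || length(age) != 1L || is.na(age)) {
    stop("age must be a single number", call. = FALSE)
  }
  if (age < 0) stop("age must be non-negative, got ", age, call. = FALSE)
  bands <- catalog$anchors$bands
  age_min_first <- bands[[1L]]$age_min
  if (age < age_min_first) {
    warning(sprintf("age %s below the youngest anchor band; using the %s band",
                    format(age), bands[[1L]]$band))
    age <- age_min_first
  }
  row <- NULL
  for (b in bands) {
    if (age >= b$age_min && age < b$age_max + 1) { row <- b; break }
  }
  if (is.null(row)) row <- bands[[length(bands)]]
  p <- row$p_omi_pct / 100
  if (sex == "male") {
    p <- apply_lr(p, catalog$anchors$male_odds_multiplier)
  }
  p
}

#' Derive the anchor table from surveillance inputs
#'
#' Reproduces the pipeline behind the shipped anchor table: a STEMI ED-visit
#' rate per 10,000 encounters is divided by the chest-pain share of ED visits
#' to give STEMI prevalence among chest-pain patients, then multiplied by the
#' occlusion-to-STEMI ratio to give the occlusion-MI anchor. The oldest band
#' is capped (rounded down) to avoid overestimation in very frail
#' populations. All values are kept at full precision; rounding to the
#' printed number of decimals happens only in display.
#'
#' @param stemi_rates Named numeric vector of STEMI visits per 10,000 ED
#'   encounters, one per age band (names are band labels).
#' @param chest_pain_share Fraction of ED visits that are chest pain
#'   (default 0.05).
#' @param omi_multiplier Ratio of occlusion MI to STEMI prevalence
#'   (default 1.7).
#' @param cap Cap, as a percent, applied to the last (oldest) band; `NULL`
#'   for no cap.
#' @return A data frame with columns `band`, `stemi_rate_per_10k`,
#'   `stemi_prevalence_pct`, `p_omi_pct`, `capped`.
#' @examples
#' derive_anchor_table(c("18-34" = 0.5, ">=85" = 83.4))
#' @export
derive_anchor_table <- function(stemi_rates, chest_pain_share = 0.05,
                                omi_multiplier = 1.7, cap = 25) {
  if (!is.numeric(stemi_rates) || any(stemi_rates <= 0)) {
    stop("stemi_rates must be positive numbers", call. = FALSE)
  }
  if (chest_pain_share <= 0 || chest_pain_share >= 1) {
    stop("chest_pain_share must be a fraction in (0,1)", call. = FALSE)
  }
  prevalence_pct <- stemi_rates / 10000 / chest_pain_share * 100
  p_omi_pct <- prevalence_pct * omi_multiplier
  capped <- rep(FALSE, length(stemi_rates))
  if (!is.null(cap) && length(stemi_rates) > 0) {
    k <- length(p_omi_pct)
    if (p_omi_pct[k] > cap) {
      p_omi_pct[k] <- cap
      capped[k] <- TRUE
    }
  }
  data.frame(
    band = if (is.null(names(stemi_rates))) as.character(seq_along(stemi_rates)) else names(stemi_rates),
    stemi_rate_per_10k = unname(stemi_rates),
    stemi_prevalence_pct = unname(prevalence_pct),
    p_omi_pct = unname(p_omi_pct),
    capped = capped,
    stringsAsFactors = FALSE
  )
}

#' Test characteristics from sensitivity and specificity
#'
#' Converts a test's accuracy into the likelihood ratios the updating engine
#' consumes: `LR+ = Sn / (1 - Sp)`, `LR- = (1 - Sn) / Sp`, and the diagnostic
#' odds ratio `DOR = LR+ / LR-`. Boundary accuracies are tolerated and
#' flagged rather than rejected: a perfectly specific test has an infinite
#' positive LR (a positive result is pathognomonic) and a perfectly sensitive
#' test has a negative LR of zero.
#'
#' @param sensitivity,specificity Fractions in (0, 1]; values of exactly 1
#'   produce flagged boundary LRs.
#' @param id,source Optional identifier and citation carried along.
#' @return An object of class `omi_test` with fields `sensitivity`,
#'   `specificity`, `lr_positive`, `lr_negative`, `dor`, and `boundary`.
#' @examples
#' lr_from_accuracy(0.436, 0.965)  # LR+ 12.5, LR- 0.58, DOR 21.3
#' lr_from_accuracy(0.80, 0.98)    # LR+ 40
#' @export
lr_from_accuracy <- function(sensitivity, specificity, id = "", source = "") {
  for (v in list(sensitivity, specificity)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v > 1) {
      stop("sensitivity and specificity must be fractions in (0, 1], got ",
           deparse(v), call. = FALSE)
    }
  }
  boundary <- character(0)
  lr_pos <- if (specificity == 1) {
    boundary <- c(boundary, "infinite positive LR (specificity = 1)")
    Inf
  } else sensitivity / (1 - specificity)
  lr_neg <- if (sensitivity == 1) {
    boundary <- c(boundary, "zero negative LR (sensitivity = 1)")
    0
  } else (1 - sensitivity) / specificity
  dor <- if (lr_neg == 0 || is.infinite(lr_pos)) Inf else lr_pos / lr_neg
  structure(
    list(id = id, sensitivity = sensitivity, specificity = specificity,
         lr_positive = lr_pos, lr_negative = lr_neg, dor = dor,
         boundary = boundary, source = source),
    class = "omi_test"
  )
}

#' @export
print.omi_test <- function(x, ...) {
  cat(sprintf("<test> %s  Sn %.1f%%  Sp %.1f%%  LR+ %.4g  LR- %.4g  DOR %.4g\n",
              if (nzchar(x$id)) x$id else "(unnamed)",
              100 * x$sensitivity, 100 * x$specificity,
              x$lr_positive, x$lr_negative, x$dor))
  if (length(x$boundary)) cat("  boundary:", paste(x$boundary, collapse = "; "), "\n")
  invisible(x)
}

#' Look up a clinical feature's likelihood ratio
#'
#' @param feature Feature id from the catalog's `clinical_features` section.
#' @param present `TRUE` for the finding being present (positive LR),
#'   `FALSE` for explicitly absent (negative LR).
#' @param catalog An `omi_catalog`.
#' @return A [likelihood_ratio()] with description and source attached.
#' @examples
#' lookup_clinical_lr("radiation_both_arms", TRUE)   # 2.6
#' lookup_clinical_lr("typical_chest_pain", FALSE)   # 0.52
#' @export
lookup_clinical_lr <- function(feature, present = TRUE, catalog = load_catalog()) {
  feats <- catalog$clinical_features
  ids <- vapply(feats, function(f) f$id, character(1))
  i <- match(feature, ids)
  if (is.na(i)) {
    stop("unknown clinical feature '", feature, "'; available: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  f <- feats[[i]]
  node <- if (isTRUE(present)) f$lr_positive else f$lr_negative
  lr_from_node(node,
               label = paste0(f$description, if (isTRUE(present)) ", present" else ", absent"),
               source = "pooled pre-ECG chest-pain likelihood ratios")
}

#' Look up a diagnostic test's likelihood ratio
#'
#' Resolves a catalog test entry (ECG tier or troponin assay) into the
#' likelihood ratio for a positive or negative result. Entries stated as
#' sensitivity/specificity are converted with [lr_from_accuracy()]; entries
#' stated as direct LRs are returned as published.
#'
#' @param test Test id from the catalog's `tests` section.
#' @param result `"positive"` or `"negative"`.
#' @param catalog An `omi_catalog`.
#' @return A [likelihood_ratio()].
#' @examples
#' lookup_test_lr("ecg_ste_only", "positive")        # ~12.5
#' lookup_test_lr("ecg_omi_comprehensive", "negative")  # ~0.23
#' @export
lookup_test_lr <- function(test, result = c("positive", "negative"),
                           catalog = load_catalog()) {
  result <- match.arg(result)
  tc <- lookup_test(test, catalog)
  value <- if (result == "positive") tc$lr_positive else tc$lr_negative
  if (!is.finite(value) || value <= 0) {
    stop("test '", test, "' has a boundary ", result, " LR (", value,
         "); it cannot be applied as a finite multiplier", call. = FALSE)
  }
  likelihood_ratio(value,
                   label = paste0(tc$id, ", ", result),
                   source = tc$source)
}

#' @rdname lookup_test_lr
#' @export
lookup_test <- function(test, catalog = load_catalog()) {
  tests <- catalog$tests
  ids <- vapply(tests, function(t) t$id, character(1))
  i <- match(test, ids)
  if (is.na(i)) {
    stop("unknown test '", test, "'; available: ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  t <- tests[[i]]
  src <- if (is.null(t$source)) "" else t$source
  if (!is.null(t$sensitivity)) {
    lr_from_accuracy(t$sensitivity, t$specificity, id = t$id, source = src)
  } else {
    structure(
      list(id = t$id, sensitivity = NA_real_, specificity = NA_real_,
           lr_positive = t$lr_positive$value, lr_negative = t$lr_negative$value,
           dor = t$lr_positive$value / t$lr_negative$value,
           boundary = character(0), source = src),
      class = "omi_test"
    )
  }
}

#' Validate a catalog against its own derivation rules
#'
#' Checks every anchor band against the derivation pipeline (rate / 10,000 /
#' chest-pain share x occlusion multiplier, within printed rounding of
#' +/- 0.02 percentage points), honoring per-row whitelists for published
#' values that disagree with the pipeline, and checks every
#' sensitivity/specificity test entry for internal LR/DOR consistency.
#'
#' @param catalog An `omi_catalog`.
#' @return A data frame with one row per checked item: `section`, `id`,
#'   `status` (`"ok"`, `"whitelisted"`, `"capped"`, or `"mismatch"`), and
#'   `detail`.
#' @export
catalog_validate <- function(catalog = load_catalog()) {
  a <- catalog$anchors
  rows <- list()
  for (b in a$bands) {
    derived_prev <- b$stemi_rate_per_10k / 10000 / a$chest_pain_share * 100
    derived_omi <- derived_prev * a$omi_multiplier
    status <- "ok"
    detail <- sprintf("derived prevalence %.3f%% / anchor %.3f%%; published %.3g%% / %.3g%%",
                      derived_prev, derived_omi,
                      if (is.null(b$stemi_prevalence_pct)) NA_real_ else b$stemi_prevalence_pct,
                      b$p_omi_pct)
    prev_ok <- is.null(b$stemi_prevalence_pct) ||
      abs(derived_prev - b$stemi_prevalence_pct) <= round_tolerance(b$stemi_prevalence_pct) + 1e-9
    omi_ok <- abs(derived_omi - b$p_omi_pct) <= 0.02 + round_tolerance(b$p_omi_pct) + 1e-9
    if (isTRUE(b$capped)) {
      status <- if (b$p_omi_pct <= derived_omi) "capped" else "mismatch"
      detail <- sprintf("derived anchor %.3f%% capped to %.3g%%", derived_omi, b$p_omi_pct)
    } else if (!prev_ok || !omi_ok) {
      status <- if (isTRUE(b$derivation_whitelisted)) "whitelisted" else "mismatch"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      section = "anchors", id = b$band, status = status, detail = detail,
      stringsAsFactors = FALSE
    )
  }
  for (t in catalog$tests) {
    if (!is.null(t$sensitivity)) {
      tc <- lr_from_accuracy(t$sensitivity, t$specificity, id = t$id)
      ok <- is.infinite(tc$dor) ||
        abs(tc$dor - tc$lr_positive / tc$lr_negative) <= 1e-9
      rows[[length(rows) + 1L]] <- data.frame(
        section = "tests", id = t$id,
        status = if (ok) "ok" else "mismatch",
        detail = sprintf("LR+ %.4g, LR- %.4g, DOR %.4g", tc$lr_positive,
                         tc$lr_negative, tc$dor),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# Rounding slack implied by the number of decimals the published value shows.
round_tolerance <- function(x) {
  s <- format(x)
  dec <- if (grepl("\\.", s)) nchar(sub("^[^.]*\\.", "", s)) else 0L
  0.5 * 10^(-dec)
}
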