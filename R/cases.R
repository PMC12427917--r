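#' Load a published case fixture
#'
#' The package ships five case vignettes as structured text fixtures. Each
#' records the patient's demographics, the ordered evidence sequence (catalog
#' references or explicit published LRs), and every probability checkpoint the
#' source prints, with the number of decimals it was printed at and the
#' tolerance it must reproduce within.
#'
#' @param id Case number, 1 to 5.
#' @return The parsed fixture (class `omi_case`).
#' @export
load_case <- function(id) {
  id <- suppressWarnings(as.integer(id))
  if (length(id) != 1L || is.na(id) || id < 1L || id > 5L) {
    stop("unknown case id; available cases are 1 to 5", call. = FALSE)
  }
  path <- system.file("extdata", "cases", sprintf("case-%d.yaml", id),
                      package = "omibayes", mustWork = TRUE)
  fx <- yaml::read_yaml(path)
  structure(fx, class = "omi_case", path = path)
}

# Resolve one fixture evidence entry to an evidence_item via the catalog.
resolve_evidence_entry <- function(entry, catalog) {
  lr <- if (!is.null(entry$feature)) {
    lookup_clinical_lr(entry$feature, isTRUE(entry$present), catalog)
  } else if (!is.null(entry$test)) {
    lookup_test_lr(entry$test, entry$result, catalog)
  } else if (!is.null(entry$lr)) {
    likelihood_ratio(entry$lr, label = entry$label, source = "published case value")
  } else {
    stop("evidence entry needs a 'feature', 'test', or explicit 'lr': ",
         entry$label, call. = FALSE)
  }
  evidence_item(entry$label, lr)
}

#' Replay a published case through the updating engine
#'
#' Runs a case's anchor and evidence chain and compares every printed
#' probability checkpoint against the recomputed value. Under the
#' `"printed_checkpoint"` policy the replay mirrors the source's own
#' arithmetic: at each checkpoint the computed probability is compared with
#' the printed one (pass if within the fixture's tolerance, on the percent
#' scale) and the chain then continues *from the printed value*, because that
#' is how the published walkthroughs were computed. Under `"full_precision"`
#' no substitution or rounding occurs and checkpoints are reported for
#' information only.
#'
#' @param id Case number 1-5, or an `omi_case` from [load_case()].
#' @param policy `"printed_checkpoint"` (default) or `"full_precision"`.
#' @param catalog Evidence catalog to resolve references against.
#' @param thresholds A [threshold_policy()] used to attach an action tier.
#' @return An object of class `omi_replay`: the fixture, an `omi_trace`, a
#'   checkpoint report data frame (`label`, `printed`, `computed`, `decimals`,
#'   `tolerance`, `pass`), the posterior, and the recommended tier.
#' @examples
#' \donttest{
#' rep <- replay_case(2)
#' rep$checkpoints
#' }
#' @export
replay_case <- function(id, policy = c("printed_checkpoint", "full_precision"),
                        catalog = load_catalog(),
                        thresholds = threshold_policy()) {
  policy <- match.arg(policy)
  fx <- if (inherits(id, "omi_case")) id else load_case(id)
  substitute_printed <- policy == "printed_checkpoint"

  checkpoints <- list()
  note_checkpoint <- function(label, printed_node, computed_pct) {
    tol <- printed_node$tolerance
    pass <- abs(computed_pct - printed_node$percent) <= tol + 1e-9
    checkpoints[[length(checkpoints) + 1L]] <<- data.frame(
      label = label, printed = printed_node$percent, computed = computed_pct,
      decimals = printed_node$decimals, tolerance = tol, pass = pass,
      stringsAsFactors = FALSE
    )
  }

  steps <- list()
  p <- anchor_probability(fx$age, "female", catalog)
  prior <- p
  push_step <- function(label, lr, p_pre, p_post) {
    steps[[length(steps) + 1L]] <<- data.frame(
      label = label, lr = lr, p_pre = p_pre, p_post = p_post,
      stringsAsFactors = FALSE
    )
  }

  # demographic anchor: male sex enters as an odds multiplier step
  if (identical(fx$sex, "male")) {
    mult <- catalog$anchors$male_odds_multiplier
    p_post <- apply_lr(p, mult)
    if (!is.null(fx$anchor$checkpoint)) {
      note_checkpoint("anchor (male-adjusted)", fx$anchor$checkpoint, 100 * p_post)
      if (substitute_printed) p_post <- fx$anchor$checkpoint$percent / 100
    }
    push_step("male sex (odds multiplier)", mult, p, p_post)
    p <- p_post
  } else if (!is.null(fx$anchor$checkpoint)) {
    note_checkpoint("anchor", fx$anchor$checkpoint, 100 * p)
    if (substitute_printed) p <- fx$anchor$checkpoint$percent / 100
  }

  for (entry in fx$evidence) {
    it <- resolve_evidence_entry(entry, catalog)
    p_post <- apply_lr(p, it$lr$value)
    if (!is.null(entry$checkpoint)) {
      note_checkpoint(entry$label, entry$checkpoint, 100 * p_post)
      if (substitute_printed) p_post <- entry$checkpoint$percent / 100
    }
    push_step(it$label, it$lr$value, p, p_post)
    p <- p_post
  }

  trace <- structure(
    list(prior = prior, steps = do.call(rbind, steps), posterior = p,
         policy = if (substitute_printed) printed_checkpoint() else full_precision()),
    class = "omi_trace"
  )
  structure(
    list(case = fx, trace = trace,
         checkpoints = do.call(rbind, checkpoints),
         posterior = p, tier = recommend(p, thresholds), policy = policy),
    class = "omi_replay"
  )
}

#' @export
print.omi_replay <- function(x, ...) {
  cat(sprintf("Case %d: %s (%s, age %s, %s policy)\n", x$case$id, x$case$title,
              x$case$sex, format(x$case$age), x$policy))
  cp <- x$checkpoints
  if (!is.null(cp) && nrow(cp)) {
    for (k in seq_len(nrow(cp))) {
      cat(sprintf("  %-58s printed %6.2f%%  computed %7.3f%%  %s\n",
                  substr(cp$label[k], 1, 58), cp$printed[k], cp$computed[k],
                  if (cp$pass[k]) "pass" else "FAIL"))
    }
  }
  cat(sprintf("  posterior %.1f%% -> %s\n", 100 * x$posterior, x$tier))
  invisible(x)
}

#' Replay a case with modified evidence
#'
#' Keeps a case's demographic anchor but swaps, drops, or appends evidence —
#' the "what if" exercise the case narratives themselves perform (e.g. what if
#' the pain had been pleuritic and the ECG free of occlusion signs?). The
#' original fixture is never modified. Counterfactual chains have no printed
#' checkpoints, so they run at the stated policy without substitution.
#'
#' @param id Case number 1-5, or an `omi_case`.
#' @param replace Named list: `step label -> replacement`, where the
#'   replacement is an [evidence_item()], [likelihood_ratio()], bare positive
#'   number, or a list with `feature`/`present` or `test`/`result` fields
#'   resolved against the catalog. Unmatched labels are an error.
#' @param drop Character vector of step labels to remove.
#' @param add List of additional evidence (same forms as `replace` values),
#'   appended after the existing steps.
#' @param policy,catalog,thresholds As in [replay_case()].
#' @return An `omi_replay` (with an empty checkpoint report).
#' @export
counterfactual <- function(id, replace = list(), drop = character(0), add = list(),
                           policy = c("full_precision", "printed_checkpoint"),
                           catalog = load_catalog(),
                           thresholds = threshold_policy()) {
  policy <- match.arg(policy)
  fx <- if (inherits(id, "omi_case")) id else load_case(id)
  fx <- unclass(fx)

  labels <- vapply(fx$evidence, function(e) e$label, character(1))
  unknown <- setdiff(c(names(replace), drop), labels)
  if (length(unknown)) {
    stop("counterfactual references steps not in case ", fx$id, ": ",
         paste(unknown, collapse = "; "), "\navailable: ",
         paste(labels, collapse = "; "), call. = FALSE)
  }

  to_entry <- function(x, fallback_label) {
    if (is.numeric(x) && length(x) == 1L) {
      list(label = fallback_label, lr = x)
    } else if (inherits(x, "omi_lr")) {
      list(label = if (nzchar(x$label)) x$label else fallback_label, lr = x$value)
    } else if (inherits(x, "omi_evidence")) {
      list(label = x$label, lr = x$lr$value)
    } else if (is.list(x)) {
      if (is.null(x$label)) x$label <- fallback_label
      x
    } else {
      stop("cannot interpret counterfactual evidence: ", deparse(x), call. = FALSE)
    }
  }

  evidence <- list()
  for (e in fx$evidence) {
    if (e$label %in% drop) next
    if (e$label %in% names(replace)) {
      e <- to_entry(replace[[e$label]], e$label)
    }
    e$checkpoint <- NULL   # counterfactual chains have nothing printed to hit
    evidence[[length(evidence) + 1L]] <- e
  }
  for (x in add) {
    e <- to_entry(x, "additional evidence")
    e$checkpoint <- NULL
    evidence[[length(evidence) + 1L]] <- e
  }
  fx$evidence <- evidence
  if (identical(policy, "full_precision")) fx$anchor$checkpoint <- NULL
  replay_case(structure(fx, class = "omi_case"), policy = policy,
              catalog = catalog, thresholds = thresholds)
}
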