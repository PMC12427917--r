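#' Convert a probability to odds
#'
#' Disease probabilities must be moved to the odds scale before a likelihood
#' ratio can be applied, because likelihood ratios are multiplicative on odds,
#' not on probability.
#'
#' @param p Probability as a fraction strictly inside (0, 1). Degenerate
#'   values 0 and 1 are rejected: a certainty can never be updated again,
#'   and the framework deliberately keeps every estimate revisable.
#' @return The odds `p / (1 - p)`, a positive real number.
#' @examples
#' prob_to_odds(0.5)   # 1: even odds
#' prob_to_odds(0.16)  # 0.1905
#' @seealso [odds_to_prob()], [apply_lr()]
#' @export
prob_to_odds <- function(p) {
  assert_probability(p)
  p / (1 - p)
}

#' Convert odds to a probability
#'
#' Inverse of [prob_to_odds()]: `P = odds / (1 + odds)`.
#'
#' @param o Odds, a strictly positive real number.
#' @return Probability fraction in (0, 1).
#' @examples
#' odds_to_prob(1)       # 0.5
#' odds_to_prob(3.0473)  # ~0.753
#' @export
odds_to_prob <- function(o) {
  if (!is.numeric(o) || length(o) == 0L || anyNA(o)) {
    stop("odds must be a non-missing numeric value, got ", deparse(o),
         call. = FALSE)
  }
  if (any(o <= 0) || any(!is.finite(o))) {
    stop("odds must be positive and finite, got ", paste(o[o <= 0 | !is.finite(o)], collapse = ", "),
         call. = FALSE)
  }
  o / (1 + o)
}

#' Update a probability with a likelihood ratio
#'
#' The single Bayesian step of the framework: convert the pre-test probability
#' to odds, multiply by the likelihood ratio of the new finding, and convert
#' back. Strictly increasing in both arguments; the result always stays inside
#' (0, 1) — evidence moves the estimate but never to certainty.
#'
#' @param prior Pre-test probability fraction in (0, 1).
#' @param lr Likelihood ratio, a positive real multiplier (or a
#'   [likelihood_ratio()] object, whose point value is used).
#' @return Post-test probability fraction.
#' @examples
#' apply_lr(0.008, 12.5)  # ST-elevation ECG in a low-prior patient: ~0.092
#' apply_lr(0.27, 0.28)   # negative initial troponin: ~0.094
#' @export
apply_lr <- function(prior, lr) {
  lr <- lr_value(lr)
  assert_probability(prior, "prior")
  # neutral evidence is an exact no-op, not a floating-point round trip
  if (lr == 1) return(prior)
  odds_to_prob(prob_to_odds(prior) * lr)
}

#' Likelihood ratio with optional 95% interval and provenance
#'
#' The multiplicative unit of evidence. A value above 1 supports the
#' diagnosis, below 1 refutes it. The optional interval is used by
#' [propagate_interval()] to express uncertainty in the evidence base.
#'
#' @param value Positive point value.
#' @param ci_low,ci_high Optional positive bounds with
#'   `ci_low <= value <= ci_high`.
#' @param label Short human-readable description of the finding.
#' @param source Citation text for where the value comes from.
#' @return An object of class `omi_lr`.
#' @examples
#' likelihood_ratio(2.6, 1.8, 3.7, label = "radiation to both arms")
#' @export
likelihood_ratio <- function(value, ci_low = NA_real_, ci_high = NA_real_,
                             label = "", source = "") {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value <= 0 || !is.finite(value)) {
    stop("likelihood ratio value must be a single positive finite number, got ",
         deparse(value), call. = FALSE)
  }
  ci_low <- as.numeric(ci_low)
  ci_high <- as.numeric(ci_high)
  if (!is.na(ci_low) != !is.na(ci_high)) {
    stop("ci_low and ci_high must be given together", call. = FALSE)
  }
  if (!is.na(ci_low)) {
    if (ci_low <= 0 || ci_low > value || ci_high < value) {
      stop("interval must satisfy 0 < ci_low <= value <= ci_high", call. = FALSE)
    }
  }
  structure(
    list(value = value, ci_low = ci_low, ci_high = ci_high,
         label = as.character(label), source = as.character(source)),
    class = "omi_lr"
  )
}

#' @export
print.omi_lr <- function(x, ...) {
  ci <- if (!is.na(x$ci_low)) sprintf(" (95%% CI %.3g-%.3g)", x$ci_low, x$ci_high) else ""
  cat(sprintf("<likelihood ratio> %s%.4g%s%s\n",
              if (nzchar(x$label)) paste0(x$label, ": ") else "",
              x$value, ci,
              if (nzchar(x$source)) paste0("  [", x$source, "]") else ""))
  invisible(x)
}

#' One item of diagnostic evidence
#'
#' Couples a finding label with its likelihood ratio. The direction is purely
#' descriptive: "supports" for LR > 1, "refutes" for LR < 1; an LR of exactly
#' 1 is neutral and accepts either.
#'
#' @param label Finding description, e.g. `"typical chest pain, present"`.
#' @param lr A [likelihood_ratio()] or a bare positive number.
#' @param direction Optional; inferred from the LR value when missing.
#' @return An object of class `omi_evidence`.
#' @export
evidence_item <- function(label, lr, direction = NULL) {
  if (is.numeric(lr)) lr <- likelihood_ratio(lr, label = label)
  if (!inherits(lr, "omi_lr")) stop("lr must be a likelihood_ratio or number", call. = FALSE)
  inferred <- if (lr$value > 1) "supports" else if (lr$value < 1) "refutes" else "neutral"
  if (is.null(direction)) {
    direction <- inferred
  } else {
    direction <- match.arg(direction, c("supports", "refutes", "neutral"))
    if (inferred != "neutral" && direction != inferred) {
      stop(sprintf("direction '%s' inconsistent with LR value %.4g", direction, lr$value),
           call. = FALSE)
    }
  }
  structure(list(label = as.character(label), lr = lr, direction = direction),
            class = "omi_evidence")
}

#' Rounding policies for sequential updating
#'
#' `full_precision()` carries every intermediate probability at machine
#' precision. `printed_checkpoint()` reproduces bedside / published
#' arithmetic: after each update the probability is rounded half-up on the
#' percent scale to a stated number of decimals before the next likelihood
#' ratio is applied. Published case walkthroughs demonstrably chain from
#' rounded intermediates, so replaying them exactly requires this policy.
#'
#' @param decimals Integer vector of decimal places (percent scale) applied
#'   after each step; recycled across steps.
#' @return A policy object of class `omi_policy`.
#' @export
full_precision <- function() {
  structure(list(mode = "full_precision", decimals = NULL), class = "omi_policy")
}

#' @rdname full_precision
#' @export
printed_checkpoint <- function(decimals = 1L) {
  decimals <- as.integer(decimals)
  if (length(decimals) == 0L || anyNA(decimals) || any(decimals < 0L)) {
    stop("decimals must be non-negative integers", call. = FALSE)
  }
  structure(list(mode = "printed_checkpoint", decimals = decimals),
            class = "omi_policy")
}

#' Chain a sequence of likelihood ratios onto a prior
#'
#' Applies each evidence item in order, recording the pre- and post-step
#' probability so the whole update is auditable. Under `full_precision` the
#' posterior is order-invariant and equals a single update with the product
#' of all LRs; under `printed_checkpoint` each step's output is rounded on
#' the percent scale before the next step, as in bedside nomogram use.
#'
#' @param prior Prior probability fraction in (0, 1).
#' @param evidence List of [evidence_item()]s (bare numbers and
#'   [likelihood_ratio()]s are promoted). An empty list is allowed and returns
#'   a trace whose posterior equals the prior.
#' @param policy A policy from [full_precision()] or [printed_checkpoint()].
#' @return An `omi_trace`: list with `prior`, a `steps` data frame
#'   (label, lr, p_pre, p_post), `posterior`, and `policy`.
#' @examples
#' chain_update(0.0017, list(1.3, 1.9, 2.0))
#' @export
chain_update <- function(prior, evidence, policy = full_precision()) {
  assert_probability(prior)
  stopifnot(inherits(policy, "omi_policy"))
  evidence <- lapply(evidence, as_evidence_item)
  n <- length(evidence)
  steps <- data.frame(
    label = character(n), lr = numeric(n),
    p_pre = numeric(n), p_post = numeric(n),
    stringsAsFactors = FALSE
  )
  p <- prior
  if (n > 0L) {
    dec <- if (policy$mode == "printed_checkpoint") {
      rep_len(policy$decimals, n)
    } else NULL
    for (k in seq_len(n)) {
      it <- evidence[[k]]
      p_post <- apply_lr(p, it$lr$value)
      if (!is.null(dec)) {
        p_post <- round_half_up(100 * p_post, dec[k]) / 100
        # rounding can hit 0 or 100 exactly; clamp just inside the open interval
        p_post <- min(max(p_post, 1e-12), 1 - 1e-12)
      }
      steps$label[k] <- it$label
      steps$lr[k] <- it$lr$value
      steps$p_pre[k] <- p
      steps$p_post[k] <- p_post
      p <- p_post
    }
  }
  structure(
    list(prior = prior, steps = steps, posterior = p, policy = policy),
    class = "omi_trace"
  )
}

#' @export
print.omi_trace <- function(x, ...) {
  cat(sprintf("<update trace> prior %.4g%% (%s)\n", 100 * x$prior, x$policy$mode))
  if (nrow(x$steps)) {
    for (k in seq_len(nrow(x$steps))) {
      cat(sprintf("  %2d. %-42s LR %7.4g  %7.3f%% -> %7.3f%%\n",
                  k, x$steps$label[k], x$steps$lr[k],
                  100 * x$steps$p_pre[k], 100 * x$steps$p_post[k]))
    }
  }
  cat(sprintf("  posterior %.4g%%\n", 100 * x$posterior))
  invisible(x)
}

#' Monte-Carlo interval for a chained posterior
#'
#' Propagates the 95% intervals of the evidence base through the chain.
#' Each likelihood ratio is drawn independently on the log scale as
#' Normal(log(value), sd) with sd taken from the interval width
#' `(log(ci_high) - log(ci_low)) / (2 * 1.96)`; the posterior distribution is
#' summarized by its 2.5th and 97.5th percentiles. Independence across items
#' is an acknowledged approximation, mirroring the serial-multiplication
#' assumption of the framework itself.
#'
#' @param prior Prior probability fraction.
#' @param evidence List of evidence items; every item must carry an interval.
#' @param n_draws Number of Monte-Carlo draws, at least 1000.
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @return Named numeric vector `c(lower, point, upper)` of probabilities.
#' @export
propagate_interval <- function(prior, evidence, n_draws = 10000L, seed = 1L) {
  assert_probability(prior)
  evidence <- lapply(evidence, as_evidence_item)
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 1000L) {
    stop("n_draws must be at least 1000", call. = FALSE)
  }
  missing_ci <- vapply(evidence, function(it) is.na(it$lr$ci_low), logical(1))
  if (any(missing_ci)) {
    stop("interval propagation requires a CI on every item; missing for: ",
         paste(vapply(evidence[missing_ci], function(it) it$label, character(1)),
               collapse = ", "),
         call. = FALSE)
  }
  mu <- vapply(evidence, function(it) log(it$lr$value), numeric(1))
  sd <- vapply(evidence, function(it) {
    (log(it$lr$ci_high) - log(it$lr$ci_low)) / (2 * stats::qnorm(0.975))
  }, numeric(1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  draws <- matrix(stats::rnorm(n_draws * length(mu), mean = mu, sd = sd),
                  nrow = n_draws, byrow = TRUE)
  log_odds <- log(prob_to_odds(prior)) + rowSums(draws)
  post <- odds_to_prob(exp(log_odds))
  point <- apply_lr(prior, exp(sum(mu)))
  q <- stats::quantile(post, c(0.025, 0.975), names = FALSE)
  c(lower = q[1], point = point, upper = q[2])
}

# ---- internal helpers -------------------------------------------------------

assert_probability <- function(p, what = "probability") {
  if (!is.numeric(p) || length(p) != 1L || is.na(p)) {
    stop(what, " must be a single non-missing number, got ", deparse(p),
         call. = FALSE)
  }
  if (p <= 0 || p >= 1) {
    stop(what, " must lie strictly inside (0, 1), got ", format(p),
         call. = FALSE)
  }
  invisible(p)
}

lr_value <- function(lr) {
  if (inherits(lr, "omi_lr")) lr <- lr$value
  if (!is.numeric(lr) || length(lr) != 1L || is.na(lr) || lr <= 0 || !is.finite(lr)) {
    stop("likelihood ratio must be a single positive finite number, got ",
         deparse(lr), call. = FALSE)
  }
  lr
}

as_evidence_item <- function(x) {
  if (inherits(x, "omi_evidence")) return(x)
  if (inherits(x, "omi_lr")) return(evidence_item(x$label, x))
  if (is.numeric(x) && length(x) == 1L) {
    return(evidence_item(sprintf("LR %.4g", x), x))
  }
  stop("cannot interpret evidence item of class ", paste(class(x), collapse = "/"),
       call. = FALSE)
}

# Half-up rounding (0.5 always rounds away from zero for the positive values
# used here), unlike base round()'s round-half-even. A small epsilon guards
# against values like 9.1499999999 that are 9.15 in exact arithmetic.
round_half_up <- function(x, digits = 0L) {
  scale <- 10^digits
  floor(x * scale + 0.5 + 1e-9) / scale
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
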