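# Fagan nomogram: three vertical scales on which Bayesian updating becomes a
# straight line. With the left axis carrying y = -log10(pre-test odds), the
# middle axis y = log10(LR) / 2, and the right axis y = +log10(post-test
# odds), the identity log10(post odds) = log10(pre odds) + log10(LR) is
# exactly the statement that the three anchor points are collinear when the
# axes are placed at equal horizontal spacing. The half-span middle axis is
# forced by that construction: the middle axis sits halfway between the outer
# axes, so it picks up the mean of the outer ordinates.

PROB_AXIS_MIN <- 0.001
PROB_AXIS_MAX <- 0.999
LR_AXIS_MIN <- 0.001
LR_AXIS_MAX <- 1000

#' Construct a Fagan nomogram layout
#'
#' Computes the geometry of a single Bayesian update on the classical
#' three-scale nomogram: the anchor ordinate on each axis and the tick sets.
#' Probabilities outside the drawable range (0.1%–99.9%) and likelihood
#' ratios outside 0.001–1000 are clipped to the axis limits with a warning,
#' never silently.
#'
#' @param prior Pre-test probability fraction.
#' @param lr Positive likelihood ratio.
#' @return An object of class `omi_nomogram`: anchor ordinates `y_prior`,
#'   `y_lr`, `y_posterior` (in log10-odds units), the `prior`, `lr` and
#'   `posterior` values actually drawn (after any clipping), and tick tables
#'   for the three axes.
#' @examples
#' lay <- nomogram_layout(0.196, 12.5)
#' lay$posterior  # ~0.753, read straight off the right axis
#' @export
nomogram_layout <- function(prior, lr) {
  assert_probability(prior)
  lr <- lr_value(lr)
  if (prior < PROB_AXIS_MIN || prior > PROB_AXIS_MAX) {
    warning(sprintf("prior %.4g outside the drawable axis range [%g, %g]; clipped",
                    prior, PROB_AXIS_MIN, PROB_AXIS_MAX))
    prior <- min(max(prior, PROB_AXIS_MIN), PROB_AXIS_MAX)
  }
  if (lr < LR_AXIS_MIN || lr > LR_AXIS_MAX) {
    warning(sprintf("LR %.4g outside the drawable axis range [%g, %g]; clipped",
                    lr, LR_AXIS_MIN, LR_AXIS_MAX))
    lr <- min(max(lr, LR_AXIS_MIN), LR_AXIS_MAX)
  }
  posterior <- apply_lr(prior, lr)
  y_prior <- -log10(prob_to_odds(prior))
  y_posterior <- log10(prob_to_odds(posterior))
  y_lr <- log10(lr) / 2
  structure(
    list(prior = prior, lr = lr, posterior = posterior,
         y_prior = y_prior, y_lr = y_lr, y_posterior = y_posterior,
         ticks = nomogram_ticks()),
    class = "omi_nomogram"
  )
}

#' Read the posterior off a nomogram layout geometrically
#'
#' Extends the straight line through the pre-test anchor (left axis) and the
#' LR anchor (middle axis) to its intersection with the right axis, and
#' converts that ordinate back to a probability. By construction this must
#' agree with [apply_lr()]; the function exists so the equivalence is
#' checkable rather than assumed.
#'
#' @param layout An `omi_nomogram`.
#' @return Probability fraction read off the right axis.
#' @export
nomogram_read_off <- function(layout) {
  stopifnot(inherits(layout, "omi_nomogram"))
  # axes at x = 0, 1, 2; the left ordinate already carries the axis inversion
  # (y_prior = -log10(prior odds)), so the right-axis intersection of the line
  # through (0, y_prior) and (1, y_lr) is 2 * y_lr - y_prior = log10(post odds)
  y_right <- 2 * layout$y_lr - layout$y_prior
  odds_to_prob(10^y_right)
}

nomogram_ticks <- function() {
  p_lo <- c(0.001, 0.002, 0.003, 0.005, 0.007, 0.01, 0.02, 0.03, 0.05,
            0.07, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5)
  p_ticks <- sort(unique(c(p_lo, 1 - p_lo)))
  lr_ticks <- c(0.001, 0.002, 0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5,
                1, 2, 5, 10, 20, 50, 100, 200, 500, 1000)
  list(
    prob = data.frame(
      p = p_ticks,
      y_left = -log10(p_ticks / (1 - p_ticks)),
      y_right = log10(p_ticks / (1 - p_ticks))
    ),
    lr = data.frame(lr = lr_ticks, y = log10(lr_ticks) / 2)
  )
}

#' @export
print.omi_nomogram <- function(x, ...) {
  cat(sprintf("<Fagan nomogram> prior %.4g%%  LR %.4g  posterior %.4g%%\n",
              100 * x$prior, x$lr, 100 * x$posterior))
  cat(sprintf("  anchors (log10-odds units): left %.4f, middle %.4f, right %.4f\n",
              x$y_prior, x$y_lr, x$y_posterior))
  invisible(x)
}

# ---- SVG rendering ----------------------------------------------------------

svg_num <- function(x) sprintf("%.3f", x)

#' Render a nomogram to SVG
#'
#' Writes a standalone SVG 1.1 document showing the three scales and, when a
#' chained trace is supplied, a "ladder" of successive update lines: each
#' step's posterior becomes the next step's prior, with the step labels down
#' the middle. Rendering is fully deterministic — identical inputs give
#' byte-identical files (no timestamps, fixed number formatting) — so SVG
#' output can be golden-file tested.
#'
#' @param layout An `omi_nomogram` from [nomogram_layout()], or `NULL` to
#'   draw axes only (then `trace` supplies the content, if given).
#' @param path Output file path.
#' @param trace Optional `omi_trace` from [chain_update()]; drawn as
#'   successive lines.
#' @param style Named list overriding the default colors and fonts: elements
#'   `line_color`, `axis_color`, `text_color`, `font_family`, `font_size`.
#' @return `path`, invisibly.
#' @export
render_nomogram <- function(layout = NULL, path, trace = NULL, style = list()) {
  if (!is.null(layout)) stopifnot(inherits(layout, "omi_nomogram"))
  if (!is.null(trace)) stopifnot(inherits(trace, "omi_trace"))
  st <- utils::modifyList(list(
    line_color = "#c0392b", axis_color = "#2c3e50", text_color = "#2c3e50",
    font_family = "Helvetica, Arial, sans-serif", font_size = 9
  ), style)

  width <- 460; height <- 560
  x_axis <- c(90, 230, 370)           # left, middle, right axis pixel x
  y_top <- 50; y_bottom <- 520
  y_range <- 3.1                      # logical |y| shown (log10-odds units)
  to_px <- function(y) (y_top + y_bottom) / 2 - y * (y_bottom - y_top) / (2 * y_range)

  out <- character(0)
  add <- function(...) out[[length(out) + 1L]] <<- paste0(...)
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add(sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d" viewBox="0 0 %d %d">',
              width, height, width, height))
  add(sprintf('<rect width="%d" height="%d" fill="white"/>', width, height))
  add(sprintf('<g font-family="%s" font-size="%d" fill="%s">',
              st$font_family, st$font_size, st$text_color))
  titles <- c("pre-test probability (%)", "likelihood ratio", "post-test probability (%)")
  anchors <- c("middle", "middle", "middle")
  for (i in 1:3) {
    add(sprintf('<text x="%s" y="%d" text-anchor="%s" font-weight="bold">%s</text>',
                svg_num(x_axis[i]), y_top - 20, anchors[i], titles[i]))
    add(sprintf('<line x1="%s" y1="%d" x2="%s" y2="%d" stroke="%s" stroke-width="1.2"/>',
                svg_num(x_axis[i]), y_top, svg_num(x_axis[i]), y_bottom, st$axis_color))
  }

  ticks <- nomogram_ticks()
  fmt_pct <- function(p) {
    pct <- 100 * p
    if (pct < 1) sprintf("%.1f", pct)
    else if (pct > 99) sprintf("%.1f", pct)
    else sprintf("%g", pct)
  }
  for (k in seq_len(nrow(ticks$prob))) {
    p <- ticks$prob$p[k]
    for (side in 1:2) {
      y <- if (side == 1) ticks$prob$y_left[k] else ticks$prob$y_right[k]
      if (abs(y) > y_range) next
      x0 <- x_axis[if (side == 1) 1 else 3]
      dx <- if (side == 1) -5 else 5
      ypx <- to_px(y)
      add(sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="0.8"/>',
                  svg_num(x0), svg_num(ypx), svg_num(x0 + dx), svg_num(ypx), st$axis_color))
      add(sprintf('<text x="%s" y="%s" text-anchor="%s">%s</text>',
                  svg_num(x0 + dx * 2.2), svg_num(ypx + 3),
                  if (side == 1) "end" else "start", fmt_pct(p)))
    }
  }
  for (k in seq_len(nrow(ticks$lr))) {
    y <- ticks$lr$y[k]
    if (abs(y) > y_range) next
    ypx <- to_px(y)
    add(sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="0.8"/>',
                svg_num(x_axis[2] - 4), svg_num(ypx), svg_num(x_axis[2] + 4), svg_num(ypx),
                st$axis_color))
    add(sprintf('<text x="%s" y="%s" text-anchor="start">%g</text>',
                svg_num(x_axis[2] + 9), svg_num(ypx + 3), ticks$lr$lr[k]))
  }

  draw_line <- function(prior, lr, label = NULL, idx = NULL) {
    lay <- suppressWarnings(nomogram_layout(prior, lr))
    y1 <- to_px(lay$y_prior)    # inversion is built into the ordinate
    y2 <- to_px(lay$y_posterior)
    add(sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1.4"/>',
                svg_num(x_axis[1]), svg_num(y1), svg_num(x_axis[3]), svg_num(y2),
                st$line_color))
    for (xy in list(c(x_axis[1], y1), c(x_axis[2], to_px(lay$y_lr)), c(x_axis[3], y2))) {
      add(sprintf('<circle cx="%s" cy="%s" r="2.4" fill="%s"/>',
                  svg_num(xy[1]), svg_num(xy[2]), st$line_color))
    }
    if (!is.null(label) && nzchar(label)) {
      ymid <- (y1 + y2) / 2
      add(sprintf('<text x="%s" y="%s" text-anchor="middle" font-style="italic">%s%s</text>',
                  svg_num((x_axis[1] + x_axis[3]) / 2), svg_num(ymid - 6),
                  if (is.null(idx)) "" else sprintf("%d. ", idx), xml_escape(label)))
    }
  }

  if (!is.null(trace) && nrow(trace$steps)) {
    for (k in seq_len(nrow(trace$steps))) {
      draw_line(trace$steps$p_pre[k], trace$steps$lr[k],
                label = trace$steps$label[k], idx = k)
    }
  } else if (!is.null(layout)) {
    draw_line(layout$prior, layout$lr)
  }

  add("</g>")
  add("</svg>")
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
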