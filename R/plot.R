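#' Default reliability thresholds for plots
#'
#' The conventional data-quality bands: acceptable (.60, red dotted),
#' good (.80, black solid) and excellent (.90, black dotted). Effect-size
#' plots carry no thresholds by default.
#'
#' @return Data frame with columns `value`, `style`, `colour`, `label`.
#' @export
reliability_thresholds <- function() {
  data.frame(
    value = c(0.60, 0.80, 0.90),
    style = c("dotted", "solid", "dotted"),
    colour = c("red", "black", "black"),
    label = c("acceptable", "good", "excellent"),
    stringsAsFactors = FALSE
  )
}

curve_points <- function(x) {
  df <- as.data.frame(x)
  df[!is.na(df$estimate), , drop = FALSE]
}

#' Plot a metric curve
#'
#' Draws the estimate against the number of subsampled trials with
#' percentile-CI error bars; the overall (all-trials) estimate, when
#' present, is shown as a separate annotated point to the right of the
#' grid. Reliability plots carry the conventional threshold lines by
#' default.
#'
#' @param x a `qc_curve` (from [reliability()] or [effect_size()]).
#' @param thresholds data frame like [reliability_thresholds()], or `NULL`
#'   for none. Defaults to the reliability thresholds for reliability
#'   curves and none for effect sizes.
#' @param main,ylab plot annotations.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.qc_curve <- function(x, thresholds = NULL, main = NULL, ylab = NULL,
                          ...) {
  if (is.null(thresholds) && x$metric == "reliability")
    thresholds <- reliability_thresholds()
  df <- curve_points(x)
  if (nrow(df) == 0L) stop("no available points to plot")
  if (is.null(main)) main <- paste(metric_title(x$metric), "-",
                                   contrast_label(x))
  if (is.null(ylab))
    ylab <- if (x$metric == "reliability") "reliability" else "Cohen's d"
  sub <- df[df$scope == "subsample", , drop = FALSE]
  ov <- df[df$scope == "overall", , drop = FALSE]
  xs <- sub$n_trials
  xov <- if (nrow(ov)) max(c(xs, 0)) + max(c(diff(range(xs)), 5)) * 0.15
  xlim <- range(c(xs, xov))
  ylim <- range(c(df$ci_low, df$ci_high, df$estimate, thresholds$value),
                na.rm = TRUE)
  graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = "number of trials",
                 ylab = ylab, main = main, ...)
  if (!is.null(thresholds)) {
    for (i in seq_len(nrow(thresholds))) {
      graphics::abline(h = thresholds$value[i], lty = thresholds$style[i],
                       col = thresholds$colour[i])
    }
  }
  if (nrow(sub)) {
    graphics::arrows(xs, sub$ci_low, xs, sub$ci_high, angle = 90, code = 3,
                     length = 0.03)
    graphics::lines(xs, sub$estimate, type = "b", pch = 19)
  }
  if (nrow(ov)) {
    graphics::arrows(xov, ov$ci_low, xov, ov$ci_high, angle = 90, code = 3,
                     length = 0.03, col = "blue")
    graphics::points(xov, ov$estimate, pch = 17, col = "blue")
    graphics::mtext("overall", side = 1, at = xov, line = 0.2, cex = 0.7,
                    col = "blue")
  }
  invisible(x)
}

#' Plot per-participant SME values with group means
#'
#' One dot per participant-by-condition aSME, grouped by condition, with
#' the group mean and its between-participant confidence interval
#' overlaid.
#'
#' @param x an [sme()] table.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.sme_table <- function(x, ...) {
  if (nrow(x) == 0L) stop("no SME records to plot")
  conds <- sort(unique(x$condition))
  at <- match(x$condition, conds)
  graphics::plot(jitter(at, amount = 0.08), x$asme, xaxt = "n",
                 xlab = "condition", ylab = "aSME",
                 main = "Standardized measurement error", pch = 19,
                 col = grDevices::adjustcolor("grey30", alpha.f = 0.6),
                 xlim = c(0.5, length(conds) + 0.5), ...)
  graphics::axis(1, at = seq_along(conds), labels = conds)
  gs <- tryCatch(summary(x), error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(gs)) {
    ga <- match(gs$condition, conds)
    graphics::points(ga, gs$mean_asme, pch = 18, cex = 1.6, col = "red")
    graphics::arrows(ga, gs$ci_low, ga, gs$ci_high, angle = 90, code = 3,
                     length = 0.05, col = "red")
  }
  invisible(x)
}

#' Write a metric-curve plot to a PNG file with a metadata sidecar
#'
#' Renders [plot.qc_curve()] into `path` and writes a JSON sidecar
#' (`<path>.json`) recording the plotted points, intervals and threshold
#' lines. The sidecar is the determinism contract: identical inputs yield
#' a byte-identical sidecar, while the PNG bytes themselves are not
#' promised stable across graphics library builds.
#'
#' @param x a `qc_curve`.
#' @param path output PNG path.
#' @param thresholds as in [plot.qc_curve()].
#' @param width,height,res PNG device settings.
#' @return `path`, invisibly.
#' @export
write_metric_plot <- function(x, path, thresholds = NULL, width = 900,
                              height = 600, res = 120) {
  if (is.null(thresholds) && x$metric == "reliability")
    thresholds <- reliability_thresholds()
  grDevices::png(path, width = width, height = height, res = res)
  ok <- tryCatch({
    plot(x, thresholds = if (is.null(thresholds) ||
                             nrow(thresholds) > 0L) thresholds else NULL)
    TRUE
  }, finally = grDevices::dev.off())
  meta <- list(
    metric = x$metric,
    contrast = contrast_label(x),
    points = curve_points(x),
    thresholds = if (is.null(thresholds)) list() else thresholds
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
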