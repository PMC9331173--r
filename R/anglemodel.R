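# Logarithmic vertical leaf-angle distribution model A = a*ln(RH + 1) + b.

#' Fit the vertical leaf-angle distribution model
#'
#' Fits A = a*ln(RH + 1) + b to (relative height, angle) pairs. RH enters
#' the logarithm on the percent scale (0-100), which fixes the meaning of
#' the parameters: `b` is the basal angle at RH = 0 and `a` the gain per
#' ln-unit of height. Although the model is commonly labelled a nonlinear
#' fit, it is linear in (a, b) after the substitution x = ln(RH + 1), so
#' the exact ordinary-least-squares solution on the transformed design is
#' used -- it minimizes the same sum of squared angle residuals and is
#' deterministic.
#'
#' @param samples data.frame with columns `rel_height` (percent, 0-100) and
#'   `angle_deg` (degrees, 0-90).
#' @param minFitPoints minimum number of pairs required (default 5: two
#'   parameters plus meaningful residual degrees of freedom).
#' @param weights optional nonnegative case weights (e.g. segment lengths);
#'   `NULL` (the default) weights all pairs equally.
#' @return An [AngleModelFit-class] with `a`, `b`, the Pearson correlation
#'   `r` between fitted and observed angles, and the residual RMSE in
#'   degrees.
#' @examples
#' s <- data.frame(rel_height = seq(0, 100, 10),
#'                 angle_deg = 10 * log(seq(0, 100, 10) + 1) + 30)
#' coef(fitAngleModel(s))   # a = 10, b = 30
#' @export
fitAngleModel <- function(samples, minFitPoints = 5, weights = NULL) {
  stopifnot(is.data.frame(samples),
            all(c("rel_height", "angle_deg") %in% names(samples)))
  n <- nrow(samples)
  if (n < minFitPoints)
    stop("refusing to fit: ", n, " samples < minFitPoints = ", minFitPoints)
  x <- log(samples$rel_height + 1)
  y <- samples$angle_deg
  if (stats::var(x) < .Machine$double.eps)
    stop("refusing to fit: all relative heights identical (degenerate design)")
  fit <- if (is.null(weights)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = weights)
  cf <- stats::coef(fit)
  fitted <- as.numeric(stats::fitted(fit))
  r <- if (stats::sd(fitted) < .Machine$double.eps || stats::sd(y) < .Machine$double.eps)
    1 else stats::cor(fitted, y)
  new("AngleModelFit",
      a = unname(cf[2]), b = unname(cf[1]), nSegments = n,
      r = r, rmseDeg = sqrt(mean(stats::resid(fit)^2)), converged = TRUE)
}

#' Predict leaf angle at a relative height
#'
#' Evaluates A = a*ln(RH + 1) + b. The prediction is not clamped to
#' [0, 90]; extrapolated fits may exit the physical range and the caller
#' decides how to treat that.
#'
#' @param fit an [AngleModelFit-class].
#' @param relHeight relative height(s), percent in [0, 100].
#' @return predicted angle(s), degrees.
#' @export
predictAngle <- function(fit, relHeight) {
  stopifnot(is(fit, "AngleModelFit"))
  if (any(relHeight < 0 | relHeight > 100))
    stop("relHeight outside [0, 100]")
  fit@a * log(relHeight + 1) + fit@b
}

#' @rdname predictAngle
#' @param object an [AngleModelFit-class].
#' @param newdata numeric vector of relative heights (percent).
#' @param ... ignored.
#' @export
setMethod("predict", "AngleModelFit", function(object, newdata, ...) {
  predictAngle(object, newdata)
})

#' Average leaf angle (ALA)
#'
#' Unweighted arithmetic mean of the detected leaf-segment inclination
#' angles. Each Hough segment contributes equally (segment-mean, not
#' per-identified-leaf mean).
#'
#' @param samples data.frame with column `angle_deg`, at least one row.
#' @return mean angle, degrees.
#' @export
averageLeafAngle <- function(samples) {
  stopifnot(is.data.frame(samples), "angle_deg" %in% names(samples))
  if (nrow(samples) == 0) stop("no angle samples")
  mean(samples$angle_deg)
}

#' Plausibility check of fitted parameters
#'
#' At most growth stages the fitted parameters fall in a ~ 0-20 and
#' b ~ -20-90; excursions are flagged with warnings, not errors, because
#' they can be biologically meaningful -- in particular `a` drops below
#' zero late in heading when the canopy compacts and upper leaves are no
#' longer the most erect.
#'
#' @param fit a converged [AngleModelFit-class].
#' @return character vector of flags (empty when all in range), invisibly
#'   when no flag; warnings are emitted for each flag.
#' @export
validateFitRange <- function(fit) {
  stopifnot(is(fit, "AngleModelFit"))
  if (!fit@converged) stop("fit did not converge")
  flags <- character(0)
  if (fit@a < 0)
    flags <- c(flags, "a below typical range (late-heading compaction?)")
  else if (fit@a > 20)
    flags <- c(flags, "a above typical range")
  if (fit@b < -20)
    flags <- c(flags, "b below typical range")
  else if (fit@b > 90)
    flags <- c(flags, "b above typical range")
  for (f in flags) warning(f, call. = FALSE)
  if (length(flags) == 0) invisible(flags) else flags
}
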