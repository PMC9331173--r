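# Accessors and show methods.

#' @describeIn PlantMask-class the underlying logical matrix.
#' @param object a `PlantMask`.
#' @export
setGeneric("maskMatrix", function(object) standardGeneric("maskMatrix"))

#' @rdname PlantMask-class
#' @export
setMethod("maskMatrix", "PlantMask", function(object) object@mask)

#' @describeIn PlantMask-class `TRUE` if the mask has no foreground pixel.
#' @export
setGeneric("isEmptyMask", function(object) standardGeneric("isEmptyMask"))

#' @rdname PlantMask-class
#' @export
setMethod("isEmptyMask", "PlantMask", function(object) object@empty)

#' @rdname PlantMask-class
#' @param x a `PlantMask`.
#' @export
setMethod("dim", "PlantMask", function(x) dim(x@mask))

setMethod("show", "PlantMask", function(object) {
  cat(sprintf("PlantMask %d x %d, %d foreground px%s\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              if (object@empty) " (EMPTY)" else ""))
})

#' @describeIn PlantGeometry-class relative height of the plant centroid.
#' @param object a `PlantGeometry`.
#' @export
setGeneric("rhc", function(object) standardGeneric("rhc"))

#' @rdname PlantGeometry-class
#' @export
setMethod("rhc", "PlantGeometry", function(object) object@rhc)

#' @describeIn PlantGeometry-class droop-filtered plant height, pixels.
#' @export
setGeneric("plantHeightPx", function(object) standardGeneric("plantHeightPx"))

#' @rdname PlantGeometry-class
#' @export
setMethod("plantHeightPx", "PlantGeometry", function(object) object@plantHeightPx)

#' @describeIn PlantGeometry-class binary-moment centroid, c(col, row).
#' @export
setGeneric("centroid", function(object) standardGeneric("centroid"))

#' @rdname PlantGeometry-class
#' @export
setMethod("centroid", "PlantGeometry", function(object) object@centroid)

#' @describeIn PlantGeometry-class droop-filtered extent c(topRow, bottomRow).
#' @export
setGeneric("plantExtentRows", function(object) standardGeneric("plantExtentRows"))

#' @rdname PlantGeometry-class
#' @export
setMethod("plantExtentRows", "PlantGeometry",
          function(object) c(object@topRow, object@bottomRow))

setMethod("show", "PlantGeometry", function(object) {
  cat("PlantGeometry\n")
  cat(sprintf("  extent rows : %d .. %d  (PH = %g px)\n",
              object@topRow, object@bottomRow, object@plantHeightPx))
  cat(sprintf("  centroid    : (%.1f, %.1f)  height %.1f px\n",
              object@centroid[1], object@centroid[2], object@centroidHeightPx))
  cat(sprintf("  RHC         : %.4f\n", object@rhc))
  cat(sprintf("  area        : %g px   perimeter %.1f px (+%.1f holes)\n",
              object@areaPx, object@perimeterPx, object@holePerimeterPx))
})

#' @describeIn AngleModelFit-class model coefficients `c(a =, b =)`.
#' @param object an `AngleModelFit`.
#' @param ... ignored.
#' @export
setMethod("coef", "AngleModelFit", function(object, ...) {
  c(a = object@a, b = object@b)
})

setMethod("show", "AngleModelFit", function(object) {
  cat(sprintf("AngleModelFit: A = %.3f * ln(RH + 1) + %.3f\n", object@a, object@b))
  cat(sprintf("  n = %d, r = %.3f, RMSE = %.2f deg, converged = %s\n",
              object@nSegments, object@r, object@rmseDeg, object@converged))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison of '%s': F = %.4g, p = %.4g %s%s\n",
              object@trait, object@fStatistic, object@pValue, object@stars,
              if (object@degenerate) " [degenerate: zero within-group variance]" else ""))
  if (nrow(object@tukey) > 0) {
    cat("  Tukey HSD pairs:\n")
    for (i in seq_len(nrow(object@tukey)))
      cat(sprintf("    %-12s diff = %8.4g  p_adj = %.4g %s\n",
                  object@tukey$pair[i], object@tukey$diff[i],
                  object@tukey$p_adj[i], object@tukey$stars[i]))
  }
})

setMethod("show", "MLRResult", function(object) {
  cat(sprintf("MLRResult: %s ~ intercept + %s\n", "response",
              paste(object@features, collapse = " + ")))
  print(round(object@coefficients, 6))
  cat(sprintf("  Pearson r (fitted vs measured) = %.4f  (n = %d)\n",
              object@pearsonR, length(object@fitted)))
})

setMethod("show", "SyntheticPlantSpec", function(object) {
  cat(sprintf("SyntheticPlantSpec: a = %g, b = %g, %d leaves, PH = %g px, canvas %d x %d, seed %d\n",
              object@aTrue, object@bTrue, object@nLeaves, object@plantHeightPx,
              object@canvas[1], object@canvas[2], object@seed))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d leaves, true RHC = %.4f, PH = %g px, ALA = %.1f deg\n",
              nrow(object@leaves), object@trueRhc, object@truePhPx,
              object@trueAlaDeg))
})
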