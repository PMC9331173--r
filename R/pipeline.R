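# Batch pipeline: images -> per-image trait rows.

#' Pipeline configuration
#'
#' Validated container of every tunable parameter of the image-to-traits
#' pipeline. Unknown keys are rejected, so a typo in a config file fails
#' loudly before any processing.
#'
#' @param segmentation list: `hueLo`, `hueHi`, `satLo`, `valLo` (plant HSV
#'   box), `greenHueLo`, `greenHueHi` (strict green box for GPAR),
#'   `minComponentAreaFrac` (component filter as a fraction of image area),
#'   `closingRadius` (px), `roi` (optional c(top, bottom, left, right) crop).
#' @param droopQuantile row-quantile trimmed at each vertical extreme when
#'   measuring plant height (see [plantExtent()]).
#' @param hough list: see [houghParams()]; `minLineLengthFrac` scales the
#'   minimum segment length by the plant height.
#' @param fit list: `minFitPoints` for [fitAngleModel()].
#' @param parDenominator `"mask"` or `"hull"` (see [computePAR()]).
#' @param lineSource `"skeleton"` (default) or `"edges"` raster fed to the
#'   Hough stage.
#' @param seed seed applied before any stochastic stage (the image pipeline
#'   itself is deterministic; the seed governs synthetic generation and
#'   simulation helpers driven by the same config).
#' @return validated config (named list, class `vertphenConfig`).
#' @export
pipelineConfig <- function(segmentation = list(), droopQuantile = 0.005,
                           hough = list(), fit = list(),
                           parDenominator = "mask",
                           lineSource = "skeleton", seed = 1L) {
  segDefaults <- list(hueLo = 60, hueHi = 180, satLo = 0.15, valLo = 0.10,
                      greenHueLo = 75, greenHueHi = 165,
                      minComponentAreaFrac = 0.0005, closingRadius = 2,
                      roi = NULL)
  houghDefaults <- list(rhoRes = 1, thetaResDeg = 1, threshold = 20,
                        minLineLengthFrac = 0.05, maxLineGap = 5)
  fitDefaults <- list(minFitPoints = 5)
  checkKeys <- function(given, defaults, where) {
    bad <- setdiff(names(given), names(defaults))
    if (length(bad))
      stop("unknown config key(s) in ", where, ": ", paste(bad, collapse = ", "))
    utils::modifyList(defaults, given)
  }
  if (!parDenominator %in% c("mask", "hull"))
    stop("parDenominator must be 'mask' or 'hull'")
  if (!lineSource %in% c("skeleton", "edges"))
    stop("lineSource must be 'skeleton' or 'edges'")
  if (droopQuantile < 0 || droopQuantile >= 0.5)
    stop("droopQuantile must lie in [0, 0.5)")
  cfg <- list(segmentation = checkKeys(segmentation, segDefaults, "segmentation"),
              droopQuantile = droopQuantile,
              hough = checkKeys(hough, houghDefaults, "hough"),
              fit = checkKeys(fit, fitDefaults, "fit"),
              parDenominator = parDenominator,
              lineSource = lineSource,
              seed = as.integer(seed))
  class(cfg) <- "vertphenConfig"
  cfg
}

#' Read a pipeline configuration from JSON or YAML
#'
#' The file may define any subset of the [pipelineConfig()] sections;
#' unknown keys are rejected.
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return validated config.
#' @export
readConfig <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else stop("config must be .json or .yaml/.yml")
  known <- c("segmentation", "droopQuantile", "hough", "fit",
             "parDenominator", "lineSource", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipelineConfig, raw)
}

#' Analyze one plant image
#'
#' Full processing chain for a single front-view image: HSV segmentation,
#' mask cleaning, silhouette geometry and RHC, skeleton (or Canny edge)
#' extraction, Hough leaf-segment detection, vertical leaf-angle model fit
#' and shape descriptors.
#'
#' @param image H x W x 3 array in [0, 1], or a file path.
#' @param config a [pipelineConfig()].
#' @return list: `mask` (cleaned [PlantMask-class]), `greenMask`,
#'   `geometry` ([PlantGeometry-class]), `segments` (data.frame),
#'   `fit` ([AngleModelFit-class] or `NULL`), `descriptors` (list),
#'   `warnings` (character).
#' @export
analyzePlantImage <- function(image, config = pipelineConfig()) {
  if (is.character(image)) image <- readPlantImage(image)
  sc <- config$segmentation
  warningsSeen <- character(0)
  grab <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warningsSeen <<- c(warningsSeen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  rawMask <- grab(segmentPlant(image, hsvThresholds(sc$hueLo, sc$hueHi,
                                                    sc$satLo, sc$valLo),
                               roi = sc$roi))
  if (isEmptyMask(rawMask))
    return(list(mask = rawMask, greenMask = rawMask, geometry = NULL,
                segments = NULL, fit = NULL, descriptors = NULL,
                warnings = c(warningsSeen, "empty mask: no plant found")))
  mask <- cleanMask(rawMask,
                    minComponentArea = ceiling(sc$minComponentAreaFrac *
                                                 prod(dim(image)[1:2])),
                    closingRadius = sc$closingRadius)
  if (isEmptyMask(mask))
    return(list(mask = mask, greenMask = mask, geometry = NULL,
                segments = NULL, fit = NULL, descriptors = NULL,
                warnings = c(warningsSeen, "mask empty after cleaning")))
  geom <- plantGeometry(mask, config$droopQuantile)
  lineSrc <- if (config$lineSource == "skeleton") skeletonizePlant(mask)
  else detectEdges(mask)
  hp <- houghParams(rhoRes = config$hough$rhoRes,
                    thetaResDeg = config$hough$thetaResDeg,
                    threshold = config$hough$threshold,
                    minLineLength = config$hough$minLineLengthFrac *
                      geom@plantHeightPx,
                    maxLineGap = config$hough$maxLineGap)
  segments <- grab(detectLeafLines(lineSrc, hp, geom,
                                   refineSource = maskMatrix(mask)))
  fit <- NULL
  if (nrow(segments) >= config$fit$minFitPoints &&
      stats::var(log(segments$rel_height + 1)) > .Machine$double.eps) {
    fit <- fitAngleModel(segments, minFitPoints = config$fit$minFitPoints)
    grab(validateFitRange(fit))
  } else {
    warningsSeen <- c(warningsSeen, "too few segments for angle-model fit")
  }
  desc <- shapeDescriptors(image, mask, geom,
                           greenBox = greenThresholds(sc$greenHueLo,
                                                      sc$greenHueHi,
                                                      sc$satLo, sc$valLo),
                           parDenominator = config$parDenominator)
  green <- greenFractionMask(image, mask,
                             greenThresholds(sc$greenHueLo, sc$greenHueHi,
                                             sc$satLo, sc$valLo))
  list(mask = mask, greenMask = green, geometry = geom, segments = segments,
       fit = fit, descriptors = desc, warnings = warningsSeen)
}

#' Batch-process images into a trait table
#'
#' Runs [analyzePlantImage()] on every image and assembles one trait row
#' per image. Unreadable or plant-free images are skipped with their reason
#' recorded; the run fails only if no image can be processed. Fixed images
#' plus a fixed config give byte-identical output across reruns.
#'
#' @param imagePaths character vector of PNG/JPEG paths (at least one).
#' @param config a [pipelineConfig()].
#' @param outputDir optional directory; when given, the trait table is
#'   written there as `traits.csv` and, with `writeArtifacts = TRUE`,
#'   per-image masks (`<name>_mask.png`) and segment tables
#'   (`<name>_segments.csv`).
#' @param writeArtifacts write per-image mask PNGs and segment CSVs.
#' @return data.frame, one row per processed image: `image`, `ph_px`,
#'   `centroid_height_px`, `rhc`, `area_px`, `perimeter_px`, `n_segments`,
#'   `ala_deg`, `fit_a`, `fit_b`, `fit_r`, `fit_rmse`, `fit_n`, `gpar`,
#'   `par`, `warnings`.
#' @export
runPipeline <- function(imagePaths, config = pipelineConfig(),
                        outputDir = NULL, writeArtifacts = FALSE) {
  if (length(imagePaths) < 1) stop("no input images")
  if (!is.null(outputDir))
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (path in imagePaths) {
    res <- tryCatch(analyzePlantImage(path, config), error = function(e) e)
    if (inherits(res, "error")) {
      message("skipping ", path, ": ", conditionMessage(res))
      next
    }
    g <- res$geometry
    f <- res$fit
    rows[[length(rows) + 1L]] <- data.frame(
      image = basename(path),
      ph_px = if (is.null(g)) NA_real_ else g@plantHeightPx,
      centroid_height_px = if (is.null(g)) NA_real_ else g@centroidHeightPx,
      rhc = if (is.null(g)) NA_real_ else g@rhc,
      area_px = if (is.null(g)) NA_real_ else g@areaPx,
      perimeter_px = if (is.null(g)) NA_real_ else g@perimeterPx,
      n_segments = if (is.null(res$segments)) 0L else nrow(res$segments),
      ala_deg = if (is.null(res$segments) || nrow(res$segments) == 0)
        NA_real_ else averageLeafAngle(res$segments),
      fit_a = if (is.null(f)) NA_real_ else f@a,
      fit_b = if (is.null(f)) NA_real_ else f@b,
      fit_r = if (is.null(f)) NA_real_ else f@r,
      fit_rmse = if (is.null(f)) NA_real_ else f@rmseDeg,
      fit_n = if (is.null(f)) NA_integer_ else as.integer(f@nSegments),
      gpar = if (is.null(res$descriptors)) NA_real_ else res$descriptors$gpar,
      par = if (is.null(res$descriptors)) NA_real_ else res$descriptors$par,
      warnings = paste(res$warnings, collapse = "; "))
    if (!is.null(outputDir) && writeArtifacts && !is.null(g)) {
      stem <- tools::file_path_sans_ext(basename(path))
      writeMaskPNG(res$mask, file.path(outputDir, paste0(stem, "_mask.png")))
      utils::write.csv(res$segments[, c("p1x", "p1y", "p2x", "p2y",
                                        "length_px", "angle_deg",
                                        "rel_height")],
                       file.path(outputDir, paste0(stem, "_segments.csv")),
                       row.names = FALSE)
    }
  }
  if (length(rows) == 0) stop("no image could be processed")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(outputDir))
    utils::write.csv(out, file.path(outputDir, "traits.csv"), row.names = FALSE)
  out
}
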