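#' Assemble a validated pipeline configuration
#'
#' A run configuration names exactly one input source (a fixture preset, a
#' simulation preset, or an image path), the intensity mode, the transform
#' family and its parameter grid, an optional centre-finding method, and
#' output settings.
#'
#' @param source a list with \code{kind} in \code{"fixture"},
#'   \code{"simulation"}, \code{"image"} plus the corresponding arguments
#'   (fixture: arguments of \code{\link{makeFixture}}; simulation:
#'   arguments of \code{\link{rdParams}}; image: \code{path}).
#' @param mode intensity mode for images: \code{"grey"} or
#'   \code{"greenness"}.
#' @param downsample block-mean reduction factor applied after loading.
#' @param family transform family to scan: \code{"rotation"},
#'   \code{"reflection"}, \code{"translation"}, \code{"rotation_scale"}.
#' @param angles,scales parameter grids (angles for rotation/reflection;
#'   angles x scales for rotation_scale; translation scans all shifts).
#' @param centreMethod \code{"none"}, \code{"rotational"},
#'   \code{"reflection"} or \code{"area"}.
#' @param minProminence prominence threshold for
#'   \code{\link{findSymmetries}}.
#' @param outDir output directory (created if missing).
#' @param seed integer seed forwarded to every stochastic component.
#' @return a validated config list of class \code{"symscanConfig"}.
#' @export
runConfig <- function(source, mode = "grey", downsample = 1L,
                      family = c("rotation", "reflection", "translation",
                                 "rotation_scale"),
                      angles = seq(0, 359, by = 1), scales = NULL,
                      centreMethod = c("none", "rotational", "reflection",
                                       "area"),
                      minProminence = 0.02, outDir = tempfile("symscan"),
                      seed = 1L) {
    family <- match.arg(family)
    centreMethod <- match.arg(centreMethod)
    if (!is.list(source) || is.null(source$kind) ||
        !source$kind %in% c("fixture", "simulation", "image"))
        stop("config validation: source$kind must be 'fixture', ",
             "'simulation' or 'image'")
    if (source$kind == "image" && is.null(source$path))
        stop("config validation: image source needs a path")
    if (family == "rotation_scale" && is.null(scales))
        scales <- seq(0.2, 1.2, by = 0.05)
    structure(list(source = source, mode = mode,
                   downsample = as.integer(downsample), family = family,
                   angles = angles, scales = scales,
                   centreMethod = centreMethod,
                   minProminence = minProminence, outDir = outDir,
                   seed = as.integer(seed)),
              class = "symscanConfig")
}

#' Read a pipeline configuration from YAML
#'
#' The file mirrors the arguments of \code{\link{runConfig}}.
#'
#' @param path YAML file path.
#' @return a config list of class \code{"symscanConfig"}.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    do.call(runConfig, y)
}

.polarPlotPNG <- function(curve, path) {
    grDevices::png(path, width = 600, height = 600)
    on.exit(grDevices::dev.off())
    th <- curve@param1 * pi / 180
    r <- curve@values
    r <- (r - min(r, na.rm = TRUE)) /
         max(diff(range(r, na.rm = TRUE)), .Machine$double.eps)
    graphics::plot(r * cos(th), r * sin(th), type = "l", asp = 1,
                   xlab = "", ylab = "",
                   main = sprintf("TI vs %s angle (polar)", curve@family))
    invisible(path)
}

#' Run the full symmetry-identification workflow
#'
#' Executes the standard pipeline: (1) intensity extraction from the
#' configured source; (1.1) optional automatic centre estimation; (2)-(3)
#' TI scan over the configured transform family; (4) curve export (CSV,
#' and a polar-plot PNG for angular scans); (5) ranked approximate
#' symmetries by prominence-filtered local minima. All outputs, including
#' a JSON report logging every parameter, go to \code{config$outDir}; two
#' runs with the same config and seed produce byte-identical reports.
#'
#' @param config a config from \code{\link{runConfig}}.
#' @return the report, invisibly (a list; also written to
#'   \code{report.json}).
#' @export
runPipeline <- function(config) {
    if (!inherits(config, "symscanConfig"))
        config <- do.call(runConfig, config)
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)

    ## Step 1: intensity extraction
    src <- config$source
    truth <- NULL
    field <- switch(src$kind,
        fixture = {
            args <- src[setdiff(names(src), "kind")]
            if (is.null(args$seed)) args$seed <- config$seed
            fx <- do.call(makeFixture, args)
            truth <- fx$truth
            fx$field
        },
        simulation = {
            args <- src[setdiff(names(src), "kind")]
            if (is.null(args$seed)) args$seed <- config$seed
            stateToField(simulateTuring(do.call(rdParams, args)))
        },
        image = loadIntensity(src$path, mode = config$mode))
    if (config$downsample > 1L)
        field <- downsampleField(field, config$downsample)

    ## Step 1.1: centre estimation
    centreInfo <- NULL
    centre <- field@centre
    if (config$centreMethod != "none") {
        est <- switch(config$centreMethod,
            rotational = estimateCenterRotational(field,
                downsampleFactor = min(4L, config$downsample + 3L)),
            reflection = estimateCenterReflection(field),
            area = estimateCenterArea(
                thresholdMask(field, stats::median(field@values))))
        if (est@found) centre <- est@coordinates
        centreInfo <- list(method = est@method, found = est@found,
                           coordinates = unname(est@coordinates))
    }

    ## Steps 2-4: TI scan and curve outputs
    curve <- switch(config$family,
        translation = translationTI(field),
        rotation_scale = tiScan(field, "rotation_scale",
                                angles = config$angles,
                                scales = config$scales, centre = centre),
        tiScan(field, config$family, angles = config$angles,
               centre = centre))
    curvePath <- file.path(config$outDir, "ti_curve.csv")
    writeTICurve(curve, curvePath)
    plotPath <- NULL
    if (config$family %in% c("rotation", "reflection")) {
        plotPath <- file.path(config$outDir, "ti_polar.png")
        .polarPlotPNG(curve, plotPath)
    }

    ## Step 5: ranked approximate symmetries (curves are always written,
    ## even when nothing passes prominence)
    candidates <- findSymmetries(curve, config$minProminence)
    if (nrow(candidates) > 0L) {
        best <- candidates[1L, ]
        spec <- switch(config$family,
            rotation = rotationSpec(best$param1, centre),
            reflection = reflectionSpec(best$param1, centre),
            rotation_scale = rotationScaleSpec(best$param1, best$param2,
                                               centre),
            translation = translationSpec(c(best$param1, best$param2),
                                          "periodic"))
        dm <- differenceMap(field, spec)
        dmv <- dm@values
        dmv[is.na(dmv)] <- 0
        rng <- max(abs(dmv), .Machine$double.eps)
        writeFieldPreview(intensityField((dmv + rng) / (2 * rng) * 254 + 1),
                          file.path(config$outDir, "difference_map.png"))
    }

    report <- list(
        schema = "symscan-report/1",
        config = list(source = src, mode = config$mode,
                      downsample = config$downsample,
                      family = config$family,
                      centreMethod = config$centreMethod,
                      minProminence = config$minProminence,
                      seed = config$seed),
        centre = centreInfo,
        centreUsed = unname(centre),
        nGridPoints = length(curve@values),
        candidates = candidates,
        groundTruthKnown = !is.null(truth),
        files = list(curve = basename(curvePath),
                     polar = if (!is.null(plotPath)) basename(plotPath))
    )
    jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    invisible(report)
}
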