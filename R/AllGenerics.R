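#' Accessors for calibration objects
#'
#' Small accessor generics used across the package: `ampLevels()` and
#' `cpgPositions()` return the design axes, `apparentMeth()` the apparent
#' methylation matrix, `designOf()` the embedded design, `modelId()` the
#' model identifier, `dic()` the deviance information criterion,
#' `fittedMeans()` the posterior-mean fitted grid, and `converged()` the
#' convergence flag.
#'
#' @param object an AmpliCal S4 object.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ampLevels", function(object) standardGeneric("ampLevels"))
#' @rdname accessors
#' @export
setGeneric("cpgPositions", function(object) standardGeneric("cpgPositions"))
#' @rdname accessors
#' @export
setGeneric("apparentMeth", function(object) standardGeneric("apparentMeth"))
#' @rdname accessors
#' @export
setGeneric("designOf", function(object) standardGeneric("designOf"))
#' @rdname accessors
#' @export
setGeneric("modelId", function(object) standardGeneric("modelId"))
#' @rdname accessors
#' @export
setGeneric("dic", function(object) standardGeneric("dic"))
#' @rdname accessors
#' @export
setGeneric("fittedMeans", function(object) standardGeneric("fittedMeans"))
#' @rdname accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' @rdname accessors
setMethod("ampLevels", "CalibrationDesign", function(object) object@ampLevels)
#' @rdname accessors
setMethod("ampLevels", "CalibrationData", function(object) object@design@ampLevels)
#' @rdname accessors
setMethod("ampLevels", "CPRFit", function(object) object@ampLevels)
#' @rdname accessors
setMethod("cpgPositions", "CalibrationDesign", function(object) object@cpgPositions)
#' @rdname accessors
setMethod("cpgPositions", "CalibrationData", function(object) object@design@cpgPositions)
#' @rdname accessors
setMethod("cpgPositions", "SampleData", function(object) object@cpgPositions)
#' @rdname accessors
setMethod("cpgPositions", "CalibrationCurve", function(object) object@cpgPositions)
#' @rdname accessors
setMethod("cpgPositions", "CPRFit", function(object) object@cpgPositions)
#' @rdname accessors
setMethod("apparentMeth", "CalibrationData", function(object) object@apparent)
#' @rdname accessors
setMethod("designOf", "CalibrationData", function(object) object@design)
#' @rdname accessors
setMethod("designOf", "CalibrationFit", function(object) object@data@design)
#' @rdname accessors
setMethod("modelId", "ModelSpec", function(object) object@model)
#' @rdname accessors
setMethod("modelId", "CalibrationFit", function(object) object@model)
#' @rdname accessors
setMethod("modelId", "CalibrationCurve", function(object) object@model)
#' @rdname accessors
setMethod("dic", "CalibrationFit", function(object) object@dic)
#' @rdname accessors
setMethod("fittedMeans", "CalibrationFit", function(object) object@fitted)
#' @rdname accessors
setMethod("converged", "CalibrationFit", function(object) isTRUE(object@diagnostics$converged))

#' @describeIn accessors region length in bp (`end - start`) of a design, or
#'   `NA` when no region is attached.
#' @export
regionLength <- function(object) {
  stopifnot(is(object, "CalibrationDesign"))
  if (is.null(object@region)) return(NA_integer_)
  IRanges::end(object@region) - IRanges::start(object@region)
}

setMethod("show", "CalibrationDesign", function(object) {
  cat(sprintf("CalibrationDesign '%s': %d AMP levels x %d CpGs\n",
              object@assayId, length(object@ampLevels), length(object@cpgPositions)))
  cat("  AMP levels (%):", paste(object@ampLevels, collapse = ", "), "\n")
  if (!is.null(object@region))
    cat(sprintf("  region: %s:%d-%d (%d bp)\n",
                as.character(GenomicRanges::seqnames(object@region)),
                IRanges::start(object@region), IRanges::end(object@region),
                regionLength(object)))
})

setMethod("show", "CalibrationData", function(object) {
  show(object@design)
  nmiss <- sum(is.na(object@apparent))
  cat(sprintf("  apparent methylation: %d x %d grid, %d missing cell(s)\n",
              nrow(object@apparent), ncol(object@apparent), nmiss))
})

setMethod("show", "SampleData", function(object) {
  cat(sprintf("SampleData: %d individuals (%d control, %d case) x %d CpGs\n",
              length(object@sampleIds), sum(object@group == "control"),
              sum(object@group == "case"), length(object@cpgPositions)))
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec %s (sum-to-zero constraints enforced)\n", object@model))
})

setMethod("show", "CalibrationFit", function(object) {
  cat(sprintf("CalibrationFit %s: %d x %d grid, %d posterior draws\n",
              object@model, nrow(object@fitted), ncol(object@fitted),
              nrow(object@draws$beta)))
  cat(sprintf("  DIC %.2f (pD %.2f); converged: %s\n", object@dic,
              object@dicInfo$pD, isTRUE(object@diagnostics$converged)))
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve (%s): %d CpGs, spline knots at %s\n",
              object@model, length(object@cpgPositions),
              paste(object@knotsX, collapse = ", ")))
  cat(sprintf("  monotone on [0,100]: %d of %d CpGs\n",
              sum(object@monotone), length(object@monotone)))
})

setMethod("show", "CPRFit", function(object) {
  cat(sprintf("CPRFit: per-CpG cubic polynomial regression, %d CpGs, %d AMP levels\n",
              ncol(object@coef), length(object@ampLevels)))
})

setMethod("show", "CorrectionResult", function(object) {
  cat(sprintf("CorrectionResult (%s): %d individuals, %d rows\n",
              object@method, length(unique(object@table$id)), nrow(object@table)))
})

setMethod("show", "ReferenceInterval", function(object) {
  cat(sprintf("ReferenceInterval: %.3f +/- %g x %.3f -> [%.3f, %.3f]\n",
              object@center, object@k, object@sd, object@lower, object@upper))
})

setMethod("show", "ClassificationResult", function(object) {
  tb <- table(factor(object@table$call, levels = c("loss", "normal", "gain")))
  cat(sprintf("ClassificationResult: %d loss, %d normal, %d gain (interval [%.2f, %.2f])\n",
              tb["loss"], tb["normal"], tb["gain"],
              object@interval@lower, object@interval@upper))
})
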