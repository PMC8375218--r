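#' @include AllClasses.R
NULL

#' Accessors for phaseflip classes
#'
#' `leftArm()`, `rightArm()` and `spacerRegion()` return `GRanges` of the two
#' repeat arms and the spacer of each locus; `armLength()` and
#' `locusLabels()` return per-locus vectors. `orientationTable()` extracts
#' the per-locus count table from an [OrientationCounts-class] object and
#' `fractionOn()` its ON-fraction vector. `vmr()` extracts the ratio from a
#' [VMREstimate-class]; `perCapita()` the normalised titers of a
#' [GrowthCurve-class]; `changepoints()` the changepoint times of a
#' [BurstCall-class].
#'
#' @param x An object of the relevant class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("leftArm", function(x) standardGeneric("leftArm"))
#' @rdname accessors
#' @export
setGeneric("rightArm", function(x) standardGeneric("rightArm"))
#' @rdname accessors
#' @export
setGeneric("spacerRegion", function(x) standardGeneric("spacerRegion"))
#' @rdname accessors
#' @export
setGeneric("armLength", function(x) standardGeneric("armLength"))
#' @rdname accessors
#' @export
setGeneric("locusLabels", function(x) standardGeneric("locusLabels"))
#' @rdname accessors
#' @export
setGeneric("orientationTable", function(x) standardGeneric("orientationTable"))
#' @rdname accessors
#' @export
setGeneric("fractionOn", function(x) standardGeneric("fractionOn"))
#' @rdname accessors
#' @export
setGeneric("vmr", function(x) standardGeneric("vmr"))
#' @rdname accessors
#' @export
setGeneric("perCapita", function(x) standardGeneric("perCapita"))
#' @rdname accessors
#' @export
setGeneric("changepoints", function(x) standardGeneric("changepoints"))
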