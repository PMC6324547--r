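#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

#' Parameters controlling tag tiling, alignment filtering and gap closure
#'
#' A \code{GapCloserParam} bundles every tunable of the gap-closing
#' algorithm, in the spirit of Bioconductor \code{*Param} classes.
#'
#' @slot tagLength integer(1). Length in bases of the fixed-length tags each
#'   long read is fragmented into (default 300).
#' @slot minCoverage numeric(1). Minimum alignment coverage
#'   \eqn{(match + insert)/tagLength} for a tag alignment to be retained
#'   (default 0.80, inclusive).
#' @slot minTagCount integer(1). Minimum number of retained anchors a read
#'   must have on a gap flank to count as boundary support (default 5,
#'   inclusive).
#' @slot maxDeviation numeric(1). Allowed relative deviation \eqn{c} between
#'   read-space and scaffold-space distances; tag pairs are retained iff
#'   their distance ratio lies strictly within \eqn{(1-c, 1+c)}
#'   (default 0.2).
#' @slot boundaryWindow integer(1). A read supports a gap flank only if its
#'   anchor nearest the gap lies within this many bases of the gap edge
#'   (default 1000).
#' @slot minGapLength integer(1). Minimum N-run length reported as a gap
#'   (default 1).
#' @slot iterations integer(1). Maximum number of align--filter--close
#'   rounds; the pipeline stops early once an iteration fills no bases
#'   (default 3).
#' @slot threads integer(1). Thread count forwarded to an external aligner;
#'   the R-side computation is serial and deterministic (default 1).
#' @slot seed integer(1). Seed forwarded to stochastic helpers (default 1).
#'
#' @seealso [gapCloserParam()] for construction with defaults.
#' @export
setClass("GapCloserParam",
    representation(
        tagLength      = "integer",
        minCoverage    = "numeric",
        minTagCount    = "integer",
        maxDeviation   = "numeric",
        boundaryWindow = "integer",
        minGapLength   = "integer",
        iterations     = "integer",
        threads        = "integer",
        seed           = "integer"
    )
)

setValidity("GapCloserParam", function(object) {
    msg <- character()
    one <- function(x) length(x) == 1L && !is.na(x)
    if (!one(object@tagLength) || object@tagLength < 50L)
        msg <- c(msg, "tagLength must be a single integer >= 50")
    if (!one(object@minCoverage) || object@minCoverage <= 0 ||
        object@minCoverage > 1)
        msg <- c(msg, "minCoverage must be in (0, 1]")
    if (!one(object@minTagCount) || object@minTagCount < 1L)
        msg <- c(msg, "minTagCount must be a single integer >= 1")
    if (!one(object@maxDeviation) || object@maxDeviation <= 0 ||
        object@maxDeviation >= 1)
        msg <- c(msg, "maxDeviation must be in (0, 1)")
    if (!one(object@boundaryWindow) ||
        object@boundaryWindow < object@tagLength)
        msg <- c(msg, "boundaryWindow must be >= tagLength")
    if (!one(object@minGapLength) || object@minGapLength < 1L)
        msg <- c(msg, "minGapLength must be >= 1")
    if (!one(object@iterations) || object@iterations < 1L)
        msg <- c(msg, "iterations must be >= 1")
    if (!one(object@threads) || object@threads < 1L)
        msg <- c(msg, "threads must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct a GapCloserParam
#'
#' @param tagLength tag length in bases.
#' @param minCoverage minimum alignment coverage fraction (inclusive).
#' @param minTagCount minimum boundary anchor count per read (inclusive).
#' @param maxDeviation allowed distance-ratio deviation \eqn{c}.
#' @param boundaryWindow flank window in bases for boundary support.
#' @param minGapLength minimum N-run length discovered as a gap.
#' @param iterations maximum closure iterations.
#' @param threads threads for an external aligner.
#' @param seed seed for stochastic helpers.
#' @return A [GapCloserParam-class] object.
#' @examples
#' gapCloserParam(iterations = 2)
#' @export
gapCloserParam <- function(tagLength = 300L, minCoverage = 0.80,
                           minTagCount = 5L, maxDeviation = 0.2,
                           boundaryWindow = 1000L, minGapLength = 1L,
                           iterations = 3L, threads = 1L, seed = 1L) {
    new("GapCloserParam",
        tagLength      = as.integer(tagLength),
        minCoverage    = as.numeric(minCoverage),
        minTagCount    = as.integer(minTagCount),
        maxDeviation   = as.numeric(maxDeviation),
        boundaryWindow = as.integer(boundaryWindow),
        minGapLength   = as.integer(minGapLength),
        iterations     = as.integer(iterations),
        threads        = as.integer(threads),
        seed           = as.integer(seed))
}

#' @describeIn GapCloserParam-class tag length in bases
#' @param object,x a \code{GapCloserParam}
#' @export
setGeneric("tagLength", function(x) standardGeneric("tagLength"))
#' @export
setMethod("tagLength", "GapCloserParam", function(x) x@tagLength)

#' @describeIn GapCloserParam-class minimum alignment coverage
#' @export
setGeneric("minCoverage", function(x) standardGeneric("minCoverage"))
#' @export
setMethod("minCoverage", "GapCloserParam", function(x) x@minCoverage)

#' @describeIn GapCloserParam-class minimum boundary tag count
#' @export
setGeneric("minTagCount", function(x) standardGeneric("minTagCount"))
#' @export
setMethod("minTagCount", "GapCloserParam", function(x) x@minTagCount)

#' @describeIn GapCloserParam-class allowed distance-ratio deviation c
#' @export
setGeneric("maxDeviation", function(x) standardGeneric("maxDeviation"))
#' @export
setMethod("maxDeviation", "GapCloserParam", function(x) x@maxDeviation)

#' @describeIn GapCloserParam-class boundary window in bases
#' @export
setGeneric("boundaryWindow", function(x) standardGeneric("boundaryWindow"))
#' @export
setMethod("boundaryWindow", "GapCloserParam", function(x) x@boundaryWindow)

#' @describeIn GapCloserParam-class minimum discovered gap length
#' @export
setGeneric("minGapLength", function(x) standardGeneric("minGapLength"))
#' @export
setMethod("minGapLength", "GapCloserParam", function(x) x@minGapLength)

#' @describeIn GapCloserParam-class maximum closure iterations
#' @export
setGeneric("iterations", function(x) standardGeneric("iterations"))
#' @export
setMethod("iterations", "GapCloserParam", function(x) x@iterations)

setMethod("show", "GapCloserParam", function(object) {
    cat("GapCloserParam\n",
        "  tagLength:      ", object@tagLength, "\n",
        "  minCoverage:    ", object@minCoverage, "\n",
        "  minTagCount:    ", object@minTagCount, "\n",
        "  maxDeviation:   ", object@maxDeviation, "\n",
        "  boundaryWindow: ", object@boundaryWindow, "\n",
        "  minGapLength:   ", object@minGapLength, "\n",
        "  iterations:     ", object@iterations, "\n",
        "  threads:        ", object@threads, "\n",
        "  seed:           ", object@seed, "\n", sep = "")
})

#' Result of a gap-closing run
#'
#' Returned by [runGapCloser()]. Holds the edited assembly, the per-gap
#' per-iteration report and per-iteration summaries.
#'
#' @slot assembly \code{DNAStringSet}, the gap-closed scaffolds.
#' @slot report \code{data.frame}, one row per gap per iteration (see
#'   [writeGapReport()] for the column contract).
#' @slot summary \code{data.frame}, one row per executed iteration with
#'   gap counts and filled bases.
#' @slot param the [GapCloserParam-class] used.
#' @export
setClass("GapCloserRun",
    representation(
        assembly = "DNAStringSet",
        report   = "data.frame",
        summary  = "data.frame",
        param    = "GapCloserParam"
    )
)

#' @describeIn GapCloserRun-class the gap-closed assembly
#' @param x,object a \code{GapCloserRun}
#' @export
setGeneric("finalAssembly", function(x) standardGeneric("finalAssembly"))
#' @export
setMethod("finalAssembly", "GapCloserRun", function(x) x@assembly)

#' @describeIn GapCloserRun-class per-gap per-iteration report
#' @export
setGeneric("gapReport", function(x) standardGeneric("gapReport"))
#' @export
setMethod("gapReport", "GapCloserRun", function(x) x@report)

#' @describeIn GapCloserRun-class per-iteration summary table
#' @export
setGeneric("iterationSummary", function(x) standardGeneric("iterationSummary"))
#' @export
setMethod("iterationSummary", "GapCloserRun", function(x) x@summary)

setMethod("show", "GapCloserRun", function(object) {
    s <- object@summary
    closed <- sum(object@report$status == "closed")
    cat("GapCloserRun with ", nrow(s), " iteration(s)\n", sep = "")
    cat("  scaffolds:    ", length(object@assembly), "\n", sep = "")
    cat("  gaps closed:  ", closed, "\n", sep = "")
    cat("  bases filled: ", sum(s$bases_filled), "\n", sep = "")
    cat("  residual N:   ",
        sum(Biostrings::letterFrequency(object@assembly, "N")), "\n", sep = "")
})
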