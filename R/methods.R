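#' @include AllClasses.R AllGenerics.R
NULL

# ---- InvertibleLoci ---------------------------------------------------------

#' @describeIn InvertibleLoci Number of loci.
#' @param x,object An `InvertibleLoci` object.
#' @export
setMethod("length", "InvertibleLoci", function(x) length(x@ranges))

#' @describeIn InvertibleLoci Subset loci.
#' @param i Index vector.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "InvertibleLoci", function(x, i, j, ..., drop = TRUE) {
  new("InvertibleLoci", ranges = x@ranges[i])
})

#' @describeIn InvertibleLoci Full locus spans as a `GRanges`.
#' @export
lociRanges <- function(x) {
  stopifnot(is(x, "InvertibleLoci"))
  x@ranges
}

#' @rdname accessors
#' @export
setMethod("leftArm", "InvertibleLoci", function(x) {
  gr <- x@ranges
  mc <- S4Vectors::mcols(gr)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
    IRanges::IRanges(GenomicRanges::start(gr), width = mc$arm_length))
  S4Vectors::mcols(out)$label <- mc$label
  out
})

#' @rdname accessors
#' @export
setMethod("rightArm", "InvertibleLoci", function(x) {
  gr <- x@ranges
  mc <- S4Vectors::mcols(gr)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
    IRanges::IRanges(mc$spacer_end + 1L, width = mc$arm_length))
  S4Vectors::mcols(out)$label <- mc$label
  out
})

#' @rdname accessors
#' @export
setMethod("spacerRegion", "InvertibleLoci", function(x) {
  gr <- x@ranges
  mc <- S4Vectors::mcols(gr)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
    IRanges::IRanges(mc$spacer_start, mc$spacer_end))
  S4Vectors::mcols(out)$label <- mc$label
  out
})

#' @rdname accessors
#' @export
setMethod("armLength", "InvertibleLoci", function(x)
  S4Vectors::mcols(x@ranges)$arm_length)

#' @rdname accessors
#' @export
setMethod("locusLabels", "InvertibleLoci", function(x)
  S4Vectors::mcols(x@ranges)$label)

setMethod("show", "InvertibleLoci", function(object) {
  n <- length(object)
  cat("InvertibleLoci with", n, if (n == 1L) "locus\n" else "loci\n")
  if (n) {
    mc <- S4Vectors::mcols(object@ranges)
    df <- data.frame(
      label = mc$label,
      seqnames = as.character(GenomicRanges::seqnames(object@ranges)),
      start = GenomicRanges::start(object@ranges),
      end = GenomicRanges::end(object@ranges),
      arm = mc$arm_length,
      spacer = mc$spacer_end - mc$spacer_start + 1L,
      on_definition = mc$on_definition)
    print(utils::head(df, 10L), row.names = FALSE)
    if (n > 10L) cat("...", n - 10L, "more\n")
  }
  invisible(object)
})

# Check, against the genome, that every locus satisfies the inverted-repeat
# contract: sequence(left arm) == reverse complement of sequence(right arm).

#' Verify loci against a genome sequence
#'
#' Checks literally that for every locus the left-arm sequence equals the
#' reverse complement of the right-arm sequence.
#'
#' @param loci An [InvertibleLoci-class] object.
#' @param genome A `DNAStringSet` (single sequence) or `DNAString`.
#' @return Logical vector, one entry per locus.
#' @export
validateLoci <- function(loci, genome) {
  genome <- .asGenomeString(genome)
  gr <- loci@ranges
  mc <- S4Vectors::mcols(gr)
  if (!length(gr)) return(logical(0))
  left <- substring(genome, GenomicRanges::start(gr),
                    GenomicRanges::start(gr) + mc$arm_length - 1L)
  right <- substring(genome, mc$spacer_end + 1L,
                     mc$spacer_end + mc$arm_length)
  left == .revcomp(right)
}

# coerce supported genome representations to one plain character string
.asGenomeString <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    stopifnot(length(genome) == 1L)
    return(as.character(genome[[1L]]))
  }
  if (is(genome, "DNAString")) return(as.character(genome))
  stopifnot(is.character(genome), length(genome) == 1L)
  genome
}

# ---- OrientationCounts ------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("orientationTable", "OrientationCounts", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("fractionOn", "OrientationCounts", function(x) {
  out <- x@table$fraction_on
  names(out) <- x@table$label
  out
})

setMethod("show", "OrientationCounts", function(object) {
  cat("OrientationCounts for", nrow(object@table), "loci\n")
  print(object@table, row.names = FALSE, digits = 4)
  invisible(object)
})

# ---- GrowthCurve / BurstCall ------------------------------------------------

#' @rdname accessors
#' @export
setMethod("perCapita", "GrowthCurve", function(x) x@perCapita)

setMethod("show", "GrowthCurve", function(object) {
  cat("GrowthCurve:", length(object@times), "time points,",
      format(object@infectedCells, digits = 3), "infected cells/ml\n")
  cat("  per-capita range:",
      format(range(object@perCapita), digits = 3), "\n")
  invisible(object)
})

#' @rdname accessors
#' @export
setMethod("changepoints", "BurstCall", function(x) x@changepointTimes)

setMethod("show", "BurstCall", function(object) {
  k <- length(object@changepointTimes)
  cat("BurstCall:", k, if (k == 1L) "burst\n" else "bursts\n")
  if (k)
    print(data.frame(time_min = object@changepointTimes,
                     step_per_capita = object@stepSizes), row.names = FALSE,
          digits = 3)
  cat("  total yield:", format(object@totalYield, digits = 3),
      "pfu per capita\n")
  invisible(object)
})

# ---- VMREstimate ------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("vmr", "VMREstimate", function(x) x@vmr)

setMethod("show", "VMREstimate", function(object) {
  cat("VMREstimate: vmr =", format(object@vmr, digits = 4),
      sprintf("(phage %.3g bases / %d nt; host %.3g bases / %d nt)\n",
              object@phageBases, as.integer(object@phageLen),
              object@hostBases, as.integer(object@hostLen)))
  invisible(object)
})
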