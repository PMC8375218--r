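#' @import methods
#' @importFrom GenomicRanges GRanges start end width seqnames strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

#' Invertible promoter loci
#'
#' Container for a set of invertible loci on a reference genome. Each locus is
#' a spacer (the putative promoter) flanked by a perfect inverted repeat: the
#' left arm read forward equals the reverse complement of the right arm.
#' Site-specific recombinases acting at the arms flip the intervening spacer,
#' switching the promoter between an ON and an OFF orientation.
#'
#' The `ranges` slot holds one [GenomicRanges::GRanges] span per locus,
#' covering `[left arm start, right arm end]` (1-based, inclusive, the
#' Bioconductor convention). Metadata columns record `label`, `arm_length`,
#' `spacer_start`, `spacer_end` (absolute genome coordinates), `repeat_seq`
#' (left-arm sequence), `on_definition` (`"as_reference"` or
#' `"toward_operon"`) and `flagged` (orientation convention could not be
#' resolved from an annotation).
#'
#' @slot ranges A `GRanges` of full locus spans with the metadata columns
#'   described above.
#' @seealso [findInvertedRepeatLoci()], [makeGenome()],
#'   [setOrientationConvention()]
#' @export
setClass("InvertibleLoci", representation(ranges = "GRanges"))

.ilocus_mcols <- c("label", "arm_length", "spacer_start", "spacer_end",
                   "repeat_seq", "on_definition", "reference_is_on", "flagged")

setValidity("InvertibleLoci", function(object) {
  gr <- object@ranges
  mc <- S4Vectors::mcols(gr)
  missing <- setdiff(.ilocus_mcols, colnames(mc))
  if (length(missing))
    return(paste("missing metadata columns:", paste(missing, collapse = ", ")))
  if (length(gr) == 0L) return(TRUE)
  arm <- mc$arm_length
  if (any(arm < 1L)) return("arm_length must be positive")
  if (any(GenomicRanges::start(gr) + arm != mc$spacer_start))
    return("left arm end does not abut spacer start")
  if (any(mc$spacer_end + arm != GenomicRanges::end(gr)))
    return("spacer end does not abut right arm start")
  if (any(mc$spacer_end < mc$spacer_start - 1L))
    return("negative spacer width")
  if (!all(mc$on_definition %in% c("as_reference", "toward_operon")))
    return("on_definition must be 'as_reference' or 'toward_operon'")
  TRUE
})

#' Construct an InvertibleLoci object
#'
#' @param ref_name Reference sequence name (recycled).
#' @param left_arm_start 1-based start of the left repeat arm.
#' @param arm_length Length of each repeat arm in nt.
#' @param spacer_length Length of the spacer between the arms in nt.
#' @param label Locus labels; defaults to `locus_1`, `locus_2`, ...
#' @param repeat_seq Left-arm sequence, if known (else `NA`).
#' @param on_definition Orientation convention, `"as_reference"` (the
#'   reference state is labelled ON) or `"toward_operon"`.
#' @param reference_is_on Logical; is the reference-orientation state the ON
#'   state under the chosen convention? Default `TRUE`.
#' @param flagged Logical; `TRUE` when the convention could not be resolved.
#' @return An [InvertibleLoci-class] object.
#' @export
InvertibleLoci <- function(ref_name, left_arm_start, arm_length, spacer_length,
                           label = NULL, repeat_seq = NA_character_,
                           on_definition = "as_reference",
                           reference_is_on = TRUE, flagged = FALSE) {
  n <- length(left_arm_start)
  if (is.null(label)) label <- if (n) paste0("locus_", seq_len(n)) else character(0)
  arm_length <- as.integer(rep_len(arm_length, n))
  spacer_length <- as.integer(rep_len(spacer_length, n))
  left_arm_start <- as.integer(left_arm_start)
  gr <- GenomicRanges::GRanges(
    seqnames = rep_len(ref_name, n),
    ranges = IRanges::IRanges(start = left_arm_start,
                              width = 2L * arm_length + spacer_length))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    label = label,
    arm_length = arm_length,
    spacer_start = left_arm_start + arm_length,
    spacer_end = left_arm_start + arm_length + spacer_length - 1L,
    repeat_seq = rep_len(repeat_seq, n),
    on_definition = rep_len(on_definition, n),
    reference_is_on = rep_len(reference_is_on, n),
    flagged = rep_len(flagged, n))
  new("InvertibleLoci", ranges = gr)
}

#' Per-locus orientation counts
#'
#' Result of [quantifyOrientations()]: for each invertible locus, the number
#' of concordant read pairs supporting the ON and the OFF orientation, the
#' number left ambiguous, the ON fraction and its Wilson 95% confidence
#' interval. Loci with no informative pairs carry `fraction_on = NA` and
#' `undefined = TRUE`.
#'
#' @slot table A `data.frame` with columns `label`, `n_on`, `n_off`,
#'   `n_ambiguous`, `fraction_on`, `ci_low`, `ci_high`, `undefined`.
#' @export
setClass("OrientationCounts", representation(table = "data.frame"))

setValidity("OrientationCounts", function(object) {
  tb <- object@table
  need <- c("label", "n_on", "n_off", "n_ambiguous", "fraction_on",
            "ci_low", "ci_high", "undefined")
  if (!all(need %in% names(tb)))
    return(paste("missing columns:", paste(setdiff(need, names(tb)), collapse = ", ")))
  if (any(tb$n_on < 0 | tb$n_off < 0 | tb$n_ambiguous < 0))
    return("negative counts")
  ok <- !tb$undefined
  if (any(ok & (tb$fraction_on < 0 | tb$fraction_on > 1)))
    return("fraction_on outside [0, 1]")
  if (any(ok & (tb$ci_low > tb$fraction_on | tb$ci_high < tb$fraction_on)))
    return("confidence interval does not bracket fraction_on")
  TRUE
})

#' Dual orientation reference for one locus
#'
#' The two haplotypes a read pair is competitively aligned against: the locus
#' plus flanking sequence in its reference (ON) orientation, and the same
#' window with the segment `[left arm start, right arm end]`
#' reverse-complemented (OFF). Because the arms are perfect inverted repeats
#' the two haplotypes differ only within the spacer, so only spacer-
#' overlapping bases are informative about orientation.
#'
#' @slot label Locus label.
#' @slot onHap,offHap `DNAString` haplotypes of equal length.
#' @slot spacerRange `IRanges` of the spacer within haplotype coordinates.
#' @slot locusRange `IRanges` of the full locus span (arms included) within
#'   haplotype coordinates.
#' @slot flank Flank size in nt on each side.
#' @export
setClass("DualReference", representation(
  label = "character", onHap = "DNAString", offHap = "DNAString",
  spacerRange = "IRanges", locusRange = "IRanges", flank = "integer"))

setValidity("DualReference", function(object) {
  if (length(object@onHap) != length(object@offHap))
    return("haplotypes differ in length")
  inv <- .invertSegment(as.character(object@onHap),
                        IRanges::start(object@locusRange),
                        IRanges::end(object@locusRange))
  if (inv != as.character(object@offHap))
    return("offHap is not the in-place inversion of onHap at locusRange")
  TRUE
})

#' Phage one-step growth curve
#'
#' A free-phage titer time series together with the number of infected cells
#' at time zero; `perCapita` is the titer divided by that denominator, i.e.
#' cumulative phage progeny released per infected cell.
#'
#' @slot times Sampling times in minutes, strictly increasing.
#' @slot titers Free phage titers in pfu/ml, non-negative.
#' @slot infectedCells Infected cells per ml at the start of the experiment.
#' @slot perCapita `titers / infectedCells`.
#' @export
setClass("GrowthCurve", representation(
  times = "numeric", titers = "numeric", infectedCells = "numeric",
  perCapita = "numeric"))

setValidity("GrowthCurve", function(object) {
  if (length(object@times) != length(object@titers))
    return("times and titers differ in length")
  if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
  if (any(object@titers < 0)) return("negative titer")
  if (length(object@infectedCells) != 1L || object@infectedCells <= 0)
    return("infectedCells must be a single positive number")
  TRUE
})

#' Multi-burst changepoint call on a growth curve
#'
#' @slot changepointTimes Times (minutes) of detected lysis events.
#' @slot stepSizes Per-capita pfu increment at each changepoint
#'   (back-transformed from successive log10 segment means).
#' @slot totalYield Final per-capita yield (last segment mean).
#' @slot segmentMeans Per-segment means on the per-capita scale.
#' @slot changepointIndices Index of the first sample of each new segment.
#' @export
setClass("BurstCall", representation(
  changepointTimes = "numeric", stepSizes = "numeric", totalYield = "numeric",
  segmentMeans = "numeric", changepointIndices = "integer"))

#' Virus-to-microbe ratio estimate
#'
#' Length-normalised coverage ratio: phage genome copies per host genome copy,
#' `(phage_bases / phage_len) / (host_bases / host_len)`.
#'
#' @slot phageBases,hostBases Aligned base counts attributed to each genome.
#' @slot phageLen,hostLen Genome lengths in nt.
#' @slot vmr The ratio.
#' @export
setClass("VMREstimate", representation(
  phageBases = "numeric", hostBases = "numeric",
  phageLen = "numeric", hostLen = "numeric", vmr = "numeric"))

setValidity("VMREstimate", function(object) {
  if (object@hostBases <= 0) return("host coverage must be positive")
  if (object@phageBases < 0) return("negative phage base count")
  if (object@phageLen <= 0 || object@hostLen <= 0)
    return("genome lengths must be positive")
  TRUE
})
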