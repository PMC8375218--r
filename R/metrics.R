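#' Estimate the virus-to-microbe ratio from aligned base counts
#'
#' VMR is the length-normalised coverage ratio
#' `(phage_bases / phage_len) / (host_bases / host_len)`: phage genome
#' copies per host genome copy in a shotgun-sequenced co-culture. Base
#' counts (alignment spans, not read counts) make the estimate robust to
#' read-length differences.
#'
#' @param phage_bases,host_bases Aligned base counts attributed to each
#'   genome; `host_bases` must be positive.
#' @param phage_len,host_len Genome lengths in nt.
#' @return A [VMREstimate-class] object.
#' @export
estimateVMR <- function(phage_bases, host_bases, phage_len, host_len) {
  if (host_len <= 0 || phage_len <= 0)
    stop("genome lengths must be positive")
  if (host_bases <= 0)
    stop("undefined VMR: zero host coverage")
  if (phage_bases < 0) stop("negative phage base count")
  new("VMREstimate", phageBases = as.numeric(phage_bases),
      hostBases = as.numeric(host_bases),
      phageLen = as.numeric(phage_len), hostLen = as.numeric(host_len),
      vmr = (phage_bases / phage_len) / (host_bases / host_len))
}

#' Estimate VMR from an alignment-block table
#'
#' Sums aligned reference spans per genome from a block table (e.g.
#' [minimalMap()] output against a combined host+phage reference) and calls
#' [estimateVMR()].
#'
#' @param blocks Alignment-block `data.frame` with `ref_name`, `ref_start`,
#'   `ref_end` and optionally `mapped`.
#' @param phage_name,host_name Reference names of the two genomes.
#' @param phage_len,host_len Genome lengths in nt.
#' @return A [VMREstimate-class] object.
#' @export
estimateVMRFromBlocks <- function(blocks, phage_name, host_name,
                                  phage_len, host_len) {
  if (!is.null(blocks$mapped)) blocks <- blocks[blocks$mapped, , drop = FALSE]
  spans <- blocks$ref_end - blocks$ref_start + 1L
  phage_bases <- sum(spans[blocks$ref_name == phage_name])
  host_bases <- sum(spans[blocks$ref_name == host_name])
  estimateVMR(phage_bases, host_bases, phage_len, host_len)
}

#' Competitively map metagenome reads to a host and a phage genome
#'
#' Maps every read to both genomes with [minimalMap()] and keeps, per read,
#' the placement with the higher identity (phage wins exact ties, which do
#' not occur between unrelated genomes). The result feeds
#' [estimateVMRFromBlocks()].
#'
#' @param reads Reads (`DNAStringSet` or character).
#' @param host_genome,phage_genome Genome sequences.
#' @inheritParams minimalMap
#' @return An alignment-block `data.frame` with `ref_name` set to `"host"`
#'   or `"phage"`; unmapped reads are dropped.
#' @export
mapMetagenome <- function(reads, host_genome, phage_genome, k = 21L,
                          max_mismatch_frac = 0.1) {
  rd <- as.character(reads)
  bh <- minimalMap(rd, host_genome, k, max_mismatch_frac, ref_name = "host")
  bp <- minimalMap(rd, phage_genome, k, max_mismatch_frac, ref_name = "phage")
  pick_phage <- bp$mapped & (!bh$mapped | bp$identity >= bh$identity)
  pick_host <- bh$mapped & !pick_phage
  rbind(bh[pick_host, , drop = FALSE], bp[pick_phage, , drop = FALSE])
}

#' Normalise a one-step growth curve to per-capita progeny
#'
#' @param times Sampling times in minutes, strictly increasing.
#' @param titers Free-phage titers in pfu/ml.
#' @param infected_cells Infected cells per ml at time zero; must be
#'   positive.
#' @return A [GrowthCurve-class] object with
#'   `perCapita = titers / infected_cells`.
#' @export
perCapitaProgeny <- function(times, titers, infected_cells) {
  if (length(infected_cells) != 1L || !is.finite(infected_cells) ||
      infected_cells <= 0)
    stop("infected_cells must be a single positive number")
  new("GrowthCurve", times = as.numeric(times), titers = as.numeric(titers),
      infectedCells = as.numeric(infected_cells),
      perCapita = as.numeric(titers) / infected_cells)
}

# best single split of y[lo..hi]: returns c(split index k, sse gain, jump)
# where the split forms segments [lo..k], [k+1..hi]
.bestSplit <- function(y, lo, hi, min_seg) {
  n <- hi - lo + 1L
  if (n < 2L * min_seg) return(NULL)
  seg <- y[lo:hi]
  sse <- function(v) sum((v - mean(v))^2)
  total <- sse(seg)
  best <- NULL
  for (k in seq(min_seg, n - min_seg)) {
    left <- seg[seq_len(k)]; right <- seg[seq(k + 1L, n)]
    gain <- total - sse(left) - sse(right)
    if (is.null(best) || gain > best$gain)
      best <- list(k = lo + k - 1L, gain = gain,
                   jump = mean(right) - mean(left))
  }
  best
}

#' Detect burst steps in a one-step growth curve
#'
#' Finds lysis events as changepoints in the log10 per-capita progeny
#' signal by binary segmentation: the within-segment squared error is
#' minimised, and a split is accepted only if the jump between the adjacent
#' segment means is at least `log10(min_step_factor)`. This makes the
#' "burst staircase" reading of a growth curve - including small echo
#' bursts that are easy to miss by eye - an explicit, reproducible
#' operator. Step sizes are successive segment-mean differences
#' back-transformed to the per-capita scale.
#'
#' @param curve A [GrowthCurve-class] object with at least 6 time points.
#' @param min_step_factor Minimum accepted fold-change between adjacent
#'   segments, default 1.5.
#' @param max_changepoints Maximum number of changepoints, default 6.
#' @param detection_limit Assay detection limit on the per-capita scale;
#'   zeros are replaced by half this value before the log transform.
#'   Default: the smallest positive per-capita value observed.
#' @param min_segment Minimum samples per segment, default 2.
#' @return A [BurstCall-class] object.
#' @export
detectBurstSteps <- function(curve, min_step_factor = 1.5,
                             max_changepoints = 6L, detection_limit = NULL,
                             min_segment = 2L) {
  stopifnot(is(curve, "GrowthCurve"))
  pc <- curve@perCapita
  if (length(pc) < 6L) stop("need at least 6 time points")
  if (is.null(detection_limit)) {
    pos <- pc[pc > 0]
    if (!length(pos)) stop("all titers are zero")
    detection_limit <- min(pos)
  }
  pc <- ifelse(pc <= 0, detection_limit / 2, pc)
  y <- log10(pc)
  min_jump <- log10(min_step_factor)

  splits <- integer(0)
  repeat {
    if (length(splits) >= max_changepoints) break
    bounds <- c(0L, sort(splits), length(y))
    cand <- NULL
    for (s in seq_len(length(bounds) - 1L)) {
      b <- .bestSplit(y, bounds[s] + 1L, bounds[s + 1L], min_segment)
      if (!is.null(b) && abs(b$jump) >= min_jump &&
          (is.null(cand) || b$gain > cand$gain))
        cand <- b
    }
    if (is.null(cand)) break
    splits <- c(splits, cand$k)
  }
  splits <- sort(splits)
  bounds <- c(0L, splits, length(y))
  seg_means <- vapply(seq_len(length(bounds) - 1L), function(s)
    mean(y[(bounds[s] + 1L):bounds[s + 1L]]), numeric(1))
  steps <- 10^seg_means[-1L] - 10^seg_means[-length(seg_means)]
  new("BurstCall",
      changepointTimes = as.numeric(curve@times[splits + 1L]),
      stepSizes = as.numeric(steps),
      totalYield = 10^seg_means[length(seg_means)],
      segmentMeans = 10^seg_means,
      changepointIndices = as.integer(splits + 1L))
}

#' Adsorption rate constant from a two-point free-phage assay
#'
#' Assuming first-order adsorption kinetics `P(t) = P0 exp(-k N t)`, the
#' rate constant is `k = ln(p0 / pt) / (N t)` in ml cell^-1 min^-1. The
#' canonical assay titres free phage a few minutes apart (e.g. 5 and 20 min
#' after phage addition), so `t` is the elapsed time between the two
#' measurements.
#'
#' @param p0,pt Free-phage titers (pfu/ml) at the start and after `t`
#'   minutes; both must be positive.
#' @param t_minutes Elapsed time in minutes.
#' @param cell_density Cell density `N` in cells/ml.
#' @return `k` in ml cell^-1 min^-1. A negative value (titer increased, no
#'   adsorption) is returned with a warning.
#' @export
adsorptionConstant <- function(p0, pt, t_minutes, cell_density) {
  stopifnot(p0 > 0, pt > 0, t_minutes > 0, cell_density > 0)
  k <- log(p0 / pt) / (cell_density * t_minutes)
  if (pt > p0)
    warning("titer increased over the assay window; negative rate constant ",
            "(no adsorption)")
  k
}

#' Plating / centre-of-infection efficiency
#'
#' `100 * count_with / count_without`: the percentage of colonies on
#' phage-containing overlays relative to phage-free controls (EOP, a
#' resistance measure when phage are in excess), or of infected cells
#' giving rise to plaques relative to input infected cells (EOCI).
#'
#' @param count_with Colony or plaque count with phage / from infected
#'   cells.
#' @param count_without Control count; must be positive.
#' @param mode `"EOP"` or `"EOCI"` (label only; the arithmetic is shared).
#' @return The efficiency as a percentage.
#' @export
efficiencyMetrics <- function(count_with, count_without,
                              mode = c("EOP", "EOCI")) {
  mode <- match.arg(mode)
  if (any(count_without <= 0)) stop("control count must be positive")
  if (any(count_with < 0)) stop("negative count")
  100 * count_with / count_without
}
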