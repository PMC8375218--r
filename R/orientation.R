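#' Build dual orientation references for each locus
#'
#' For every locus, extracts the locus plus `flank` nt of context in the
#' reference (ON) orientation and derives the OFF haplotype by
#' reverse-complementing the `[left arm start, right arm end]` segment in
#' place. Read pairs are classified by competitive alignment against the two
#' haplotypes; because the arms are inverted repeats, the haplotypes differ
#' only inside the spacer.
#'
#' @param genome Genome sequence (`DNAStringSet`/`DNAString`/character).
#' @param loci An [InvertibleLoci-class] object.
#' @param flank Flank size in nt on each side of the locus, default 1000.
#' @return A list of [DualReference-class] objects, one per locus.
#' @export
buildDualReferences <- function(genome, loci, flank = 1000L) {
  genome_str <- .asGenomeString(genome)
  L <- nchar(genome_str)
  gr <- lociRanges(loci)
  mc <- S4Vectors::mcols(gr)
  lapply(seq_len(length(loci)), function(i) {
    ls <- GenomicRanges::start(gr)[i]; le <- GenomicRanges::end(gr)[i]
    ws <- max(1L, ls - flank); we <- min(L, le + flank)
    on_hap <- substring(genome_str, ws, we)
    loc_s <- ls - ws + 1L; loc_e <- le - ws + 1L
    off_hap <- .invertSegment(on_hap, loc_s, loc_e)
    new("DualReference",
        label = mc$label[i],
        onHap = Biostrings::DNAString(on_hap),
        offHap = Biostrings::DNAString(off_hap),
        spacerRange = IRanges::IRanges(mc$spacer_start[i] - ws + 1L,
                                       mc$spacer_end[i] - ws + 1L),
        locusRange = IRanges::IRanges(loc_s, loc_e),
        flank = as.integer(flank))
  })
}

# concordance + spacer-overlap + identity summary of mate alignments against
# one haplotype
.pairSummary <- function(h1, h2, spacer_s, spacer_e, min_insert, max_insert) {
  both <- h1$mapped & h2$mapped
  opp <- both & h1$strand != h2$strand
  lo <- pmin(h1$ref_start, h2$ref_start)
  hi <- pmax(h1$ref_end, h2$ref_end)
  insert <- hi - lo + 1L
  left_fwd <- ifelse(h1$ref_start <= h2$ref_start, h1$strand, h2$strand) == "+"
  concordant <- opp & left_fwd & insert >= min_insert & insert <= max_insert
  concordant[is.na(concordant)] <- FALSE
  ov1 <- pmax(0L, pmin(h1$ref_end, spacer_e) - pmax(h1$ref_start, spacer_s) + 1L)
  ov2 <- pmax(0L, pmin(h2$ref_end, spacer_e) - pmax(h2$ref_start, spacer_s) + 1L)
  ov <- pmax(ov1, ov2)
  ov[is.na(ov)] <- 0L
  score <- h1$identity + h2$identity
  score[is.na(score)] <- -Inf
  list(concordant = concordant, overlap = ifelse(concordant, ov, 0L),
       score = ifelse(concordant, score, -Inf))
}

#' Classify read pairs against one locus's dual references
#'
#' A pair is called ON when it aligns concordantly to the ON haplotype with
#' at least `min_informative_overlap` bases of either mate inside the spacer
#' and either fails to align concordantly to the OFF haplotype or aligns
#' with a lower summed identity there; symmetrically for OFF. Everything
#' else - flank-only pairs, discordant pairs, ties - is AMBIGUOUS.
#'
#' @param mate1,mate2 Reads (`DNAStringSet` or character), parallel vectors.
#' @param dual A [DualReference-class] object.
#' @param min_informative_overlap Minimum spacer overlap in nt, default 10;
#'   arms and flanks are identical between haplotypes, so only spacer bases
#'   carry orientation signal.
#' @param k,max_mismatch_frac Passed to [minimalMap()].
#' @param min_insert,max_insert Concordance insert bounds in nt.
#' @return A `data.frame` with one row per pair: `call` (`"ON"`, `"OFF"`,
#'   `"AMBIGUOUS"`), `overlap` (spacer overlap supporting the call) and
#'   `touches` (pair aligned concordantly to either haplotype).
#' @export
classifyPairs <- function(mate1, mate2, dual, min_informative_overlap = 10L,
                          k = 21L, max_mismatch_frac = 0.1,
                          min_insert = 100L, max_insert = 1000L) {
  m1 <- as.character(mate1); m2 <- as.character(mate2)
  stopifnot(length(m1) == length(m2))
  sp_s <- IRanges::start(dual@spacerRange)
  sp_e <- IRanges::end(dual@spacerRange)
  on1 <- minimalMap(m1, dual@onHap, k, max_mismatch_frac)
  on2 <- minimalMap(m2, dual@onHap, k, max_mismatch_frac)
  off1 <- minimalMap(m1, dual@offHap, k, max_mismatch_frac)
  off2 <- minimalMap(m2, dual@offHap, k, max_mismatch_frac)
  s_on <- .pairSummary(on1, on2, sp_s, sp_e, min_insert, max_insert)
  s_off <- .pairSummary(off1, off2, sp_s, sp_e, min_insert, max_insert)

  call <- rep("AMBIGUOUS", length(m1))
  on_ok <- s_on$concordant & s_on$overlap >= min_informative_overlap &
    (!s_off$concordant | s_on$score > s_off$score)
  off_ok <- s_off$concordant & s_off$overlap >= min_informative_overlap &
    (!s_on$concordant | s_off$score > s_on$score)
  call[on_ok & !off_ok] <- "ON"
  call[off_ok & !on_ok] <- "OFF"
  data.frame(call = call,
             overlap = ifelse(call == "ON", s_on$overlap,
                              ifelse(call == "OFF", s_off$overlap, 0L)),
             touches = s_on$concordant | s_off$concordant,
             stringsAsFactors = FALSE)
}

#' Quantify per-locus ON/OFF orientation fractions from read pairs
#'
#' The computation behind population-level phase-variation profiling: for
#' every invertible locus, count concordantly aligned read pairs supporting
#' the ON and the OFF orientation and report the ON fraction with a Wilson
#' 95% confidence interval. Pairs informative for more than one locus are
#' assigned to the locus with the larger spacer overlap; ties are dropped as
#' ambiguous.
#'
#' @param reads Either a list with elements `mate1` and `mate2`
#'   (`DNAStringSet`s or character vectors of equal length), or the path to
#'   a SAM file of paired-end alignments against the dual references (the
#'   reference names must be `"<label>|ON"` / `"<label>|OFF"`, as written by
#'   [writeDualReferences()]).
#' @param genome Genome sequence the loci refer to.
#' @param loci An [InvertibleLoci-class] object.
#' @param flank Dual-reference flank in nt, default 1000.
#' @param conf Confidence level of the Wilson interval, default 0.95.
#' @inheritParams classifyPairs
#' @return An [OrientationCounts-class] object with one row per locus. Loci
#'   with zero informative pairs have `fraction_on = NA` and
#'   `undefined = TRUE`.
#' @export
quantifyOrientations <- function(reads, genome, loci, flank = 1000L,
                                 min_informative_overlap = 10L, k = 21L,
                                 max_mismatch_frac = 0.1, min_insert = 100L,
                                 max_insert = 1000L, conf = 0.95) {
  labs <- locusLabels(loci)
  n_loci <- length(loci)
  genome_str <- .asGenomeString(genome)
  valid <- validateLoci(loci, genome_str) &
    GenomicRanges::end(lociRanges(loci)) <= nchar(genome_str)
  if (any(!valid))
    warning("skipping loci inconsistent with the reference: ",
            paste(labs[!valid], collapse = ", "))

  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    counts <- .countsFromSam(reads, genome_str, loci, valid, flank,
                             min_informative_overlap, min_insert, max_insert)
  } else {
    counts <- .countsFromReads(reads, genome_str, loci, valid, flank,
                               min_informative_overlap, k, max_mismatch_frac,
                               min_insert, max_insert)
  }

  orientationCounts(labs, counts$n_on, counts$n_off, counts$n_amb,
                    conf = conf,
                    note = ifelse(valid, NA_character_,
                                  "locus_inconsistent_with_reference"))
}

#' Build an OrientationCounts object from per-locus pair counts
#'
#' Computes the ON fraction and its Wilson confidence interval from raw
#' counts; this is the reporting path used by [quantifyOrientations()] and
#' can be applied directly to externally produced count tables.
#'
#' @param label Locus labels.
#' @param n_on,n_off,n_ambiguous Pair counts per locus.
#' @param conf Confidence level, default 0.95.
#' @param note Optional per-locus note column.
#' @return An [OrientationCounts-class] object.
#' @export
orientationCounts <- function(label, n_on, n_off, n_ambiguous = 0L,
                              conf = 0.95, note = NA_character_) {
  n <- length(label)
  tb <- data.frame(label = label,
                   n_on = as.integer(rep_len(n_on, n)),
                   n_off = as.integer(rep_len(n_off, n)),
                   n_ambiguous = as.integer(rep_len(n_ambiguous, n)),
                   stringsAsFactors = FALSE)
  n_inf <- tb$n_on + tb$n_off
  tb$fraction_on <- ifelse(n_inf > 0, tb$n_on / n_inf, NA_real_)
  ci <- t(vapply(seq_len(n), function(i)
    .wilson(tb$n_on[i], n_inf[i], conf), numeric(2)))
  tb$ci_low <- ci[, 1L]; tb$ci_high <- ci[, 2L]
  tb$undefined <- n_inf == 0L
  tb$note <- rep_len(note, n)
  new("OrientationCounts", table = tb)
}

.countsFromReads <- function(reads, genome_str, loci, valid, flank,
                             min_ov, k, max_mismatch_frac,
                             min_insert, max_insert) {
  stopifnot(is.list(reads), all(c("mate1", "mate2") %in% names(reads)))
  m1 <- as.character(reads$mate1); m2 <- as.character(reads$mate2)
  n_loci <- length(loci)
  duals <- buildDualReferences(genome_str, loci, flank)
  calls <- matrix("AMBIGUOUS", nrow = length(m1), ncol = n_loci)
  ovs <- matrix(0L, nrow = length(m1), ncol = n_loci)
  touches <- matrix(FALSE, nrow = length(m1), ncol = n_loci)
  for (j in which(valid)) {
    cl <- classifyPairs(m1, m2, duals[[j]], min_ov, k, max_mismatch_frac,
                        min_insert, max_insert)
    calls[, j] <- cl$call; ovs[, j] <- cl$overlap; touches[, j] <- cl$touches
  }
  informative <- calls != "AMBIGUOUS"
  ovs[!informative] <- 0L
  best <- max.col(ovs, ties.method = "first")
  best_ov <- ovs[cbind(seq_len(nrow(ovs)), best)]
  n_best <- rowSums(ovs == best_ov & informative & best_ov > 0L)
  assigned <- ifelse(best_ov > 0L & n_best == 1L, best, NA_integer_)

  n_on <- n_off <- n_amb <- integer(n_loci)
  for (j in seq_len(n_loci)) {
    sel <- !is.na(assigned) & assigned == j
    n_on[j] <- sum(sel & calls[, j] == "ON")
    n_off[j] <- sum(sel & calls[, j] == "OFF")
    n_amb[j] <- sum(touches[, j] & !sel)
  }
  list(n_on = n_on, n_off = n_off, n_amb = n_amb)
}

# SAM route: each concordant pair is attributed to the haplotype reference it
# aligned to; competitive rescoring is not possible without the reads, so
# spacer overlap is the only informativeness gate.
.countsFromSam <- function(path, genome_str, loci, valid, flank,
                           min_ov, min_insert, max_insert) {
  prs <- parsePairedAlignments(path, min_insert, max_insert)
  n_loci <- length(loci)
  duals <- buildDualReferences(genome_str, loci, flank)
  n_on <- n_off <- n_amb <- integer(n_loci)
  for (j in which(valid)) {
    d <- duals[[j]]
    sp_s <- IRanges::start(d@spacerRange); sp_e <- IRanges::end(d@spacerRange)
    for (state in c("ON", "OFF")) {
      rn <- paste0(d@label, "|", state)
      sel <- prs$concordant & !is.na(prs$ref1) & prs$ref1 == rn
      if (!any(sel)) next
      ov1 <- pmax(0L, pmin(prs$end1[sel], sp_e) - pmax(prs$start1[sel], sp_s) + 1L)
      ov2 <- pmax(0L, pmin(prs$end2[sel], sp_e) - pmax(prs$start2[sel], sp_s) + 1L)
      inf <- pmax(ov1, ov2) >= min_ov
      if (state == "ON") n_on[j] <- sum(inf) else n_off[j] <- sum(inf)
      n_amb[j] <- n_amb[j] + sum(!inf)
    }
  }
  list(n_on = n_on, n_off = n_off, n_amb = n_amb)
}

#' Write dual references as FASTA
#'
#' Writes the ON and OFF haplotype of each locus as `"<label>|ON"` /
#' `"<label>|OFF"` records, the reference layout expected by the SAM input
#' mode of [quantifyOrientations()].
#'
#' @param duals A list of [DualReference-class] objects.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
writeDualReferences <- function(duals, path) {
  seqs <- Biostrings::DNAStringSet(unlist(lapply(duals, function(d)
    stats::setNames(list(as.character(d@onHap), as.character(d@offHap)),
                    paste0(d@label, "|", c("ON", "OFF"))))))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
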