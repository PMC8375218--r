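#' Find candidate invertible loci as inverted-repeat pairs
#'
#' Scans a genome for perfect inverted-repeat pairs with a bounded spacer:
#' the architecture of phase-variable promoters, where a site-specific
#' recombinase flips the spacer between two complementary repeat arms.
#'
#' In seeded mode (`seed_motif` given) every occurrence pair
#' `motif ... reverse complement of motif` with a spacer length inside
#' `spacer_range` is reported, with the arm fixed to the motif. In de novo
#' mode all maximal perfect inverted-repeat pairs with arm length
#' `>= min_arm_len` and spacer in range are reported; maximal means the arms
#' cannot be extended (outward or inward) while remaining perfect
#' complements. Overlapping candidates are deduplicated greedily, preferring
#' longer arms and, among equal arms, smaller spacers (local pairing).
#'
#' @param genome Genome sequence (`DNAStringSet`/`DNAString`/character).
#' @param min_arm_len Minimum arm length in nt, default 10 (must be >= 6).
#' @param spacer_range Closed integer spacer-length range, default
#'   `c(150, 250)` nt, bracketing the 183-186 nt promoter cassettes of
#'   *Bacteroides* CPS loci with margin.
#' @param seed_motif Optional arm sequence to seed the search (e.g.
#'   `"GTTCGTTTAA"`).
#' @param ref_name Reference name used when `genome` is unnamed.
#' @return An [InvertibleLoci-class] object, sorted by position. The
#'   `repeat_seq` column carries the left-arm sequence, supporting grouping
#'   of loci that share an identical repeat.
#' @export
findInvertedRepeatLoci <- function(genome, min_arm_len = 10L,
                                   spacer_range = c(150L, 250L),
                                   seed_motif = NULL, ref_name = "ref") {
  stopifnot(min_arm_len >= 6L, spacer_range[1L] <= spacer_range[2L],
            spacer_range[1L] >= 0L)
  if (is(genome, "DNAStringSet") && !is.null(names(genome)))
    ref_name <- names(genome)[1L]
  s <- .asGenomeString(genome)
  L <- nchar(s)
  arm0 <- if (is.null(seed_motif)) min_arm_len else nchar(seed_motif)
  if (L < 2L * arm0 + spacer_range[1L]) {
    warning("genome shorter than the smallest reportable locus; empty result")
    return(InvertibleLoci(ref_name, integer(0), integer(0), integer(0),
                          repeat_seq = character(0)))
  }
  cand <- if (is.null(seed_motif)) {
    .denovoCandidates(s, min_arm_len, spacer_range)
  } else {
    .seededCandidates(s, seed_motif, spacer_range)
  }
  cand <- .dedupCandidates(cand)
  if (!nrow(cand)) {
    return(InvertibleLoci(ref_name, integer(0), integer(0), integer(0),
                          repeat_seq = character(0)))
  }
  InvertibleLoci(ref_name, cand$left_start, cand$arm, cand$spacer,
                 repeat_seq = substring(s, cand$left_start,
                                        cand$left_start + cand$arm - 1L))
}

# seeded mode: exact occurrences of motif paired with occurrences of its
# reverse complement at spacer distance
.seededCandidates <- function(s, motif, spacer_range) {
  m <- nchar(motif)
  subject <- Biostrings::DNAString(s)
  lefts <- BiocGenerics::start(
    Biostrings::matchPattern(Biostrings::DNAString(motif), subject))
  rights <- BiocGenerics::start(
    Biostrings::matchPattern(
      Biostrings::reverseComplement(Biostrings::DNAString(motif)), subject))
  if (!length(lefts) || !length(rights))
    return(data.frame(left_start = integer(0), arm = integer(0),
                      spacer = integer(0)))
  pairs <- expand.grid(i = lefts, j = rights)
  pairs$spacer <- pairs$j - (pairs$i + m)
  pairs <- pairs[pairs$spacer >= spacer_range[1L] &
                 pairs$spacer <= spacer_range[2L], , drop = FALSE]
  data.frame(left_start = pairs$i, arm = m, spacer = pairs$spacer)
}

# raw complement lookup (N and friends never match anything)
.compRaw <- function() {
  comp <- raw(256)
  comp[as.integer(charToRaw("A")) + 1L] <- charToRaw("T")
  comp[as.integer(charToRaw("T")) + 1L] <- charToRaw("A")
  comp[as.integer(charToRaw("C")) + 1L] <- charToRaw("G")
  comp[as.integer(charToRaw("G")) + 1L] <- charToRaw("C")
  comp
}

# de novo mode: k-mer seeds between the genome and its reverse complement,
# grouped by antidiagonal and extended to maximal complementary arms
.denovoCandidates <- function(s, min_arm_len, spacer_range) {
  empty <- data.frame(left_start = integer(0), arm = integer(0),
                      spacer = integer(0))
  L <- nchar(s)
  k <- min_arm_len
  if (L < 2L * k + spacer_range[1L]) return(empty)
  np <- L - k + 1L
  kmers <- substring(s, seq_len(np), seq_len(np) + k - 1L)
  rckmers <- .revcomp(kmers)
  lt <- data.table::data.table(kmer = kmers, i = seq_len(np))
  rt <- data.table::data.table(kmer = rckmers, j = seq_len(np))
  seeds <- merge(lt, rt, by = "kmer", allow.cartesian = TRUE)
  # seed arm [i, i+k-1] pairs with [j, j+k-1]; keep left-before-right seeds
  # whose seed spacer could still reach the range after (inward) extension:
  # extension never increases the spacer, and the rightmost seed window of a
  # maximal arm has seed spacer equal to the true spacer.
  seeds <- seeds[j > i]
  seeds[, spacer := j - i - k]
  seeds <- seeds[spacer >= spacer_range[1L]]
  if (!nrow(seeds)) return(empty)

  sraw <- charToRaw(s)
  comp <- .compRaw()
  is_comp <- function(p, q) comp[as.integer(sraw[p]) + 1L] == sraw[q]

  seeds[, antidiag := i + j + k - 1L]
  # one extension per (antidiagonal, seed run): collapse seeds of the same
  # arm by keeping, per antidiagonal, distinct maximal intervals
  out <- vector("list", nrow(seeds))
  n_out <- 0L
  done <- character(0)
  for (r in seq_len(nrow(seeds))) {
    i <- seeds$i[r]; c_ad <- seeds$antidiag[r]
    lo <- i; hi <- i + k - 1L
    while (lo > 1L && c_ad - lo + 1L <= L && is_comp(lo - 1L, c_ad - lo + 1L))
      lo <- lo - 1L
    while (hi + 1L < c_ad - hi - 1L && is_comp(hi + 1L, c_ad - hi - 1L))
      hi <- hi + 1L
    key <- paste(lo, hi, c_ad, sep = ":")
    if (key %in% done) next
    done <- c(done, key)
    armlen <- hi - lo + 1L
    spacer <- c_ad - 2L * hi - 1L
    if (armlen >= min_arm_len && spacer >= spacer_range[1L] &&
        spacer <= spacer_range[2L] && c_ad - lo <= L) {
      n_out <- n_out + 1L
      out[[n_out]] <- c(left_start = lo, arm = armlen, spacer = spacer)
    }
  }
  if (!n_out) return(empty)
  res <- as.data.frame(do.call(rbind, out[seq_len(n_out)]))
  unique(res)
}

# greedy deduplication of overlapping candidates: longest arm first, then
# smallest spacer (nearest partner), then leftmost
.dedupCandidates <- function(cand) {
  if (!nrow(cand)) return(cand)
  ord <- order(-cand$arm, cand$spacer, cand$left_start)
  cand <- cand[ord, , drop = FALSE]
  span_s <- cand$left_start
  span_e <- cand$left_start + 2L * cand$arm + cand$spacer - 1L
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    sel <- which(keep)
    if (!length(sel) ||
        all(span_e[r] < span_s[sel] | span_s[r] > span_e[sel]))
      keep[r] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  cand[order(cand$left_start), , drop = FALSE]
}

#' Match a degenerate IUPAC motif on both strands
#'
#' @param genome Genome sequence (`DNAStringSet`/`DNAString`/character).
#' @param motif IUPAC motif string (e.g. `"ARACGTTCGTN"`); `N` matches any
#'   base, `R` purines, and so on.
#' @param ref_name Reference name used when `genome` is unnamed.
#' @return A `data.frame` of hits: `ref_name`, `start`, `end` (1-based
#'   inclusive, always on the forward coordinate system), `strand`,
#'   `matched_seq` (the forward-strand genome sequence at the hit).
#' @export
matchIupacMotif <- function(genome, motif, ref_name = "ref") {
  ok <- strsplit(toupper(motif), "")[[1L]] %in%
    names(Biostrings::IUPAC_CODE_MAP)
  if (!all(ok))
    stop("invalid IUPAC code in motif: ",
         paste(unique(strsplit(toupper(motif), "")[[1L]][!ok]), collapse = ", "))
  if (is(genome, "DNAStringSet") && !is.null(names(genome)))
    ref_name <- names(genome)[1L]
  subject <- Biostrings::DNAString(.asGenomeString(genome))
  pat <- Biostrings::DNAString(toupper(motif))
  fwd <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
  rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat), subject,
                                  fixed = FALSE)
  starts <- c(BiocGenerics::start(fwd), BiocGenerics::start(rev))
  df <- data.frame(
    ref_name = rep_len(ref_name, length(starts)),
    start = starts,
    end = c(BiocGenerics::end(fwd), BiocGenerics::end(rev)),
    strand = rep(c("+", "-"), c(length(fwd), length(rev))),
    stringsAsFactors = FALSE)
  df <- df[order(df$start, df$strand), , drop = FALSE]
  df$matched_seq <- if (nrow(df))
    substring(as.character(subject), df$start, df$end) else character(0)
  rownames(df) <- NULL
  df
}

#' Resolve the ON-orientation convention from an operon annotation
#'
#' Labels each locus's reference-orientation state as ON or OFF using the
#' position of the nearest operon the promoter could drive. The direction
#' the promoter points in the reference orientation must be supplied
#' (`promoter_strand`, typically from transcription-start analysis). A locus
#' whose promoter points at an operon starting within `window` nt downstream
#' keeps `reference_is_on = TRUE`; if the only eligible operon lies on the
#' opposite side (so the promoter must flip to drive it) the reference state
#' is labelled OFF. Loci with no eligible operon, or when no annotation is
#' given, keep the `as_reference` convention and are flagged.
#'
#' @param loci An [InvertibleLoci-class] object.
#' @param operons Optional `GRanges` of operons (strand-aware; transcription
#'   starts at `start` on `+`, at `end` on `-`).
#' @param window Maximum promoter-to-operon distance in nt, default 5000.
#' @param promoter_strand Direction of the promoter in the reference
#'   orientation, `"+"` (rightward, the default) or `"-"`, recycled per
#'   locus.
#' @return The loci with `on_definition`, `reference_is_on` and `flagged`
#'   updated.
#' @export
setOrientationConvention <- function(loci, operons = NULL, window = 5000L,
                                     promoter_strand = "+") {
  n <- length(loci)
  promoter_strand <- rep_len(promoter_strand, n)
  gr <- loci@ranges
  mc <- S4Vectors::mcols(gr)
  if (is.null(operons) || n == 0L) {
    mc$on_definition <- rep("as_reference", n)
    mc$reference_is_on <- rep(TRUE, n)
    mc$flagged <- rep(TRUE, n)
    S4Vectors::mcols(loci@ranges) <- mc
    return(loci)
  }
  op_strand <- as.character(GenomicRanges::strand(operons))
  op_start <- GenomicRanges::start(operons)
  op_end <- GenomicRanges::end(operons)
  for (i in seq_len(n)) {
    ls <- GenomicRanges::start(gr)[i]; le <- GenomicRanges::end(gr)[i]
    # distance to each operon's transcription start, on the side it is
    # readable from: rightward for '+' operons, leftward for '-' operons
    d_right <- ifelse(op_strand == "+" & op_start > le,
                      op_start - le, NA_real_)
    d_left <- ifelse(op_strand == "-" & op_end < ls,
                     ls - op_end, NA_real_)
    best_right <- suppressWarnings(min(d_right, na.rm = TRUE))
    best_left <- suppressWarnings(min(d_left, na.rm = TRUE))
    has_right <- is.finite(best_right) && best_right <= window
    has_left <- is.finite(best_left) && best_left <= window
    if (!has_right && !has_left) {
      mc$on_definition[i] <- "as_reference"
      mc$reference_is_on[i] <- TRUE
      mc$flagged[i] <- TRUE
      next
    }
    toward_right <- if (has_right && has_left) best_right <= best_left
                    else has_right
    mc$on_definition[i] <- "toward_operon"
    mc$reference_is_on[i] <- if (promoter_strand[i] == "+") toward_right
                             else !toward_right
    mc$flagged[i] <- FALSE
  }
  S4Vectors::mcols(loci@ranges) <- mc
  loci
}
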