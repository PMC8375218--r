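#' Minimal read mapper for low-error data
#'
#' Maps reads to a single reference by exact k-mer seeding on both strands
#' followed by ungapped extension over the full read. Only the unique best
#' placement is reported; ties, reads without a seed, and placements
#' exceeding the mismatch budget are reported unmapped. Identity is computed
#' as matches divided by aligned length. Intended for synthetic, low-error
#' reads where gapped alignment is unnecessary.
#'
#' @param reads A `DNAStringSet` (or character vector) of reads. Names are
#'   used as read ids; unnamed reads get `read_1`, `read_2`, ...
#' @param reference Reference sequence: `DNAStringSet` of length 1,
#'   `DNAString`, or a single character string.
#' @param k Seed length, default 21 (near-unique in megabase-scale genomes,
#'   robust at low substitution error); must be >= 11.
#' @param max_mismatch_frac Maximum tolerated mismatch fraction, default 0.1.
#' @param ref_name Reference name recorded in the output.
#' @return A `data.frame` of alignment blocks (1-based inclusive
#'   coordinates): `read_id`, `read_start`, `read_end`, `ref_name`,
#'   `ref_start`, `ref_end`, `strand`, `identity`, `evalue` (always `NA`),
#'   `mapped`. Unmapped reads keep a row with `mapped = FALSE`.
#' @export
minimalMap <- function(reads, reference, k = 21L, max_mismatch_frac = 0.1,
                       ref_name = "ref") {
  if (k < 11L) stop("seed length k must be >= 11")
  refstr <- .asGenomeString(reference)
  if (missing(ref_name) && is(reference, "DNAStringSet") &&
      !is.null(names(reference)))
    ref_name <- names(reference)[1L]
  if (nchar(refstr) < k)
    stop("reference shorter than seed length k")
  ids <- names(reads)
  reads <- as.character(reads)
  if (is.null(ids)) ids <- paste0("read_", seq_along(reads))
  if (!length(reads)) {
    return(data.frame(read_id = character(0), read_start = integer(0),
                      read_end = integer(0), ref_name = character(0),
                      ref_start = integer(0), ref_end = integer(0),
                      strand = character(0), identity = numeric(0),
                      evalue = numeric(0), mapped = logical(0),
                      stringsAsFactors = FALSE))
  }
  hits <- .minimal_map_cpp(reads, refstr, as.integer(k), max_mismatch_frac)
  data.frame(read_id = ids,
             read_start = hits$read_start, read_end = hits$read_end,
             ref_name = ifelse(hits$mapped, ref_name, NA_character_),
             ref_start = hits$ref_start, ref_end = hits$ref_end,
             strand = hits$strand, identity = hits$identity,
             evalue = NA_real_, mapped = hits$mapped,
             stringsAsFactors = FALSE)
}

#' Split-map long reads into local alignment blocks
#'
#' Seeds every k-mer of each read against the reference on both strands and
#' groups co-diagonal seeds into ungapped local alignment blocks, so a read
#' spanning an inverted segment yields multiple blocks with the internal
#' block on the opposite strand. This is the internal stand-in for a local
#' aligner when analysing synthetic long reads; real data would normally
#' arrive as PAF/BLAST tables via [parseAlignmentTable()].
#'
#' @inheritParams minimalMap
#' @param min_seeds Minimum number of seed k-mers supporting a block,
#'   default 2 (suppresses isolated spurious matches).
#' @param max_seed_gap Co-diagonal seeds further apart than this on the
#'   read are split into separate blocks, default 100 nt; this is what
#'   separates the collinear segments on either side of an inverted or
#'   displaced region from each other.
#' @return A `data.frame` of alignment blocks with the same columns as
#'   [minimalMap()] plus `read_length`; one row per block, multiple rows per
#'   read possible, only mapped blocks reported.
#' @export
splitMap <- function(reads, reference, k = 21L, min_seeds = 2L,
                     max_seed_gap = 100L, ref_name = "ref") {
  if (k < 11L) stop("seed length k must be >= 11")
  refstr <- .asGenomeString(reference)
  if (missing(ref_name) && is(reference, "DNAStringSet") &&
      !is.null(names(reference)))
    ref_name <- names(reference)[1L]
  if (nchar(refstr) < k) stop("reference shorter than seed length k")
  ids <- names(reads)
  reads <- as.character(reads)
  if (is.null(ids)) ids <- paste0("read_", seq_along(reads))

  empty <- data.frame(read_id = character(0), read_length = integer(0),
                      read_start = integer(0), read_end = integer(0),
                      ref_name = character(0), ref_start = integer(0),
                      ref_end = integer(0), strand = character(0),
                      identity = numeric(0), evalue = numeric(0),
                      mapped = logical(0), stringsAsFactors = FALSE)
  if (!length(reads)) return(empty)

  L <- nchar(refstr)
  ref_kmers <- substring(refstr, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
  ref_dt <- data.table::data.table(kmer = ref_kmers,
                                   refpos = seq_along(ref_kmers))

  lens <- nchar(reads)
  usable <- which(lens >= k)
  if (!length(usable)) return(empty)
  read_tabs <- lapply(usable, function(i) {
    np <- lens[i] - k + 1L
    data.table::data.table(
      ridx = i, readpos = seq_len(np),
      kmer = substring(reads[i], seq_len(np), seq_len(np) + k - 1L))
  })
  rd <- data.table::rbindlist(read_tabs)
  rd[, rckmer := .revcomp(kmer)]

  fwd <- merge(rd[, .(ridx, readpos, kmer)], ref_dt, by = "kmer",
               allow.cartesian = TRUE)
  rev <- merge(rd[, .(ridx, readpos, kmer = rckmer)], ref_dt, by = "kmer",
               allow.cartesian = TRUE)
  blocks <- list()
  if (nrow(fwd)) {
    fwd[, diag := refpos - readpos]
    data.table::setorder(fwd, ridx, diag, readpos)
    fwd[, sub := cumsum(c(0L, as.integer(diff(readpos) > max_seed_gap))),
        by = .(ridx, diag)]
    bf <- fwd[, .(n = .N, rs = min(readpos), re = max(readpos) + k - 1L),
              by = .(ridx, diag, sub)]
    bf[, `:=`(strand = "+", ref_s = diag + rs, ref_e = diag + re)]
    blocks <- c(blocks, list(bf[, .(ridx, strand, rs, re, ref_s, ref_e, n)]))
  }
  if (nrow(rev)) {
    rev[, adiag := readpos + refpos]
    data.table::setorder(rev, ridx, adiag, readpos)
    rev[, sub := cumsum(c(0L, as.integer(diff(readpos) > max_seed_gap))),
        by = .(ridx, adiag)]
    br <- rev[, .(n = .N, rs = min(readpos), re = max(readpos) + k - 1L),
              by = .(ridx, adiag, sub)]
    # read start maps to antidiag - readpos (k-mer start); block ref span:
    br[, `:=`(strand = "-",
              ref_s = adiag - (re - k + 1L),
              ref_e = adiag - rs + k - 1L)]
    blocks <- c(blocks, list(br[, .(ridx, strand, rs, re, ref_s, ref_e, n)]))
  }
  if (!length(blocks)) return(empty)
  bl <- data.table::rbindlist(blocks)
  bl <- bl[n >= min_seeds]
  if (!nrow(bl)) return(empty)
  data.table::setorder(bl, ridx, rs)

  # identity by direct comparison of the block's read and reference segments
  seg_read <- substring(reads[bl$ridx], bl$rs, bl$re)
  seg_ref <- substring(refstr, bl$ref_s, bl$ref_e)
  flip <- bl$strand == "-"
  seg_ref[flip] <- .revcomp(seg_ref[flip])
  mism <- .countMismatches(seg_read, seg_ref)
  width <- bl$re - bl$rs + 1L

  data.frame(read_id = ids[bl$ridx], read_length = lens[bl$ridx],
             read_start = bl$rs, read_end = bl$re,
             ref_name = ref_name, ref_start = bl$ref_s, ref_end = bl$ref_e,
             strand = bl$strand, identity = 1 - mism / width,
             evalue = NA_real_, mapped = TRUE, stringsAsFactors = FALSE)
}
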