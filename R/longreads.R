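#' Filter and chain long-read alignment blocks
#'
#' Applies the retention filters for within-read rearrangement detection and
#' orders the surviving blocks of each read along the read axis. Reads of at
#' most `min_read_len` nt are dropped entirely; individual blocks are kept
#' only if their aligned length exceeds `min_block_len`, their identity
#' exceeds `min_identity`, and (when an e-value is present, e.g. from BLAST
#' tabular input) the e-value is at most `max_evalue`. Within a read, blocks
#' overlapping an already accepted, higher-scoring block on the read axis by
#' more than `overlap_tol` nt are discarded.
#'
#' @param blocks Alignment-block `data.frame` (from [parseAlignmentTable()],
#'   [splitMap()] or [minimalMap()]); must contain `read_id`, `read_start`,
#'   `read_end`, `ref_start`, `ref_end`, `strand`, `identity`, and
#'   optionally `read_length` and `evalue`.
#' @param min_read_len Minimum read length in nt (exclusive), default 1000.
#' @param min_block_len Minimum aligned block length in nt (exclusive),
#'   default 200.
#' @param min_identity Minimum identity fraction (exclusive), default 0.9.
#' @param max_evalue Maximum e-value (inclusive), default `1e-20`; applied
#'   only to blocks that carry a non-`NA` e-value.
#' @param read_lengths Optional named vector of read lengths, used when the
#'   table has no `read_length` column (BLAST tabular); otherwise read
#'   length falls back to the largest `read_end` seen per read.
#' @param overlap_tol Tolerated on-read overlap between blocks in nt,
#'   default 20.
#' @return The filtered blocks, sorted by `read_id` then `read_start` - one
#'   chain per remaining read.
#' @export
chainReadBlocks <- function(blocks, min_read_len = 1000L, min_block_len = 200L,
                            min_identity = 0.9, max_evalue = 1e-20,
                            read_lengths = NULL, overlap_tol = 20L) {
  if (!nrow(blocks)) return(blocks)
  if (!is.null(blocks$mapped)) blocks <- blocks[blocks$mapped, , drop = FALSE]
  if (!nrow(blocks)) return(blocks)

  rl <- blocks$read_length
  if (is.null(rl)) rl <- rep(NA_integer_, nrow(blocks))
  if (!is.null(read_lengths))
    rl <- ifelse(is.na(rl), unname(read_lengths[blocks$read_id]), rl)
  fallback <- stats::ave(blocks$read_end, blocks$read_id, FUN = max)
  rl <- ifelse(is.na(rl), fallback, rl)

  keep <- rl > min_read_len &
    (blocks$read_end - blocks$read_start + 1L) > min_block_len &
    blocks$identity > min_identity
  if (!is.null(blocks$evalue))
    keep <- keep & (is.na(blocks$evalue) | blocks$evalue <= max_evalue)
  blocks <- blocks[keep, , drop = FALSE]
  if (!nrow(blocks)) return(blocks)

  # resolve on-read overlaps: greedy by score (identity x length)
  blocks$`.score` <- blocks$identity *
    (blocks$read_end - blocks$read_start + 1L)
  out <- lapply(split(blocks, blocks$read_id), function(b) {
    b <- b[order(-b$`.score`), , drop = FALSE]
    keep <- logical(nrow(b))
    for (r in seq_len(nrow(b))) {
      sel <- which(keep)
      ov <- if (length(sel))
        pmax(0L, pmin(b$read_end[r], b$read_end[sel]) -
               pmax(b$read_start[r], b$read_start[sel]) + 1L)
      else 0L
      if (all(ov <= overlap_tol)) keep[r] <- TRUE
    }
    b <- b[keep, , drop = FALSE]
    b[order(b$read_start), , drop = FALSE]
  })
  blocks <- do.call(rbind, out)
  blocks$`.score` <- NULL
  rownames(blocks) <- NULL
  blocks
}

#' Detect within-read rearrangement events
#'
#' Walks each read's chain of alignment blocks in read order and emits
#' events at block junctions. Adjacent blocks on opposite strands emit an
#' `inverted` event anchored at the boundary of the inverted (minority
#' strand) block facing the junction, so a fully spanned inversion
#' contributes an event at each of its two edges. Adjacent same-strand
#' blocks whose reference gap differs from their read gap by more than
#' `min_shift` nt emit a `displaced` event carrying that shift, anchored at
#' the downstream block's reference start. Single-block (collinear) chains
#' emit nothing.
#'
#' @param chains Filtered blocks from [chainReadBlocks()].
#' @param min_shift Minimum reference shift in nt (exclusive), default 200.
#' @return A `data.frame` of events: `read_id`, `kind` (`"inverted"` or
#'   `"displaced"`), `ref_pos`, `shift` (`NA` for inverted events),
#'   `strands` (e.g. `"+/-"`).
#' @export
detectRearrangements <- function(chains, min_shift = 200L) {
  empty <- data.frame(read_id = character(0), kind = character(0),
                      ref_pos = integer(0), shift = integer(0),
                      strands = character(0), stringsAsFactors = FALSE)
  if (!nrow(chains)) return(empty)
  out <- lapply(split(chains, chains$read_id), function(b) {
    n <- nrow(b)
    if (n < 2L) return(NULL)
    b <- b[order(b$read_start), , drop = FALSE]
    # dominant strand by aligned read length; ties resolved toward '+'
    wid <- b$read_end - b$read_start + 1L
    plus_w <- sum(wid[b$strand == "+"])
    dominant <- if (plus_w >= sum(wid) / 2) "+" else "-"
    ev <- vector("list", n - 1L)
    for (r in seq_len(n - 1L)) {
      a <- b[r, ]; d <- b[r + 1L, ]
      if (a$strand != d$strand) {
        inner <- if (a$strand != dominant && d$strand == dominant) "a"
                 else "d"
        ref_pos <- if (inner == "a") a$ref_end else d$ref_start
        ev[[r]] <- data.frame(read_id = a$read_id, kind = "inverted",
                              ref_pos = ref_pos, shift = NA_integer_,
                              strands = paste0(a$strand, "/", d$strand),
                              stringsAsFactors = FALSE)
      } else {
        read_gap <- d$read_start - a$read_end - 1L
        ref_gap <- if (a$strand == "+") d$ref_start - a$ref_end - 1L
                   else a$ref_start - d$ref_end - 1L
        shift <- ref_gap - read_gap
        if (abs(shift) > min_shift) {
          ev[[r]] <- data.frame(read_id = a$read_id, kind = "displaced",
                                ref_pos = d$ref_start, shift = shift,
                                strands = paste0(a$strand, "/", d$strand),
                                stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, ev)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Bin rearrangement events into a genome-wide hotspot histogram
#'
#' Event start coordinates are binned into fixed-width windows; bins whose
#' event count reaches `min_count` are flagged as recombination hotspots.
#' The default threshold is `max(5, qpois(0.999, total events / bins))`: the
#' 99.9th percentile of a uniform (Poisson) background, floored at 5. The
#' raw histogram is always returned so other thresholds can be applied.
#'
#' @param events Event `data.frame` from [detectRearrangements()].
#' @param genome_length Reference length in nt.
#' @param bin_width Bin width in nt, default 1000.
#' @param min_count Hotspot threshold; `NULL` (default) uses the Poisson
#'   upper-tail rule above.
#' @return A `data.frame` with one row per bin: `bin_index` (0-based),
#'   `ref_start`, `ref_end` (1-based inclusive, clipped to the genome),
#'   `event_count`, `is_hotspot`.
#' @export
hotspotHistogram <- function(events, genome_length, bin_width = 1000L,
                             min_count = NULL) {
  stopifnot(bin_width >= 1L, genome_length >= 1L)
  n_bins <- as.integer(ceiling(genome_length / bin_width))
  counts <- integer(n_bins)
  if (nrow(events)) {
    idx <- pmin(as.integer((events$ref_pos - 1L) %/% bin_width), n_bins - 1L)
    tab <- tabulate(idx + 1L, nbins = n_bins)
    counts <- as.integer(tab)
  }
  if (is.null(min_count))
    min_count <- max(5L, qpois(0.999, sum(counts) / n_bins))
  data.frame(bin_index = seq_len(n_bins) - 1L,
             ref_start = (seq_len(n_bins) - 1L) * bin_width + 1L,
             ref_end = pmin(seq_len(n_bins) * bin_width,
                            as.integer(genome_length)),
             event_count = counts,
             is_hotspot = counts >= min_count & counts > 0L)
}
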