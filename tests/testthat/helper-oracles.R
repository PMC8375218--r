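# Independent oracles and small fixture builders shared across tests.

rc_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Brute-force inverted-repeat oracle: enumerate every (left start, spacer)
# pair, test arm complementarity by direct character comparison, extend
# maximally with vector ops, and deduplicate greedily. Written independently
# of the package's seeded/hashed implementation.
oracle_inverted_repeats <- function(s, min_arm = 10L,
                                    spacer_range = c(150L, 250L)) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1L]]
  co <- chartr("ACGT", "TGCA", ch)
  hits <- list()
  for (sp in seq(spacer_range[1L], spacer_range[2L])) {
    i_max <- n - 2L * min_arm - sp + 1L
    if (i_max < 1L) next
    i <- seq_len(i_max)
    j <- i + min_arm + sp          # right arm start
    ok <- rep(TRUE, i_max)
    for (t in 0:(min_arm - 1L))
      ok <- ok & ch[i + t] == co[j + min_arm - 1L - t]
    for (ii in i[ok]) {
      jj <- ii + min_arm + sp
      csum <- ii + jj + min_arm - 1L   # paired positions sum to this
      lo <- ii; hi <- ii + min_arm - 1L
      while (lo > 1L && csum - lo + 1L <= n && ch[lo - 1L] == co[csum - lo + 1L])
        lo <- lo - 1L
      while (hi + 1L < csum - hi - 1L && ch[hi + 1L] == co[csum - hi - 1L])
        hi <- hi + 1L
      hits[[length(hits) + 1L]] <-
        c(left_start = lo, arm = hi - lo + 1L, spacer = csum - 2L * hi - 1L)
    }
  }
  if (!length(hits))
    return(data.frame(left_start = integer(0), arm = integer(0),
                      spacer = integer(0)))
  cand <- unique(as.data.frame(do.call(rbind, hits)))
  cand <- cand[cand$spacer >= spacer_range[1L] &
               cand$spacer <= spacer_range[2L] &
               cand$arm >= min_arm, , drop = FALSE]
  if (!nrow(cand)) return(cand)
  # greedy non-overlap selection: longest arm, then smallest spacer, leftmost
  cand <- cand[order(-cand$arm, cand$spacer, cand$left_start), , drop = FALSE]
  e <- cand$left_start + 2L * cand$arm + cand$spacer - 1L
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    prev <- which(keep)
    if (!length(prev) ||
        all(e[r] < cand$left_start[prev] | cand$left_start[r] > e[prev]))
      keep[r] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$left_start), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

# loci as a comparable data.frame
loci_df <- function(loci) {
  gr <- lociRanges(loci)
  mc <- S4Vectors::mcols(gr)
  data.frame(left_start = GenomicRanges::start(gr),
             arm = mc$arm_length,
             spacer = mc$spacer_end - mc$spacer_start + 1L)
}

# IUPAC motif hits via regex expansion (independent of Biostrings matching)
oracle_iupac_hits <- function(s, motif) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  to_re <- function(m) paste(map[strsplit(m, "")[[1L]]], collapse = "")
  find_all <- function(re) {
    out <- integer(0)
    off <- 0L
    sub <- s
    repeat {
      m <- regexpr(re, sub, perl = TRUE)
      if (m < 0) break
      out <- c(out, off + as.integer(m))
      off <- off + as.integer(m)
      sub <- substring(s, off + 1L)
    }
    out
  }
  fwd <- find_all(to_re(motif))
  rev <- find_all(to_re(rc_chr(motif)))
  w <- nchar(motif)
  df <- data.frame(start = c(fwd, rev), end = c(fwd, rev) + w - 1L,
                   strand = rep(c("+", "-"), c(length(fwd), length(rev))))
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# write a PAF file from an alignment-block table (1-based inclusive in,
# 0-based half-open out)
write_paf <- function(blocks, path) {
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                   blocks$read_id, blocks$read_length,
                   blocks$read_start - 1L, blocks$read_end,
                   blocks$strand, blocks$ref_name, blocks$ref_length,
                   blocks$ref_start - 1L, blocks$ref_end,
                   blocks$n_match, blocks$aln_len, 60L)
  writeLines(lines, path)
  path
}

# minimal SAM writer for paired records
write_sam <- function(recs, seqlens, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), seqlens))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  recs$qname, recs$flag, recs$rname, recs$pos, 60L,
                  recs$cigar, "*", 0L, 0L, recs$seq, "*")
  writeLines(c(hdr, body), path)
  path
}
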