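#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] /
#' [Biostrings::readQualityScaledDNAStringSet()] that preserves FASTQ
#' qualities and accepts gzip-compressed input. Records are returned in file
#' order.
#'
#' @param path Path to a FASTA or FASTQ file, optionally gzipped.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (from the file extension).
#' @return A `DNAStringSet` (FASTA) or `QualityScaledDNAStringSet` (FASTQ).
#' @export
readSequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    base <- sub("\\.(gz|bgz)$", "", path, ignore.case = TRUE)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  tryCatch({
    if (format == "fastq")
      # the quality-aware reader warns about dropping (empty) metadata
      # columns during construction; that is internal noise
      suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    else
      Biostrings::readDNAStringSet(path, format = "fasta")
  }, error = function(e) {
    stop("parse error in ", path, " (", format, "): ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Write sequences to FASTA or FASTQ
#'
#' @param x A `DNAStringSet` or `QualityScaledDNAStringSet`.
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`; defaults to `"fastq"` when `x`
#'   carries qualities.
#' @return `path`, invisibly.
#' @export
writeSequences <- function(x, path, format = NULL) {
  if (is.null(format))
    format <- if (is(x, "QualityScaledXStringSet")) "fastq" else "fasta"
  if (format == "fastq") {
    if (is(x, "QualityScaledXStringSet")) {
      Biostrings::writeXStringSet(x, path, format = "fastq",
                                  qualities = Biostrings::quality(x))
    } else {
      Biostrings::writeXStringSet(x, path, format = "fastq")
    }
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  }
  invisible(path)
}

#' Parse tabular alignments (PAF or BLAST outfmt 6)
#'
#' Normalises both dialects to one alignment-block table in 1-based inclusive
#' coordinates on the forward reference strand. BLAST rows reported on the
#' minus strand (subject start > subject end) are flipped and the strand set
#' to `"-"`; percent identity is converted to a fraction.
#'
#' @param path Path to the alignment table.
#' @param dialect `"PAF"` or `"BLAST6"` (12-column BLAST `-outfmt 6`).
#' @return A `data.frame` with columns `read_id`, `read_length` (`NA` for
#'   BLAST6), `read_start`, `read_end`, `ref_name`, `ref_start`, `ref_end`,
#'   `strand`, `identity`, `evalue` (`NA` for PAF).
#' @export
parseAlignmentTable <- function(path, dialect = c("PAF", "BLAST6")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  empty <- data.frame(read_id = character(0), read_length = integer(0),
                      read_start = integer(0), read_end = integer(0),
                      ref_name = character(0), ref_start = integer(0),
                      ref_end = integer(0), strand = character(0),
                      identity = numeric(0), evalue = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- 12L
  bad <- which(lengths(fields) < ncol_min)
  if (length(bad))
    stop("parse error: line ", bad[1L], " has ", lengths(fields)[bad[1L]],
         " columns, expected >= ", ncol_min)
  m <- do.call(rbind, lapply(fields, `[`, seq_len(ncol_min)))

  .num <- function(x, what) {
    out <- suppressWarnings(as.numeric(x))
    if (anyNA(out))
      stop("parse error: non-numeric ", what, " at line ",
           which(is.na(out))[1L])
    out
  }

  if (dialect == "PAF") {
    # qname qlen qstart qend strand tname tlen tstart tend nmatch alnlen mapq
    strand <- m[, 5L]
    if (!all(strand %in% c("+", "-")))
      stop("parse error: invalid PAF strand field")
    nmatch <- .num(m[, 10L], "match count")
    alnlen <- .num(m[, 11L], "alignment length")
    data.frame(
      read_id = m[, 1L],
      read_length = as.integer(.num(m[, 2L], "read length")),
      read_start = as.integer(.num(m[, 3L], "query start")) + 1L,
      read_end = as.integer(.num(m[, 4L], "query end")),
      ref_name = m[, 6L],
      ref_start = as.integer(.num(m[, 8L], "target start")) + 1L,
      ref_end = as.integer(.num(m[, 9L], "target end")),
      strand = strand,
      identity = ifelse(alnlen > 0, nmatch / alnlen, NA_real_),
      evalue = NA_real_,
      stringsAsFactors = FALSE)
  } else {
    # qaccver saccver pident length mismatch gapopen qstart qend sstart send
    # evalue bitscore
    ss <- as.integer(.num(m[, 9L], "subject start"))
    se <- as.integer(.num(m[, 10L], "subject end"))
    minus <- ss > se
    data.frame(
      read_id = m[, 1L],
      read_length = NA_integer_,
      read_start = as.integer(.num(m[, 7L], "query start")),
      read_end = as.integer(.num(m[, 8L], "query end")),
      ref_name = m[, 2L],
      ref_start = ifelse(minus, se, ss),
      ref_end = ifelse(minus, ss, se),
      strand = ifelse(minus, "-", "+"),
      identity = .num(m[, 3L], "percent identity") / 100,
      evalue = .num(m[, 11L], "e-value"),
      stringsAsFactors = FALSE)
  }
}

#' Parse paired-end alignments from a SAM file
#'
#' Joins mates by query name and decides concordance. When the file uses the
#' proper-pair flag (bit 0x2 set on at least one record), that flag is
#' trusted; otherwise concordance is recomputed from an explicit contract:
#' both mates mapped to the same reference on opposite strands in
#' forward-reverse orientation with an outer insert within
#' `[min_insert, max_insert]`.
#'
#' @param path Path to a SAM file with paired-end flags.
#' @param min_insert,max_insert Insert-size bounds (nt) used when concordance
#'   must be recomputed. Defaults 100 and 1000, bracketing typical ~350 bp
#'   shotgun libraries.
#' @return A `data.frame`, one row per pair: `pair_id`, per-mate `ref`,
#'   `start`, `end`, `strand`, `mapped` columns (suffixes `1`/`2`),
#'   `concordant` and `insert_size` (`NA` when not computable). Orphan mates
#'   are emitted with the other mate unmapped; a single warning reports the
#'   orphan count.
#' @export
parsePairedAlignments <- function(path, min_insert = 100L, max_insert = 1000L) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "strand")))[[1L]]
  flag <- res$flag
  primary <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  paired <- bitwAnd(flag, 0x1L) != 0L
  keep <- primary & paired
  qname <- res$qname[keep]
  flag <- flag[keep]
  mapped <- bitwAnd(flag, 0x4L) == 0L
  first <- bitwAnd(flag, 0x40L) != 0L
  rname <- as.character(res$rname)[keep]
  pos <- res$pos[keep]
  refw <- .cigarRefWidth(res$cigar[keep])
  endp <- pos + refw - 1L
  strand <- ifelse(bitwAnd(flag, 0x10L) != 0L, "-", "+")

  ids <- unique(qname)
  idx1 <- match(ids, ifelse(first, qname, NA))
  idx2 <- match(ids, ifelse(!first, qname, NA))
  orphans <- sum(is.na(idx1) | is.na(idx2))
  if (orphans)
    warning(orphans, " orphan mate(s): pair emitted with unmapped marker")

  .take <- function(v, i, fill) ifelse(is.na(i), fill, v[ifelse(is.na(i), 1L, i)])
  m1_mapped <- .take(mapped, idx1, FALSE)
  m2_mapped <- .take(mapped, idx2, FALSE)
  df <- data.frame(
    pair_id = ids,
    ref1 = .take(rname, idx1, NA_character_),
    start1 = .take(pos, idx1, NA_integer_),
    end1 = .take(endp, idx1, NA_integer_),
    strand1 = .take(strand, idx1, NA_character_),
    mapped1 = m1_mapped,
    ref2 = .take(rname, idx2, NA_character_),
    start2 = .take(pos, idx2, NA_integer_),
    end2 = .take(endp, idx2, NA_integer_),
    strand2 = .take(strand, idx2, NA_character_),
    mapped2 = m2_mapped,
    stringsAsFactors = FALSE)
  df$ref1[!df$mapped1] <- NA; df$ref2[!df$mapped2] <- NA

  both <- df$mapped1 & df$mapped2 & !is.na(df$ref1) & !is.na(df$ref2) &
    df$ref1 == df$ref2
  outer_lo <- pmin(df$start1, df$start2)
  outer_hi <- pmax(df$end1, df$end2)
  df$insert_size <- ifelse(both, outer_hi - outer_lo + 1L, NA_integer_)

  if (any(bitwAnd(flag, 0x2L) != 0L)) {
    proper <- bitwAnd(flag, 0x2L) != 0L
    df$concordant <- .take(proper, idx1, FALSE) & .take(proper, idx2, FALSE)
  } else {
    df$concordant <- .concordantContract(df, min_insert, max_insert)
  }
  df
}

# FR concordance contract: same ref, opposite strands, leftmost mate forward,
# insert within bounds
.concordantContract <- function(df, min_insert, max_insert) {
  both <- df$mapped1 & df$mapped2 & !is.na(df$ref1) & !is.na(df$ref2) &
    df$ref1 == df$ref2
  opp <- both & df$strand1 != df$strand2
  left_fwd <- ifelse(df$start1 <= df$start2, df$strand1, df$strand2) == "+"
  ins_ok <- !is.na(df$insert_size) & df$insert_size >= min_insert &
    df$insert_size <= max_insert
  as.logical(opp & left_fwd & ins_ok)
}

# reference-consumed width of CIGAR strings (M, D, N, =, X)
.cigarRefWidth <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1L]])
    ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1L]]
    sum(lens[ops %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}
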