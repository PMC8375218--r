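#' Generate a genome with planted invertible loci
#'
#' Builds a random background sequence and plants `n_loci` non-overlapping
#' invertible loci, each consisting of the repeat arm, a random spacer whose
#' length is drawn uniformly from `spacer_range`, and the reverse complement
#' of the arm. The planted (reference) state of every locus is declared ON.
#'
#' @param genome_length Genome length in nt.
#' @param n_loci Number of loci to plant.
#' @param repeat_seq Arm sequence; default `"GTTCGTTTAA"`, the perfectly
#'   conserved 10 nt repeat flanking phase-variable capsular polysaccharide
#'   promoters in *Bacteroides*.
#' @param spacer_range Closed integer range of spacer lengths, default
#'   `c(183, 186)` nt (the promoter cassette between the arms).
#' @param gc GC content of the random background, default 0.42
#'   (Bacteroides-like).
#' @param seed Optional RNG seed; identical seeds give identical output.
#' @param min_separation Minimum distance (nt) between locus spans and from
#'   the genome ends, default 2500 so that default read inserts and dual
#'   reference flanks never bridge two loci.
#' @param ref_name Name for the generated sequence.
#' @return A list with `genome` (named `DNAStringSet` of length 1) and
#'   `loci` (an [InvertibleLoci-class] truth object).
#' @export
makeGenome <- function(genome_length, n_loci, repeat_seq = "GTTCGTTTAA",
                       spacer_range = c(183L, 186L), gc = 0.42, seed = NULL,
                       min_separation = 2500L, ref_name = "synthetic_genome") {
  stopifnot(nchar(repeat_seq) >= 6L, genome_length > 0L, n_loci >= 0L,
            spacer_range[1L] <= spacer_range[2L])
  .withSeed(seed, {
    bg <- .randomDNA(genome_length, gc)
    arm <- nchar(repeat_seq)
    if (n_loci == 0L) {
      loci <- InvertibleLoci(ref_name, integer(0), integer(0), integer(0),
                             repeat_seq = character(0))
    } else {
      max_span <- 2L * arm + spacer_range[2L]
      starts <- .placeLoci(genome_length, n_loci, max_span, min_separation)
      spacer_len <- sample(seq(spacer_range[1L], spacer_range[2L]),
                           n_loci, replace = TRUE)
      spacers <- vapply(spacer_len, function(n) .randomDNA(n, gc), character(1))
      cassette <- paste0(repeat_seq, spacers, .revcomp(repeat_seq))
      for (i in seq_len(n_loci)) {
        bg <- paste0(substr(bg, 1L, starts[i] - 1L), cassette[i],
                     substr(bg, starts[i] + nchar(cassette[i]),
                            genome_length))
      }
      loci <- InvertibleLoci(ref_name, starts, arm, spacer_len,
                             repeat_seq = repeat_seq)
    }
    genome <- Biostrings::DNAStringSet(bg)
    names(genome) <- ref_name
    list(genome = genome, loci = loci)
  })
}

# sample non-overlapping locus start positions uniformly among valid
# configurations (spacing construction: sorted uniforms plus fixed gaps)
.placeLoci <- function(genome_length, n_loci, span, min_separation) {
  lo <- min_separation + 1L
  hi <- genome_length - span - min_separation + 1L
  step <- span + min_separation
  slack <- (hi - lo) - (n_loci - 1L) * step
  if (hi < lo || slack < 0L)
    stop("placement error: loci plus margins exceed genome length")
  u <- sort(as.integer(floor(runif(n_loci) * (slack + 1L))))
  lo + u + (seq_len(n_loci) - 1L) * step
}

#' Assign per-cell locus orientations
#'
#' Draws an independent Bernoulli orientation for every cell at every locus,
#' producing the mixed-orientation population whose reads downstream modules
#' quantify. OFF is realised, at read-simulation time, by
#' reverse-complementing the genome segment spanning the locus (arms
#' included); because the arms are perfect inverted repeats only the spacer
#' actually changes.
#'
#' @param loci An [InvertibleLoci-class] object.
#' @param on_fractions Numeric vector, one ON probability per locus,
#'   each in `[0, 1]`.
#' @param n_cells Number of cells in the simulated population.
#' @param seed Optional RNG seed.
#' @return A list of class `PopulationState`: `assignment` (logical
#'   `n_cells` x `n_loci` matrix, `TRUE` = ON), `on_fractions`, `n_cells`.
#' @export
assignOrientations <- function(loci, on_fractions, n_cells, seed = NULL) {
  n_loci <- length(loci)
  if (length(on_fractions) != n_loci)
    stop("need exactly one on_fraction per locus")
  if (any(on_fractions < 0 | on_fractions > 1))
    stop("on_fractions must lie in [0, 1]")
  stopifnot(n_cells >= 1L)
  .withSeed(seed, {
    assignment <- vapply(seq_len(n_loci), function(j)
      runif(n_cells) < on_fractions[j], logical(n_cells))
    assignment <- matrix(assignment, nrow = n_cells, ncol = n_loci,
                         dimnames = list(NULL, locusLabels(loci)))
    structure(list(assignment = assignment, on_fractions = on_fractions,
                   n_cells = n_cells),
              class = "PopulationState")
  })
}

# build the haplotype string for one ON/OFF state pattern: reverse-complement
# the [left arm start, right arm end] segment of every OFF locus
.haplotypeForPattern <- function(genome_str, loci, state) {
  gr <- lociRanges(loci)
  out <- genome_str
  for (j in which(!state))
    out <- .invertSegment(out, GenomicRanges::start(gr)[j],
                          GenomicRanges::end(gr)[j])
  out
}

# cache of haplotype strings keyed by the ON/OFF pattern of each cell
.haplotypeCache <- function(genome_str, loci, assignment) {
  keys <- apply(assignment, 1L, function(s) paste(as.integer(s), collapse = ""))
  uk <- unique(keys)
  haps <- vapply(uk, function(k) {
    state <- as.logical(as.integer(strsplit(k, "")[[1L]]))
    .haplotypeForPattern(genome_str, loci, state)
  }, character(1))
  list(keys = keys, haps = haps)
}

# inject i.i.d. substitution errors into a character vector of sequences
.addSubstitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, rate)
  idx <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(lens[i], nerr[i])
    s <- strsplit(seqs[i], "")[[1L]]
    s[pos] <- vapply(s[pos], function(b)
      sample(setdiff(bases, b), 1L), character(1), USE.NAMES = FALSE)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate paired-end reads from a mixed-orientation population
#'
#' Fragments are drawn uniformly from the haplotypes of randomly chosen
#' cells; the insert length is Normal(`insert_mean`, `insert_sd`) truncated
#' at `read_length` below and the genome length above. Substitution errors
#' are i.i.d. at `error_rate`. Truth labels record, per pair, the source
#' cell, the fragment interval, the overlapped locus (if any), its
#' orientation in that cell, and the largest overlap of either mate with the
#' locus spacer (the informative signal for orientation classification).
#'
#' @param genome A `DNAStringSet`/`DNAString`/character genome.
#' @param loci An [InvertibleLoci-class] object (may be empty).
#' @param population A `PopulationState` from [assignOrientations()].
#' @param n_pairs Number of read pairs.
#' @param read_length Read length in nt, default 150.
#' @param insert_mean,insert_sd Insert distribution in nt, defaults 350 and
#'   35 (typical sheared shotgun library).
#' @param error_rate Per-base substitution probability, default 0.001.
#' @param region Optional `c(start, end)` restricting fragment placement,
#'   e.g. to enrich for locus-overlapping pairs.
#' @param seed Optional RNG seed.
#' @return A list: `mate1`, `mate2` (`DNAStringSet`s, mate2 stored
#'   reverse-complemented as sequenced) and `truth` (`data.frame` with
#'   `pair_id`, `cell`, `start`, `end`, `insert`, `locus`, `state`,
#'   `spacer_overlap`).
#' @export
simulatePairedReads <- function(genome, loci, population, n_pairs,
                                read_length = 150L, insert_mean = 350,
                                insert_sd = 35, error_rate = 0.001,
                                region = NULL, seed = NULL) {
  genome_str <- .asGenomeString(genome)
  L <- nchar(genome_str)
  stopifnot(n_pairs >= 0L, read_length >= 1L)
  if (n_pairs == 0L) {
    return(list(mate1 = Biostrings::DNAStringSet(), mate2 = Biostrings::DNAStringSet(),
                truth = data.frame(pair_id = character(0), cell = integer(0),
                                   start = integer(0), end = integer(0),
                                   insert = integer(0), locus = character(0),
                                   state = character(0),
                                   spacer_overlap = integer(0))))
  }
  .withSeed(seed, {
    cache <- .haplotypeCache(genome_str, loci, population$assignment)
    cells <- sample.int(population$n_cells, n_pairs, replace = TRUE)
    ins <- as.integer(round(rnorm(n_pairs, insert_mean, insert_sd)))
    ins <- pmin(pmax(ins, read_length), L)
    lo <- 1L; hi <- L
    if (!is.null(region)) { lo <- as.integer(region[1L]); hi <- as.integer(region[2L]) }
    ins <- pmin(ins, hi - lo + 1L)
    starts <- lo + as.integer(floor(runif(n_pairs) * (hi - ins - lo + 2L)))
    ends <- starts + ins - 1L

    frag <- character(n_pairs)
    key <- cache$keys[cells]
    for (k in unique(key)) {
      sel <- key == k
      frag[sel] <- substring(cache$haps[[k]], starts[sel], ends[sel])
    }
    m1 <- substr(frag, 1L, read_length)
    m2 <- .revcomp(substring(frag, ins - read_length + 1L, ins))
    m1 <- .addSubstitutions(m1, error_rate)
    m2 <- .addSubstitutions(m2, error_rate)

    truth <- data.frame(pair_id = sprintf("pair_%d", seq_len(n_pairs)),
                        cell = cells, start = starts, end = ends,
                        insert = ins, locus = NA_character_,
                        state = NA_character_, spacer_overlap = 0L,
                        stringsAsFactors = FALSE)
    if (length(loci)) {
      sp <- spacerRegion(loci)
      sps <- GenomicRanges::start(sp); spe <- GenomicRanges::end(sp)
      labs <- locusLabels(loci)
      m1s <- starts; m1e <- starts + read_length - 1L
      m2s <- ends - read_length + 1L; m2e <- ends
      for (j in seq_along(labs)) {
        ov1 <- pmax(0L, pmin(m1e, spe[j]) - pmax(m1s, sps[j]) + 1L)
        ov2 <- pmax(0L, pmin(m2e, spe[j]) - pmax(m2s, sps[j]) + 1L)
        ov <- pmax(ov1, ov2)
        hit <- ov > truth$spacer_overlap
        truth$locus[hit] <- labs[j]
        truth$state[hit] <- ifelse(population$assignment[cells[hit], j],
                                   "ON", "OFF")
        truth$spacer_overlap[hit] <- ov[hit]
      }
    }
    mate1 <- Biostrings::DNAStringSet(m1); names(mate1) <- truth$pair_id
    mate2 <- Biostrings::DNAStringSet(m2); names(mate2) <- truth$pair_id
    list(mate1 = mate1, mate2 = mate2, truth = truth)
  })
}

#' Log-normal length parameters from a median and IQR
#'
#' Solves for the `meanlog`/`sdlog` of a log-normal whose median and
#' inter-quartile range match the given values:
#' `meanlog = log(median)` and `sdlog = asinh(iqr / (2 median)) / qnorm(0.75)`.
#'
#' @param median_len,iqr_len Target median and IQR in nt. Defaults 1882 and
#'   4697, the heavy-tailed length profile of a typical nanopore rapid
#'   library.
#' @return Named numeric vector `c(meanlog, sdlog)`.
#' @export
fitLongReadLengths <- function(median_len = 1882, iqr_len = 4697) {
  c(meanlog = log(median_len),
    sdlog = asinh(iqr_len / (2 * median_len)) / stats::qnorm(0.75))
}

#' Simulate long reads from a mixed-orientation population
#'
#' Read lengths are log-normal (see [fitLongReadLengths()]), truncated to
#' `[min_length, genome length]`. Reads are drawn from per-cell haplotypes,
#' so a read spanning a locus whose state differs from the reference
#' orientation contains an internally inverted segment relative to the
#' reference. Half of the reads are emitted reverse-complemented.
#'
#' @inheritParams simulatePairedReads
#' @param n_reads Number of reads.
#' @param length_meanlog,length_sdlog Log-normal length parameters; defaults
#'   from `fitLongReadLengths()`.
#' @param error_rate Per-base substitution probability, default 0.05.
#' @param min_length Minimum read length, default 50 nt (shorter reads are
#'   uninformative and real basecalled libraries contain few of them;
#'   keeping the floor low preserves the configured length distribution).
#' @return A list: `reads` (`DNAStringSet`) and `truth` (`data.frame` with
#'   `read_id`, `cell`, `start`, `end`, `length`, `strand`, and
#'   `flipped_loci`, a comma-separated list of overlapped loci whose state
#'   in the source cell is OFF, i.e. inverted relative to the reference).
#' @export
simulateLongReads <- function(genome, loci, population, n_reads,
                              length_meanlog = fitLongReadLengths()[["meanlog"]],
                              length_sdlog = fitLongReadLengths()[["sdlog"]],
                              error_rate = 0.05, min_length = 50L,
                              seed = NULL) {
  genome_str <- .asGenomeString(genome)
  L <- nchar(genome_str)
  stopifnot(n_reads >= 0L)
  empty_truth <- data.frame(read_id = character(0), cell = integer(0),
                            start = integer(0), end = integer(0),
                            length = integer(0), strand = character(0),
                            flipped_loci = character(0))
  if (n_reads == 0L)
    return(list(reads = Biostrings::DNAStringSet(), truth = empty_truth))
  .withSeed(seed, {
    cache <- .haplotypeCache(genome_str, loci, population$assignment)
    cells <- sample.int(population$n_cells, n_reads, replace = TRUE)
    # rejection-sample the truncated log-normal (no boundary atoms)
    lens <- as.integer(round(rlnorm(n_reads, length_meanlog, length_sdlog)))
    for (it in seq_len(50L)) {
      bad <- lens < min_length | lens > L
      if (!any(bad)) break
      lens[bad] <- as.integer(round(rlnorm(sum(bad), length_meanlog,
                                           length_sdlog)))
    }
    lens <- pmin(pmax(lens, min_length), L)
    starts <- as.integer(floor(runif(n_reads) * (L - lens + 1L))) + 1L
    ends <- starts + lens - 1L
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)

    seqs <- character(n_reads)
    key <- cache$keys[cells]
    for (k in unique(key)) {
      sel <- key == k
      seqs[sel] <- substring(cache$haps[[k]], starts[sel], ends[sel])
    }
    seqs[strands == "-"] <- .revcomp(seqs[strands == "-"])
    seqs <- .addSubstitutions(seqs, error_rate)

    flipped <- character(n_reads)
    if (length(loci)) {
      gr <- lociRanges(loci)
      labs <- locusLabels(loci)
      for (j in seq_along(labs)) {
        ov <- pmin(ends, GenomicRanges::end(gr)[j]) -
          pmax(starts, GenomicRanges::start(gr)[j]) + 1L
        off <- ov > 0L & !population$assignment[cells, j]
        flipped[off] <- ifelse(flipped[off] == "", labs[j],
                               paste(flipped[off], labs[j], sep = ","))
      }
    }
    ids <- sprintf("long_%d", seq_len(n_reads))
    reads <- Biostrings::DNAStringSet(seqs); names(reads) <- ids
    list(reads = reads,
         truth = data.frame(read_id = ids, cell = cells, start = starts,
                            end = ends, length = lens, strand = strands,
                            flipped_loci = flipped, stringsAsFactors = FALSE))
  })
}

#' Simulate a host/phage metagenome mixture at a target VMR
#'
#' Per-read sources are drawn so that the expected per-base coverage ratio
#' phage:host equals `vmr`: with genome lengths `Lp` and `Lh`, the phage
#' read probability is `vmr * Lp / (vmr * Lp + Lh)`.
#'
#' @param host_genome,phage_genome Genomes (`DNAStringSet`/`DNAString`/
#'   character).
#' @param vmr Target virus-to-microbe ratio, `>= 0`.
#' @param n_reads Number of (single-end) reads.
#' @param read_length Read length in nt, default 150.
#' @param error_rate Per-base substitution probability, default 0.001.
#' @param seed Optional RNG seed.
#' @return A list: `reads` (`DNAStringSet`) and `truth` (`data.frame` with
#'   `read_id`, `source` in `{"host", "phage"}`, `start`, `strand`).
#' @export
simulateMetagenome <- function(host_genome, phage_genome, vmr, n_reads,
                               read_length = 150L, error_rate = 0.001,
                               seed = NULL) {
  if (vmr < 0) stop("vmr must be >= 0")
  host <- .asGenomeString(host_genome)
  phage <- .asGenomeString(phage_genome)
  Lh <- nchar(host); Lp <- nchar(phage)
  stopifnot(Lh >= read_length, Lp >= read_length, n_reads >= 0L)
  p_phage <- vmr * Lp / (vmr * Lp + Lh)
  .withSeed(seed, {
    src <- ifelse(runif(n_reads) < p_phage, "phage", "host")
    glen <- ifelse(src == "phage", Lp, Lh)
    starts <- as.integer(floor(runif(n_reads) * (glen - read_length + 1L))) + 1L
    gs <- ifelse(src == "phage", phage, host)
    seqs <- substring(gs, starts, starts + read_length - 1L)
    strands <- sample(c("+", "-"), max(n_reads, 0L), replace = TRUE)
    seqs[strands == "-"] <- .revcomp(seqs[strands == "-"])
    seqs <- .addSubstitutions(seqs, error_rate)
    ids <- sprintf("mg_%d", seq_len(n_reads))
    reads <- Biostrings::DNAStringSet(seqs); names(reads) <- ids
    list(reads = reads,
         truth = data.frame(read_id = ids, source = src, start = starts,
                            strand = strands, stringsAsFactors = FALSE))
  })
}
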