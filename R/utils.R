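# shared internal helpers

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#' @importFrom methods is new validObject
#' @importFrom stats rbinom rnorm runif rlnorm qpois quantile
NULL

# reverse complement of plain character vectors
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# run expr with a locally seeded RNG, restoring global state afterwards
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# draw a random DNA string of length n with given GC content
.randomDNA <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Wilson score interval for a binomial proportion
.wilson <- function(x, n, conf = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

# reverse-complement the substring [s, e] (1-based inclusive) in place
.invertSegment <- function(x, s, e) {
  paste0(substr(x, 1L, s - 1L), .revcomp(substr(x, s, e)),
         substr(x, e + 1L, nchar(x)))
}

# number of mismatching characters between equal-length strings (vectorised)
.countMismatches <- function(a, b) {
  stopifnot(length(a) == length(b))
  vapply(seq_along(a), function(i) {
    ra <- charToRaw(a[[i]]); rb <- charToRaw(b[[i]])
    stopifnot(length(ra) == length(rb))
    sum(ra != rb)
  }, integer(1))
}
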