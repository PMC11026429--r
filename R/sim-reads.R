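#' Simulate error-free shotgun reads from a random genome
#'
#' Draws a uniform-random A/C/G/T genome of `genome_length` bases and
#' samples `round(coverage * genome_length / read_length)` error-free reads
#' of fixed length with uniformly random start positions on the forward
#' strand, giving an expected per-base depth equal to `coverage`.
#'
#' @param genome_length Genome length in bases.
#' @param coverage Target fold coverage (> 0).
#' @param read_length Read length in bases (<= `genome_length`).
#' @param seed Integer seed.
#' @param genome Optional genome string to sample from instead of a random
#'   one (its length overrides `genome_length`).
#' @return Object of class `read_sim`: list with `genome`, `reads`
#'   (character vector), `starts`, `coverage`, `read_length`, `seed`.
#' @examples
#' rs <- simulate_reads(10000, coverage = 10, read_length = 100, seed = 1)
#' length(rs$reads) # ~1000
#' @export
simulate_reads <- function(genome_length, coverage, read_length, seed,
                           genome = NULL) {
  if (coverage <= 0) stop("'coverage' must be > 0")
  if (!is.null(genome)) genome_length <- nchar(genome)
  if (read_length < 1L) stop("'read_length' must be >= 1")
  if (read_length > genome_length)
    stop("'read_length' exceeds 'genome_length'")
  with_seed(seed, {
    if (is.null(genome))
      genome <- paste(sample(c("A", "C", "G", "T"), genome_length,
                             replace = TRUE), collapse = "")
    n_reads <- max(1L, as.integer(round(coverage * genome_length /
                                          read_length)))
    starts <- sample.int(genome_length - read_length + 1L, n_reads,
                         replace = TRUE)
    reads <- substring(genome, starts, starts + read_length - 1L)
    structure(list(genome = genome, reads = reads, starts = starts,
                   coverage = coverage, read_length = read_length,
                   seed = seed),
              class = "read_sim")
  })
}
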