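# k-mer genome-size estimation: canonical k-mer counting, automated peak
# picking on the multiplicity histogram, and size = total k-mers / peak.
#
# k-mers are packed into doubles (2 bits per base, exact up to k = 26) so
# counting tens of millions of k-mers stays vectorized; grouping is done by
# data.table.

.base_code_lut <- local({
  lut <- rep(NA_real_, 256L)
  lut[utf8ToInt("A")] <- 0; lut[utf8ToInt("a")] <- 0
  lut[utf8ToInt("C")] <- 1; lut[utf8ToInt("c")] <- 1
  lut[utf8ToInt("G")] <- 2; lut[utf8ToInt("g")] <- 2
  lut[utf8ToInt("T")] <- 3; lut[utf8ToInt("t")] <- 3
  lut
})

#' Count canonical k-mers in a set of reads
#'
#' Extracts every k-length window of every read, takes the canonical form
#' (the lexicographic minimum of the forward k-mer and its reverse
#' complement) and tabulates the multiplicity histogram: how many distinct
#' canonical k-mers occur 1x, 2x, ... across the read set. Windows
#' containing non-ACGT characters are dropped.
#'
#' @param reads Character vector of reads, or a `read_sim` object.
#' @param k Word size (1 <= k <= 26; 21 is the conventional choice).
#' @return Object of class `kmer_histogram`: list with `k`, `multiplicity`
#'   (sorted integer vector), `count` (distinct k-mers at each
#'   multiplicity), `n_distinct` and `total_kmers` (= sum of multiplicity *
#'   count = number of k-mer instances).
#' @examples
#' count_kmers("ACGT", k = 4) # one window, histogram {1: 1}
#' @export
count_kmers <- function(reads, k) {
  if (inherits(reads, "read_sim")) reads <- reads$reads
  k <- as.integer(k)
  if (k < 1L || k > 26L) stop("'k' must be in 1..26")
  if (length(reads) == 0L) stop("'reads' is empty")
  lens <- nchar(reads)
  nw <- pmax(lens - k + 1L, 0L)
  if (sum(nw) == 0L) stop("all reads are shorter than k = ", k)

  x <- .base_code_lut[utf8ToInt(paste(reads, collapse = ""))]
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  keep_reads <- nw > 0L
  starts <- sequence(nw[keep_reads], from = offsets[keep_reads] + 1L)

  # rolling 2-bit packing of every k-window as one C-level convolution per
  # strand; exact in doubles up to k = 26 (4^26 < 2^53)
  fwd_all <- stats::filter(x, 4^(0:(k - 1L)), method = "convolution",
                           sides = 1L)
  rc_all <- stats::filter(3 - x, 4^((k - 1L):0), method = "convolution",
                          sides = 1L)
  ends <- starts + k - 1L
  canon <- pmin(as.numeric(fwd_all[ends]), as.numeric(rc_all[ends]))
  canon <- canon[!is.na(canon)]
  if (length(canon) == 0L) stop("no k-mer window free of ambiguous bases")

  km <- NULL; mult <- NULL # appease R CMD check; data.table NSE below
  per_kmer <- data.table::data.table(km = canon)[, .N, by = km]
  histo <- per_kmer[, list(count = .N), by = list(mult = N)]
  data.table::setorder(histo, mult)

  structure(list(k = k,
                 multiplicity = histo$mult,
                 count = as.numeric(histo$count),
                 n_distinct = nrow(per_kmer),
                 total_kmers = sum(histo$mult * histo$count)),
            class = "kmer_histogram")
}

#' Build a k-mer histogram object from multiplicity/count pairs
#'
#' @param multiplicity Integer vector of depths (>= 1).
#' @param count Number of distinct k-mers at each depth.
#' @param k Word size the histogram was computed with (optional metadata).
#' @return A `kmer_histogram`.
#' @export
kmer_histogram <- function(multiplicity, count, k = NA_integer_) {
  if (length(multiplicity) != length(count))
    stop("'multiplicity' and 'count' must have equal length")
  if (any(multiplicity < 1L)) stop("multiplicities must be >= 1")
  if (any(count < 0)) stop("counts must be >= 0")
  o <- order(multiplicity)
  structure(list(k = k, multiplicity = as.integer(multiplicity[o]),
                 count = as.numeric(count[o]),
                 n_distinct = sum(count),
                 total_kmers = sum(multiplicity[o] * count[o])),
            class = "kmer_histogram")
}

#' Read a two-column multiplicity/count histogram TSV
#'
#' Accepts the two-column `multiplicity<TAB>count` export format of common
#' k-mer counters (with or without a header row).
#'
#' @param path Path to the TSV.
#' @param k Optional word size metadata.
#' @return A `kmer_histogram`.
#' @export
read_kmer_histogram <- function(path, k = NA_integer_) {
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^[0-9]", first)
  df <- utils::read.delim(path, header = has_header,
                          col.names = c("multiplicity", "count"))
  kmer_histogram(df$multiplicity, df$count, k = k)
}

#' Locate the homozygous-coverage peak of a k-mer histogram
#'
#' Smooths the dense histogram with a centered 3-bin moving average and
#' returns the multiplicity with the largest smoothed count among
#' multiplicities strictly above `error_cutoff` (the low-depth region
#' dominated by sequencing errors). Ties in the smoothed counts are broken
#' by the larger raw count (so an isolated spike is its own peak), then by
#' the lower multiplicity.
#'
#' @param hist A `kmer_histogram`.
#' @param error_cutoff Multiplicities <= this value are never the peak
#'   (default 3).
#' @return The peak depth (integer).
#' @export
find_peak <- function(hist, error_cutoff = 3L) {
  stopifnot(inherits(hist, "kmer_histogram"))
  m_max <- max(hist$multiplicity)
  dense <- numeric(m_max)
  dense[hist$multiplicity] <- hist$count
  above <- hist$multiplicity > error_cutoff
  if (!any(above) || sum(hist$count[above]) == 0)
    stop("no histogram mass above error_cutoff = ", error_cutoff)
  padded <- c(0, dense, 0)
  smooth <- (padded[seq_len(m_max)] + dense + padded[seq_len(m_max) + 2L]) / 3
  cand <- which(seq_len(m_max) > error_cutoff)
  best <- cand[smooth[cand] == max(smooth[cand])]
  if (length(best) > 1L)
    best <- best[dense[best] == max(dense[best])]
  as.integer(best[1L])
}

#' Estimate genome size from a k-mer histogram
#'
#' Genome size in bases is the total number of k-mer instances divided by
#' the homozygous peak depth. By default the numerator excludes instances at
#' multiplicities at or below `error_cutoff`, since that mass comes mostly
#' from sequencing errors; both totals are reported.
#'
#' @param hist A `kmer_histogram`.
#' @param peak Peak depth; found with [find_peak()] when omitted.
#' @param error_cutoff Error-region bound (also passed to [find_peak()]).
#' @param exclude_error Exclude error-region mass from the numerator
#'   (default TRUE).
#' @return Object of class `genome_size_estimate`: list with `size_bases`,
#'   `peak_depth`, `total_kmers`, `total_kmers_used`, `error_cutoff`, `k`.
#' @examples
#' h <- kmer_histogram(c(1, 10), c(100, 800), k = 21)
#' estimate_size(h)$size_bases # 800 * 10 / 10 = 800
#' @export
estimate_size <- function(hist, peak = NULL, error_cutoff = 3L,
                          exclude_error = TRUE) {
  stopifnot(inherits(hist, "kmer_histogram"))
  if (is.null(peak)) peak <- find_peak(hist, error_cutoff)
  if (peak <= 0) stop("'peak' must be > 0")
  total <- hist$total_kmers
  keep <- if (exclude_error) hist$multiplicity > error_cutoff
          else rep(TRUE, length(hist$multiplicity))
  used <- sum(hist$multiplicity[keep] * hist$count[keep])
  structure(list(size_bases = used / peak,
                 peak_depth = peak,
                 total_kmers = total,
                 total_kmers_used = used,
                 error_cutoff = if (exclude_error) error_cutoff else 0L,
                 k = hist$k),
            class = "genome_size_estimate")
}
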