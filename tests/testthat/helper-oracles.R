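# Independent brute-force oracles for the NG86 counting rules. These
# deliberately share no code with the package implementation: translation
# goes straight through the genetic-code table, sites are enumerated change
# by change, and pathways are enumerated by recursion.

oracle_translate <- function(codon) {
  unname(Biostrings::GENETIC_CODE[[codon]])
}

oracle_sense_codons <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
})

# fractional synonymous/nonsynonymous site counts of one codon
oracle_sites <- function(codon) {
  nts <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    syn <- 0
    nonstop <- 0
    for (nt in setdiff(nts, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- nt
      if (oracle_translate(alt) == "*") next
      nonstop <- nonstop + 1
      if (oracle_translate(alt) == oracle_translate(codon)) syn <- syn + 1
    }
    if (nonstop > 0) s <- s + syn / nonstop
  }
  c(s = s, n = 3 - s)
}

# all stop-free substitution pathways codon1 -> codon2, each as c(sd, nd)
oracle_paths <- function(codon1, codon2) {
  if (codon1 == codon2) return(list(c(0, 0)))
  out <- list()
  c1 <- strsplit(codon1, "")[[1]]
  c2 <- strsplit(codon2, "")[[1]]
  for (pos in which(c1 != c2)) {
    mid <- codon1
    substr(mid, pos, pos) <- c2[pos]
    if (oracle_translate(mid) == "*") next
    step <- if (oracle_translate(mid) == oracle_translate(codon1))
      c(1, 0) else c(0, 1)
    for (rest in oracle_paths(mid, codon2))
      out[[length(out) + 1L]] <- step + rest
  }
  out
}

oracle_diffs <- function(codon1, codon2) {
  paths <- oracle_paths(codon1, codon2)
  if (length(paths) == 0L) return(c(sd = NA_real_, nd = NA_real_))
  avg <- Reduce(`+`, paths) / length(paths)
  c(sd = avg[1], nd = avg[2])
}

# full NG86 (S, N, Sd, Nd) for a pair of sense-codon vectors, skipping
# columns with no stop-free pathway (mirrors the estimator's contract)
oracle_pair_stats <- function(codons1, codons2) {
  S1 <- S2 <- Sd <- Nd <- 0
  used <- 0L
  for (i in seq_along(codons1)) {
    d <- oracle_diffs(codons1[i], codons2[i])
    if (anyNA(d)) next
    used <- used + 1L
    S1 <- S1 + oracle_sites(codons1[i])[["s"]]
    S2 <- S2 + oracle_sites(codons2[i])[["s"]]
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  S <- (S1 + S2) / 2
  c(S = S, N = 3 * used - S, Sd = Sd, Nd = Nd, codons_used = used)
}

random_sense_codons <- function(n) {
  sample(oracle_sense_codons, n, replace = TRUE)
}

# exhaustive minimum within-cluster SSE over all 2-cluster bipartitions
oracle_best_bipartition_sse <- function(x) {
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  best <- Inf
  for (mask in seq_len(2^n - 2L)) {
    grp <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
    best <- min(best, sse(x[grp]) + sse(x[!grp]))
  }
  best
}
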