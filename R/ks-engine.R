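#' Synonymous and nonsynonymous site counts of a codon
#'
#' Counts synonymous (s) and nonsynonymous (n) sites of a single sense codon
#' under the Nei-Gojobori (1986) convention: at each of the three positions
#' the synonymous fraction is the number of single-nucleotide changes that
#' preserve the amino acid divided by the number of changes that do not
#' create a stop codon (stop targets are excluded from the denominator).
#' s is the sum of the three fractions and n = 3 - s.
#'
#' @param codon A single 3-letter codon string (A/C/G/T; case-insensitive,
#'   U accepted for T). Stop codons and ambiguous codons are rejected.
#' @return Named numeric vector `c(s = , n = )` with `s + n == 3`.
#' @examples
#' count_sites("GCT") # Ala: s = 1, n = 2
#' count_sites("TGG") # Trp: s = 0, n = 3
#' @export
count_sites <- function(codon) {
  tab <- .codon_tables()
  codon <- .normalize_seq(codon)
  if (length(codon) != 1L || nchar(codon) != 3L)
    stop("'codon' must be a single 3-letter string")
  if (codon %in% tab$stop_codons)
    stop("stop codon '", codon, "' has no defined site counts")
  i <- unname(tab$codon_index[codon])
  if (is.na(i))
    stop("ambiguous or invalid codon '", codon, "'")
  c(s = tab$site_s[i], n = tab$site_n[i])
}

#' Pathway-averaged substitution differences between two codons
#'
#' Classifies the nucleotide differences between two sense codons into
#' synonymous (sd) and nonsynonymous (nd) substitutions, averaging over all
#' orderings of the single-nucleotide steps (Nei-Gojobori equal pathway
#' weighting). Orderings that pass through a stop codon are excluded from
#' the average; if every ordering is blocked both counts are `NA`.
#'
#' @param codon1,codon2 Sense codons as 3-letter strings.
#' @return Named numeric vector `c(sd = , nd = )`; `sd + nd` equals the
#'   number of differing positions when at least one pathway is valid.
#' @examples
#' count_differences("GCT", "GCC") # sd = 1, nd = 0
#' count_differences("TTT", "GTA") # sd = 0.5, nd = 1.5
#' @export
count_differences <- function(codon1, codon2) {
  tab <- .codon_tables()
  codon1 <- .normalize_seq(codon1)
  codon2 <- .normalize_seq(codon2)
  for (cd in c(codon1, codon2)) {
    if (nchar(cd) != 3L) stop("codons must be 3-letter strings")
    if (cd %in% tab$stop_codons) stop("stop codon '", cd, "' not allowed")
  }
  i <- unname(tab$codon_index[codon1])
  j <- unname(tab$codon_index[codon2])
  if (is.na(i) || is.na(j)) stop("ambiguous or invalid codon")
  c(sd = tab$SD[i, j], nd = tab$ND[i, j])
}

#' Jukes-Cantor multiple-hit correction
#'
#' Converts an observed proportion of differing sites into an expected
#' number of substitutions per site: d = -(3/4) ln(1 - 4p/3). The
#' correction is defined for p < 0.75; at or beyond that bound the process
#' is saturated and `Inf` is returned.
#'
#' @param p Proportion(s) of differing sites, >= 0. (Pathway averaging can
#'   push the raw proportion slightly above 1 on very short sequences;
#'   anything at or beyond 0.75 is saturated either way.)
#' @return Substitutions per site; `Inf` where `p >= 0.75` (saturation),
#'   `NA` propagated.
#' @examples
#' jc_correct(0.5) # ~0.8240
#' @export
jc_correct <- function(p) {
  if (any(p < 0, na.rm = TRUE))
    stop("'p' must be a non-negative proportion")
  d <- ifelse(p >= 0.75, Inf, -0.75 * log(1 - 4 * p / 3))
  ifelse(p == 0, 0, d)
}

#' In-frame codon alignment pair
#'
#' Lightweight container for two aligned coding sequences of equal length,
#' a multiple of 3, read in frame 0. Validation only; estimation is done by
#' [estimate_ks()].
#'
#' @param seq1,seq2 Aligned nucleotide strings (A/C/G/T/-/N; other symbols
#'   are treated as ambiguous and their codon columns skipped).
#' @param gene_ids Length-2 character vector of identifiers.
#' @return An object of class `codon_alignment_pair`.
#' @export
codon_alignment_pair <- function(seq1, seq2, gene_ids = c("seq1", "seq2")) {
  seq1 <- .normalize_seq(seq1)
  seq2 <- .normalize_seq(seq2)
  if (nchar(seq1) != nchar(seq2))
    stop("aligned sequences must have equal length")
  if (nchar(seq1) %% 3L != 0L)
    stop("alignment length must be a multiple of 3")
  if (length(gene_ids) != 2L)
    stop("'gene_ids' must have length 2")
  structure(list(seq1 = seq1, seq2 = seq2,
                 gene_ids = as.character(gene_ids)),
            class = "codon_alignment_pair")
}

#' Estimate Ks and Ka for one aligned coding-sequence pair (NG86)
#'
#' Nei-Gojobori (1986) counting with Jukes-Cantor correction. Site counts
#' are averaged across the two sequences (S = (S1 + S2)/2); differences are
#' pathway-averaged per codon column; pS = Sd/S and pN = Nd/N are corrected
#' with [jc_correct()]. Codon columns containing gaps or ambiguous bases in
#' either sequence are skipped pairwise; columns containing a stop codon are
#' skipped with a warning (or rejected when `strict_stops = TRUE`); columns
#' whose substitution pathways all pass through stops are skipped with a
#' warning.
#'
#' @param pair A [codon_alignment_pair()], or the first sequence when
#'   `seq2` is given.
#' @param seq2 Optional second sequence (then `pair` is the first).
#' @param gene_ids Identifiers used in the output row.
#' @param strict_stops Reject the pair if any usable column contains a stop
#'   codon.
#' @return One-row data frame with columns `gene1, gene2, codons_used, S,
#'   N, Sd, Nd, pS, pN, Ka, Ks, flag`; `flag` is one of `ok`, `saturated`
#'   (pS >= 0.75, Ks infinite), `too_short` (no usable codon columns), or
#'   `undefined` (S = 0).
#' @examples
#' estimate_ks("GCTGCT", "GCCGCT") # pS = 0.5, Ks ~ 0.8240
#' @export
estimate_ks <- function(pair, seq2 = NULL, gene_ids = NULL,
                        strict_stops = FALSE) {
  if (inherits(pair, "codon_alignment_pair")) {
    if (is.null(gene_ids)) gene_ids <- pair$gene_ids
    seq1 <- pair$seq1
    seq2 <- pair$seq2
  } else {
    if (is.null(seq2)) stop("supply a codon_alignment_pair or two sequences")
    if (is.null(gene_ids)) gene_ids <- c("seq1", "seq2")
    p <- codon_alignment_pair(pair, seq2, gene_ids)
    seq1 <- p$seq1
    seq2 <- p$seq2
  }
  tab <- .codon_tables()

  cod1 <- .split_codons(seq1)
  cod2 <- .split_codons(seq2)
  idx1 <- unname(tab$codon_index[cod1])
  idx2 <- unname(tab$codon_index[cod2])

  has_stop <- cod1 %in% tab$stop_codons | cod2 %in% tab$stop_codons
  if (any(has_stop)) {
    if (strict_stops)
      stop("pair ", gene_ids[1L], "/", gene_ids[2L], ": ",
           sum(has_stop), " codon column(s) contain stop codons")
    warning(sum(has_stop), " codon column(s) contain stop codons; skipped")
  }
  usable <- !is.na(idx1) & !is.na(idx2)

  if (any(usable)) {
    blocked <- is.na(tab$SD[cbind(idx1[usable], idx2[usable])])
    if (any(blocked)) {
      warning(sum(blocked),
              " codon column(s) have no stop-free substitution pathway; skipped")
      usable[usable][blocked] <- FALSE
    }
  }

  rec <- data.frame(gene1 = gene_ids[1L], gene2 = gene_ids[2L],
                    codons_used = sum(usable), S = NA_real_, N = NA_real_,
                    Sd = NA_real_, Nd = NA_real_, pS = NA_real_,
                    pN = NA_real_, Ka = NA_real_, Ks = NA_real_,
                    flag = "too_short", stringsAsFactors = FALSE)
  if (!any(usable)) return(rec)

  i1 <- idx1[usable]
  i2 <- idx2[usable]
  rec$S <- (sum(tab$site_s[i1]) + sum(tab$site_s[i2])) / 2
  rec$N <- (sum(tab$site_n[i1]) + sum(tab$site_n[i2])) / 2
  rec$Sd <- sum(tab$SD[cbind(i1, i2)])
  rec$Nd <- sum(tab$ND[cbind(i1, i2)])

  if (rec$S == 0) {
    rec$flag <- "undefined"
    if (rec$N > 0) {
      rec$pN <- rec$Nd / rec$N
      rec$Ka <- jc_correct(rec$pN)
    }
    return(rec)
  }
  rec$pS <- rec$Sd / rec$S
  rec$pN <- if (rec$N > 0) rec$Nd / rec$N else NA_real_
  rec$Ks <- jc_correct(rec$pS)
  rec$Ka <- if (is.na(rec$pN)) NA_real_ else jc_correct(rec$pN)
  rec$flag <- if (rec$pS >= 0.75) "saturated" else "ok"
  rec
}

#' Estimate Ks/Ka for a batch of aligned pairs
#'
#' Applies [estimate_ks()] to each element of a list of pairs. Per-pair
#' failures never abort the batch: a pair that cannot be scored at all is
#' returned with flag `undefined` and `NA` statistics.
#'
#' @param pairs List whose elements are [codon_alignment_pair()] objects or
#'   lists with `seq1`, `seq2` and optional `gene_ids`.
#' @param strict_stops Passed through to [estimate_ks()].
#' @return Data frame with one row per input pair, in input order.
#' @export
batch_ks <- function(pairs, strict_stops = FALSE) {
  empty <- estimate_ks("AAA", "AAA")[0, ]
  if (length(pairs) == 0L) return(empty)
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    ids <- if (!is.null(p$gene_ids)) p$gene_ids else
      c(paste0("pair", i, "_1"), paste0("pair", i, "_2"))
    tryCatch(
      if (inherits(p, "codon_alignment_pair"))
        estimate_ks(p, strict_stops = strict_stops)
      else
        estimate_ks(p$seq1, p$seq2, gene_ids = ids,
                    strict_stops = strict_stops),
      error = function(e) {
        warning("pair ", i, " (", ids[1L], "/", ids[2L],
                ") could not be scored: ", conditionMessage(e))
        data.frame(gene1 = ids[1L], gene2 = ids[2L], codons_used = 0L,
                   S = NA_real_, N = NA_real_, Sd = NA_real_, Nd = NA_real_,
                   pS = NA_real_, pN = NA_real_, Ka = NA_real_, Ks = NA_real_,
                   flag = "undefined", stringsAsFactors = FALSE)
      })
  })
  do.call(rbind, rows)
}
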