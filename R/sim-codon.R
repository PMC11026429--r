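# Event-based synonymous-only sequence evolution. The process is the
# generative counterpart of NG86: substitution events are Poisson in number
# and each event picks uniformly among the changes that are synonymous for
# the *current* sequence, so multiple hits (including back-substitutions)
# occur naturally and exercise the Jukes-Cantor correction.

.KS_SATURATION_BOUND <- 0.75

# apply n_events synonymous events to a vector of sense-codon indices
.evolve_codons <- function(idx, n_events, tab = .codon_tables()) {
  if (n_events == 0L) return(idx)
  for (e in seq_len(n_events)) {
    w <- tab$n_syn_nb[idx]
    tot <- sum(w)
    if (tot == 0L) {
      warning("sequence admits no synonymous change; ",
              n_events - e + 1L, " event(s) not applied")
      break
    }
    slot <- sample.int(length(idx), 1L, prob = w)
    nb <- tab$syn_nb[[idx[slot]]]
    idx[slot] <- nb[sample.int(length(nb), 1L)]
  }
  idx
}

.random_ancestor <- function(n_codons, tab = .codon_tables()) {
  sample.int(length(tab$sense_codons), n_codons, replace = TRUE)
}

.codon_string <- function(idx, tab = .codon_tables()) {
  paste(tab$sense_codons[idx], collapse = "")
}

.check_ks_level <- function(ks, what = "ks_true") {
  if (any(ks < 0))
    stop("'", what, "' must be non-negative")
  if (any(ks >= .KS_SATURATION_BOUND))
    stop("'", what, "' = ", max(ks), " is at or beyond the Jukes-Cantor ",
         "saturation bound (", .KS_SATURATION_BOUND,
         "); estimates would be undefined")
  invisible(ks)
}

#' Simulate a duplicate gene pair with known synonymous divergence
#'
#' Draws a random stop-free ancestor of `n_codons` codons (uniform over the
#' 61 sense codons), then applies `Poisson(ks_true * S)` synonymous
#' substitution events to one copy, where S is the NG86 synonymous site
#' count of the ancestor. Each event picks uniformly among the single
#' nucleotide changes that are synonymous for the current sequence; multiple
#' hits are allowed; no nonsynonymous event is ever applied, so the two
#' copies always translate to the same protein.
#'
#' @param n_codons Ancestor length in codons (>= 1).
#' @param ks_true Expected synonymous substitutions per synonymous site
#'   (0 <= ks_true < 0.75).
#' @param seed Integer seed; identical inputs give identical output.
#' @return Object of class `codon_pair_sim`: list with `seq1` (ancestor),
#'   `seq2` (diverged copy), `gene_ids`, `n_codons`, `ks_true`, `n_events`
#'   (events actually drawn), `S_ancestor` and `seed`.
#' @examples
#' p <- simulate_codon_pair(300, 0.102, seed = 1)
#' estimate_ks(p$seq1, p$seq2)$Ks
#' @export
simulate_codon_pair <- function(n_codons, ks_true, seed) {
  if (n_codons < 1L) stop("'n_codons' must be >= 1")
  .check_ks_level(ks_true)
  tab <- .codon_tables()
  with_seed(seed, {
    anc <- .random_ancestor(n_codons, tab)
    S_anc <- sum(tab$site_s[anc])
    n_events <- stats::rpois(1L, ks_true * S_anc)
    der <- .evolve_codons(anc, n_events, tab)
    structure(list(seq1 = .codon_string(anc, tab),
                   seq2 = .codon_string(der, tab),
                   gene_ids = c("ancestor", "derived"),
                   n_codons = n_codons, ks_true = ks_true,
                   n_events = n_events, S_ancestor = S_anc, seed = seed),
              class = "codon_pair_sim")
  })
}
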