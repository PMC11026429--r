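# Genetic-code lookup tables for NG86 counting, built once per session from
# the standard nuclear code (translation table 1) and cached. All downstream
# site/difference counting is table lookup, so per-pair estimation is O(L).

.ks_cache <- new.env(parent = emptyenv())

# orderings of 1..k single-nucleotide steps, k = 1..3
.perm_sets <- list(
  matrix(1L, 1L, 1L),
  matrix(c(1L, 2L, 2L, 1L), 2L, 2L, byrow = TRUE),
  matrix(c(1L, 2L, 3L, 1L, 3L, 2L, 2L, 1L, 3L,
           2L, 3L, 1L, 3L, 1L, 2L, 3L, 2L, 1L), 6L, 3L, byrow = TRUE)
)

# pathway-averaged (sd, nd) between two sense codons; orderings passing
# through a stop codon are excluded; c(NA, NA) if every ordering is blocked
.pathway_counts <- function(chars1, chars2, code) {
  diff_pos <- which(chars1 != chars2)
  k <- length(diff_pos)
  if (k == 0L) return(c(0, 0))
  perms <- .perm_sets[[k]]
  sd_tot <- 0
  nd_tot <- 0
  n_valid <- 0L
  for (r in seq_len(nrow(perms))) {
    cur <- chars1
    aa_cur <- code[[paste(cur, collapse = "")]]
    sd <- 0L
    nd <- 0L
    ok <- TRUE
    for (pos in diff_pos[perms[r, ]]) {
      cur[pos] <- chars2[pos]
      aa_new <- code[[paste(cur, collapse = "")]]
      if (aa_new == "*") {
        ok <- FALSE
        break
      }
      if (aa_new == aa_cur) sd <- sd + 1L else nd <- nd + 1L
      aa_cur <- aa_new
    }
    if (ok) {
      sd_tot <- sd_tot + sd
      nd_tot <- nd_tot + nd
      n_valid <- n_valid + 1L
    }
  }
  if (n_valid == 0L) return(c(NA_real_, NA_real_))
  c(sd_tot / n_valid, nd_tot / n_valid)
}

.codon_tables <- function() {
  tab <- .ks_cache$tables
  if (!is.null(tab)) return(tab)

  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  aa <- unname(code)
  sense <- which(aa != "*")
  sense_codons <- codons[sense]
  sense_aa <- aa[sense]
  stop_codons <- codons[aa == "*"]
  n <- length(sense_codons) # 61

  codon_index <- stats::setNames(rep(NA_integer_, 64L), codons)
  codon_index[sense_codons] <- seq_len(n)

  nts <- c("A", "C", "G", "T")
  cmat <- do.call(rbind, strsplit(sense_codons, "", fixed = TRUE))

  # fractional synonymous site count per codon: at each position, the
  # fraction of non-stop single-nucleotide changes that preserve the amino
  # acid (stop targets drop out of the denominator); syn_nb lists the sense
  # codons reachable by one synonymous change (the simulator's event targets)
  site_s <- numeric(n)
  syn_nb <- vector("list", n)
  for (i in seq_len(n)) {
    s_i <- 0
    nb <- integer(0)
    for (pos in 1:3) {
      alts <- setdiff(nts, cmat[i, pos])
      targets <- vapply(alts, function(a) {
        cd <- cmat[i, ]
        cd[pos] <- a
        paste(cd, collapse = "")
      }, character(1))
      target_aa <- code[targets]
      keep <- target_aa != "*"
      if (!any(keep)) next
      is_syn <- target_aa[keep] == sense_aa[i]
      s_i <- s_i + sum(is_syn) / sum(keep)
      nb <- c(nb, unname(codon_index[targets[keep][is_syn]]))
    }
    site_s[i] <- s_i
    syn_nb[[i]] <- nb
  }

  SD <- matrix(0, n, n)
  ND <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      cnt <- .pathway_counts(cmat[i, ], cmat[j, ], code)
      SD[i, j] <- SD[j, i] <- cnt[1L]
      ND[i, j] <- ND[j, i] <- cnt[2L]
    }
  }

  tab <- list(
    code = code,
    sense_codons = sense_codons,
    sense_aa = sense_aa,
    stop_codons = stop_codons,
    codon_index = codon_index,
    site_s = site_s,
    site_n = 3 - site_s,
    syn_nb = syn_nb,
    n_syn_nb = lengths(syn_nb),
    SD = SD,
    ND = ND
  )
  .ks_cache$tables <- tab
  tab
}

.split_codons <- function(seq) {
  l <- nchar(seq)
  substring(seq, seq.int(1L, l, 3L), seq.int(3L, l, 3L))
}

.normalize_seq <- function(seq) {
  chartr("u", "T", chartr("U", "T", toupper(seq)))
}
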