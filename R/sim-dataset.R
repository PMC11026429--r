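# Synthetic allotetraploid dataset generator. Default parameters encode the
# study system: a 15-chromosome allotetraploid whose subgenome A (8
# chromosomes) sits at ortholog Ks ~0.05 to the reference diploid, subgenome
# B (7 chromosomes) at ~0.09, and whose homeologous duplicate pairs diverge
# at Ks ~0.102.

.default_membership <- function(n_chromosomes = 15L) {
  ids <- sprintf("chr%02d", seq_len(n_chromosomes))
  if (n_chromosomes == 15L) {
    # subgenome A: chromosomes 1,3,5,7,8,10,13,14; B: 2,4,6,9,11,12,15
    a <- c(1L, 3L, 5L, 7L, 8L, 10L, 13L, 14L)
    m <- ifelse(seq_len(15L) %in% a, "A", "B")
  } else {
    m <- rep(c("A", "B"), length.out = n_chromosomes)
  }
  stats::setNames(m, ids)
}

#' Parameterization of a synthetic allotetraploid scenario
#'
#' Bundles and validates every knob of the generator. The defaults are the
#' study conditions: 15 chromosomes split 8/7 between subgenomes A and B,
#' ortholog divergence to the reference diploid 0.05 (A) and 0.09 (B),
#' homeolog (paralog) divergence 0.102, 50 genes per chromosome of 300
#' codons each.
#'
#' The three pairwise Ks levels must admit a star phylogeny: the implied
#' branch lengths `(ks_A + ks_par - ks_B)/2`, `(ks_B + ks_par - ks_A)/2`
#' and `(ks_A + ks_B - ks_par)/2` must all be non-negative.
#'
#' @param n_chromosomes Number of focal chromosomes.
#' @param subgenome_membership Named character vector chromosome -> "A"/"B";
#'   default is the 8/7 split over `chr01..chr15`.
#' @param ks_ortholog_A,ks_ortholog_B Expected Ks between a focal copy on an
#'   A (resp. B) chromosome and the reference diploid ortholog.
#' @param ks_paralog Expected Ks between the two focal homeologous copies.
#' @param genes_per_chromosome Minimum number of focal genes placed on every
#'   chromosome (>= 1).
#' @param codons_per_gene Gene length in codons.
#' @param focal_species,reference_species Species labels used in output
#'   tables.
#' @param seed Integer RNG seed.
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_chromosomes = 15L,
                         subgenome_membership = NULL,
                         ks_ortholog_A = 0.05,
                         ks_ortholog_B = 0.09,
                         ks_paralog = 0.102,
                         genes_per_chromosome = 50L,
                         codons_per_gene = 300L,
                         focal_species = "focal",
                         reference_species = "reference",
                         seed = 1L) {
  n_chromosomes <- as.integer(n_chromosomes)
  if (n_chromosomes < 1L) stop("'n_chromosomes' must be >= 1")
  if (is.null(subgenome_membership))
    subgenome_membership <- .default_membership(n_chromosomes)
  if (length(subgenome_membership) != n_chromosomes)
    stop("'subgenome_membership' must name all ", n_chromosomes,
         " chromosomes")
  if (is.null(names(subgenome_membership)) ||
      anyDuplicated(names(subgenome_membership)))
    stop("'subgenome_membership' must have unique chromosome names")
  if (!all(subgenome_membership %in% c("A", "B")))
    stop("memberships must be 'A' or 'B'")
  for (ks in c(ks_ortholog_A = ks_ortholog_A, ks_ortholog_B = ks_ortholog_B,
               ks_paralog = ks_paralog))
    .check_ks_level(ks, "Ks level")
  branch <- c(A = (ks_ortholog_A + ks_paralog - ks_ortholog_B) / 2,
              B = (ks_ortholog_B + ks_paralog - ks_ortholog_A) / 2,
              ref = (ks_ortholog_A + ks_ortholog_B - ks_paralog) / 2)
  if (any(branch < 0))
    stop("Ks levels violate the triangle condition; no star phylogeny ",
         "reproduces all three pairwise divergences")
  if (genes_per_chromosome < 1L) stop("'genes_per_chromosome' must be >= 1")
  if (codons_per_gene < 1L) stop("'codons_per_gene' must be >= 1")
  if (identical(focal_species, reference_species))
    stop("focal and reference species must differ")
  structure(list(n_chromosomes = n_chromosomes,
                 subgenome_membership = subgenome_membership,
                 ks_ortholog_A = ks_ortholog_A,
                 ks_ortholog_B = ks_ortholog_B,
                 ks_paralog = ks_paralog,
                 branch_lengths = branch,
                 genes_per_chromosome = as.integer(genes_per_chromosome),
                 codons_per_gene = as.integer(codons_per_gene),
                 focal_species = focal_species,
                 reference_species = reference_species,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Generate a synthetic allotetraploid ortholog dataset
#'
#' For each orthogroup, a stop-free random ancestor is evolved along a star
#' phylogeny with three tips -- the reference diploid copy and the two focal
#' homeologous copies -- using synonymous-only Poisson substitution events
#' (see [simulate_codon_pair()]). Branch lengths are chosen so that every
#' pairwise expected divergence equals the scenario's levels exactly:
#' focal-A vs reference = `ks_ortholog_A`, focal-B vs reference =
#' `ks_ortholog_B`, focal-A vs focal-B = `ks_paralog`.
#'
#' The A copies are dealt round-robin across subgenome-A chromosomes and
#' the B copies across subgenome-B chromosomes; the number of orthogroups
#' is `genes_per_chromosome * max(#A, #B)`, so every chromosome carries at
#' least `genes_per_chromosome` genes.
#'
#' @param scenario A [sim_scenario()].
#' @param out_dir Optional directory; when given, writes `sequences.fasta`
#'   (ids `<orthogroup>|<species>|<chromosome>`), `gene_map.tsv`
#'   (`gene species chromosome orthogroup`), `orthogroups.tsv` and
#'   `truth.json`.
#' @return Object of class `sim_dataset`: list with `sequences` (named
#'   character vector), `gene_map`, `orthogroup_table`, `pairs` (one row
#'   per orthogroup: focal pair plus reference gene), and `truth` (the
#'   scenario).
#' @export
simulate_dataset <- function(scenario, out_dir = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  tab <- .codon_tables()
  mem <- scenario$subgenome_membership
  chr_A <- names(mem)[mem == "A"]
  chr_B <- names(mem)[mem == "B"]
  # degenerate scenarios with a single subgenome still emit two focal
  # copies per orthogroup; the homeless copy is placed across all
  # chromosomes (its divergence level still follows its nominal subgenome)
  if (length(chr_A) == 0L) chr_A <- names(mem)
  if (length(chr_B) == 0L) chr_B <- names(mem)
  n_og <- scenario$genes_per_chromosome * max(length(chr_A), length(chr_B))
  og_ids <- sprintf("OG%04d", seq_len(n_og))
  chrom_A <- rep_len(chr_A, n_og)
  chrom_B <- rep_len(chr_B, n_og)
  br <- scenario$branch_lengths
  L <- scenario$codons_per_gene

  with_seed(scenario$seed, {
    seq_ref <- seq_a <- seq_b <- character(n_og)
    for (g in seq_len(n_og)) {
      anc <- .random_ancestor(L, tab)
      S_anc <- sum(tab$site_s[anc])
      ev <- stats::rpois(3L, br * S_anc)
      seq_a[g] <- .codon_string(.evolve_codons(anc, ev[1L], tab), tab)
      seq_b[g] <- .codon_string(.evolve_codons(anc, ev[2L], tab), tab)
      seq_ref[g] <- .codon_string(.evolve_codons(anc, ev[3L], tab), tab)
    }
    gene_a <- paste(og_ids, scenario$focal_species, chrom_A, sep = "|")
    gene_b <- paste(og_ids, scenario$focal_species, chrom_B, sep = "|")
    gene_r <- paste(og_ids, scenario$reference_species, "refChr", sep = "|")

    sequences <- stats::setNames(c(seq_a, seq_b, seq_ref),
                                 c(gene_a, gene_b, gene_r))
    gene_map <- data.frame(
      gene = c(gene_a, gene_b, gene_r),
      species = rep(c(scenario$focal_species, scenario$focal_species,
                      scenario$reference_species), each = n_og),
      chromosome = c(chrom_A, chrom_B, rep("refChr", n_og)),
      orthogroup = rep(og_ids, 3L),
      stringsAsFactors = FALSE)
    pairs <- data.frame(orthogroup = og_ids,
                        focal_gene_1 = gene_a,
                        focal_gene_2 = gene_b,
                        reference_gene = gene_r,
                        stringsAsFactors = FALSE)
    out <- structure(list(
      sequences = sequences,
      gene_map = gene_map,
      orthogroup_table = gene_map[, c("gene", "species", "orthogroup")],
      pairs = pairs,
      truth = scenario), class = "sim_dataset")

    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_fasta(sequences, file.path(out_dir, "sequences.fasta"))
      write_tsv(gene_map, file.path(out_dir, "gene_map.tsv"))
      write_tsv(out$orthogroup_table, file.path(out_dir, "orthogroups.tsv"))
      truth <- scenario
      class(truth) <- NULL
      jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    out
  })
}
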