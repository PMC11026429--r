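# Synthetic allotetraploid dataset generator: structure, determinism, and
# the three pairwise divergence contracts.

small_scenario <- function(seed = 1L, ...) {
  sim_scenario(n_chromosomes = 4L,
               subgenome_membership = stats::setNames(c("A", "B", "A", "B"),
                                                      paste0("chr", 1:4)),
               genes_per_chromosome = 3L, codons_per_gene = 100L,
               seed = seed, ...)
}

test_that("scenario validation catches inconsistent inputs", {
  expect_error(sim_scenario(n_chromosomes = 3,
                            subgenome_membership = c(chr1 = "A", chr2 = "B")),
               "name all")
  expect_error(sim_scenario(subgenome_membership =
                              stats::setNames(rep("C", 15),
                                              sprintf("chr%02d", 1:15))),
               "'A' or 'B'")
  expect_error(sim_scenario(ks_paralog = 0.8), "saturation")
  # paralog divergence larger than the sum of ortholog levels: no star tree
  expect_error(sim_scenario(ks_ortholog_A = 0.01, ks_ortholog_B = 0.01,
                            ks_paralog = 0.1), "triangle")
  expect_error(sim_scenario(genes_per_chromosome = 0), ">= 1")
})

test_that("each orthogroup carries two focal copies and one reference", {
  ds <- simulate_dataset(small_scenario())
  n_og <- nrow(ds$pairs)
  expect_equal(n_og, 3L * 2L) # genes_per_chromosome * max(#A, #B)
  expect_equal(length(ds$sequences), 3L * n_og)
  counts <- table(ds$gene_map$orthogroup, ds$gene_map$species)
  expect_true(all(counts[, "focal"] == 2L))
  expect_true(all(counts[, "reference"] == 1L))
  # sequence lengths are full codons and translations are stop-free
  expect_true(all(nchar(ds$sequences) == 300L))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(ds$sequences), no.init.codon = TRUE))
  expect_false(any(grepl("*", aa, fixed = TRUE)))
})

test_that("a minimal one-chromosome scenario emits exactly 3 sequences", {
  sc <- sim_scenario(n_chromosomes = 1L,
                     subgenome_membership = c(chr1 = "A"),
                     ks_ortholog_A = 0.06, ks_ortholog_B = 0.06,
                     ks_paralog = 0.1,
                     genes_per_chromosome = 1L, codons_per_gene = 50L)
  ds <- simulate_dataset(sc)
  expect_equal(length(ds$sequences), 3L)
  expect_equal(nrow(ds$pairs), 1L)
})

test_that("identical scenario and seed reproduce byte-identical files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(small_scenario(seed = 42L), out_dir = d1)
  simulate_dataset(small_scenario(seed = 42L), out_dir = d2)
  for (f in c("sequences.fasta", "gene_map.tsv", "orthogroups.tsv",
              "truth.json"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6),
                     label = f)
  d3 <- withr::local_tempdir()
  simulate_dataset(small_scenario(seed = 43L), out_dir = d3)
  expect_false(identical(readBin(file.path(d1, "sequences.fasta"), "raw", 1e6),
                         readBin(file.path(d3, "sequences.fasta"), "raw", 1e6)))
})

test_that("pairwise divergences track the scenario's three Ks levels", {
  # one large-ish scenario; compare cohort medians of the three pair types
  sc <- sim_scenario(n_chromosomes = 2L,
                     subgenome_membership = c(chr1 = "A", chr2 = "B"),
                     genes_per_chromosome = 150L, codons_per_gene = 300L,
                     seed = 7L)
  ds <- simulate_dataset(sc)
  kst <- dataset_ks_tables(ds)
  ortho <- kst$ortholog_ks[kst$ortholog_ks$flag == "ok", ]
  chrom <- ds$gene_map$chromosome[match(ortho$gene1, ds$gene_map$gene)]
  expect_equal(stats::median(ortho$Ks[chrom == "chr1"]), 0.05,
               tolerance = 0.01 / 0.05)
  expect_equal(stats::median(ortho$Ks[chrom == "chr2"]), 0.09,
               tolerance = 0.01 / 0.09)
  par <- kst$paralog_ks[kst$paralog_ks$flag == "ok", ]
  expect_equal(stats::median(par$Ks), 0.102, tolerance = 0.01 / 0.102)
})
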