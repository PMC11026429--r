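# Chromosome-level Ks summaries and exact two-cluster subgenome phasing.

make_summaries <- function(medians, ids = sprintf("c%02d", seq_along(medians))) {
  data.frame(chromosome = ids, n_genes = 50L, median_ks = medians,
             mean_ks = medians, iqr_ks = 0.01, assigned = TRUE,
             stringsAsFactors = FALSE)
}

test_that("per-chromosome summaries aggregate ok-flagged records", {
  ks <- data.frame(gene1 = c("g1", "g2", "g3", "g4"),
                   Ks = c(0.04, 0.05, 0.06, 9),
                   flag = c("ok", "ok", "ok", "saturated"),
                   stringsAsFactors = FALSE)
  map <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    chromosome = "c1", stringsAsFactors = FALSE)
  s <- summarize_by_chromosome(ks, map, min_genes = 3L)
  expect_equal(s$n_genes, 3L)       # the saturated record is excluded
  expect_equal(s$median_ks, 0.05)
  expect_true(s$assigned)
  expect_warning(summarize_by_chromosome(ks, map, min_genes = 10L),
                 "unassigned")
  ks_bad <- ks
  ks_bad$flag <- "saturated"
  expect_error(suppressWarnings(summarize_by_chromosome(ks_bad, map)),
               "no ok-flagged")
})

test_that("a well-separated 2+2 vector splits at the obvious gap", {
  part <- partition_two_clusters(make_summaries(c(0.048, 0.052, 0.089,
                                                  0.091)))
  expect_equal(part$sizes, c(A = 2L, B = 2L))
  expect_equal(part$assignment$subgenome, c("A", "A", "B", "B"))
  expect_false(part$ambiguous)
})

test_that("the contiguous split equals the exhaustive bipartition optimum", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(3:10, 1L)
    x <- round(stats::runif(n, 0.02, 0.15), 4)
    part <- partition_two_clusters(make_summaries(x))
    lab <- part$assignment$subgenome[match(sprintf("c%02d", seq_len(n)),
                                           part$assignment$chromosome)]
    if (part$ambiguous) next
    sse <- function(v) sum((v - mean(v))^2)
    achieved <- sse(x[lab == "A"]) + sse(x[lab == "B"])
    expect_equal(achieved, oracle_best_bipartition_sse(x),
                 tolerance = 1e-12)
  }
  # and once at the full problem size
  x <- with_seed(15, stats::runif(15, 0.02, 0.15))
  part <- partition_two_clusters(make_summaries(x), ambiguity_ratio = 0)
  lab <- part$assignment$subgenome[match(sprintf("c%02d", 1:15),
                                         part$assignment$chromosome)]
  sse <- function(v) sum((v - mean(v))^2)
  expect_equal(sse(x[lab == "A"]) + sse(x[lab == "B"]),
               oracle_best_bipartition_sse(x), tolerance = 1e-12)
})

test_that("subgenome A is always the lower-Ks cluster", {
  part <- partition_two_clusters(make_summaries(c(0.09, 0.05, 0.091, 0.049)))
  a <- part$assignment
  expect_true(all(a$median_ks[a$subgenome == "A"] <
                    min(a$median_ks[a$subgenome == "B"])))
  expect_lt(part$centers[["A"]], part$centers[["B"]])
})

test_that("degenerate and barely-separated inputs are flagged ambiguous", {
  part <- partition_two_clusters(make_summaries(rep(0.07, 5)))
  expect_true(part$ambiguous)
  expect_true(all(is.na(part$assignment$subgenome)))
  # overlapping continuum: gap indistinguishable from within-cluster spread
  part2 <- partition_two_clusters(make_summaries(seq(0.05, 0.064,
                                                     by = 0.001)))
  expect_true(part2$ambiguous)
})

test_that("input order never changes the partition", {
  x <- c(0.051, 0.048, 0.088, 0.052, 0.093, 0.09, 0.049)
  ids <- paste0("chr", seq_along(x))
  ref <- partition_two_clusters(make_summaries(x, ids))
  for (rep in 1:5) {
    perm <- sample(seq_along(x))
    shuffled <- partition_two_clusters(make_summaries(x[perm], ids[perm]))
    expect_equal(shuffled$assignment, ref$assignment)
    expect_equal(shuffled$sizes, ref$sizes)
  }
})

test_that("chromosomes below min_genes stay out of the partition", {
  s <- make_summaries(c(0.05, 0.051, 0.09, 0.091, 0.07))
  s$assigned[5] <- FALSE
  part <- partition_two_clusters(s)
  expect_equal(part$unassigned, "c05")
  expect_equal(nrow(part$assignment), 4L)
})

test_that("homeolog consistency is 1 on perfect phasing, 0 on collapsed", {
  part <- partition_two_clusters(make_summaries(c(0.05, 0.09),
                                                c("cA", "cB")))
  map <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    chromosome = c("cA", "cB", "cA", "cA"),
                    stringsAsFactors = FALSE)
  pairs <- data.frame(focal_gene_1 = c("g1", "g3"),
                      focal_gene_2 = c("g2", "g4"),
                      stringsAsFactors = FALSE)
  hc <- homeolog_consistency(part, pairs, map)
  expect_equal(hc$fraction, 0.5)
  expect_equal(hc$n_pairs_used, 2L)
  # both copies of both pairs on subgenome A
  same <- data.frame(focal_gene_1 = c("g1", "g3"),
                     focal_gene_2 = c("g3", "g4"),
                     stringsAsFactors = FALSE)
  expect_equal(homeolog_consistency(part, same, map)$fraction, 0)
})

test_that("shuffled chromosome labels give near-random split fractions", {
  # 8 A-chromosomes, 7 B-chromosomes, pairs always (A-chrom, B-chrom):
  # under random relabeling P(split) = 2 * 8 * 7 / (15 * 14) = 8/15
  chroms <- sprintf("c%02d", 1:15)
  medians <- c(rep(0.05, 8), rep(0.09, 7)) + seq(0, 0.0014, by = 1e-4)
  part <- partition_two_clusters(make_summaries(medians, chroms))
  n_pairs <- 200L
  map <- data.frame(gene = c(sprintf("a%03d", 1:n_pairs),
                             sprintf("b%03d", 1:n_pairs)),
                    chromosome = c(rep_len(chroms[1:8], n_pairs),
                                   rep_len(chroms[9:15], n_pairs)),
                    stringsAsFactors = FALSE)
  pairs <- data.frame(focal_gene_1 = sprintf("a%03d", 1:n_pairs),
                      focal_gene_2 = sprintf("b%03d", 1:n_pairs),
                      stringsAsFactors = FALSE)
  expect_equal(homeolog_consistency(part, pairs, map)$fraction, 1)
  set.seed(123)
  fracs <- vapply(1:20, function(i) {
    shuf <- map
    relabel <- sample(chroms)
    shuf$chromosome <- relabel[match(map$chromosome, chroms)]
    homeolog_consistency(part, pairs, shuf)$fraction
  }, numeric(1))
  expect_equal(mean(fracs), 2 * 8 * 7 / (15 * 14), tolerance = 0.1)
})
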