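# Subgenome phasing from chromosome-level Ks distributions. Each focal
# chromosome is summarized by the median Ks of its genes against the
# reference diploid; the chromosome medians are then split into two groups
# by the exact optimal 1-D two-cluster partition (sorted medians, all
# contiguous splits, minimum within-cluster sum of squares -- provably the
# global optimum in one dimension). The lower-Ks group is subgenome A.

#' Summarize gene-level Ks by chromosome
#'
#' Joins a Ks table (one row per focal gene versus the reference) to a
#' gene-to-chromosome map and computes per-chromosome summaries over
#' records with flag `ok`. Chromosomes with fewer than `min_genes` usable
#' records are reported but marked unassignable.
#'
#' @param ks_table Data frame with columns `gene1` (focal gene id), `Ks`,
#'   `flag` (as produced by [batch_ks()]).
#' @param gene_map Data frame with columns `gene`, `chromosome`.
#' @param min_genes Minimum usable records per chromosome (default 10).
#' @return Data frame with one row per chromosome: `chromosome`, `n_genes`,
#'   `median_ks`, `mean_ks`, `iqr_ks`, `assigned` (logical).
#' @export
summarize_by_chromosome <- function(ks_table, gene_map, min_genes = 10L) {
  if (!all(c("gene1", "Ks", "flag") %in% names(ks_table)))
    stop("'ks_table' needs columns gene1, Ks, flag")
  if (!all(c("gene", "chromosome") %in% names(gene_map)))
    stop("'gene_map' needs columns gene, chromosome")
  ok <- ks_table[ks_table$flag == "ok", , drop = FALSE]
  chrom <- gene_map$chromosome[match(ok$gene1, gene_map$gene)]
  keep <- !is.na(chrom)
  if (!any(keep))
    stop("no ok-flagged Ks record maps to a chromosome")
  if (!all(keep))
    warning(sum(!keep), " ok-flagged record(s) have no chromosome; dropped")
  ok <- ok[keep, , drop = FALSE]
  chrom <- chrom[keep]

  split_ks <- split(ok$Ks, chrom)
  out <- data.frame(
    chromosome = names(split_ks),
    n_genes = vapply(split_ks, length, integer(1)),
    median_ks = vapply(split_ks, stats::median, numeric(1)),
    mean_ks = vapply(split_ks, mean, numeric(1)),
    iqr_ks = vapply(split_ks, stats::IQR, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out$assigned <- out$n_genes >= min_genes
  if (any(!out$assigned))
    warning(sum(!out$assigned), " chromosome(s) below min_genes = ",
            min_genes, " left unassigned: ",
            paste(out$chromosome[!out$assigned], collapse = ", "))
  out
}

# exact optimal 1-D 2-cluster split by within-cluster SSE; input sorted
.best_contiguous_split <- function(x_sorted) {
  n <- length(x_sorted)
  sse <- function(v) sum((v - mean(v))^2)
  costs <- vapply(seq_len(n - 1L), function(i)
    sse(x_sorted[seq_len(i)]) + sse(x_sorted[seq.int(i + 1L, n)]),
    numeric(1))
  i <- which.min(costs)
  list(split_after = i, cost = costs[i])
}

#' Partition chromosomes into two subgenomes by Ks
#'
#' Deterministic, seed-free two-cluster assignment of per-chromosome median
#' Ks values: medians are sorted and all n - 1 contiguous splits evaluated;
#' the split minimizing the total within-cluster sum of squared deviations
#' is exact and (in one dimension) globally optimal over all bipartitions.
#' The cluster with the lower Ks center is labeled subgenome A.
#'
#' The partition is flagged ambiguous when the gap between the clusters is
#' smaller than `ambiguity_ratio` times the pooled within-cluster
#' interquartile range (or when the gap is zero); labels are then withheld
#' (`NA`) since the two-subgenome reading is not supported by the data.
#'
#' @param summaries Data frame from [summarize_by_chromosome()] (rows with
#'   `assigned = FALSE` are excluded and reported as unassigned).
#' @param ambiguity_ratio Separation threshold (default 1).
#' @return Object of class `subgenome_partition`: list with `assignment`
#'   (data frame `chromosome, median_ks, subgenome`), `centers`
#'   (median-of-medians per cluster), `sizes`, `gap`, `pooled_iqr`,
#'   `separation` (gap / pooled IQR, `Inf` when the pooled IQR is 0),
#'   `ambiguous`, `unassigned`.
#' @export
partition_two_clusters <- function(summaries, ambiguity_ratio = 1) {
  need <- c("chromosome", "median_ks")
  if (!all(need %in% names(summaries)))
    stop("'summaries' needs columns chromosome, median_ks")
  used <- if ("assigned" %in% names(summaries))
    summaries[summaries$assigned, , drop = FALSE] else summaries
  unassigned <- setdiff(summaries$chromosome, used$chromosome)
  if (nrow(used) < 2L)
    stop("need at least 2 assignable chromosomes")

  o <- order(used$median_ks, used$chromosome)
  x <- used$median_ks[o]
  ids <- used$chromosome[o]
  best <- .best_contiguous_split(x)
  lower <- seq_len(best$split_after)
  upper <- seq.int(best$split_after + 1L, length(x))

  gap <- x[upper[1L]] - x[lower[length(lower)]]
  dev <- c(x[lower] - stats::median(x[lower]),
           x[upper] - stats::median(x[upper]))
  pooled_iqr <- stats::IQR(dev)
  separation <- if (pooled_iqr > 0) gap / pooled_iqr else
    if (gap > 0) Inf else 0
  ambiguous <- gap <= 0 ||
    (pooled_iqr > 0 && gap < ambiguity_ratio * pooled_iqr)

  sub <- rep(NA_character_, length(x))
  if (!ambiguous) {
    sub[lower] <- "A"
    sub[upper] <- "B"
  }
  assignment <- data.frame(chromosome = ids, median_ks = x,
                           subgenome = sub, stringsAsFactors = FALSE)
  assignment <- assignment[order(assignment$chromosome), , drop = FALSE]
  row.names(assignment) <- NULL
  structure(list(
    assignment = assignment,
    centers = c(A = stats::median(x[lower]), B = stats::median(x[upper])),
    sizes = c(A = length(lower), B = length(upper)),
    gap = gap,
    pooled_iqr = pooled_iqr,
    separation = separation,
    ambiguous = ambiguous,
    unassigned = unassigned), class = "subgenome_partition")
}

#' Fraction of paralog pairs phased into different subgenomes
#'
#' For each focal paralog pair, looks up the subgenome of each copy's
#' chromosome and reports the fraction of pairs whose two copies lie in
#' different subgenomes. Pairs touching an unassigned chromosome are
#' excluded from the denominator.
#'
#' @param partition A [partition_two_clusters()] result.
#' @param pairs Data frame with columns `focal_gene_1`, `focal_gene_2`.
#' @param gene_map Data frame with columns `gene`, `chromosome`.
#' @return List with `fraction` (in `[0, 1]`, `NaN` when no pair is
#'   scorable), `n_pairs_used`, and `detail` (per-pair breakdown).
#' @export
homeolog_consistency <- function(partition, pairs, gene_map) {
  stopifnot(inherits(partition, "subgenome_partition"))
  assign_map <- stats::setNames(partition$assignment$subgenome,
                                partition$assignment$chromosome)
  chr1 <- gene_map$chromosome[match(pairs$focal_gene_1, gene_map$gene)]
  chr2 <- gene_map$chromosome[match(pairs$focal_gene_2, gene_map$gene)]
  s1 <- assign_map[chr1]
  s2 <- assign_map[chr2]
  usable <- !is.na(s1) & !is.na(s2)
  detail <- data.frame(focal_gene_1 = pairs$focal_gene_1,
                       focal_gene_2 = pairs$focal_gene_2,
                       subgenome_1 = unname(s1), subgenome_2 = unname(s2),
                       split_across = ifelse(usable, s1 != s2, NA),
                       stringsAsFactors = FALSE)
  list(fraction = mean(detail$split_across[usable]),
       n_pairs_used = sum(usable),
       detail = detail)
}
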