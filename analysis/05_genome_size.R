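#!/usr/bin/env Rscript
# Step 5 -- k-mer genome-size estimation on simulated reads.
#
# Simulates error-free 100 b reads at 30x coverage from a 300 kb random
# genome, counts canonical 21-mers, locates the homozygous coverage peak
# and estimates genome size as total k-mers / peak depth. (300 kb keeps
# this driver quick; the estimator is scale-free.)

suppressPackageStartupMessages(library(ksphase))

genome_length <- 3e5
rs <- simulate_reads(genome_length, coverage = 30, read_length = 100,
                     seed = derive_seed(1L, "reads"))
cat("simulated", length(rs$reads), "reads\n")

h <- count_kmers(rs, k = 21)
dir.create("results", showWarnings = FALSE)
write_tsv(data.frame(multiplicity = h$multiplicity, count = h$count),
          "results/kmer_histogram.tsv")

est <- estimate_size(h)
cat(sprintf("k = %d: %d distinct k-mers, %.0f instances\n",
            h$k, h$n_distinct, h$total_kmers))
cat(sprintf("coverage peak at %dx\n", est$peak_depth))
cat(sprintf("estimated genome size: %.0f b (truth %.0f b, error %+.2f%%)\n",
            est$size_bases, genome_length,
            100 * (est$size_bases / genome_length - 1)))
jsonlite::write_json(unclass(est), "results/genome_size.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/genome_size.json\n")
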