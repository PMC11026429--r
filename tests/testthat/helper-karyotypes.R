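# Random karyotype generator for property tests: partitions a random
# subset of the block alphabet into chromosomes with internal centromeres
# (>= 2 blocks each) and random orientations.

block_alphabet <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J",
                    "KL", "MN", "O", "P", "Q", "R", "S", "T", "U", "V",
                    "Wa", "Wb", "X")

random_karyotype <- function(n_chrom = 4L, min_blocks = 2L) {
  labels <- sample(block_alphabet, n_chrom * max(min_blocks, 2L) +
                     sample(0:3, 1L))
  cuts <- sort(sample(seq.int(min_blocks, length(labels) - min_blocks),
                      n_chrom - 1L))
  bounds <- c(0L, cuts, length(labels))
  chroms <- lapply(seq_len(n_chrom), function(i) {
    blocks <- labels[seq.int(bounds[i] + 1L, bounds[i + 1L])]
    flip <- runif(length(blocks)) < 0.3
    blocks[flip] <- paste0("-", blocks[flip])
    cent <- if (length(blocks) >= 2L)
      sample.int(length(blocks) - 1L, 1L) else NA_integer_
    chromosome_model(paste0("c", i), blocks, cent)
  })
  karyotype(chroms)
}
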