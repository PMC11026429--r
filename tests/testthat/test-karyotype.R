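# Genomic-block karyotype algebra: parsing, WGD, NCI, inversion,
# copy-number accounting and ancestral matching.

test_that("parsing and serialization are mutually inverse", {
  k <- parse_karyotype("AK2: D E | .")
  expect_equal(n_chromosomes(k), 1L)
  expect_equal(k$chromosomes[["AK2"]]$blocks, c("D", "E"))
  expect_equal(k$chromosomes[["AK2"]]$centromere, 2L)
  expect_equal(serialize_karyotype(k), "AK2: D E | .")
  expect_error(parse_karyotype("c1: Z9 ."), "unknown block")
  expect_error(parse_karyotype("c1: A | B | C ."), "centromere")
  expect_error(parse_karyotype("Qa"), "expected")
  # sub-block qualifiers are restricted to W
  expect_error(parse_karyotype("c1: Aa ."), "unknown block")
  k2 <- parse_karyotype(c("# comment", "c1: -Wa KL | MN ."))
  expect_equal(k2$chromosomes[["c1"]]$blocks, c("-Wa", "KL", "MN"))
})

test_that("serialization round-trips on random karyotypes", {
  set.seed(12)
  for (rep in 1:300) {
    k <- random_karyotype(n_chrom = sample(2:5, 1L))
    expect_equal(serialize_karyotype(parse_karyotype(serialize_karyotype(k))),
                 serialize_karyotype(k))
  }
})

test_that("the shipped presets have the published structure", {
  ack <- karyotype_preset("ACK_Cardamineae_n8")
  expect_equal(n_chromosomes(ack), 8L)
  expect_equal(ack$chromosomes[["AK1"]]$blocks, c("A", "B", "C"))
  expect_equal(ack$chromosomes[["AK8/6"]]$blocks, c("O", "P", "Wb", "X"))
  raq <- karyotype_preset("R_aquatica_n15")
  expect_equal(n_chromosomes(raq), 15L)
  expect_equal(sub("^-", "", raq$chromosomes[["RaChr15"]]$blocks),
               c("O", "P", "E", "D", "Wb", "X"))
})

test_that("whole-genome duplication doubles chromosomes and blocks", {
  ack <- karyotype_preset("ACK_Cardamineae_n8")
  dup <- whole_genome_duplication(ack)
  expect_equal(n_chromosomes(dup), 16L)
  expect_equal(block_copy_numbers(dup)$copy_number,
               2 * block_copy_numbers(ack)$copy_number)
  expect_equal(n_chromosomes(whole_genome_duplication(karyotype())), 0L)
})

test_that("NCI splices the donor at the recipient centromere", {
  k16 <- whole_genome_duplication(karyotype_preset("ACK_Cardamineae_n8"))
  k15 <- nested_chromosome_insertion(k16, "AK8/6_2", "AK2_2", "inverted")
  expect_equal(n_chromosomes(k15), 15L)
  fused <- k15$chromosomes[["AK8/6_2"]]
  expect_equal(fused$blocks, c("O", "P", "-E", "-D", "Wb", "X"))
  expect_false("AK2_2" %in% names(k15$chromosomes))
  # block content is conserved by the fusion
  expect_equal(block_copy_numbers(k15)$copy_number,
               block_copy_numbers(k16)$copy_number)
  # forward orientation keeps the donor's order
  fwd <- nested_chromosome_insertion(k16, "AK8/6_2", "AK2_2", "forward")
  expect_equal(fwd$chromosomes[["AK8/6_2"]]$blocks,
               c("O", "P", "D", "E", "Wb", "X"))
})

test_that("NCI rejects invalid donors and recipients", {
  k <- whole_genome_duplication(karyotype_preset("ACK_Cardamineae_n8"))
  expect_error(nested_chromosome_insertion(k, "AK2_1", "AK2_1"), "differ")
  expect_error(nested_chromosome_insertion(k, "nope", "AK2_1"),
               "no chromosome")
  # AK2 has a terminal centromere: cannot receive an insertion
  expect_error(nested_chromosome_insertion(k, "AK2_1", "AK1_1"), "terminal")
})

test_that("segment inversion flips order and signs and is an involution", {
  ch <- chromosome_model("c", c("O", "P", "-E", "-D", "Wb", "X"), 2L)
  inv <- invert_segment(ch, 3L, 4L)
  expect_equal(inv$blocks, c("O", "P", "D", "E", "Wb", "X"))
  expect_equal(invert_segment(inv, 3L, 4L)$blocks, ch$blocks)
  expect_error(invert_segment(ch, 4L, 99L), "out of range")
  # paracentric mode refuses to span the centromere (between P and -E)
  expect_error(invert_segment(ch, 1L, 3L, paracentric = TRUE),
               "centromere")
  expect_equal(invert_segment(ch, 3L, 6L, paracentric = TRUE)$blocks,
               c("O", "P", "-X", "-Wb", "D", "E"))
})

test_that("block copy numbers combine the W halves and call ploidy", {
  ack <- block_copy_numbers(karyotype_preset("ACK_Cardamineae_n8"))
  expect_true(all(ack$copy_number == 1))
  expect_false(ack$tetraploid_call)
  raq <- block_copy_numbers(karyotype_preset("R_aquatica_n15"))
  expect_equal(sum(raq$copy_number == 2), 22L)
  expect_equal(raq$copy_number[["W"]], 2) # (2 Wa + 2 Wb) / 2
  expect_true(raq$tetraploid_call)
})

test_that("ancestral matching classifies the reconstructed karyotype", {
  raq <- karyotype_preset("R_aquatica_n15")
  ack <- karyotype_preset("ACK_Cardamineae_n8")
  res <- match_ancestral(raq, ack)
  expect_equal(res$n_shared, 14L)
  expect_equal(res$n_derived, 1L)
  derived <- res$classification$chromosome[res$classification$status ==
                                             "derived"]
  expect_equal(derived, "RaChr15")
  expect_equal(res$events$kind, "NCI")
  expect_equal(res$events$donor, "AK2")
  expect_equal(res$events$recipient, "AK8/6")
  # an ancestral karyotype against itself is all shared, no events
  self <- match_ancestral(ack, ack)
  expect_equal(self$n_shared, 8L)
  expect_equal(nrow(self$events), 0L)
})

test_that("matching ignores inversions but respects W halves", {
  ack <- karyotype_preset("ACK_Cardamineae_n8")
  inv <- invert_segment(ack$chromosomes[["AK1"]], 1L, 2L)
  k <- karyotype(list(inv))
  expect_equal(match_ancestral(k, ack)$n_shared, 1L)
  # Wa does not match a chromosome whose content has Wb
  wa_for_wb <- karyotype(list(chromosome_model("x",
                                               c("O", "P", "Wa", "X"), 2L)))
  expect_equal(match_ancestral(wa_for_wb, ack)$n_shared, 0L)
})

test_that("random WGD + NCI karyotypes are recovered by the detector", {
  set.seed(2024)
  n_checked <- 0L
  for (rep in 1:60) {
    k0 <- random_karyotype(n_chrom = sample(3:5, 1L))
    dup <- whole_genome_duplication(k0)
    ids <- names(dup$chromosomes)
    # recipient needs an internal centromere
    ok_rec <- vapply(dup$chromosomes, function(ch)
      !is.na(ch$centromere) && ch$centromere > 0L &&
        ch$centromere < length(ch$blocks), logical(1))
    recips <- ids[ok_rec]
    if (length(recips) == 0L) next
    recipient <- sample(recips, 1L)
    donor <- sample(setdiff(ids, recipient), 1L)
    orient <- sample(c("forward", "inverted"), 1L)
    k1 <- nested_chromosome_insertion(dup, recipient, donor, orient)
    expect_equal(n_chromosomes(k1), 2L * n_chromosomes(k0) - 1L)
    res <- match_ancestral(k1, k0)
    expect_equal(res$n_derived, 1L)
    expect_equal(res$events$donor, sub("_[12]$", "", donor))
    expect_equal(res$events$recipient, sub("_[12]$", "", recipient))
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 40L)
})
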