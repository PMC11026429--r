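# NG86 counting engine: worked examples, brute-force oracle equivalence,
# and the record-level contracts (flags, symmetry, conservation).

test_that("site counts match hand enumeration for canonical codons", {
  expect_equal(count_sites("GCT"), c(s = 1, n = 2)) # Ala: 4-fold 3rd position
  expect_equal(count_sites("TGG"), c(s = 0, n = 3)) # Trp: no synonymous change
  expect_equal(count_sites("ATG"), c(s = 0, n = 3)) # Met
  # Tyr TAT: two of the three 3rd-position changes hit stops and leave the
  # denominator; the remaining change (TAC) is synonymous
  expect_equal(count_sites("TAT"), c(s = 1, n = 2))
  expect_error(count_sites("TAA"), "stop")
  expect_error(count_sites("AC-"), "invalid")
})

test_that("pathway-averaged differences match hand enumeration", {
  expect_equal(count_differences("GCT", "GCC"), c(sd = 1, nd = 0))
  expect_equal(count_differences("AAA", "AAA"), c(sd = 0, nd = 0))
  # Phe -> Val via Val (1 syn + 1 nonsyn) or via Leu (0 + 2); average
  expect_equal(count_differences("TTT", "GTA"), c(sd = 0.5, nd = 1.5))
  expect_error(count_differences("TGA", "TGG"), "stop")
})

test_that("Jukes-Cantor correction has the closed form and its bounds", {
  expect_identical(jc_correct(0), 0)
  expect_equal(jc_correct(0.5), -0.75 * log(1 / 3), tolerance = 1e-12)
  expect_identical(jc_correct(0.75), Inf)
  expect_identical(jc_correct(0.8), Inf)
  expect_error(jc_correct(-0.1), "proportion")
  p <- seq(0.01, 0.7, by = 0.01)
  d <- jc_correct(p)
  expect_true(all(d >= p))         # correction only inflates
  expect_true(all(diff(d) > 0))    # strictly increasing
})

test_that("the worked two-codon example gives the textbook record", {
  rec <- estimate_ks("GCTGCT", "GCCGCT")
  expect_equal(rec$S, 2)
  expect_equal(rec$N, 4)
  expect_equal(rec$Sd, 1)
  expect_equal(rec$Nd, 0)
  expect_equal(rec$pS, 0.5)
  expect_equal(rec$Ks, 0.8239592, tolerance = 1e-6)
  expect_equal(rec$Ka, 0)
  expect_equal(rec$flag, "ok")
})

test_that("(S, N, Sd, Nd) equal brute-force enumeration on random pairs", {
  set.seed(421)
  for (rep in 1:1000) {
    n_cod <- sample(1:2, 1L)
    c1 <- random_sense_codons(n_cod)
    c2 <- random_sense_codons(n_cod)
    expected <- oracle_pair_stats(c1, c2)
    rec <- suppressWarnings(
      estimate_ks(paste(c1, collapse = ""), paste(c2, collapse = "")))
    expect_equal(rec$S, expected[["S"]], tolerance = 1e-9)
    expect_equal(rec$N, expected[["N"]], tolerance = 1e-9)
    expect_equal(rec$Sd, expected[["Sd"]], tolerance = 1e-9)
    expect_equal(rec$Nd, expected[["Nd"]], tolerance = 1e-9)
    expect_equal(rec$codons_used, expected[["codons_used"]])
  }
})

test_that("estimation is symmetric and conserves site totals", {
  set.seed(77)
  for (rep in 1:25) {
    s1 <- paste(random_sense_codons(40), collapse = "")
    s2 <- paste(random_sense_codons(40), collapse = "")
    a <- suppressWarnings(estimate_ks(s1, s2))
    b <- suppressWarnings(estimate_ks(s2, s1))
    for (col in c("codons_used", "S", "N", "Sd", "Nd", "pS", "pN",
                  "Ka", "Ks", "flag"))
      expect_equal(a[[col]], b[[col]])
    expect_equal(a$S + a$N, 3 * a$codons_used, tolerance = 1e-6)
    if (a$flag == "ok") expect_gte(a$Ks, a$pS)
  }
})

test_that("identical sequences give zero divergence", {
  s <- paste(random_sense_codons(300), collapse = "")
  rec <- estimate_ks(s, s)
  expect_equal(rec$Ks, 0)
  expect_equal(rec$Ka, 0)
  expect_equal(rec$flag, "ok")
})

test_that("gap and ambiguous codons are skipped pairwise", {
  # first codon has a gap in seq1, third an N in seq2: only codon 2 usable
  rec <- estimate_ks("GC-GCTAAA", "GCCGCTANA")
  expect_equal(rec$codons_used, 1L)
  expect_equal(rec$S, 1)
  expect_equal(rec$Sd, 0)
})

test_that("stop codons invalidate their column, or the pair in strict mode", {
  expect_warning(rec <- estimate_ks("TAAGCT", "TGAGCT"), "stop")
  expect_equal(rec$codons_used, 1L)
  expect_error(estimate_ks("TAAGCT", "TGAGCT", strict_stops = TRUE), "stop")
})

test_that("saturated pairs are flagged with non-finite Ks", {
  # every column is one synonymous difference at a 4-fold site: pS = 1
  rec <- estimate_ks("GGTGGT", "GGAGGC")
  expect_equal(rec$pS, 1)
  expect_equal(rec$flag, "saturated")
  expect_false(is.finite(rec$Ks))
})

test_that("an all-Met/Trp pair has no synonymous sites and is undefined", {
  rec <- estimate_ks("ATGTGG", "ATGTGG")
  expect_equal(rec$S, 0)
  expect_equal(rec$flag, "undefined")
})

test_that("batch estimation preserves order and isolates failures", {
  expect_equal(nrow(batch_ks(list())), 0L)
  pairs <- list(
    list(seq1 = "GCTGCT", seq2 = "GCCGCT", gene_ids = c("g1", "r1")),
    list(seq1 = "GGTGGT", seq2 = "GGAGGC", gene_ids = c("g2", "r2")),
    list(seq1 = "GCT", seq2 = "GCTGCT", gene_ids = c("g3", "r3")))
  tab <- suppressWarnings(batch_ks(pairs))
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$gene1, c("g1", "g2", "g3"))
  expect_equal(tab$flag, c("ok", "saturated", "undefined"))
})
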