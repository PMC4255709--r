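test_that("scan finds forward, reverse and overlapping occurrences", {
  occ <- scan_motif(c(a = "ACGCGCA"), "CGCGC")
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$offset, 1L)
  expect_equal(occ$strand, "+")

  occ <- scan_motif(c(a = "CGCGCGC"), "CGCGC", strands = "forward")
  expect_equal(occ$offset, c(0L, 2L))

  # GCGCG carries CGCGC only on the reverse strand
  occ <- scan_motif(c(a = "GCGCG"), "CGCGC")
  expect_equal(occ$strand, "-")
  expect_equal(nrow(scan_motif(c(a = "GCGCG"), "CGCGC", strands = "forward")), 0L)
})

test_that("IUPAC codes match their base sets and N never matches", {
  expect_equal(nrow(scan_motif(c(a = "ACGCGCG"), "MCGCGCS")), 1L)
  expect_equal(nrow(scan_motif(c(a = "TCGCGCA"), "MCGCGCS")), 0L)
  expect_equal(nrow(scan_motif(c(a = "CGNGC"), "CGCGC")), 0L)
  expect_equal(nrow(scan_motif(c(a = "CGNGCGC"), "CG")), 2L)
  expect_error(scan_motif(c(a = "ACGT"), "CGX"), "IUPAC")
})

test_that("both-strand count = forward(pattern) + forward(revcomp)", {
  withr::local_seed(31)
  for (motif in c("TGCCGC", "CGCGC", "MCGCGCS")) {
    rc <- paste(rev(chartr("ACGTMSK", "TGCAKSM",
                           strsplit(motif, "")[[1]])), collapse = "")
    for (i in 1:10) {
      s <- c(x = random_dna(300, gc = 0.65))
      both <- nrow(scan_motif(s, motif))
      fwd <- nrow(scan_motif(s, motif, strands = "forward"))
      rev_ <- nrow(scan_motif(s, rc, strands = "forward"))
      expect_equal(both, fwd + rev_)
    }
  }
})

test_that("per-sequence counts agree with an independent regex oracle", {
  withr::local_seed(8)
  seqs <- vapply(1:100, function(i) random_dna(sample(100:400, 1), gc = 0.6),
                 character(1))
  names(seqs) <- paste0("s", 1:100)
  for (motif in c("TGCCGC", "CGCGC")) {
    counts <- per_sequence_counts(seqs, motif)
    oracle <- vapply(seqs, count_occurrences_oracle, numeric(1), motif = motif)
    expect_equal(counts$count, unname(oracle))
  }
})

test_that("presence fraction and density follow their definitions", {
  seqs <- c(a = "ACGCGCA", b = "TTTTTTT")
  expect_equal(presence_fraction(seqs, "CGCGC"), 50)
  expect_equal(presence_fraction(c(a = "ACGCGCA", b = "GCGCGTT"), "CGCGC"), 100)
  # presence invariant to duplicating every sequence
  dup <- c(seqs, stats::setNames(seqs, c("a2", "b2")))
  expect_equal(presence_fraction(dup, "CGCGC"), 50)
  expect_error(presence_fraction(character(0), "CG"), "no sequences")

  s1k <- paste0(paste(rep("A", 970), collapse = ""),
                "TGCCGCTGCCGCTGCCGCTGCCGC", "AAAAAA")
  st <- motif_stats(c(x = s1k), "TGCCGC", background_density = 0.5)
  expect_equal(st$density, 4.0)
  expect_equal(st$relative_density, 8.0)
})

test_that("pooled density is count/length pooled, not mean of densities", {
  seqs <- c(a = paste0("TGCCGC", paste(rep("A", 94), collapse = "")),  # 100 bp
            b = paste(rep("T", 900), collapse = ""))                   # 900 bp
  st <- motif_stats(seqs, "TGCCGC")
  expect_equal(st$density, 1000 * 1 / 1000)
  expect_false(isTRUE(all.equal(st$density, mean(c(10, 0)))))
})

test_that("shuffle reduction is exactly zero for a dinucleotide motif", {
  sim <- sim_cgi_seqs(20, c(200, 400), cpg_per_kbp = 80, gc = 0.6, seed = 13)
  red <- shuffle_reduction(sim$seqs, "CG", seed = 5)
  expect_equal(red$occurrence_reduction_pct, 0)
  expect_equal(red$zero_before, red$zero_after)
})

test_that("shuffle reduction is reproducible and bounded on enriched sets", {
  sim <- sim_cgi_seqs(40, c(400, 600), cpg_per_kbp = 80, gc = 0.6,
                      motifs = list(list(pattern = "CGCGC", count = 3)),
                      seed = 17)
  red1 <- shuffle_reduction(sim$seqs, "CGCGC", seed = 23)
  red2 <- shuffle_reduction(sim$seqs, "CGCGC", seed = 23)
  expect_identical(red1, red2)
  expect_true(red1$occurrence_reduction_pct > 0)
  expect_gte(red1$zero_after, red1$zero_before)
})

test_that("local density control is 100% when distributions coincide", {
  # a sequence set whose motif occurrences survive shuffling unchanged in
  # count can still move bins; instead verify the trivial identity directly:
  # comparing a set against itself (seeded shuffle yielding the identical
  # multiset) is emulated by a motif equal to a single dinucleotide, whose
  # occurrence count is shuffle-invariant
  sim <- sim_cgi_seqs(10, c(200, 300), cpg_per_kbp = 90, gc = 0.6, seed = 3)
  ctl <- local_density_control(sim$seqs, "CG", window = 50, seed = 11)
  expect_true(ctl$defined)
  expect_true(ctl$explained_pct > 80)  # CpG content is preserved by design
  # no occurrences at all -> undefined
  ctl0 <- local_density_control(c(a = "TTTTTTTTTT"), "CGCGC", seed = 1)
  expect_false(ctl0$defined)
  expect_true(is.na(ctl0$explained_pct))
  expect_error(local_density_control(sim$seqs, "CGCGC", window = 2, seed = 1),
               "window")
})

test_that("embedded motif occurrences are largely independent of CpG density", {
  # motifs placed uniformly (independent of CpG-dense windows) are mostly not
  # explained by local CpG density
  sim <- sim_cgi_seqs(60, c(400, 600), cpg_per_kbp = 40, gc = 0.5,
                      motifs = list(list(pattern = "TGCCGC", count = 3,
                                         mode = "independent")),
                      seed = 29)
  ctl <- local_density_control(sim$seqs, "TGCCGC", window = 100, seed = 31)
  expect_true(ctl$explained_pct < 40)
})
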