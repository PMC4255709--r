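tr <- function(chrom, start, end, strand) {
  data.frame(chrom = chrom, start = start, end = end, strand = strand)
}
cgi <- function(start, end, name = "c1", chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end, name = name)
}

test_that("the four location rules classify single-transcript layouts", {
  t_plus <- tr("chr1", 5200, 15200, "+")  # TSS 5200, window [4200, 6200)
  expect_equal(classify_cgis(cgi(5100, 5400), t_plus)$final_class,
               "promoter_associated")
  t_long <- tr("chr1", 2000, 20000, "+")
  expect_equal(classify_cgis(cgi(10000, 10400), t_long)$final_class,
               "intragenic_like")
  # distal: overlaps [20000, 21000)
  expect_equal(classify_cgis(cgi(20500, 20900), t_long)$final_class,
               "intragenic_like")
  # minus strand: TSS at end, downstream window left of start
  t_minus <- tr("chr1", 2000, 20000, "-")
  expect_equal(classify_cgis(cgi(19500, 19900), t_minus)$final_class,
               "promoter_associated")
  expect_equal(classify_cgis(cgi(1200, 1600), t_minus)$final_class,
               "intragenic_like")  # downstream of TES (= start)
  # strandless transcript: end-associated near either end
  t_un <- tr("chr1", 2000, 20000, "*")
  expect_equal(classify_cgis(cgi(1500, 1900), t_un)$final_class,
               "end_associated")
  expect_equal(classify_cgis(cgi(20200, 20600), t_un)$final_class,
               "end_associated")
  # no transcript overlap at all
  expect_equal(classify_cgis(cgi(40000, 40400), t_plus)$final_class,
               "transcript_free")
  expect_equal(classify_cgis(cgi(100, 400), tr("chr2", 0, 1000, "+")[0, ])$final_class,
               "transcript_free")
})

test_that("conflicting labels make the classification ambiguous", {
  # promoter window of transcript A plus intragenic in transcript B
  t2 <- rbind(tr("chr1", 10000, 20000, "+"), tr("chr1", 8000, 30000, "+"))
  got <- classify_cgis(cgi(9900, 10200), t2)
  expect_equal(got$final_class, "ambiguous")
  expect_match(got$labels, "intragenic")
  expect_match(got$labels, "promoter_associated")
  # intragenic + distal_intragenic stays unambiguous
  t3 <- rbind(tr("chr1", 2000, 20000, "+"), tr("chr1", 1000, 9500, "+"))
  got <- classify_cgis(cgi(9700, 10100), t3)
  expect_equal(got$final_class, "intragenic_like")
})

test_that("classification is invariant to transcript order", {
  t2 <- rbind(tr("chr1", 10000, 20000, "+"), tr("chr1", 8000, 30000, "+"),
              tr("chr1", 40000, 50000, "*"))
  a <- classify_cgis(cgi(9900, 10200), t2)
  b <- classify_cgis(cgi(9900, 10200), t2[c(3, 1, 2), ])
  expect_equal(a$final_class, b$final_class)
  expect_equal(a$labels, b$labels)
})

test_that("body overlap without any label is flagged, not mislabelled", {
  # CGI straddles the transcript 3' boundary outside every window
  t_plus <- tr("chr1", 2000, 20000, "+")
  got <- classify_cgis(cgi(19900, 21300), t_plus)  # spans end, beyond window
  expect_true(got$boundary_overlap ||
                got$final_class == "intragenic_like")  # distal window overlap
  got <- classify_cgis(cgi(1500, 2500), t_plus)  # spans 5' boundary, PA window
  expect_equal(got$final_class, "promoter_associated")
})

test_that("generated layouts are classified to 100% truth agreement", {
  lay <- sim_layout(n_per_class = 3, seed = 71)
  got <- classify_cgis(lay$cgis, lay$transcripts)
  truth <- lay$truth$class[match(got$cgi_id, lay$truth$cgi_id)]
  expect_equal(got$final_class, truth)
  # classes partition the input: one final class per CGI
  expect_equal(nrow(got), nrow(lay$cgis))
  expect_true(all(got$final_class %in%
                    c("promoter_associated", "intragenic_like",
                      "end_associated", "ambiguous", "transcript_free")))
})

test_that("promoters require CGI and H3K4me3 support and merge", {
  trs <- rbind(tr("chr1", 10000, 20000, "+"),   # TSS 10000
               tr("chr1", 11500, 22000, "+"),   # TSS 11500 (window overlaps)
               tr("chr1", 50000, 60000, "+"))   # TSS 50000, no H3K4me3
  cgis_u <- cgi(9800, 10200, "u1")
  cgis_u <- rbind(cgis_u, cgi(11400, 11800, "u2"), cgi(49800, 50300, "u3"))
  h3k4 <- data.frame(chrom = "chr1", start = c(9500, 11000),
                     end = c(10500, 12000))
  prom <- define_promoters(trs, cgis_u, h3k4)
  # first two windows [9000,11000) and [10500,12500) merge into one
  expect_equal(nrow(prom), 1L)
  expect_equal(prom$start, 9000)
  expect_equal(prom$end, 12500)
})

test_that("methylation-state calling applies thresholds and coverage filter", {
  expect_equal(call_methylation_state(10, 20), "unmethylated")
  expect_equal(call_methylation_state(85, 20), "methylated")
  expect_equal(call_methylation_state(50, 20), "intermediate")
  expect_equal(call_methylation_state(10, 3), "no_call")
  # boundaries are strict (<low, >high)
  expect_equal(call_methylation_state(20, 20), "intermediate")
  expect_equal(call_methylation_state(80, 20), "intermediate")
  expect_equal(call_methylation_state(c(5, 95, 50), c(10, 10, 2)),
               c("unmethylated", "methylated", "no_call"))
  expect_error(call_methylation_state(120, 10), "within")
  expect_error(call_methylation_state(50, 10, low = 80, high = 20))
})

test_that("crosstab excludes ambiguous CGIs and row-normalises", {
  df <- data.frame(
    final_class = c("promoter_associated", "promoter_associated",
                    "intragenic_like", "ambiguous"),
    meth_state = c("unmethylated", "unmethylated", "methylated", "methylated"))
  ct <- class_state_crosstab(df)
  expect_equal(sum(ct$counts), 3)
  expect_equal(ct$counts["promoter_associated", "unmethylated"], 2,
               ignore_attr = TRUE)
  expect_equal(ct$percent["promoter_associated", "unmethylated"], 100,
               ignore_attr = TRUE)
  empty <- class_state_crosstab(df[0, ])
  expect_equal(sum(empty$counts), 0)
})
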