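fixture_genes <- function() {
  suppressMessages(read_gene_table(promoccupy_example("table2_genes.tsv")))
}
fixture_peaks <- function() {
  suppressMessages(read_peaks(promoccupy_example("table2_peaks_treatment.broadPeak"),
                              name = "KL"))
}

test_that("promoter windows are strand-aware, 3300 bp, TSS-anchored", {
  g <- data.frame(gene_id = c("p", "m"), symbol = c("P", "M"),
                  chrom = "chr1", start = c(137277488, 65201025),
                  end = c(137299726, 65262463), strand = c("+", "-"))
  w <- promoter_window(g)
  expect_equal(w$end - w$start, c(3300, 3300))
  # plus strand: [tss - 3000, tss + 300)
  expect_equal(c(w$start[1], w$end[1]), c(137274488, 137277788))
  # minus strand: TSS is the last base; window extends 3000 bp to higher coords
  expect_equal(w$tss[2], 65262462)
  expect_equal(c(w$start[2], w$end[2]), c(65262163, 65265463))
  # a gene with 0-based tss 3000 fills [0, 3300) exactly
  g2 <- data.frame(gene_id = "e", symbol = "E", chrom = "chr1",
                   start = 3000, end = 5000, strand = "+")
  expect_equal(unlist(promoter_window(g2)[c("start", "end")],
                      use.names = FALSE), c(0, 3300))
  # off-chromosome windows are clamped with a warning
  g3 <- data.frame(gene_id = "c", symbol = "C", chrom = "chr1",
                   start = 1000, end = 5000, strand = "+")
  expect_warning(wc <- promoter_window(g3), "clamped")
  expect_equal(wc$start, 0)
  expect_error(promoter_window(g2, upstream = 0, downstream = 0))
})

test_that("window length is upstream + downstream on either strand", {
  withr::with_seed(31, {
    for (i in 1:20) {
      up <- sample(0:5000, 1); dn <- sample(0:1000, 1)
      if (up + dn == 0) dn <- 300
      g <- data.frame(gene_id = "g", symbol = "G", chrom = "chr1",
                      start = sample(10000:20000, 1), strand = sample(c("+", "-"), 1))
      g$end <- g$start + sample(1000:5000, 1)
      w <- suppressWarnings(promoter_window(g, up, dn))
      if (w$start > 0) expect_equal(w$end - w$start, up + dn)
    }
  })
})

test_that("occupancy of published loci reproduces printed overlaps", {
  genes <- fixture_genes()
  occ <- promoter_occupancy(genes, fixture_peaks())
  # multi-peak promoter: the two Wnt4 peaks contribute 244 + 846 bp
  wnt4 <- occ[occ$symbol == "Wnt4", ]
  expect_equal(wnt4$overlap_bp, 1090)
  expect_equal(wnt4$percent, 33)
  expect_equal(wnt4$n_peaks, 2L)
  # minus-strand gene with a barely-overlapping peak
  frzb <- occ[occ$symbol == "Frzb", ]
  expect_equal(frzb$overlap_bp, 103)
  expect_equal(frzb$percent, 3)
})

test_that("occupancy edge cases: empty set, full span, absent chromosome", {
  g <- data.frame(gene_id = "g", symbol = "G", chrom = "chr9",
                  start = 50000, end = 60000, strand = "+")
  expect_equal(promoter_occupancy(g, peak_set())$overlap_bp, 0)
  full <- peak_set(genomic_intervals("chr9", 40000, 60000))
  expect_equal(promoter_occupancy(g, full)$percent, 100)
  elsewhere <- peak_set(genomic_intervals("chr10", 40000, 60000))
  expect_equal(promoter_occupancy(g, elsewhere)$percent_raw, 0)
})

test_that("percent is invariant under splitting a peak into abutting halves", {
  withr::with_seed(32, {
    g <- data.frame(gene_id = "g", symbol = "G", chrom = "chr1",
                    start = 50000, end = 60000, strand = "-")
    for (i in 1:20) {
      s <- sample(48000:62000, 1); len <- sample(200:4000, 1)
      whole <- peak_set(genomic_intervals("chr1", s, s + len))
      cut <- s + sample(seq_len(len - 1), 1)
      halves <- peak_set(genomic_intervals(rep("chr1", 2), c(s, cut),
                                           c(cut, s + len)))
      expect_equal(promoter_occupancy(g, halves)$percent_raw,
                   promoter_occupancy(g, whole)$percent_raw)
    }
  })
})

test_that("percents are invariant under coordinate reflection + strand flip", {
  genes <- fixture_genes()
  peaks <- fixture_peaks()
  C <- 2e8  # larger than any fixture coordinate
  refl_genes <- transform(genes, start = C - end, end = C - start,
                          strand = ifelse(strand == "+", "-", "+"))
  refl_peaks <- peak_set(data.frame(chrom = peaks$peaks$chrom,
                                    start = C - peaks$peaks$end,
                                    end = C - peaks$peaks$start))
  orig <- promoter_occupancy(genes, peaks)
  refl <- promoter_occupancy(refl_genes, refl_peaks)
  expect_equal(refl$percent_raw, orig$percent_raw)
})

test_that("overlap_bp matches the per-base oracle on random configurations", {
  withr::with_seed(33, {
    for (i in 1:200) {
      strand <- sample(c("+", "-"), 1)
      gs <- sample(6000:90000, 1)
      g <- data.frame(gene_id = "g", symbol = "G", chrom = "chrT",
                      start = gs, end = gs + sample(500:5000, 1),
                      strand = strand)
      pk <- random_intervals(sample(1:12, 1), max_coord = 1e5, max_len = 3000)
      occ <- promoter_occupancy(g, peak_set(pk))
      w <- promoter_window(g)
      expect_equal(occ$overlap_bp,
                   brute_window_overlap("chrT", w$start, w$end, pk))
    }
  })
})

test_that("treatment-specific peaks require zero control overlap by default", {
  tr <- peak_set(genomic_intervals(rep("chr1", 3), c(0, 100, 200),
                                   c(50, 150, 260)), name = "t")
  expect_equal(n_peaks(treatment_specific_peaks(tr, peak_set())), 3)
  expect_equal(n_peaks(treatment_specific_peaks(tr, tr)), 0)
  # a single shared base pair excludes the peak
  ctl <- peak_set(genomic_intervals("chr1", 49, 60))
  kept <- treatment_specific_peaks(tr, ctl)
  expect_equal(kept$peaks$start, c(100, 200))
  # the fractional-overlap relaxation keeps it
  relaxed <- treatment_specific_peaks(tr, ctl, max_control_overlap_frac = 0.1)
  expect_equal(n_peaks(relaxed), 3)
})

test_that("report keeps treatment-only occupied promoters in gene order", {
  genes <- fixture_genes()
  tr <- fixture_peaks()
  rep0 <- occupancy_report(genes, tr, peak_set(name = "control"))
  expect_equal(rep0$symbol, genes$symbol)
  expect_equal(rep0$locus, format_locus(genes))
  # a control peak on one promoter removes exactly that row
  ctl <- peak_set(genomic_intervals("chr4", 137274700, 137274800))
  rep1 <- occupancy_report(genes, tr, ctl)
  expect_false("Wnt4" %in% rep1$symbol)
  expect_equal(nrow(rep1), 13)
  # genes with zero treatment overlap are excluded
  extra <- rbind(genes, data.frame(gene_id = "gX", symbol = "NoPeak",
                                   chrom = "chr7", start = 1e6, end = 2e6,
                                   strand = "+"))
  rep2 <- occupancy_report(extra, tr, peak_set(name = "control"))
  expect_false("NoPeak" %in% rep2$symbol)
})
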