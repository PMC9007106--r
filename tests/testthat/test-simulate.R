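small_spec <- function(seed = 1, n_genes = 6,
                       fractions = c(0.3, 0.5, 0, 0.08, 0.9, 0.25),
                       treatment_only = TRUE, n_bg = 8) {
  sim_spec(seed = seed, chrom_sizes = c(chrS = 1.2e6), n_genes = n_genes,
           planted = data.frame(gene = seq_along(fractions),
                                fraction = fractions,
                                treatment_only = treatment_only),
           background_peaks = list(n = n_bg, min_len = 200, max_len = 1200))
}

test_that("generators are pure functions of the spec (seed fixed => identical)", {
  s <- small_spec(seed = 9)
  g1 <- simulate_annotation(s); g2 <- simulate_annotation(s)
  expect_identical(g1, g2)
  p1 <- simulate_peaksets(s, g1); p2 <- simulate_peaksets(s, g2)
  expect_identical(p1, p2)
  expect_identical(simulate_ct(s)$ct, simulate_ct(s)$ct)
  expect_identical(simulate_fiber_areas(s), simulate_fiber_areas(s))
  # a different seed changes the draws
  expect_false(identical(simulate_annotation(small_spec(seed = 10)), g1))
  # generators leave the caller's RNG stream untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulate_annotation(s)); after <- runif(1)
  expect_identical(before, after)
})

test_that("written simulations are byte-identical under a fixed seed", {
  s <- small_spec(seed = 4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- suppressMessages(write_simulation(s, d1))
  p2 <- suppressMessages(write_simulation(s, d2))
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
})

test_that("annotation packing respects clearance or fails loudly", {
  g <- simulate_annotation(small_spec(seed = 2))
  expect_equal(nrow(g), 6)
  expect_true(all(g$strand %in% c("+", "-")))
  # promoter windows never collide between genes
  w <- promoter_window(g)
  expect_equal(covered_length(w), sum(w$end - w$start))
  none <- data.frame(gene = integer(), fraction = numeric(),
                     treatment_only = logical())
  expect_equal(nrow(simulate_annotation(sim_spec(n_genes = 0, planted = none))), 0)
  tiny <- sim_spec(chrom_sizes = c(chrS = 2e4), n_genes = 10, planted = none)
  expect_error(simulate_annotation(tiny), "infeasible packing")
})

test_that("planted peaks realize the intended overlap exactly", {
  s <- small_spec(seed = 3)
  g <- simulate_annotation(s)
  ps <- simulate_peaksets(s, g)
  occ <- promoter_occupancy(g, ps$treatment)
  tr <- ps$truth
  expect_equal(occ$overlap_bp[match(tr$gene_id, occ$gene_id)], tr$planted_bp)
  expect_equal(occ$percent[match(tr$gene_id, occ$gene_id)],
               tr$expected_percent)
  # the zero-fraction gene received no peak
  expect_equal(tr$planted_bp[tr$fraction == 0], 0)
})

test_that("shared and control-matched peaks vanish from the differential set", {
  s <- small_spec(seed = 6, treatment_only = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))
  g <- simulate_annotation(s)
  ps <- simulate_peaksets(s, g)
  sp <- treatment_specific_peaks(ps$treatment, ps$control)
  # background peaks are shared, planted non-treatment-only peaks duplicated:
  # only the treatment-only planted peaks survive
  keep <- ps$truth$treatment_only & ps$truth$planted_bp >= 1
  expect_equal(n_peaks(sp), sum(keep))
  rep <- occupancy_report(g, sp, ps$control)
  expect_equal(rep$gene_id, ps$truth$gene_id[keep])
  expect_equal(rep$percent, ps$truth$expected_percent[keep])
  # duplicating every treatment peak into control empties the differential set
  dup <- peak_set(ps$treatment$peaks, name = "dup")
  expect_equal(n_peaks(treatment_specific_peaks(ps$treatment, dup)), 0)
})

test_that("coverage is background everywhere and enriched inside peaks", {
  s <- small_spec(seed = 7)
  g <- simulate_annotation(s)
  ps <- simulate_peaksets(s, g)
  cov <- simulate_coverage(s, ps$treatment)
  pk <- ps$treatment$peaks[1, ]
  center <- floor((pk$start + pk$end) / 2)
  v <- bin_density(cov, pk$chrom, center, flank = 1000, bin_size = 50)
  expect_equal(max(v), 5)   # background 1 x enrichment 5
  expect_equal(v[1], 1, tolerance = 1e-9)
  # enrichment factor 1 gives a uniform track
  s1 <- small_spec(seed = 7)
  s1$coverage$enrichment <- 1
  cov1 <- simulate_coverage(s1, ps$treatment)
  v1 <- bin_density(cov1, pk$chrom, center, flank = 1000, bin_size = 50)
  expect_equal(v1, rep(1, 40))
})

test_that("fiber generator matches its lognormal parameters", {
  s <- sim_spec(seed = 8, fiber = list(groups = c("Wt", "KLTg"),
                                       meanlog = c(log(600), log(420)),
                                       sdlog = c(0, 0), n = c(50, 50)))
  fa <- simulate_fiber_areas(s)
  expect_equal(fa$Wt, rep(600, 50))
  expect_equal(fa$KLTg, rep(420, 50))
  big <- sim_spec(seed = 8, fiber = list(groups = c("Wt", "KLTg"),
                                         meanlog = c(log(600), log(420)),
                                         sdlog = c(0.45, 0.45), n = c(1e4, 1e4)))
  fb <- simulate_fiber_areas(big)
  ratio <- csa_stats(fb$KLTg)$mean / csa_stats(fb$Wt)$mean
  expect_equal(ratio, 0.7, tolerance = 0.02)
})

test_that("simulated files re-enter the pipeline through the readers", {
  s <- small_spec(seed = 11)
  d <- withr::local_tempdir()
  paths <- suppressMessages(write_simulation(s, d))
  g <- suppressMessages(read_gene_table(paths[["genes"]]))
  tr <- suppressMessages(read_peaks(paths[["treatment"]], name = "treatment"))
  ctl <- suppressMessages(read_peaks(paths[["control"]], name = "control"))
  truth <- utils::read.csv(paths[["truth"]])
  rep <- occupancy_report(g, treatment_specific_peaks(tr, ctl), ctl)
  keep <- truth$treatment_only & truth$planted_bp >= 1
  expect_equal(rep$gene_id, truth$gene_id[keep])
  expect_equal(rep$percent, truth$expected_percent[keep])
  cov <- suppressMessages(read_bedgraph(paths[["coverage"]]))
  expect_s3_class(cov, "coverage_track")
})
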