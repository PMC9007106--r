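# Seeded generators for every input the pipeline consumes, with recorded
# ground truth. Planted promoter overlaps are realized as one contiguous
# peak fully inside the promoter window covering exactly
# round(fraction * window) bp, so the intended percent is exact by
# construction. All generators are pure functions of the spec: the seed is
# threaded through withr::with_seed (distinct sub-streams per generator)
# and never touches the caller's RNG state.

.SEED_ANNOT <- 101L
.SEED_PEAKS <- 202L
.SEED_CT <- 303L
.SEED_FIBER <- 404L

#' Simulation specification
#'
#' Bundles every tunable of the synthetic-data generators. The defaults
#' emulate the study design the package targets: one ~3 Mb chromosome
#' carrying 14 Wnt-pathway-like genes whose promoters are planted with
#' the published occupancy fractions (treatment-only), background peaks
#' away from all promoters, 5-fold read-density enrichment inside peaks
#' over a unit background, a two-group qPCR design (n = 5 per group,
#' three stable reference genes, Ct noise SD 0.2 cycles), and lognormal
#' fiber areas with a 30% smaller treated-group mean (~500 fibers per
#' group, the study's per-section sampling floor).
#'
#' @param seed Integer seed; fixing it makes every generator
#'   byte-reproducible.
#' @param chrom_sizes Named numeric vector of chromosome sizes (bp).
#' @param n_genes Number of genes to place.
#' @param planted Data frame with columns `gene` (index into the
#'   annotation), `fraction` (intended promoter-overlap fraction in
#'   `[0, 1]`), `treatment_only` (logical).
#' @param background_peaks List `n`, `min_len`, `max_len`: count and
#'   length range (bp) of peaks placed >= 3300 bp away from every
#'   promoter, present in both conditions.
#' @param coverage List `background`, `enrichment`: read depth is
#'   `background` everywhere and `background * enrichment` inside peaks.
#' @param ct List `groups` (two labels), `n_per_group`, `reference_ct`
#'   (named baseline Cts of reference genes), `target_ct` (named baseline
#'   Cts of target genes), `fold_change` (named fold-changes applied to
#'   the second group), `noise_sd` (Gaussian Ct noise, cycles).
#' @param fiber List `groups`, `meanlog`, `sdlog`, `n` (parallel vectors;
#'   lognormal area model per group, areas in um^2).
#' @param upstream,downstream Promoter window extents used when planting.
#' @return An object of class `sim_spec`.
#' @examples
#' spec <- sim_spec(seed = 7)
#' genes <- simulate_annotation(spec)
#' @export
sim_spec <- function(seed = 1,
                     chrom_sizes = c(chr1 = 3e6),
                     n_genes = 14,
                     planted = data.frame(
                       gene = 1:14,
                       fraction = c(0.33, 0.40, 0.17, 0.43, 0.10, 0.03, 0.29,
                                    0.14, 0.39, 0.18, 0.46, 0.38, 0.20, 0.08),
                       treatment_only = TRUE),
                     background_peaks = list(n = 40, min_len = 200,
                                             max_len = 1500),
                     coverage = list(background = 1, enrichment = 5),
                     ct = list(groups = c("vehicle", "klotho"),
                               n_per_group = 5,
                               reference_ct = c(Srp14 = 20, Hprt1 = 22,
                                                Rnps1 = 24),
                               target_ct = c(Wnt4 = 26, Wnt9a = 26,
                                             Wnt10a = 26),
                               fold_change = c(Wnt4 = 0.5, Wnt9a = 0.5,
                                               Wnt10a = 0.5),
                               noise_sd = 0.2),
                     fiber = list(groups = c("Wt", "KLTg"),
                                  meanlog = c(log(600), log(420)),
                                  sdlog = c(0.45, 0.45),
                                  n = c(500, 500)),
                     upstream = 3000, downstream = 300) {
  stopifnot(length(seed) == 1, is.finite(seed),
            !is.null(names(chrom_sizes)), all(chrom_sizes > 0),
            n_genes >= 0)
  if (nrow(planted)) {
    stopifnot(all(planted$fraction >= 0), all(planted$fraction <= 1),
              all(planted$gene >= 1), all(planted$gene <= n_genes),
              !anyDuplicated(planted$gene))
  }
  structure(list(seed = as.integer(seed), chrom_sizes = chrom_sizes,
                 n_genes = n_genes, planted = planted,
                 background_peaks = background_peaks, coverage = coverage,
                 ct = ct, fiber = fiber, upstream = upstream,
                 downstream = downstream), class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf("<sim_spec> seed %d: %d gene(s) on %d chromosome(s), %d planted promoter(s)\n",
              x$seed, x$n_genes, length(x$chrom_sizes),
              if (is.null(x$planted)) 0L else nrow(x$planted)))
  invisible(x)
}

#' Simulate a gene annotation
#'
#' Places non-overlapping genes (lengths 2-20 kb) along the chromosomes
#' with at least 6.7 kb between neighbors, so every promoter window has
#' >= 3300 bp of clearance from any other gene's window and from the
#' chromosome ends. Strands are Bernoulli(1/2) draws from the seeded
#' stream.
#'
#' @param spec A [sim_spec()].
#' @return Gene data frame in the [read_gene_table()] layout (0-based
#'   half-open coordinates).
#' @export
simulate_annotation <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  wlen <- spec$upstream + spec$downstream
  clearance <- wlen + 3400  # window extent outside the gene + margin
  withr::with_seed(spec$seed + .SEED_ANNOT, {
    rows <- list()
    chrom_i <- 1L
    cursor <- clearance
    for (i in seq_len(spec$n_genes)) {
      len <- round(stats::runif(1, 2000, 20000))
      gap <- round(stats::runif(1, 6700, 12000))
      while (chrom_i <= length(spec$chrom_sizes) &&
             cursor + len + clearance > spec$chrom_sizes[chrom_i]) {
        chrom_i <- chrom_i + 1L
        cursor <- clearance
      }
      if (chrom_i > length(spec$chrom_sizes)) {
        stop(sprintf("infeasible packing: gene %d does not fit in chrom_sizes", i))
      }
      rows[[i]] <- data.frame(
        gene_id = sprintf("SIMG%05d", i), symbol = sprintf("gene%d", i),
        chrom = names(spec$chrom_sizes)[chrom_i], start = cursor,
        end = cursor + len, strand = sample(c("+", "-"), 1),
        stringsAsFactors = FALSE)
      cursor <- cursor + len + gap
    }
    if (length(rows) == 0) {
      return(data.frame(gene_id = character(), symbol = character(),
                        chrom = character(), start = numeric(),
                        end = numeric(), strand = character(),
                        stringsAsFactors = FALSE))
    }
    do.call(rbind, rows)
  })
}

#' Simulate treatment and control peak sets with ground truth
#'
#' Each planted gene receives one treatment peak placed uniformly inside
#' its promoter window covering exactly `round(fraction * window)` bp;
#' genes not flagged `treatment_only` get the identical peak in the
#' control set (so the differential step removes them). Background peaks
#' (shared between the two conditions) are rejection-sampled at least
#' 3300 bp away from every promoter window and free of mutual overlap.
#'
#' @param spec A [sim_spec()].
#' @param genes Annotation from [simulate_annotation()].
#' @return List with `treatment` and `control` ([peak_set()]s) and
#'   `truth` (data frame `gene_id`, `symbol`, `fraction`, `planted_bp`,
#'   `expected_percent`, `treatment_only`).
#' @export
simulate_peaksets <- function(spec, genes) {
  stopifnot(inherits(spec, "sim_spec"))
  wlen <- spec$upstream + spec$downstream
  wins <- if (nrow(genes)) promoter_window(genes, spec$upstream, spec$downstream)
          else NULL
  withr::with_seed(spec$seed + .SEED_PEAKS, {
    tr <- list(); ctl <- list()
    truth <- list()
    pl <- spec$planted
    for (i in seq_len(NROW(pl))) {
      g <- pl$gene[i]
      width <- round_half_up(pl$fraction[i] * wlen)
      truth[[i]] <- data.frame(
        gene_id = genes$gene_id[g], symbol = genes$symbol[g],
        fraction = pl$fraction[i], planted_bp = width,
        expected_percent = round_half_up(100 * width / wlen),
        treatment_only = pl$treatment_only[i], stringsAsFactors = FALSE)
      if (width < 1) next
      off <- sample.int(wlen - width + 1, 1) - 1
      pk <- data.frame(chrom = wins$chrom[g], start = wins$start[g] + off,
                       end = wins$start[g] + off + width,
                       name = sprintf("planted_%s", genes$symbol[g]),
                       stringsAsFactors = FALSE)
      tr[[length(tr) + 1]] <- pk
      if (!pl$treatment_only[i]) ctl[[length(ctl) + 1]] <- pk
    }
    # forbidden zones: promoter windows padded by the window length
    forb <- if (!is.null(wins)) {
      data.frame(chrom = wins$chrom, start = pmax(0, wins$start - wlen),
                 end = wins$end + wlen, stringsAsFactors = FALSE)
    } else data.frame(chrom = character(), start = numeric(), end = numeric())
    placed <- if (length(tr)) do.call(rbind, tr) else
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 stringsAsFactors = FALSE)
    bg <- list()
    nbg <- spec$background_peaks$n %||% 0
    for (j in seq_len(nbg)) {
      len <- round(stats::runif(1, spec$background_peaks$min_len,
                                spec$background_peaks$max_len))
      ok <- FALSE
      for (try in 1:1000) {
        ci <- sample.int(length(spec$chrom_sizes), 1,
                         prob = spec$chrom_sizes / sum(spec$chrom_sizes))
        cn <- names(spec$chrom_sizes)[ci]
        s <- floor(stats::runif(1, 0, spec$chrom_sizes[ci] - len))
        cand <- data.frame(chrom = cn, start = s, end = s + len,
                           stringsAsFactors = FALSE)
        clash <- function(d) nrow(d) > 0 &&
          any(d$chrom == cn & pmin(d$end, s + len) > pmax(d$start, s))
        if (!clash(forb) && !clash(placed) &&
            !(length(bg) && clash(do.call(rbind, bg)))) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place background peak away from promoters")
      cand$name <- sprintf("bg_%d", j)
      bg[[j]] <- cand
    }
    t_peaks <- do.call(rbind, c(tr, bg))
    c_peaks <- do.call(rbind, c(ctl, bg))
    list(treatment = peak_set(t_peaks, name = "treatment"),
         control = peak_set(c_peaks, name = "control"),
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(gene_id = character(), symbol = character(),
                      fraction = numeric(), planted_bp = numeric(),
                      expected_percent = numeric(),
                      treatment_only = logical(), stringsAsFactors = FALSE))
  })
}

#' Simulate a coverage track enriched at peaks
#'
#' Piecewise-constant depth: `background` everywhere and
#' `background * enrichment` inside the (merged) peaks. Deterministic
#' given the spec and peaks.
#'
#' @param spec A [sim_spec()].
#' @param peaks A [peak_set()] to enrich over.
#' @return A [coverage_track()].
#' @export
simulate_coverage <- function(spec, peaks) {
  stopifnot(inherits(spec, "sim_spec"), inherits(peaks, "peak_set"))
  b <- spec$coverage$background
  e <- spec$coverage$enrichment
  m <- merge_intervals(peaks$peaks)
  rows <- list()
  for (cn in names(spec$chrom_sizes)) {
    size <- spec$chrom_sizes[[cn]]
    mc <- m[m$chrom == cn, , drop = FALSE]
    edges <- sort(unique(c(0, size, mc$start, mc$end)))
    seg <- data.frame(chrom = cn, start = edges[-length(edges)],
                      end = edges[-1], stringsAsFactors = FALSE)
    inpeak <- vapply(seq_len(nrow(seg)), function(i) {
      any(mc$start <= seg$start[i] & mc$end >= seg$end[i])
    }, TRUE)
    seg$depth <- ifelse(inpeak, b * e, b)
    rows[[cn]] <- seg[seg$depth > 0, , drop = FALSE]
  }
  coverage_track(do.call(rbind, rows))
}

#' Simulate a qPCR Ct table
#'
#' Reference genes sit at their baseline Cts in every sample; each target
#' gene is shifted by `-log2(fold_change)` cycles in the second group
#' (higher expression means a lower Ct); Gaussian noise of the specified
#' SD is added to every Ct.
#'
#' @param spec A [sim_spec()].
#' @return A [ct_table()].
#' @export
simulate_ct <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  cs <- spec$ct
  stopifnot(length(cs$groups) >= 2)
  withr::with_seed(spec$seed + .SEED_CT, {
    group <- rep(cs$groups, each = cs$n_per_group)
    ns <- length(group)
    genes <- c(names(cs$reference_ct), names(cs$target_ct))
    ct <- matrix(NA_real_, ns, length(genes),
                 dimnames = list(sprintf("%s_%d", group,
                                         sequence(rep(cs$n_per_group,
                                                      length(cs$groups)))),
                                 genes))
    for (g in names(cs$reference_ct)) ct[, g] <- cs$reference_ct[[g]]
    for (g in names(cs$target_ct)) {
      f <- cs$fold_change[[g]] %||% 1
      shift <- ifelse(group == cs$groups[2], -log2(f), 0)
      ct[, g] <- cs$target_ct[[g]] + shift
    }
    if (cs$noise_sd > 0) {
      ct <- ct + matrix(stats::rnorm(length(ct), 0, cs$noise_sd),
                        nrow(ct), ncol(ct))
    }
    ct_table(ct, group = group, reference_genes = names(cs$reference_ct))
  })
}

#' Simulate fiber cross-sectional areas
#'
#' Lognormal draws per group using the spec's `meanlog`/`sdlog`/`n`.
#'
#' @param spec A [sim_spec()].
#' @return Named list of numeric area vectors (um^2), one per group.
#' @export
simulate_fiber_areas <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  fs <- spec$fiber
  withr::with_seed(spec$seed + .SEED_FIBER, {
    out <- lapply(seq_along(fs$groups), function(i) {
      stats::rlnorm(fs$n[i], fs$meanlog[i], fs$sdlog[i])
    })
    names(out) <- fs$groups
    out
  })
}

#' Run every generator and write the files a pipeline run consumes
#'
#' Writes `genes.tsv`, `treatment.broadPeak`, `control.broadPeak`,
#' `coverage.bedGraph`, `ct.csv`, `fibers_<group>.csv` and `truth.csv`
#' into `outdir`.
#'
#' @param spec A [sim_spec()].
#' @param outdir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(spec, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genes <- simulate_annotation(spec)
  ps <- simulate_peaksets(spec, genes)
  cov <- simulate_coverage(spec, ps$treatment)
  ctab <- simulate_ct(spec)
  fib <- simulate_fiber_areas(spec)
  paths <- c(genes = file.path(outdir, "genes.tsv"),
             treatment = file.path(outdir, "treatment.broadPeak"),
             control = file.path(outdir, "control.broadPeak"),
             coverage = file.path(outdir, "coverage.bedGraph"),
             ct = file.path(outdir, "ct.csv"),
             truth = file.path(outdir, "truth.csv"))
  write_gene_table(genes, paths["genes"])
  write_peaks(ps$treatment, paths["treatment"])
  write_peaks(ps$control, paths["control"])
  write_bedgraph(cov, paths["coverage"])
  utils::write.csv(data.frame(sample = rownames(ctab$ct), group = ctab$group,
                              ctab$ct, check.names = FALSE),
                   paths["ct"], row.names = FALSE)
  utils::write.csv(ps$truth, paths["truth"], row.names = FALSE)
  for (g in names(fib)) {
    p <- file.path(outdir, sprintf("fibers_%s.csv", g))
    utils::write.csv(data.frame(area = fib[[g]]), p, row.names = FALSE)
    paths[paste0("fibers_", g)] <- p
  }
  invisible(paths)
}
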