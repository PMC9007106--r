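# The core statistic: percent of a strand-aware promoter window covered by
# the union of broad histone-mark peaks, and the treatment-specific peak
# sets it is computed on.

#' Strand-aware promoter windows
#'
#' The promoter window spans `upstream` bp 5' of the transcription start
#' site (TSS) and `downstream` bp 3' of it along the gene's own
#' orientation, for a total length of `upstream + downstream` (default
#' 3000 + 300 = 3300 bp). The TSS is the 0-based first transcribed base:
#' `start` for plus-strand genes, `end - 1` for minus-strand genes. In
#' internal coordinates the window is `[tss - upstream, tss + downstream)`
#' on the plus strand and `[tss - downstream + 1, tss + upstream + 1)` on
#' the minus strand (the same convention as `GenomicRanges::promoters()`).
#' Windows running off the chromosome start are clamped at 0 with a
#' warning.
#'
#' @param genes Gene data frame ([read_gene_table()]).
#' @param upstream,downstream Non-negative window extents in bp (not both
#'   zero).
#' @return Interval data frame with one window per gene plus `gene_id`,
#'   `symbol`, `strand`, `tss` columns.
#' @examples
#' g <- data.frame(gene_id = "g1", symbol = "G1", chrom = "chr1",
#'                 start = 137277488, end = 137299726, strand = "+")
#' promoter_window(g)
#' @export
promoter_window <- function(genes, upstream = 3000, downstream = 300) {
  stopifnot(upstream >= 0, downstream >= 0, upstream + downstream > 0)
  validate_intervals(genes, what = "gene")
  stopifnot(all(genes$strand %in% c("+", "-")))
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  ws <- ifelse(genes$strand == "+", tss - upstream, tss - downstream + 1)
  we <- ws + upstream + downstream
  if (any(ws < 0)) {
    warning(sprintf("%d promoter window(s) clamped at chromosome start",
                    sum(ws < 0)))
    ws <- pmax(ws, 0)  # end unchanged; a clamped window is shorter
  }
  data.frame(gene_id = genes$gene_id, symbol = genes$symbol,
             chrom = genes$chrom, start = ws, end = we,
             strand = genes$strand, tss = tss, stringsAsFactors = FALSE)
}

#' Promoter occupancy by a peak set
#'
#' For each gene, computes the number of promoter-window base pairs
#' covered by the union of the peaks (peaks are merged first so
#' overlapping or abutting peaks are never double-counted) and the percent
#' of the window covered. `percent` is rounded half-up to an integer, the
#' convention used for published occupancy tables; `percent_raw` is the
#' unrounded value.
#'
#' @inheritParams promoter_window
#' @param peaks A [peak_set()]. A gene on a chromosome absent from the
#'   set has zero overlap.
#' @return Data frame with one row per gene: `gene_id`, `symbol`,
#'   `locus` (printed 1-based closed gene location), `peaks`
#'   (semicolon-joined printed loci of the original peaks intersecting the
#'   window), `n_peaks`, `overlap_bp`, `percent_raw`, `percent`.
#' @export
promoter_occupancy <- function(genes, peaks, upstream = 3000, downstream = 300) {
  win <- promoter_window(genes, upstream, downstream)
  pk <- peaks$peaks
  merged <- merge_intervals(pk)
  res <- lapply(seq_len(nrow(win)), function(i) {
    w <- win[i, ]
    m <- merged[merged$chrom == w$chrom, , drop = FALSE]
    ov <- if (nrow(m)) sum(pmax(0, pmin(m$end, w$end) - pmax(m$start, w$start)))
          else 0
    hits <- pk[pk$chrom == w$chrom &
                 pmin(pk$end, w$end) > pmax(pk$start, w$start), , drop = FALSE]
    list(ov = ov, hits = if (nrow(hits)) paste(format_locus(hits),
                                               collapse = "; ") else "",
         nh = nrow(hits))
  })
  wlen <- win$end - win$start
  data.frame(gene_id = win$gene_id, symbol = win$symbol,
             locus = format_locus(genes),
             peaks = vapply(res, `[[`, "", "hits"),
             n_peaks = vapply(res, `[[`, 0L, "nh"),
             overlap_bp = vapply(res, `[[`, 0, "ov"),
             percent_raw = 100 * vapply(res, `[[`, 0, "ov") / wlen,
             percent = round_half_up(100 * vapply(res, `[[`, 0, "ov") / wlen),
             stringsAsFactors = FALSE)
}

#' Peaks specific to the treatment condition
#'
#' Returns the treatment peaks "found after treatment but not in the
#' control condition". By default a treatment peak is excluded if it
#' shares even a single base pair with any control peak;
#' `max_control_overlap_frac` relaxes this to tolerate up to that fraction
#' of the treatment peak's length overlapping control peaks.
#'
#' @param treatment,control [peak_set()] objects.
#' @param max_control_overlap_frac Highest tolerated fraction of a
#'   treatment peak covered by control peaks (default 0: strict
#'   zero-overlap).
#' @return A [peak_set()] containing the retained treatment peaks, sorted;
#'   the inputs are not modified.
#' @export
treatment_specific_peaks <- function(treatment, control,
                                     max_control_overlap_frac = 0) {
  stopifnot(inherits(treatment, "peak_set"), inherits(control, "peak_set"),
            max_control_overlap_frac >= 0, max_control_overlap_frac <= 1)
  tp <- treatment$peaks
  if (nrow(tp) == 0 || nrow(control$peaks) == 0) {
    return(peak_set(tp, name = paste0(treatment$name, "_specific")))
  }
  cm <- merge_intervals(control$peaks)
  ovfrac <- vapply(seq_len(nrow(tp)), function(i) {
    m <- cm[cm$chrom == tp$chrom[i], , drop = FALSE]
    if (!nrow(m)) return(0)
    ov <- sum(pmax(0, pmin(m$end, tp$end[i]) - pmax(m$start, tp$start[i])))
    ov / (tp$end[i] - tp$start[i])
  }, 0)
  keep <- if (max_control_overlap_frac == 0) ovfrac == 0
          else ovfrac <= max_control_overlap_frac
  peak_set(tp[keep, , drop = FALSE],
           name = paste0(treatment$name, "_specific"))
}

#' Treatment-only promoter occupancy report
#'
#' The headline table of the pipeline: genes whose promoter windows
#' overlap peaks in the treatment condition while showing 0% overlap with
#' any control peak. Rows keep the input gene order and carry the printed
#' gene locus, the overlapping treatment peak loci, and the integer
#' percent of the window covered.
#'
#' @inheritParams promoter_window
#' @param treatment,control [peak_set()] objects.
#' @return Data frame with columns `symbol`, `locus`, `gene_id`, `peaks`,
#'   `overlap_bp`, `percent_raw`, `percent`, filtered to genes with
#'   treatment overlap > 0 bp and control overlap == 0 bp.
#' @examples
#' genes <- read_gene_table(promoccupy_example("table2_genes.tsv"))
#' kl <- read_peaks(promoccupy_example("table2_peaks_treatment.broadPeak"))
#' occupancy_report(genes, kl, peak_set())
#' @export
occupancy_report <- function(genes, treatment, control,
                             upstream = 3000, downstream = 300) {
  stopifnot(nrow(genes) > 0)
  occ_t <- promoter_occupancy(genes, treatment, upstream, downstream)
  occ_c <- promoter_occupancy(genes, control, upstream, downstream)
  keep <- occ_t$overlap_bp > 0 & occ_c$overlap_bp == 0
  out <- occ_t[keep, c("symbol", "locus", "gene_id", "peaks",
                       "overlap_bp", "percent_raw", "percent"), drop = FALSE]
  rownames(out) <- NULL
  out
}
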