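# Peak-centered read-density matrices from step-function coverage, the
# reference-point ("center") mode of the usual ChIP-seq matrix/heatmap
# tooling, computed exactly by integrating the step function over bins.

# exact integral of the depth step function over [a, b) on one chromosome
.integrate_depth <- function(iv, a, b) {
  if (nrow(iv) == 0 || b <= a) return(0)
  # cumulative integral at interval starts
  w <- iv$end - iv$start
  cum <- c(0, cumsum(iv$depth * w))
  int_to <- function(x) {
    k <- findInterval(x, iv$start)
    if (k == 0) return(0)
    cum[k] + iv$depth[k] * max(0, min(x, iv$end[k]) - iv$start[k])
  }
  int_to(b) - int_to(a)
}

#' Mean read depth in fixed-width bins around a reference point
#'
#' Bin `i` (1-based) covers
#' `[center - flank + (i-1) * bin_size, center - flank + i * bin_size)`;
#' its value is the integral of the coverage step function over the bin
#' divided by `bin_size`, i.e. the exact mean depth. Positions off the
#' chromosome (or in coverage gaps) contribute depth 0.
#'
#' @param track A [coverage_track()].
#' @param chrom Chromosome of the reference point.
#' @param center 0-based reference position.
#' @param flank Half-width of the profiled region in bp (`flank > 0`,
#'   divisible by `bin_size`).
#' @param bin_size Bin width in bp.
#' @return Numeric vector of `2 * flank / bin_size` mean depths.
#' @export
bin_density <- function(track, chrom, center, flank = 1000, bin_size = 50) {
  stopifnot(inherits(track, "coverage_track"), flank > 0, bin_size > 0,
            center >= 0)
  if (flank %% bin_size != 0) {
    stop(sprintf("flank (%d) must be divisible by bin_size (%d)",
                 flank, bin_size))
  }
  iv <- track$intervals[track$intervals$chrom == chrom, , drop = FALSE]
  nb <- 2 * flank / bin_size
  edges <- center - flank + bin_size * (0:nb)
  vapply(seq_len(nb), function(i) {
    .integrate_depth(iv, edges[i], edges[i + 1]) / bin_size
  }, 0)
}

#' Peak-centered density matrix
#'
#' One row per peak, centered at `floor((start + end) / 2)`, profiled
#' `flank` bp to each side in `bin_size` bins. With `skip_zeros`, rows
#' whose every bin is exactly zero are removed (and counted in
#' `rows_dropped`), matching the usual practice of excluding uncovered
#' regions from heatmaps. Rows are ordered by descending row mean, ties
#' broken by region id, giving a deterministic heatmap order.
#'
#' @param track A [coverage_track()].
#' @param peaks A non-empty [peak_set()].
#' @param flank Half-width in bp (default 1000, i.e. the +/- 1 kb window).
#' @param bin_size Bin width in bp (default 50).
#' @param skip_zeros Drop all-zero rows (default `TRUE`).
#' @return An object of class `density_matrix`: list with `values`
#'   (regions x bins matrix, row names = region ids), `flank`, `bin_size`,
#'   `rows_dropped`.
#' @export
density_matrix <- function(track, peaks, flank = 1000, bin_size = 50,
                           skip_zeros = TRUE) {
  stopifnot(inherits(peaks, "peak_set"))
  pk <- peaks$peaks
  if (nrow(pk) == 0) stop("density_matrix: empty peak set")
  ids <- if (!is.null(pk$name) && !anyDuplicated(pk$name)) pk$name
         else format_locus(pk)
  centers <- floor((pk$start + pk$end) / 2)
  vals <- t(vapply(seq_len(nrow(pk)), function(i) {
    bin_density(track, pk$chrom[i], centers[i], flank, bin_size)
  }, numeric(2 * flank / bin_size)))
  rownames(vals) <- ids
  dropped <- 0L
  if (skip_zeros) {
    zero <- rowSums(vals != 0) == 0
    dropped <- sum(zero)
    vals <- vals[!zero, , drop = FALSE]
  }
  ord <- order(-rowMeans(vals), rownames(vals))
  structure(list(values = vals[ord, , drop = FALSE], flank = flank,
                 bin_size = bin_size, rows_dropped = dropped),
            class = "density_matrix")
}

#' @export
print.density_matrix <- function(x, ...) {
  cat(sprintf(
    "<density_matrix> %d region(s) x %d bin(s) (flank %d bp, bin %d bp), %d all-zero row(s) dropped\n",
    nrow(x$values), ncol(x$values), x$flank, x$bin_size, x$rows_dropped))
  invisible(x)
}

#' Render a density matrix as a heatmap
#'
#' Presentation only: a base-graphics image of the (row-ordered) matrix
#' with the reference point marked.
#'
#' @param x A `density_matrix`.
#' @param col Color ramp.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.density_matrix <- function(x, col = grDevices::hcl.colors(64, "Blues 3",
                                                               rev = TRUE),
                                ...) {
  nb <- ncol(x$values)
  graphics::image(x = seq(-x$flank + x$bin_size / 2, x$flank, x$bin_size),
                  y = seq_len(nrow(x$values)),
                  z = t(x$values[rev(seq_len(nrow(x$values))), , drop = FALSE]),
                  col = col, xlab = "distance from peak center (bp)",
                  ylab = "peaks", yaxt = "n", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Write a density matrix as CSV
#'
#' @param x A `density_matrix`.
#' @param path Output path. Columns are bin centers relative to the
#'   reference point; the first column holds region ids.
#' @return `path`, invisibly.
#' @export
write_density_matrix <- function(x, path) {
  df <- data.frame(region = rownames(x$values), x$values, check.names = FALSE)
  names(df)[-1] <- seq(-x$flank + x$bin_size / 2, x$flank, x$bin_size)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
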