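# Internal coordinate convention: 0-based half-open [start, end), as in BED.
# Printed loci and gene tables are 1-based closed and converted at the boundary.

# Arithmetic ("half-up") rounding; base round() rounds half to even, which
# does not match printed integer percentages.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a table of genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`
#' (0-based half-open) plus any extra columns passed through. The
#' constructor validates `end > start` and `start >= 0`.
#'
#' @param chrom Character vector of chromosome names (kept verbatim; no
#'   "chr" stripping).
#' @param start,end Integer-valued vectors, 0-based half-open.
#' @param ... Further equal-length columns (e.g. `name`, `score`).
#' @return A data frame with one row per interval.
#' @examples
#' genomic_intervals("chr1", 0, 10)
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer(), ...) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end), ...,
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(!is.finite(x$start) | !is.finite(x$end) |
                 x$start != floor(x$start) | x$end != floor(x$end))
  if (length(bad)) {
    stop(sprintf("%s %d has non-integer coordinates (%s:%s-%s)", what, bad[1],
                 x$chrom[bad[1]], format(x$start[bad[1]]), format(x$end[bad[1]])))
  }
  bad <- which(x$start < 0)
  if (length(bad)) stop(sprintf("%s %d has negative start %d", what, bad[1], x$start[bad[1]]))
  bad <- which(x$end <= x$start)
  if (length(bad)) {
    stop(sprintf("%s %d is empty or inverted: %s:%s-%s", what, bad[1],
                 x$chrom[bad[1]], format(x$start[bad[1]]), format(x$end[bad[1]])))
  }
  invisible(x)
}

# Hyphen variants accepted between coordinates: ASCII "-", Unicode hyphen
# U+2010 (used in the source tables), en dash U+2013.
.locus_re <- "^\\s*([^:[:space:]]+):([0-9]+)\\s*[-‐–]\\s*([0-9]+)\\s*$"

#' Parse printed genomic loci
#'
#' Loci printed as `"chr4:137277489-137299726"` are 1-based closed
#' (Ensembl table convention) and are converted to the internal 0-based
#' half-open representation. Unicode hyphen (U+2010) and en dash are
#' accepted as the coordinate separator.
#'
#' @param text Character vector of locus strings.
#' @return Interval data frame (one row per input string).
#' @examples
#' parse_locus("chr1:1-1")          # single-base interval [0, 1)
#' parse_locus("chr4:137277489-137299726")
#' @seealso [format_locus()] for the inverse.
#' @export
parse_locus <- function(text) {
  text <- as.character(text)
  m <- regmatches(text, regexec(.locus_re, text))
  bad <- which(lengths(m) != 4)
  if (length(bad)) {
    stop(sprintf("malformed locus string: '%s'", text[bad[1]]))
  }
  chrom <- vapply(m, `[`, "", 2L)
  s1 <- suppressWarnings(as.numeric(vapply(m, `[`, "", 3L)))
  e1 <- suppressWarnings(as.numeric(vapply(m, `[`, "", 4L)))
  inv <- which(s1 > e1)
  if (length(inv)) {
    stop(sprintf("inverted coordinates in locus '%s' (start %s > end %s)",
                 text[inv[1]], format(s1[inv[1]]), format(e1[inv[1]])))
  }
  genomic_intervals(chrom, s1 - 1, e1)
}

#' Format intervals as printed 1-based closed loci
#'
#' @param x Interval data frame.
#' @return Character vector like `"chr1:101-200"`.
#' @export
format_locus <- function(x) {
  validate_intervals(x)
  sprintf("%s:%.0f-%.0f", x$chrom, x$start + 1, x$end)
}

#' Interval length in base pairs
#' @param x Interval data frame.
#' @return Numeric vector of lengths (`end - start`).
#' @export
interval_length <- function(x) x$end - x$start

#' Pairwise overlap length between two intervals
#'
#' Element-wise over two interval tables (recycled to a common length).
#' Intervals on different chromosomes overlap by 0 bp; the function is
#' symmetric in its arguments.
#'
#' @param a,b Interval data frames.
#' @return Numeric vector of overlap lengths in bp (>= 0).
#' @examples
#' overlap_length(genomic_intervals("chr1", 0, 10), genomic_intervals("chr1", 5, 15))
#' @export
overlap_length <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  n <- max(nrow(a), nrow(b))
  if (n == 0) return(numeric(0))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  ov <- pmax(0, pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi]))
  ov[a$chrom[ai] != b$chrom[bi]] <- 0
  ov
}

# sorted sweep over one chromosome: merge overlapping/abutting intervals
.merge_one <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  grp <- cumsum(c(TRUE, start[-1] > cummax(end[-length(end)])))
  data.frame(start = unname(tapply(start, grp, min)),
             end = unname(tapply(end, grp, max)))
}

#' Merge intervals into a disjoint sorted union
#'
#' Overlapping and abutting intervals on the same chromosome are merged,
#' so the summed length of the output equals the length of the set union.
#' The operation is idempotent. Extra columns are dropped.
#'
#' @param x Interval data frame.
#' @return Interval data frame, sorted by chromosome then start, pairwise
#'   disjoint and non-abutting.
#' @examples
#' merge_intervals(genomic_intervals(c("chr1", "chr1"), c(0, 5), c(10, 15)))
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(split(x[c("start", "end")], x$chrom), function(d) {
    .merge_one(d$start, d$end)
  })
  chroms <- sort(names(out))
  res <- do.call(rbind, lapply(chroms, function(cc) {
    cbind(chrom = cc, out[[cc]], stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Total covered length of an interval set
#'
#' Length in bp of the union of the intervals (overlaps counted once).
#'
#' @param x Interval data frame.
#' @return Single number, bp.
#' @export
covered_length <- function(x) {
  m <- merge_intervals(x)
  sum(m$end - m$start)
}
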