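# Readers/writers for the plain-text formats the pipeline consumes:
# BED / MACS2 broadPeak (0-based half-open), bedGraph, GMT, and a 1-based
# closed gene annotation TSV. Readers are strict by design: malformed
# records fail with file:line context rather than being silently skipped.

#' Construct a peak set
#'
#' A peak set is a labeled, per-chromosome sorted collection of intervals
#' with optional `name`/`score` columns. Duplicate `(chrom, start, end)`
#' rows are dropped with a warning.
#'
#' @param peaks Interval data frame (may be empty).
#' @param name Label for the set (e.g. `"KL"`, `"control"`).
#' @return An object of class `peak_set` with elements `name` and `peaks`.
#' @examples
#' peak_set(genomic_intervals("chr1", 100, 250), name = "demo")
#' peak_set()  # empty set
#' @export
peak_set <- function(peaks = NULL, name = "peaks") {
  if (is.null(peaks)) {
    peaks <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                        stringsAsFactors = FALSE)
  }
  validate_intervals(peaks, what = "peak")
  key <- paste(peaks$chrom, peaks$start, peaks$end)
  if (anyDuplicated(key)) {
    warning(sprintf("dropped %d duplicate peak(s) in '%s'",
                    sum(duplicated(key)), name))
    peaks <- peaks[!duplicated(key), , drop = FALSE]
  }
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(name = name, peaks = peaks), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set '%s'> %d peak(s) on %d chromosome(s)\n",
              x$name, nrow(x$peaks), length(unique(x$peaks$chrom))))
  invisible(x)
}

#' Number of peaks in a peak set
#' @param x A `peak_set`.
#' @return Integer count.
#' @export
n_peaks <- function(x) nrow(x$peaks)

.read_data_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

.num_or_stop <- function(x, path, lineno, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | (what != "depth" & v != floor(v)))
  if (length(bad)) {
    stop(sprintf("%s:%d: non-%s %s field '%s'", path, lineno[bad[1]],
                 if (what == "depth") "numeric" else "integer", what, x[bad[1]]))
  }
  v
}

#' Read a BED or broadPeak file into a peak set
#'
#' Coordinates are ingested as 0-based half-open (no shift). `track`,
#' `browser` and `#` lines are skipped; each data line needs at least
#' three tab/space-separated fields. Column 4 (name) and 5 (score) are
#' kept when present. Records with `end <= start` or non-integer
#' coordinates fail with file:line context.
#'
#' @param path File path.
#' @param fmt `"broadPeak"` or `"bed"` (parsed identically; broadPeak is
#'   BED6+3).
#' @param name Label for the returned set; defaults to the file name.
#' @return A [peak_set()].
#' @export
read_peaks <- function(path, fmt = c("broadPeak", "bed"), name = NULL) {
  fmt <- match.arg(fmt)
  name <- name %||% basename(path)
  d <- .read_data_lines(path)
  if (length(d$lines) == 0) {
    warning(sprintf("%s: no peak records", path))
    return(peak_set(name = name))
  }
  f <- strsplit(d$lines, "[\t ]+")
  short <- which(lengths(f) < 3)
  if (length(short)) {
    stop(sprintf("%s:%d: expected >= 3 fields, got %d",
                 path, d$lineno[short[1]], lengths(f)[short[1]]))
  }
  chrom <- vapply(f, `[`, "", 1L)
  start <- .num_or_stop(vapply(f, `[`, "", 2L), path, d$lineno, "start")
  end <- .num_or_stop(vapply(f, `[`, "", 3L), path, d$lineno, "end")
  bad <- which(end <= start | start < 0)
  if (length(bad)) {
    stop(sprintf("%s:%d: invalid interval %s:%s-%s", path, d$lineno[bad[1]],
                 chrom[bad[1]], format(start[bad[1]]), format(end[bad[1]])))
  }
  pk <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (all(lengths(f) >= 4)) pk$name <- vapply(f, `[`, "", 4L)
  if (all(lengths(f) >= 5)) {
    pk$score <- suppressWarnings(as.numeric(vapply(f, `[`, "", 5L)))
  }
  ps <- peak_set(pk, name = name)
  message(sprintf("read_peaks: %d peak(s) from %s", n_peaks(ps), path))
  ps
}

#' Write a peak set as BED
#'
#' @param x A [peak_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(x, path) {
  pk <- x$peaks
  cols <- c("chrom", "start", "end", intersect(c("name", "score"), names(pk)))
  utils::write.table(format(pk[cols], scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation TSV
#'
#' Expects a header with columns `gene_id`, `symbol`, `chrom`, `start`,
#' `end`, `strand`; `start`/`end` are 1-based closed (Ensembl convention)
#' and are converted to the internal 0-based half-open representation.
#' Strand must be `"+"` or `"-"` (the typographic minus U+2212 is also
#' accepted and normalized); duplicate `gene_id`s are an error.
#'
#' @param path File path.
#' @return Data frame with columns `gene_id`, `symbol`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`.
#' @seealso [promoter_window()], [occupancy_report()]
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  g <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene_id", "symbol", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(g))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")))
  }
  g$strand[g$strand == "−"] <- "-"
  bad <- which(!g$strand %in% c("+", "-"))
  if (length(bad)) {
    stop(sprintf("%s: gene '%s' has invalid strand '%s' (must be + or -)",
                 path, g$gene_id[bad[1]], g$strand[bad[1]]))
  }
  dup <- which(duplicated(g$gene_id))
  if (length(dup)) {
    stop(sprintf("%s: duplicate gene_id '%s'", path, g$gene_id[dup[1]]))
  }
  out <- data.frame(gene_id = g$gene_id, symbol = g$symbol, chrom = g$chrom,
                    start = g$start - 1, end = g$end, strand = g$strand,
                    stringsAsFactors = FALSE)
  validate_intervals(out, what = "gene")
  message(sprintf("read_gene_table: %d gene(s) from %s", nrow(out), path))
  out
}

#' Write a gene table (1-based closed TSV)
#' @param genes Gene data frame as returned by [read_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  g <- genes
  g$start <- g$start + 1
  utils::write.table(g[c("gene_id", "symbol", "chrom", "start", "end", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a coverage track
#'
#' A step-function read-depth track: per-chromosome sorted,
#' non-overlapping intervals each carrying a non-negative depth; positions
#' not covered by any interval have depth 0.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `depth`.
#' @param coalesce Merge adjacent equal-depth intervals (default `TRUE`).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(intervals = NULL, coalesce = TRUE) {
  if (is.null(intervals)) {
    intervals <- data.frame(chrom = character(), start = numeric(),
                            end = numeric(), depth = numeric(),
                            stringsAsFactors = FALSE)
  }
  stopifnot("depth" %in% names(intervals))
  validate_intervals(intervals, what = "coverage interval")
  if (any(intervals$depth < 0) || anyNA(intervals$depth)) {
    bad <- which(is.na(intervals$depth) | intervals$depth < 0)[1]
    stop(sprintf("negative or missing depth at %s:%s-%s",
                 intervals$chrom[bad], format(intervals$start[bad]),
                 format(intervals$end[bad])))
  }
  iv <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  same <- iv$chrom[-1] == iv$chrom[-nrow(iv)]
  if (nrow(iv) > 1 && any(same & iv$start[-1] < iv$end[-nrow(iv)])) {
    i <- which(same & iv$start[-1] < iv$end[-nrow(iv)])[1]
    stop(sprintf("overlapping coverage intervals at %s:%s", iv$chrom[i + 1],
                 format(iv$start[i + 1])))
  }
  if (coalesce && nrow(iv) > 1) {
    run <- cumsum(c(TRUE, !(same & iv$start[-1] == iv$end[-nrow(iv)] &
                              iv$depth[-1] == iv$depth[-nrow(iv)])))
    iv <- data.frame(chrom = tapply(iv$chrom, run, `[`, 1),
                     start = tapply(iv$start, run, `[`, 1),
                     end = tapply(iv$end, run, function(x) x[length(x)]),
                     depth = tapply(iv$depth, run, `[`, 1),
                     stringsAsFactors = FALSE)
  }
  rownames(iv) <- NULL
  structure(list(intervals = iv), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d interval(s), %d chromosome(s), max depth %s\n",
              nrow(x$intervals), length(unique(x$intervals$chrom)),
              if (nrow(x$intervals)) format(max(x$intervals$depth)) else "0"))
  invisible(x)
}

#' Read a bedGraph coverage file
#'
#' Four columns (`chrom start end value`, 0-based half-open). Overlapping
#' intervals and negative values are rejected with line context; adjacent
#' equal-value intervals are coalesced.
#'
#' @param path File path.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path) {
  d <- .read_data_lines(path)
  if (length(d$lines) == 0) {
    warning(sprintf("%s: no coverage records", path))
    return(coverage_track())
  }
  f <- strsplit(d$lines, "[\t ]+")
  short <- which(lengths(f) < 4)
  if (length(short)) {
    stop(sprintf("%s:%d: bedGraph needs 4 fields, got %d",
                 path, d$lineno[short[1]], lengths(f)[short[1]]))
  }
  chrom <- vapply(f, `[`, "", 1L)
  start <- .num_or_stop(vapply(f, `[`, "", 2L), path, d$lineno, "start")
  end <- .num_or_stop(vapply(f, `[`, "", 3L), path, d$lineno, "end")
  depth <- .num_or_stop(vapply(f, `[`, "", 4L), path, d$lineno, "depth")
  bad <- which(depth < 0)
  if (length(bad)) {
    stop(sprintf("%s:%d: negative depth %s", path, d$lineno[bad[1]],
                 format(depth[bad[1]])))
  }
  tr <- coverage_track(data.frame(chrom = chrom, start = start, end = end,
                                  depth = depth, stringsAsFactors = FALSE))
  message(sprintf("read_bedgraph: %d interval(s) from %s",
                  nrow(tr$intervals), path))
  tr
}

#' Write a coverage track as bedGraph
#' @param x A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  iv <- x$intervals
  utils::write.table(format(iv, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (member gene identifiers;
#'   deduplicated).
#' @param descriptions Optional named character vector of term
#'   descriptions.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), !anyDuplicated(names(sets)))
  sets <- lapply(sets, function(s) unique(s[nzchar(s)]))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning(sprintf("dropped %d empty gene set(s)", sum(empty)))
    sets <- sets[!empty]
  }
  desc <- rep(NA_character_, length(sets))
  names(desc) <- names(sets)
  if (!is.null(descriptions)) {
    hit <- intersect(names(descriptions), names(sets))
    desc[hit] <- descriptions[hit]
  }
  structure(list(sets = sets, descriptions = desc),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d set(s), sizes %s\n", length(x$sets),
              if (length(x$sets)) paste(range(lengths(x$sets)), collapse = "-")
              else "-"))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: `term <tab> description <tab> member...`. Members are
#' deduplicated within a set; lines with fewer than three fields are an
#' error; sets left empty are dropped with a warning.
#'
#' @param path File path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  d <- .read_data_lines(path)
  f <- strsplit(d$lines, "\t")
  short <- which(lengths(f) < 3)
  if (length(short)) {
    stop(sprintf("%s:%d: GMT line needs >= 3 fields, got %d",
                 path, d$lineno[short[1]], lengths(f)[short[1]]))
  }
  terms <- vapply(f, `[`, "", 1L)
  if (anyDuplicated(terms)) {
    stop(sprintf("%s: duplicate term '%s'", path, terms[duplicated(terms)][1]))
  }
  sets <- lapply(f, function(x) x[-(1:2)])
  names(sets) <- terms
  desc <- vapply(f, `[`, "", 2L)
  names(desc) <- terms
  gsc <- gene_set_collection(sets, desc)
  message(sprintf("read_gmt: %d set(s) from %s", length(gsc$sets), path))
  gsc
}

#' Write a gene-set collection as GMT
#' @param x A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  lines <- vapply(names(x$sets), function(tm) {
    d <- x$descriptions[[tm]]
    paste(c(tm, if (is.na(d)) "na" else d, x$sets[[tm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Path to a bundled example data file
#'
#' The package ships the published 14-gene Wnt-pathway promoter fixture:
#' `table2_genes.tsv` (gene loci with strand; coordinates 1-based closed),
#' `table2_peaks_treatment.broadPeak` (the H3K27me2/3 peaks called in the
#' Klotho-treated condition, 0-based half-open), and a small
#' `wnt_sets.gmt` collection for the enrichment examples.
#'
#' @param file File name; with no argument, lists available files.
#' @return Absolute path (or a character vector of file names).
#' @examples
#' promoccupy_example()
#' read_gene_table(promoccupy_example("table2_genes.tsv"))
#' @export
promoccupy_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "promoccupy")))
  }
  p <- system.file("extdata", file, package = "promoccupy")
  if (p == "") stop(sprintf("no bundled file '%s'", file))
  p
}
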