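# qPCR normalization: per-sample normalization factor = geometric mean of
# reference-gene Ct values; relative quantity = base^(NF - Ct); each target
# gene scaled so its highest relative expression is 1.

#' Construct a Ct table
#'
#' @param ct Numeric matrix or data frame of cycle-threshold values, rows
#'   = samples (row names used as sample labels), columns = genes. All
#'   reference-gene Cts must be finite and positive; missing values are
#'   allowed in target genes only and propagate to the output.
#' @param group Group assignment per sample (length = rows of `ct`).
#' @param reference_genes Character vector of reference-gene column names
#'   (non-empty).
#' @return An object of class `ct_table`.
#' @examples
#' ct <- matrix(c(20, 20.5, 22, 22.4, 25, 24), nrow = 2,
#'              dimnames = list(c("s1", "s2"), c("Srp14", "Hprt1", "Wnt4")))
#' ct_table(ct, group = c("vehicle", "klotho"),
#'          reference_genes = c("Srp14", "Hprt1"))
#' @export
ct_table <- function(ct, group, reference_genes) {
  ct <- as.matrix(ct)
  stopifnot(is.numeric(ct), !is.null(colnames(ct)))
  if (is.null(rownames(ct))) rownames(ct) <- paste0("sample_", seq_len(nrow(ct)))
  stopifnot(length(group) == nrow(ct))
  reference_genes <- as.character(reference_genes)
  if (length(reference_genes) == 0) stop("need at least one reference gene")
  miss <- setdiff(reference_genes, colnames(ct))
  if (length(miss)) {
    stop(sprintf("reference gene(s) not in table: %s",
                 paste(miss, collapse = ", ")))
  }
  refs <- ct[, reference_genes, drop = FALSE]
  bad <- which(is.na(refs) | refs <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid reference Ct for sample '%s', gene '%s'",
                 rownames(ct)[bad[1, 1]], reference_genes[bad[1, 2]]))
  }
  if (any(ct[!is.na(ct)] <= 0)) stop("Ct values must be positive")
  structure(list(ct = ct, group = as.character(group),
                 reference_genes = reference_genes), class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("<ct_table> %d sample(s) x %d gene(s); reference: %s\n",
              nrow(x$ct), ncol(x$ct), paste(x$reference_genes, collapse = ", ")))
  invisible(x)
}

#' Per-sample normalization factor
#'
#' The geometric mean of the reference-gene Ct values,
#' `(prod ct)^(1/m)`, computed as `exp(mean(log(ct)))`.
#'
#' @param x Numeric vector of reference Cts for one sample, or a
#'   [ct_table()] (returning one factor per sample).
#' @return Normalization factor(s) in cycles.
#' @examples
#' normalization_factor(c(20, 21, 22))
#' @export
normalization_factor <- function(x) UseMethod("normalization_factor")

#' @export
normalization_factor.default <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0 || anyNA(x) || any(x <= 0)) {
    stop("reference Ct values must be present and positive")
  }
  exp(mean(log(x)))
}

#' @export
normalization_factor.ct_table <- function(x) {
  refs <- x$ct[, x$reference_genes, drop = FALSE]
  stats::setNames(exp(rowMeans(log(refs))), rownames(x$ct))
}

#' Relative expression with max-to-1 scaling
#'
#' Raw relative quantity for sample `s`, gene `g` is
#' `base^(NF_s - Ct_{s,g})` with `NF_s` the sample's geometric-mean
#' reference factor; the default `base = 2` assumes 100% amplification
#' efficiency (use `10^(-1/slope)` from a standard curve otherwise).
#' Each target gene is then scaled so its highest relative expression
#' across samples is exactly 1. Missing target Cts propagate; the
#' per-gene maximum is taken over non-missing samples. Genes whose
#' maximum is attained by more than one sample are flagged in the
#' `ties` element.
#'
#' @param table A [ct_table()].
#' @param efficiency_base Amplification base per cycle (default 2).
#' @return An object of class `relative_expression`: list with `raw` and
#'   `scaled` (samples x target genes matrices), `nf` (per-sample factor,
#'   cycles), `group`, and `ties` (character vector of tied genes).
#' @export
relative_expression <- function(table, efficiency_base = 2) {
  stopifnot(inherits(table, "ct_table"), efficiency_base > 1)
  nf <- normalization_factor(table)
  targets <- setdiff(colnames(table$ct), table$reference_genes)
  if (length(targets) == 0) stop("no target genes in the Ct table")
  tc <- table$ct[, targets, drop = FALSE]
  all_missing <- colSums(!is.na(tc)) == 0
  if (any(all_missing)) {
    stop(sprintf("target gene(s) missing in every sample: %s",
                 paste(targets[all_missing], collapse = ", ")))
  }
  raw <- efficiency_base^(nf - tc)
  maxes <- apply(raw, 2, max, na.rm = TRUE)
  scaled <- sweep(raw, 2, maxes, `/`)
  ties <- targets[vapply(seq_along(targets), function(j) {
    sum(raw[, j] == maxes[j], na.rm = TRUE) > 1
  }, TRUE)]
  if (length(ties)) {
    message(sprintf("max-to-1 tie in gene(s): %s (all tied samples scaled to 1)",
                    paste(ties, collapse = ", ")))
  }
  structure(list(raw = raw, scaled = scaled, nf = nf, group = table$group,
                 ties = ties), class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf("<relative_expression> %d sample(s) x %d target gene(s)\n",
              nrow(x$scaled), ncol(x$scaled)))
  invisible(x)
}

#' Group means and SEM of relative expression
#'
#' @param x A [relative_expression()].
#' @param which `"scaled"` (default) or `"raw"`.
#' @return Data frame with one row per (group, gene): `group`, `gene`,
#'   `mean`, `sem`, `n`.
#' @export
summarize_expression <- function(x, which = c("scaled", "raw")) {
  which <- match.arg(which)
  m <- x[[which]]
  out <- do.call(rbind, lapply(unique(x$group), function(g) {
    sub <- m[x$group == g, , drop = FALSE]
    do.call(rbind, lapply(colnames(sub), function(gene) {
      v <- sub[, gene]
      v <- v[!is.na(v)]
      data.frame(group = g, gene = gene, mean = mean(v),
                 sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
                 n = length(v), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
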