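# Over-representation of a query gene list against gene-set collections.
# The upper-tail hypergeometric probability is authored here in log space
# (log-gamma combinatorics) so it stays exact for genome-scale universes;
# the EASE variant penalizes the hit count by one, as in DAVID's modified
# Fisher's exact test.

.check_hyper_args <- function(x, n, K, N) {
  stopifnot(length(x) == 1, length(n) == 1, length(K) == 1, length(N) == 1)
  if (anyNA(c(x, n, K, N)) || any(c(x, n, K, N) != floor(c(x, n, K, N))) ||
      any(c(x, n, K, N) < 0)) {
    stop("x, n, K, N must be non-negative integers")
  }
  if (n > N || K > N || x > min(n, K)) {
    stop(sprintf("invalid counts: need x <= min(n, K), n <= N, K <= N (got x=%d n=%d K=%d N=%d)",
                 x, n, K, N))
  }
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= x)` where `X` counts annotated genes in a query of size `n`
#' drawn without replacement from a universe of `N` genes of which `K`
#' are annotated:
#' `sum_{k=x}^{min(n,K)} C(K,k) C(N-K,n-k) / C(N,n)`.
#' Terms are accumulated in log space via [lchoose()] so the sum neither
#' overflows nor underflows for genome-scale `N`.
#'
#' @param x Observed hits in the query.
#' @param n Query size.
#' @param K Annotated genes in the universe.
#' @param N Universe size.
#' @return Probability in `(0, 1]`; exactly 1 when `x = 0`.
#' @seealso [ease_p()] for the DAVID/EASE variant.
#' @export
hypergeom_upper_tail <- function(x, n, K, N) {
  .check_hyper_args(x, n, K, N)
  if (x == 0) return(1)
  ks <- x:min(n, K)
  lg <- lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)
  lg <- lg[is.finite(lg)]
  if (!length(lg)) return(0)
  m <- max(lg)
  min(1, exp(m + log(sum(exp(lg - m)))))
}

#' EASE-penalized over-representation probability
#'
#' DAVID's "modified Fisher's exact test": the hit count is reduced by
#' one before taking the upper tail, i.e.
#' `ease_p(x, n, K, N) = hypergeom_upper_tail(x - 1, n, K, N)`. This is a
#' deliberately conservative score: it is always at least as large as the
#' unpenalized p-value, and a single-hit term scores 1.
#'
#' @inheritParams hypergeom_upper_tail
#' @return Probability in `(0, 1]`; requires `x >= 1`.
#' @export
ease_p <- function(x, n, K, N) {
  .check_hyper_args(x, n, K, N)
  if (x < 1) stop("ease_p is undefined for x = 0 (nothing to penalize)")
  hypergeom_upper_tail(x - 1, n, K, N)
}

#' Gene-set over-representation analysis
#'
#' Tests each gene set for over-representation in the query relative to
#' an explicit universe. Set membership is intersected with the universe
#' before counting; sets with no universe member are not tested; query
#' genes outside the universe are dropped with a warning. Results are
#' sorted by ascending p-value, ties broken by term id.
#'
#' @param query Character vector of query gene identifiers (e.g. genes
#'   with occupied promoters).
#' @param universe Character vector of all eligible gene identifiers
#'   (deduplicated internally).
#' @param sets A [gene_set_collection()].
#' @param method `"hypergeometric"` (raw upper tail) or `"ease"`
#'   (hit count penalized by one; single-hit terms score 1).
#' @param adjust Add Benjamini-Hochberg adjusted p-values across all
#'   tested terms.
#' @return Data frame with columns `term`, `description`, `x`, `n`, `K`,
#'   `N`, `p_value`, `neg_log10_p`, `fold` (`(x/n) / (K/N)`), and
#'   `p_adjusted` when `adjust = TRUE`.
#' @examples
#' sets <- gene_set_collection(list(A = c("g1", "g2"), B = c("g3", "g4")))
#' enrich(c("g1", "g2"), paste0("g", 1:20), sets)
#' @export
enrich <- function(query, universe, sets,
                   method = c("hypergeometric", "ease"), adjust = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(sets, "gene_set_collection"))
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (length(universe) == 0) stop("empty universe")
  if (length(query) == 0) stop("empty query")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("dropped %d query gene(s) not in the universe",
                    length(outside)))
    query <- intersect(query, universe)
    if (length(query) == 0) stop("no query gene is in the universe")
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets$sets), function(tm) {
    members <- intersect(sets$sets[[tm]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    x <- length(intersect(query, members))
    p <- if (x == 0) 1
         else if (method == "ease") ease_p(x, n, K, N)
         else hypergeom_upper_tail(x, n, K, N)
    data.frame(term = tm, description = sets$descriptions[[tm]],
               x = x, n = n, K = K, N = N, p_value = p,
               neg_log10_p = -log10(p), fold = (x / n) / (K / N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(term = character(), description = character(),
                      x = integer(), n = integer(), K = integer(),
                      N = integer(), p_value = numeric(),
                      neg_log10_p = numeric(), fold = numeric(),
                      stringsAsFactors = FALSE)
  }
  if (adjust) res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
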