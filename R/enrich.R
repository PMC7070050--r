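#' Upper-tail hypergeometric p-value
#'
#' Probability of drawing at least `k` marked genes when `n` genes are
#' drawn without replacement from a universe of `N` genes of which `K`
#' are marked:
#' `p = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`.
#'
#' @param N universe size.
#' @param K marked genes in the universe.
#' @param n query (draw) size.
#' @param k observed overlap.
#' @return p-value in (0, 1].
#' @examples
#' hypergeom_pvalue(10, 4, 3, 2)  # 40/120 = 1/3
#' hypergeom_pvalue(5, 2, 2, 2)   # 1/10
#' @export
hypergeom_pvalue <- function(N, K, n, k) {
  stopifnot(length(N) == 1 || length(N) == length(k))
  bad <- K > N | n > N | k > pmin(K, n) | k < 0 | K < 0 | n < 0 | N < 0
  if (any(bad))
    stop("hypergeometric bounds violated: need 0 <= k <= min(K, n), K <= N, n <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} (p_(j) * m / j)`, capped at 1, returned in the
#' input order.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed; kept
#'   `NA` and excluded from `m`).
#' @return Adjusted values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Hypergeometric over-representation of annotation terms
#'
#' One row per term with at least one query member: universe size `N`,
#' term size in the universe `K`, query size `n`, overlap `k`, the
#' upper-tail hypergeometric p-value and its BH adjustment across all
#' tested terms.  Terms with fewer than `min_term_size` members in the
#' universe are skipped.
#'
#' @param query character vector of gene ids; must be a subset of
#'   `universe`.
#' @param annotation data.frame with columns `gene_id`, `term_id`
#'   (one row per membership), or a named list term -> gene ids.
#' @param universe character vector of gene ids defining the background.
#' @param min_term_size smallest testable term (default 2).
#' @return data.frame `term_id, N, K, n, k, p, FDR`, sorted by FDR then
#'   p.
#' @export
enrich <- function(query, annotation, universe, min_term_size = 2) {
  query <- unique(query); universe <- unique(universe)
  extra <- setdiff(query, universe)
  if (length(extra) > 0)
    stop("query genes outside the universe: ",
         paste(head(extra, 5), collapse = ", "),
         if (length(extra) > 5) " ..." else "")
  if (is.data.frame(annotation)) {
    annotation <- split(annotation$gene_id, annotation$term_id)
  }
  annotation <- lapply(annotation, function(g) intersect(unique(g), universe))
  ann <- annotation[vapply(annotation, length, 1L) >= min_term_size]
  N <- length(universe); n <- length(query)
  rows <- lapply(names(ann), function(term) {
    K <- length(ann[[term]])
    k <- length(intersect(ann[[term]], query))
    if (k == 0) return(NULL)
    data.frame(term_id = term, N = N, K = K, n = n, k = k,
               p = hypergeom_pvalue(N, K, n, k))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0)
    return(data.frame(term_id = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), p = numeric(),
                      FDR = numeric()))
  out <- do.call(rbind, rows)
  out$FDR <- bh_adjust(out$p)
  out <- out[order(out$FDR, out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname enrich
#' @param file TSV path for an annotation map with columns `gene_id`,
#'   `term_id`.
#' @export
read_annotation <- function(file) {
  df <- read.delim(file)
  if (!all(c("gene_id", "term_id") %in% names(df)))
    stop("annotation map needs columns gene_id, term_id")
  df
}
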