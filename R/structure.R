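#' Sample-sample Pearson correlation
#'
#' Pearson correlation between transformed expression profiles of all
#' sample pairs; the default transform is `log2(FPKM + 1)`.
#'
#' @param em an `expression_matrix`.
#' @param transform function applied to the FPKM matrix before
#'   correlating (default `log2(x + 1)`).
#' @param genes optional gene subset (e.g. the union of expressed
#'   genes).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(em, transform = function(x) log2(x + 1),
                               genes = NULL) {
  x <- em$fpkm
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  if (ncol(x) < 2)
    stop("need at least two samples")
  x <- transform(x)
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("constant sample vector(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "),
         " (Pearson correlation undefined)")
  cor(x)
}

#' Unsupervised hierarchical clustering of samples
#'
#' Average-linkage clustering on the distance `1 - r` (Pearson), cut at
#' `k` clusters.
#'
#' @param r correlation matrix from [correlation_matrix()] (or an
#'   `expression_matrix`, correlated with defaults first).
#' @param k number of clusters to cut at.
#' @param method linkage (default "average").
#' @return list with `hclust` (the tree), `labels` (named cluster index
#'   per sample) and `newick` (the dendrogram as a Newick string).
#' @export
hierarchical_cluster <- function(r, k, method = "average") {
  if (inherits(r, "expression_matrix")) r <- correlation_matrix(r)
  n <- ncol(r)
  if (k < 1 || k > n)
    stop("k must be between 1 and the number of samples (", n, ")")
  hc <- hclust(as.dist(1 - r), method = method)
  labels <- cutree(hc, k = k)
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, labels = labels, newick = newick)
}

#' Principal component analysis of samples
#'
#' PCA of gene-centered transformed expression (samples as
#' observations); components are ordered by explained variance.
#'
#' @param em an `expression_matrix`.
#' @param transform as in [correlation_matrix()].
#' @param genes optional gene subset.
#' @return list with `coords` (samples x PCs), `explained` (fraction of
#'   variance per PC, non-increasing).
#' @export
pca_samples <- function(em, transform = function(x) log2(x + 1),
                        genes = NULL) {
  x <- em$fpkm
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  if (ncol(x) < 2)
    stop("need at least two samples")
  x <- transform(x)
  keep <- apply(x, 1, sd) > 0
  if (sum(keep) < 2)
    stop("fewer than 2 non-constant genes")
  pr <- prcomp(t(x[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  expl <- pr$sdev^2 / sum(pr$sdev^2)
  list(coords = pr$x, explained = expl)
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant agreement between two partitions of the same
#' items; 1 means identical partitions, values near 0 mean chance
#' agreement.  Used to score recovered sample/gene clusterings against
#' planted truth.
#'
#' @param a,b two label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
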