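#' FPKM normalization
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `FPKM(g, s) = count(g, s) * 1e9 / (length(g) * total(s))`, where
#' `total(s)` is the column sum of counts for sample `s`.
#'
#' @param cm a [count_matrix()].
#' @return An object of class `expression_matrix`: list with `fpkm`
#'   (numeric matrix, same dimnames as the counts), `samples` (the
#'   sample sheet) and `method = "fpkm"`.
#' @examples
#' cm <- count_matrix(
#'   matrix(c(100L, 0L), 2, 1, dimnames = list(c("g1", "g2"), "s1")),
#'   lengths = c(g1 = 1000, g2 = 500),
#'   samples = data.frame(sample_id = "s1", cell_type = "AC", replicate = 1))
#' # g1 sits at 100 / (1 kb * 1e-4 million reads)... i.e. 1e9*100/(1000*100)
#' compute_fpkm(cm)$fpkm
#' @export
compute_fpkm <- function(cm) {
  totals <- colSums(cm$counts)
  if (any(totals <= 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(cm$counts)[totals <= 0], collapse = ", "))
  fpkm <- cm$counts * 1e9 / outer(cm$lengths, totals)
  structure(list(fpkm = fpkm, samples = cm$samples, method = "fpkm"),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix (", x$method, "): ", nrow(x$fpkm), " genes x ",
      ncol(x$fpkm), " samples\n", sep = "")
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes with all-positive counts of
#' `count(g, s) / geometric_mean_g`, where the geometric mean is taken
#' across samples.  Factors are rescaled so their geometric mean is 1.
#'
#' @param cm a [count_matrix()] or a bare counts matrix.
#' @return Named positive numeric vector, one factor per sample, with
#'   geometric mean 1.
#' @export
size_factors <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (ncol(counts) == 1L)
    return(setNames(1, colnames(counts)))
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep))
    stop("no gene has positive counts in every sample; ",
         "filter to a common detected gene set first")
  lg <- log(counts[keep, , drop = FALSE])
  ref <- rowMeans(lg)                      # log geometric mean per gene
  sf <- apply(exp(lg - ref), 2, median)
  sf <- sf / exp(mean(log(sf)))            # geometric mean 1
  sf
}

#' Expressed-gene sets at an FPKM threshold
#'
#' A gene counts as expressed in a cell type when its mean FPKM across
#' that type's replicates reaches (`strict = FALSE`, the default,
#' i.e. `>=`) or exceeds (`strict = TRUE`, i.e. `>`) the threshold.
#'
#' @param em an `expression_matrix` from [compute_fpkm()].
#' @param group cell-type label.
#' @param threshold FPKM threshold (default 1).
#' @param strict use strict inequality `>` instead of `>=`.
#' @return Character vector of gene ids.
#' @export
expressed_genes <- function(em, group, threshold = 1, strict = FALSE) {
  idx <- which(em$samples$cell_type == group)
  if (length(idx) == 0L)
    stop("unknown cell type: ", group)
  m <- rowMeans(em$fpkm[, idx, drop = FALSE])
  keep <- if (strict) m > threshold else m >= threshold
  rownames(em$fpkm)[keep]
}

#' Mean FPKM per cell type
#'
#' @param em an `expression_matrix`.
#' @param cell_types cell types to include (default: all present, in
#'   sample-sheet order).
#' @return Matrix genes x cell types of replicate-mean FPKM.
#' @export
group_means <- function(em, cell_types = unique(em$samples$cell_type)) {
  out <- vapply(cell_types, function(ct) {
    idx <- which(em$samples$cell_type == ct)
    if (length(idx) == 0L) stop("unknown cell type: ", ct)
    rowMeans(em$fpkm[, idx, drop = FALSE])
  }, numeric(nrow(em$fpkm)))
  out <- matrix(out, nrow = nrow(em$fpkm),
                dimnames = list(rownames(em$fpkm), cell_types))
  out
}

#' @rdname compute_fpkm
#' @param em an `expression_matrix`.
#' @param file output TSV path.
#' @export
write_fpkm <- function(em, file) {
  df <- data.frame(gene_id = rownames(em$fpkm), em$fpkm, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
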