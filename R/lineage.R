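#' Lineage-maintained gene sets
#'
#' A gene is apical-lineage (ACL) maintained when it is upregulated in
#' the apical daughter at the 1-cell stage (AC vs BC) and still
#' upregulated in the embryo proper at the 32-cell stage (32E vs 32S);
#' basal-lineage (BCL) maintained genes are the analogous intersection
#' of the downregulated sets.
#'
#' @param deg_1cell list with `up`/`down` gene sets of the AC:BC
#'   contrast.
#' @param deg_32cell list with `up`/`down` gene sets of the 32E:32S
#'   contrast.
#' @return list with `ACL_maintained`, `BCL_maintained` (disjoint
#'   character vectors).
#' @export
lineage_maintained <- function(deg_1cell, deg_32cell) {
  for (d in list(deg_1cell, deg_32cell)) {
    if (!all(c("up", "down") %in% names(d)))
      stop("DEG inputs need 'up' and 'down' sets")
    if (length(intersect(d$up, d$down)) > 0)
      stop("malformed DE calls: up and down sets overlap")
  }
  list(ACL_maintained = intersect(deg_1cell$up, deg_32cell$up),
       BCL_maintained = intersect(deg_1cell$down, deg_32cell$down))
}

#' Transcript-fate classification of daughter-cell DEGs
#'
#' Each differentially expressed gene between the apical (AC) and basal
#' (BC) daughter cells is assigned one of three mechanisms, based on
#' replicate-mean FPKM in the zygote (Zy24), the favored daughter `D`,
#' the other daughter `O`, and the two 32-cell samples:
#'
#' * `inherited_asymmetric` - present in the zygote (`Zy24 >= high`),
#'   partitioned into one daughter, and gone by the 32-cell stage
#'   (`max(32E, 32S) < negligible`);
#' * `de_novo` - absent from the zygote (`Zy24 < negligible`) and newly
#'   transcribed in the favored daughter (`D >= high`);
#' * `selective_deletion` - present in the zygote and retained in the
#'   favored daughter (`Zy24 >= high`, `D >= high`) while degraded in
#'   the other (`O < negligible`);
#' * `unclassified` otherwise.
#'
#' Rules are applied in that order, so a gene matching several
#' inequalities gets the first.
#'
#' @param em an `expression_matrix` containing Zy24, AC, BC, 32E, 32S
#'   samples.
#' @param deg_AC_BC list with `up` (AC-favored) and `down` (BC-favored)
#'   gene sets of the AC:BC contrast.
#' @param high_fpkm "highly expressed" threshold (default 5 FPKM).
#' @param negligible_fpkm "negligible" threshold (default 1 FPKM).
#' @return data.frame `gene_id`, `favored_lineage` ("ACL"/"BCL"),
#'   `mechanism`.
#' @export
classify_transcript_fate <- function(em, deg_AC_BC, high_fpkm = 5,
                                     negligible_fpkm = 1) {
  need <- c("Zy24", "AC", "BC", "32E", "32S")
  missing <- setdiff(need, unique(em$samples$cell_type))
  if (length(missing) > 0)
    stop("expression matrix lacks cell type(s): ",
         paste(missing, collapse = ", "))
  gm <- group_means(em, need)
  genes <- c(deg_AC_BC$up, deg_AC_BC$down)
  favored <- rep(c("ACL", "BCL"),
                 c(length(deg_AC_BC$up), length(deg_AC_BC$down)))
  if (!all(genes %in% rownames(gm)))
    stop("DEG gene(s) absent from the expression matrix")
  zy <- gm[genes, "Zy24"]
  d <- ifelse(favored == "ACL", gm[genes, "AC"], gm[genes, "BC"])
  o <- ifelse(favored == "ACL", gm[genes, "BC"], gm[genes, "AC"])
  late_max <- pmax(gm[genes, "32E"], gm[genes, "32S"])
  mech <- rep("unclassified", length(genes))
  mech[zy >= high_fpkm & late_max < negligible_fpkm] <- "inherited_asymmetric"
  sel <- mech == "unclassified" & zy < negligible_fpkm & d >= high_fpkm
  mech[sel] <- "de_novo"
  sel <- mech == "unclassified" & zy >= high_fpkm & d >= high_fpkm &
    o < negligible_fpkm
  mech[sel] <- "selective_deletion"
  data.frame(gene_id = genes, favored_lineage = favored, mechanism = mech,
             row.names = NULL)
}

#' Expression-profile grouping of a gene set
#'
#' Hierarchical clustering (average linkage, 1 - Pearson distance, the
#' same conventions as the sample-level clustering) of per-gene mean
#' expression profiles across cell types, cut at `k` groups.  Profiles
#' are `log2(FPKM + 1)` and, with `scale = "zscore"` (default), z-scored
#' per gene so groups reflect profile shape (correlation distance);
#' `scale = "log"` keeps absolute levels and switches to Euclidean
#' distance so groups reflect expression level.
#'
#' @param em an `expression_matrix`.
#' @param genes gene set to cluster (non-empty).
#' @param k number of groups (1 <= k <= number of genes).
#' @param cell_types profile columns, in order (default: all types in
#'   the sample sheet).
#' @param scale "zscore" or "log".
#' @return list with `groups` (named integer vector), `k`,
#'   `group_profiles` (k x cell types matrix of group-mean profiles).
#' @export
cluster_profiles <- function(em, genes, k,
                             cell_types = unique(em$samples$cell_type),
                             scale = c("zscore", "log")) {
  scale <- match.arg(scale)
  if (length(genes) == 0)
    stop("empty gene set")
  if (k < 1 || k > length(genes))
    stop("k must be between 1 and the set size (", length(genes), ")")
  gm <- group_means(em, cell_types)
  if (!all(genes %in% rownames(gm)))
    stop("gene(s) absent from the expression matrix")
  x <- log2(gm[genes, , drop = FALSE] + 1)
  if (scale == "zscore") {
    mu <- rowMeans(x); s <- apply(x, 1, sd)
    s[s == 0] <- 1                     # flat profiles stay flat at 0
    x <- (x - mu) / s
  }
  if (k == length(genes)) {
    groups <- setNames(seq_along(genes), genes)
  } else if (k == 1) {
    groups <- setNames(rep(1L, length(genes)), genes)
  } else {
    if (scale == "zscore") {
      # shape grouping: correlation distance; guard constant rows
      # (undefined r -> treated as uncorrelated)
      cc <- suppressWarnings(cor(t(x)))
      cc[!is.finite(cc)] <- 0
      diag(cc) <- 1
      d <- as.dist(1 - cc)
    } else {
      # level grouping: correlation is blind to absolute level, so use
      # Euclidean distance on the log profiles
      d <- dist(x)
    }
    hc <- hclust(d, method = "average")
    groups <- cutree(hc, k = k)
    names(groups) <- genes
  }
  prof <- t(sapply(sort(unique(groups)), function(g)
    colMeans(x[names(groups)[groups == g], , drop = FALSE])))
  list(groups = groups, k = k, group_profiles = prof)
}
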