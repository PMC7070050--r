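#' Construct a gene-by-sample count matrix with metadata
#'
#' The root input of the pipeline: integer counts per (gene, sample),
#' gene lengths in nucleotides, and a sample sheet assigning each sample
#' to a cell type and replicate.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param lengths numeric vector of gene lengths (nt), named by gene id
#'   or in row order of `counts`.
#' @param samples data.frame with columns `sample_id`, `cell_type`,
#'   `replicate`; one row per column of `counts`.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts`, `lengths`, `samples`.
#' @examples
#' cm <- count_matrix(
#'   matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2"))),
#'   lengths = c(g1 = 1000, g2 = 2000),
#'   samples = data.frame(sample_id = c("s1", "s2"),
#'                        cell_type = c("AC", "BC"), replicate = c(1, 1)))
#' @export
count_matrix <- function(counts, lengths, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in counts")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integral")
  if (is.null(names(lengths))) {
    if (length(lengths) != nrow(counts))
      stop("lengths must match the number of genes")
    names(lengths) <- rownames(counts)
  }
  lengths <- lengths[rownames(counts)]
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("every gene needs a positive length")
  samples <- as.data.frame(samples)
  req <- c("sample_id", "cell_type", "replicate")
  if (!all(req %in% names(samples)))
    stop("sample sheet needs columns: ", paste(req, collapse = ", "))
  if (!setequal(samples$sample_id, colnames(counts)) ||
      anyDuplicated(samples$sample_id))
    stop("sample sheet must match count columns one-to-one")
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, lengths = lengths, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("cell types:", paste(unique(x$samples$cell_type), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# Column indices of the samples belonging to one cell type.
group_columns <- function(cm, cell_type) {
  idx <- which(cm$samples$cell_type == cell_type)
  if (length(idx) == 0L)
    stop("unknown cell type: ", cell_type)
  idx
}

#' Write / read a count matrix as TSV files
#'
#' The counts table has columns `gene_id`, `length`, then one column per
#' sample; the sample sheet has `sample_id`, `cell_type`, `replicate`.
#'
#' @param cm a [count_matrix()].
#' @param counts_file,samples_file paths of the two TSV files.
#' @return `write_counts` returns the paths invisibly; `read_counts`
#'   returns a [count_matrix()].
#' @export
write_counts <- function(cm, counts_file, samples_file) {
  df <- data.frame(gene_id = rownames(cm$counts),
                   length = unname(cm$lengths),
                   cm$counts, check.names = FALSE)
  write.table(df, counts_file, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cm$samples, samples_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(counts_file, samples_file))
}

#' @rdname write_counts
#' @export
read_counts <- function(counts_file, samples_file) {
  df <- read.delim(counts_file, check.names = FALSE)
  samples <- read.delim(samples_file)
  counts <- as.matrix(df[, setdiff(names(df), c("gene_id", "length")),
                         drop = FALSE])
  rownames(counts) <- df$gene_id
  count_matrix(counts, setNames(df$length, df$gene_id), samples)
}
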