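#' Promoter window around a transcription start site
#'
#' The scanned promoter region is -500 to +100 relative to the TSS in
#' transcription orientation.  On the + strand this is the genomic
#' interval `[tss - 500, tss + 100]` (1-based, inclusive, clipped at 1);
#' on the - strand it mirrors to `[tss - 100, tss + 500]`.
#'
#' @param tss 1-based genomic TSS position.
#' @param strand `"+"` or `"-"`.
#' @param upstream,downstream window bounds (defaults 500 and 100 nt).
#' @return Integer vector `c(start, end)` (genomic, 1-based inclusive).
#' @export
promoter_window <- function(tss, strand, upstream = 500, downstream = 100) {
  if (tss < 1) stop("tss must be >= 1")
  if (strand == "+") {
    c(max(1L, tss - upstream), tss + downstream)
  } else if (strand == "-") {
    c(max(1L, tss - downstream), tss + upstream)
  } else {
    stop("unknown strand symbol: ", strand)
  }
}

#' Build a position-weight motif
#'
#' @param tf_id transcription-factor id.
#' @param matrix 4 x width numeric matrix, rows A, C, G, T; columns are
#'   normalized to probabilities.
#' @param threshold_frac hit threshold as a fraction of the maximum
#'   attainable log-odds score (default 0.8).
#' @param pseudo probability floor added before log-odds (default 1e-3)
#'   so zero entries stay finite.
#' @return list of class `motif` with elements `tf_id`, `prob`,
#'   `logodds` (log2 odds vs uniform background), `consensus`,
#'   `max_score`, `threshold`.
#' @export
motif <- function(tf_id, matrix, threshold_frac = 0.8, pseudo = 1e-3) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4) stop("motif matrix needs rows A, C, G, T")
  if (ncol(matrix) < 4) stop("motif length must be >= 4")
  rownames(matrix) <- c("A", "C", "G", "T")
  prob <- sweep(matrix, 2, colSums(matrix), "/")
  p <- sweep(prob + pseudo, 2, colSums(prob + pseudo), "/")
  lo <- log2(p / 0.25)
  consensus <- paste(rownames(prob)[apply(prob, 2, which.max)],
                     collapse = "")
  max_score <- sum(apply(lo, 2, max))
  structure(list(tf_id = tf_id, prob = prob, logodds = lo,
                 consensus = consensus, max_score = max_score,
                 threshold = threshold_frac * max_score),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat("motif", x$tf_id, "consensus", x$consensus,
      sprintf("(threshold %.2f of max %.2f)\n", x$threshold, x$max_score))
  invisible(x)
}

#' @rdname motif
#' @param consensus consensus string over ACGT.
#' @param dominant probability of the consensus base per column
#'   (default 0.94).
#' @param ... passed to [motif()].
#' @export
consensus_motif <- function(tf_id, consensus, dominant = 0.94, ...) {
  bases <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - dominant) / 3, 4, length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(bases, rownames(m)), seq_along(bases))] <- dominant
  motif(tf_id, m, ...)
}

# reverse-complement of a log-odds (or probability) matrix
revcomp_matrix <- function(m) {
  m <- m[c("T", "G", "C", "A"), rev(seq_len(ncol(m))), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  m
}

#' Scan promoter windows for motif hits
#'
#' Log-odds scan (uniform background) of both strands of the
#' -500..+100 promoter window of every promoter.  A hit is any position
#' whose score reaches the motif's threshold; `N` bases contribute a
#' zero (background) score.
#'
#' @param promoters promoter set as produced by
#'   [simulate_promoters()] (or assembled by hand): list with `seqs`
#'   (named character vector or `DNAStringSet`, sequences in gene
#'   orientation) and `table` (data.frame `gene_id`, `tss_offset` -
#'   1-based TSS position within the oriented sequence - plus optional
#'   genomic columns).
#' @param motifs list of [motif()] objects.
#' @param upstream,downstream window bounds (defaults 500/100).
#' @return data.frame `tf_id`, `gene_id`, `rel_pos` (position of the
#'   match start relative to the TSS, 0 = TSS), `strand` (`"+"` =
#'   gene-sense), `score`, `width`.
#' @export
scan_promoters <- function(promoters, motifs, upstream = 500,
                           downstream = 100) {
  seqs <- promoters$seqs
  if (!is.character(seqs)) seqs <- as.character(seqs)  # DNAStringSet etc.
  tab <- promoters$table
  seqs <- seqs[tab$gene_id]
  if (any(is.na(seqs)))
    stop("promoter sequence missing for some genes")
  starts <- tab$tss_offset - upstream
  ends <- tab$tss_offset + downstream
  short <- starts < 1 | ends > nchar(seqs)
  if (any(short))
    stop("promoter window extends past the available sequence for: ",
         paste(head(tab$gene_id[short], 5), collapse = ", "))
  win <- substr(seqs, starts, ends)
  L <- upstream + downstream + 1
  # integer-coded base matrix, promoters x positions; N/other -> NA
  B <- matrix(match(unlist(strsplit(toupper(win), "")),
                    c("A", "C", "G", "T")),
              nrow = length(win), ncol = L, byrow = TRUE)
  hits <- list()
  for (mt in motifs) {
    if (!inherits(mt, "motif")) stop("motifs must be motif() objects")
    w <- ncol(mt$logodds)
    if (w > L)
      stop("motif ", mt$tf_id, " longer than the promoter window")
    for (str in c("+", "-")) {
      lo <- if (str == "+") mt$logodds else revcomp_matrix(mt$logodds)
      P <- L - w + 1
      SC <- matrix(0, nrow(B), P)
      for (j in seq_len(w)) {
        contrib <- matrix(lo[, j][B[, j:(j + P - 1), drop = FALSE]],
                          nrow(B), P)
        contrib[is.na(contrib)] <- 0   # N scores as background
        SC <- SC + contrib
      }
      idx <- which(SC >= mt$threshold, arr.ind = TRUE)
      if (nrow(idx) > 0) {
        hits[[length(hits) + 1]] <- data.frame(
          tf_id = mt$tf_id,
          gene_id = tab$gene_id[idx[, 1]],
          rel_pos = idx[, 2] - 1L - upstream,
          strand = str,
          score = SC[idx],
          width = w)
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(tf_id = character(), gene_id = character(),
                      rel_pos = integer(), strand = character(),
                      score = numeric(), width = integer()))
  out <- do.call(rbind, hits)
  out <- out[order(out$tf_id, out$gene_id, out$rel_pos, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Motif enrichment among a DEG set
#'
#' Per transcription factor, a hypergeometric test of the genes carrying
#' at least one promoter-window hit against the DEG set within the
#' universe, BH-adjusted across TFs.  TFs with no hit in the universe
#' get `p = 1`.
#'
#' @param deg_set character vector of DEG ids (subset of `universe`).
#' @param hits data.frame from [scan_promoters()].
#' @param universe background gene ids (whose promoters were scanned).
#' @param tf_ids TFs to report (default: those present in `hits`).
#' @return data.frame `tf_id, N, K, n, k, p, FDR`, sorted by FDR then p.
#' @export
tf_motif_enrichment <- function(deg_set, hits, universe,
                                tf_ids = unique(hits$tf_id)) {
  universe <- unique(universe)
  extra <- setdiff(deg_set, universe)
  if (length(extra) > 0)
    stop("DEG set not contained in the universe: ",
         paste(head(extra, 5), collapse = ", "))
  by_tf <- split(hits$gene_id, hits$tf_id)
  N <- length(universe); n <- length(unique(deg_set))
  rows <- lapply(tf_ids, function(tf) {
    g <- intersect(unique(by_tf[[tf]]), universe)
    K <- length(g)
    k <- length(intersect(g, deg_set))
    data.frame(tf_id = tf, N = N, K = K, n = n, k = k,
               p = hypergeom_pvalue(N, K, n, k))
  })
  out <- do.call(rbind, rows)
  out$FDR <- bh_adjust(out$p)
  out <- out[order(out$FDR, out$p), ]
  rownames(out) <- NULL
  out
}

#' Coexpression filter for TF-target links
#'
#' Pearson correlation between the TF's and the target's mean-FPKM
#' profiles over the same ordered cell types; the link passes when the
#' correlation strictly exceeds `r_min`.
#'
#' @param tf_profile,target_profile numeric vectors (same length >= 3).
#' @param r_min correlation threshold (default 0.87).
#' @return list with `pass` (logical), `r`, and `reason` (set when the
#'   correlation is undefined).
#' @export
coexpression_filter <- function(tf_profile, target_profile, r_min = 0.87) {
  if (length(tf_profile) != length(target_profile) ||
      length(tf_profile) < 3)
    stop("profiles must share the same ordered cell types (length >= 3)")
  if (sd(tf_profile) == 0 || sd(target_profile) == 0)
    return(list(pass = FALSE, r = NA_real_,
                reason = "undefined correlation"))
  r <- cor(tf_profile, target_profile)
  list(pass = r > r_min, r = r, reason = NULL)
}

#' Assemble the TF regulatory network
#'
#' An edge tf -> gene requires all three evidence sources: the TF's
#' motif is enriched in the DEG set (FDR below `fdr_max`), the gene's
#' promoter window carries a hit for that TF, and the TF-gene
#' coexpression filter passes.
#'
#' @param enriched data.frame from [tf_motif_enrichment()].
#' @param hits data.frame from [scan_promoters()].
#' @param coexpr data.frame with columns `tf_id`, `gene_id`, `r`,
#'   `pass` (e.g. from [coexpression_table()]).
#' @param fdr_max enrichment cutoff for a TF to enter the network
#'   (default 0.05).
#' @return data.frame `tf_id`, `gene_id`, `r` - the edge list.
#' @export
build_network <- function(enriched, hits, coexpr, fdr_max = 0.05) {
  keep_tf <- enriched$tf_id[enriched$FDR < fdr_max]
  pairs <- unique(hits[hits$tf_id %in% keep_tf, c("tf_id", "gene_id")])
  if (nrow(pairs) == 0)
    return(data.frame(tf_id = character(), gene_id = character(),
                      r = numeric()))
  key <- paste(coexpr$tf_id, coexpr$gene_id)
  m <- match(paste(pairs$tf_id, pairs$gene_id), key)
  ok <- !is.na(m) & coexpr$pass[m]
  out <- pairs[ok, , drop = FALSE]
  out$r <- coexpr$r[m[ok]]
  out <- out[order(out$tf_id, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Coexpression table for candidate TF-target pairs
#'
#' Applies [coexpression_filter()] to every (TF, gene) pair appearing in
#' `hits`, using `log2(mean FPKM + 1)` profiles over `cell_types`.
#'
#' @param em an `expression_matrix`.
#' @param hits data.frame from [scan_promoters()].
#' @param tf_genes named character vector mapping `tf_id` to the TF's
#'   own gene id in the expression matrix.
#' @param cell_types ordered profile columns (default: all).
#' @param r_min see [coexpression_filter()].
#' @return data.frame `tf_id`, `gene_id`, `r`, `pass`.
#' @export
coexpression_table <- function(em, hits, tf_genes,
                               cell_types = unique(em$samples$cell_type),
                               r_min = 0.87) {
  gm <- log2(group_means(em, cell_types) + 1)
  pairs <- unique(hits[, c("tf_id", "gene_id")])
  pairs <- pairs[pairs$gene_id %in% rownames(gm) &
                   pairs$tf_id %in% names(tf_genes), , drop = FALSE]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    tfg <- tf_genes[[pairs$tf_id[i]]]
    cf <- coexpression_filter(gm[tfg, ], gm[pairs$gene_id[i], ],
                              r_min = r_min)
    data.frame(tf_id = pairs$tf_id[i], gene_id = pairs$gene_id[i],
               r = cf$r, pass = cf$pass)
  })
  if (length(res) == 0)
    return(data.frame(tf_id = character(), gene_id = character(),
                      r = numeric(), pass = logical()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Read / write JASPAR-style motif matrices
#'
#' Plain-text format: a `>tf_id` header line followed by four lines
#' `A [ n n n ... ]` etc.  Counts (or probabilities) are normalized
#' per column on read.
#'
#' @param file path.
#' @param motifs list of [motif()] objects.
#' @param ... passed to [motif()] on read (e.g. `threshold_frac`).
#' @return `read_motifs` returns a list of [motif()] objects.
#' @export
read_motifs <- function(file, ...) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  lapply(seq_along(heads), function(i) {
    id <- sub("^>\\s*", "", lines[heads[i]])
    block <- lines[(heads[i] + 1):(heads[i] + 4)]
    rows <- lapply(block, function(l) {
      x <- sub("^[ACGT]", "", l)
      as.numeric(regmatches(x, gregexpr("[0-9eE.+-]+", x,
                                        perl = TRUE))[[1]])
    })
    motif(id, do.call(rbind, rows), ...)
  })
}

#' @rdname read_motifs
#' @export
write_motifs <- function(motifs, file) {
  con <- file(file, "w"); on.exit(close(con))
  for (mt in motifs) {
    writeLines(paste0(">", mt$tf_id), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(paste0(b, " [ ",
                        paste(format(mt$prob[b, ], digits = 6),
                              collapse = " "), " ]"), con)
  }
  invisible(file)
}

#' Write motif hits as BED6
#'
#' Converts gene-oriented hit positions to genomic coordinates using the
#' promoter table (columns `chrom`, `tss` - genomic 1-based - and
#' `strand`), 0-based half-open, score = log-odds score, strand =
#' genomic strand of the matched motif.
#'
#' @param hits data.frame from [scan_promoters()].
#' @param promoters promoter set (see [scan_promoters()]).
#' @param file output path.
#' @export
write_hits_bed <- function(hits, promoters, file) {
  tab <- promoters$table
  m <- match(hits$gene_id, tab$gene_id)
  gstrand <- tab$strand[m]; tss <- tab$tss[m]
  w <- hits$width
  plus <- gstrand == "+"
  start1 <- ifelse(plus, tss + hits$rel_pos, tss - hits$rel_pos - w + 1)
  end1 <- start1 + w - 1
  hit_strand <- ifelse((hits$strand == "+") == plus, "+", "-")
  bed <- data.frame(chrom = tab$chrom[m], start = start1 - 1L, end = end1,
                    name = paste(hits$tf_id, hits$gene_id, sep = ":"),
                    score = round(hits$score, 3), strand = hit_strand)
  write.table(bed, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}
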