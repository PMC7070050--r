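#' Transcript models as an exon table
#'
#' Transcript models are held as a data.frame with one row per exon:
#' columns `transcript_id`, `gene_id`, `chrom`, `strand`, `start`,
#' `end` (1-based inclusive).  Exons of a transcript must be disjoint
#' and are stored sorted by `start`.
#'
#' @param exons data.frame with the columns above.
#' @return The validated, sorted exon table (class `transcript_models`).
#' @export
transcript_models <- function(exons) {
  req <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  if (!all(req %in% names(exons)))
    stop("exon table needs columns: ", paste(req, collapse = ", "))
  if (any(exons$end < exons$start))
    stop("malformed exon(s): end < start")
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  for (tx in split(exons, exons$transcript_id)) {
    if (length(unique(tx$strand)) != 1 || length(unique(tx$chrom)) != 1)
      stop("transcript ", tx$transcript_id[1],
           " mixes strands or chromosomes")
    if (nrow(tx) > 1 && any(tx$start[-1] <= tx$end[-nrow(tx)]))
      stop("overlapping exons in transcript ", tx$transcript_id[1])
  }
  rownames(exons) <- NULL
  class(exons) <- c("transcript_models", "data.frame")
  exons
}

#' @rdname transcript_models
#' @param tx a `transcript_models` table.
#' @return `transcript_lengths`: named vector of summed exon lengths.
#' @export
transcript_lengths <- function(tx) {
  vapply(split(tx, tx$transcript_id),
         function(t) sum(t$end - t$start + 1), 1)
}

tx_granges <- function(tx) {
  GenomicRanges::GRanges(tx$chrom,
                         IRanges::IRanges(tx$start, tx$end),
                         strand = tx$strand,
                         transcript_id = tx$transcript_id,
                         gene_id = tx$gene_id)
}

#' lncRNA candidate filter
#'
#' Removes (a) transcripts shorter than `min_len` (summed exon length)
#' and (b) single-exon transcripts whose exon overlaps a same-strand
#' coding exon.  Multi-exon transcripts overlapping coding genes are
#' retained and classified as sense lncRNA candidates downstream.
#'
#' @param transcripts candidate `transcript_models` table.
#' @param coding coding-gene `transcript_models` table.
#' @param min_len minimum transcript length (default 200 nt).
#' @return Character vector of surviving transcript ids.
#' @export
filter_candidates <- function(transcripts, coding, min_len = 200) {
  transcripts <- transcript_models(transcripts)
  lens <- transcript_lengths(transcripts)
  n_exons <- table(transcripts$transcript_id)
  keep <- names(lens)[lens >= min_len]
  single <- names(n_exons)[n_exons == 1]
  if (length(single) > 0 && nrow(coding) > 0) {
    cand_gr <- tx_granges(transcripts[transcripts$transcript_id %in% single, ])
    cod_gr <- tx_granges(coding)
    ov <- GenomicRanges::findOverlaps(cand_gr, cod_gr, ignore.strand = FALSE)
    bad <- unique(cand_gr$transcript_id[S4Vectors::queryHits(ov)])
    keep <- setdiff(keep, bad)
  }
  sort(keep)
}

#' Genomic-context class of a lncRNA candidate
#'
#' `sense` when the candidate has exonic overlap with a coding gene on
#' the same strand; `antisense` when it overlaps coding exons only on
#' the opposite strand; `intergenic` otherwise.
#'
#' @param transcripts candidate `transcript_models` table.
#' @param coding coding-gene `transcript_models` table.
#' @return data.frame `transcript_id`, `context`.
#' @export
classify_context <- function(transcripts, coding) {
  cand_gr <- tx_granges(transcript_models(transcripts))
  ids <- unique(transcripts$transcript_id)
  if (nrow(coding) == 0)
    return(data.frame(transcript_id = ids, context = "intergenic"))
  cod_gr <- tx_granges(coding)
  same <- GenomicRanges::findOverlaps(cand_gr, cod_gr, ignore.strand = FALSE)
  any_ov <- GenomicRanges::findOverlaps(cand_gr, cod_gr, ignore.strand = TRUE)
  sense_tx <- unique(cand_gr$transcript_id[S4Vectors::queryHits(same)])
  ov_tx <- unique(cand_gr$transcript_id[S4Vectors::queryHits(any_ov)])
  context <- ifelse(ids %in% sense_tx, "sense",
                    ifelse(ids %in% ov_tx, "antisense", "intergenic"))
  data.frame(transcript_id = ids, context = context)
}

#' Consensus lncRNA vote
#'
#' A transcript is annotated as a lncRNA when at least `min_votes` of
#' the `n_scorers` coding-potential programs judge it noncoding
#' (the at-least-four-of-five rule by default).
#'
#' @param votes logical vector of per-scorer noncoding verdicts.
#' @param n_scorers expected number of scorers (default 5).
#' @param min_votes votes required (default 4).
#' @return TRUE when called as a lncRNA.
#' @export
vote_lncRNA <- function(votes, n_scorers = 5, min_votes = 4) {
  if (length(votes) != n_scorers)
    stop("expected ", n_scorers, " votes, got ", length(votes))
  if (any(is.na(votes)))
    stop("votes must not be NA")
  sum(votes) >= min_votes
}

#' Longest open reading frame, 6-frame
#'
#' Longest ATG..stop ORF over the three frames of both strands;
#' length in codons, the stop codon excluded.
#'
#' @param seq character DNA sequence (ACGTN).
#' @return Longest ORF length in codons (0 when none).
#' @export
longest_orf <- function(seq) {
  if (nchar(seq) == 0) stop("empty sequence")
  rc <- function(s) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  best <- 0L
  for (s in c(toupper(seq), rc(toupper(seq)))) {
    n <- nchar(s)
    for (off in 0:2) {
      codons <- substring(s, seq(1 + off, n - 2, by = 3),
                          seq(3 + off, n, by = 3))
      if (length(codons) == 0) next
      is_start <- codons == "ATG"
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      open_from <- NA_integer_
      for (i in seq_along(codons)) {
        if (is.na(open_from) && is_start[i]) open_from <- i
        if (!is.na(open_from) && is_stop[i]) {
          best <- max(best, i - open_from)
          open_from <- NA_integer_
        }
      }
    }
  }
  best
}

#' Built-in coding-potential scorers
#'
#' Lightweight scorers standing behind the consensus vote; each returns
#' TRUE when it judges the transcript noncoding.
#'
#' * `orf_scorer`: longest 6-frame ORF shorter than `min_codons`
#'   (default 100).
#' * `hexamer_scorer`: mean log-ratio of coding vs noncoding hexamer
#'   frequencies below 0 (tables from [build_hexamer_tables()]).
#' * `stop_density_scorer`: in each forward frame the reading starts at
#'   the first ATG; the scorer votes noncoding when the stop density
#'   downstream of that ATG exceeds `max_density` (default 0.02) in
#'   every frame, or when no frame contains an ATG at all.
#'
#' @param seq character DNA sequence over ACGTN.
#' @param min_codons ORF threshold in codons.
#' @param tables list with numeric vectors `coding`, `noncoding` of
#'   length 4096 (hexamer frequencies, any common order of names).
#' @param max_density stop-density threshold.
#' @return Logical: TRUE = votes noncoding.
#' @export
orf_scorer <- function(seq, min_codons = 100) {
  longest_orf(seq) < min_codons
}

#' @rdname orf_scorer
#' @export
hexamer_scorer <- function(seq, tables) {
  if (nchar(seq) < 6) stop("sequence shorter than one hexamer")
  s <- toupper(seq)
  hx <- substring(s, 1:(nchar(s) - 5), 6:nchar(s))
  hx <- hx[!grepl("N", hx)]
  if (length(hx) == 0) return(TRUE)
  lr <- log(tables$coding[hx] / tables$noncoding[hx])
  mean(lr, na.rm = TRUE) < 0
}

#' @rdname orf_scorer
#' @export
stop_density_scorer <- function(seq, max_density = 0.02) {
  if (nchar(seq) == 0) stop("empty sequence")
  s <- toupper(seq); n <- nchar(s)
  dens <- sapply(0:2, function(off) {
    codons <- substring(s, seq(1 + off, n - 2, by = 3),
                        seq(3 + off, n, by = 3))
    first_atg <- match("ATG", codons)
    if (is.na(first_atg)) return(Inf)       # frame never opens a read
    codons <- codons[first_atg:length(codons)]
    mean(codons %in% c("TAA", "TAG", "TGA"))
  })
  min(dens) > max_density
}

#' Hexamer frequency tables from training sequences
#'
#' @param coding_seqs,noncoding_seqs character vectors of training
#'   sequences.
#' @param pseudo pseudocount per hexamer (default 1).
#' @return list with named frequency vectors `coding` and `noncoding`
#'   over all 4096 hexamers.
#' @export
build_hexamer_tables <- function(coding_seqs, noncoding_seqs, pseudo = 1) {
  all_hex <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 6))[, 6:1],
                   1, paste, collapse = "")
  count <- function(seqs) {
    tab <- setNames(rep(pseudo, length(all_hex)), all_hex)
    for (s in toupper(seqs)) {
      if (nchar(s) < 6) next
      hx <- substring(s, 1:(nchar(s) - 5), 6:nchar(s))
      hx <- hx[!grepl("N", hx)]
      t2 <- table(hx)
      tab[names(t2)] <- tab[names(t2)] + as.numeric(t2)
    }
    tab / sum(tab)
  }
  list(coding = count(coding_seqs), noncoding = count(noncoding_seqs))
}

#' Run the consensus lncRNA caller on candidate transcripts
#'
#' Applies the three built-in scorers plus optional external votes
#' (e.g. from stand-alone coding-potential tools, as a data.frame with
#' `transcript_id` and one logical column per tool) and the
#' at-least-`min_votes` consensus rule.
#'
#' @param transcripts candidate `transcript_models` table.
#' @param coding coding-gene `transcript_models` table (for context).
#' @param seqs named character vector of candidate transcript sequences.
#' @param hexamer_tables see [build_hexamer_tables()].
#' @param external_votes optional data.frame of extra per-tool votes.
#' @param min_votes consensus threshold (default 4).
#' @return data.frame `transcript_id`, `context`, one column per
#'   scorer, `n_votes`, `is_lncRNA`.
#' @export
call_lncRNAs <- function(transcripts, coding, seqs, hexamer_tables,
                         external_votes = NULL, min_votes = 4) {
  ids <- unique(transcripts$transcript_id)
  if (!all(ids %in% names(seqs)))
    stop("sequence missing for some candidates")
  ctx <- classify_context(transcripts, coding)
  votes <- data.frame(
    transcript_id = ids,
    orf = vapply(seqs[ids], orf_scorer, TRUE),
    hexamer = vapply(seqs[ids], hexamer_scorer, TRUE,
                     tables = hexamer_tables),
    stop_density = vapply(seqs[ids], stop_density_scorer, TRUE),
    row.names = NULL)
  if (!is.null(external_votes)) {
    m <- match(ids, external_votes$transcript_id)
    if (any(is.na(m)))
      stop("external votes missing for some candidates")
    ev <- external_votes[m, setdiff(names(external_votes), "transcript_id"),
                         drop = FALSE]
    votes <- cbind(votes, ev)
  }
  vote_cols <- setdiff(names(votes), "transcript_id")
  n_scorers <- length(vote_cols)
  votes$n_votes <- rowSums(votes[, vote_cols, drop = FALSE])
  votes$is_lncRNA <- vapply(seq_len(nrow(votes)), function(i)
    vote_lncRNA(as.logical(votes[i, vote_cols]), n_scorers = n_scorers,
                min_votes = min_votes), TRUE)
  merge(ctx, votes, by = "transcript_id", sort = TRUE)
}

# introns of one exon chain (data.frame start/end sorted); returns
# matrix with columns s, e (possibly 0 rows)
chain_introns <- function(ex) {
  if (nrow(ex) < 2) return(cbind(s = integer(0), e = integer(0)))
  cbind(s = ex$end[-nrow(ex)] + 1L, e = ex$start[-1] - 1L)
}

# classify the local difference between two exon chains of one gene
classify_pair <- function(ex1, ex2, strand) {
  span <- c(max(min(ex1$start), min(ex2$start)),
            min(max(ex1$end), max(ex2$end)))
  if (span[1] > span[2]) return(NULL)     # no shared span
  in_span <- function(i) i[, "s"] > span[1] & i[, "e"] < span[2]
  i1 <- chain_introns(ex1); i1 <- i1[in_span(i1), , drop = FALSE]
  i2 <- chain_introns(ex2); i2 <- i2[in_span(i2), , drop = FALSE]
  key <- function(m) paste(m[, "s"], m[, "e"])
  d1 <- i1[!(key(i1) %in% key(i2)), , drop = FALSE]
  d2 <- i2[!(key(i2) %in% key(i1)), , drop = FALSE]
  if (nrow(d1) == 0 && nrow(d2) == 0) return(NULL)
  # orient so d1 is the side with fewer (or equal) differing introns
  if (nrow(d1) > nrow(d2)) { tmp <- d1; d1 <- d2; d2 <- tmp }
  type <- "complex"; region <- c(min(c(d1[, "s"], d2[, "s"])),
                                 max(c(d1[, "e"], d2[, "e"])))
  if (nrow(d1) == 0 && nrow(d2) == 1) {
    # an intron of one chain entirely exonic in the other
    type <- "intron_retention"
    region <- c(d2[1, "s"], d2[1, "e"])
  } else if (nrow(d1) == 1 && nrow(d2) == 2) {
    J <- d1[1, ]; a <- d2[1, ]; b <- d2[2, ]
    if (a[["s"]] == J[["s"]] && b[["e"]] == J[["e"]] &&
        a[["e"]] < b[["s"]]) {
      type <- "exon_skipping"
      region <- c(a[["e"]] + 1L, b[["s"]] - 1L)
    }
  } else if (nrow(d1) == 1 && nrow(d2) == 1) {
    a <- d1[1, ]; b <- d2[1, ]
    overlap <- a[["s"]] <= b[["e"]] && b[["s"]] <= a[["e"]]
    if (overlap && a[["s"]] == b[["s"]] && a[["e"]] != b[["e"]]) {
      # 3' intron boundary differs on the genomic + orientation
      type <- if (strand == "+") "alt_acceptor" else "alt_donor"
      region <- c(min(a[["e"]], b[["e"]]) + 1L, max(a[["e"]], b[["e"]]))
    } else if (overlap && a[["e"]] == b[["e"]] && a[["s"]] != b[["s"]]) {
      type <- if (strand == "+") "alt_donor" else "alt_acceptor"
      region <- c(min(a[["s"]], b[["s"]]), max(a[["s"]], b[["s"]]) - 1L)
    }
  }
  list(type = type, region = region)
}

#' Classify alternative-splicing events between isoforms of a gene
#'
#' All isoform pairs within each gene are compared over their shared
#' genomic span.  A skipped internal exon gives `exon_skipping`; a
#' shared intron differing only at its 5' (transcription orientation)
#' boundary gives `alt_donor`, only at its 3' boundary `alt_acceptor`;
#' an intron of one isoform lying entirely inside an exon of the other
#' gives `intron_retention`; any other local difference is `complex`.
#' Donor/acceptor are strand-aware, and the classification does not
#' depend on the order of the two isoforms.
#'
#' @param transcripts `transcript_models` exon table (one or more
#'   genes).
#' @param fpkm optional named vector of transcript FPKM; isoforms below
#'   `min_fpkm` are dropped before comparison.
#' @param min_fpkm expression filter (default 1).
#' @return data.frame `gene_id`, `isoform_a`, `isoform_b`, `type`,
#'   `region_start`, `region_end`.
#' @export
detect_as_events <- function(transcripts, fpkm = NULL, min_fpkm = 1) {
  tx <- transcript_models(transcripts)
  if (!is.null(fpkm)) {
    keep <- names(fpkm)[fpkm >= min_fpkm]
    tx <- tx[tx$transcript_id %in% keep, , drop = FALSE]
  }
  out <- list()
  for (g in unique(tx$gene_id)) {
    sub <- tx[tx$gene_id == g, , drop = FALSE]
    if (length(unique(sub$strand)) > 1)
      stop("isoforms of gene ", g, " lie on different strands")
    iso <- split(sub, sub$transcript_id)
    if (length(iso) < 2) next
    ids <- names(iso)
    for (pair in combn(ids, 2, simplify = FALSE)) {
      ev <- classify_pair(iso[[pair[1]]], iso[[pair[2]]],
                          strand = sub$strand[1])
      if (is.null(ev)) next
      out[[length(out) + 1]] <- data.frame(
        gene_id = g, isoform_a = pair[1], isoform_b = pair[2],
        type = ev$type, region_start = ev$region[1],
        region_end = ev$region[2])
    }
  }
  if (length(out) == 0)
    return(data.frame(gene_id = character(), isoform_a = character(),
                      isoform_b = character(), type = character(),
                      region_start = integer(), region_end = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cell-type-specific and lineage-maintained isoforms
#'
#' Given per-cell-type sets of expressed isoforms, an isoform is
#' cell-type-specific when present in that type and absent from its
#' counterpart (AC vs BC, 32E vs 32S), and lineage-maintained when
#' specific to the lineage's cell type at both stages (apical: AC and
#' 32E; basal: BC and 32S).
#'
#' @param sets named list of character vectors of isoform ids, with
#'   names among AC, BC, 32E, 32S.
#' @param counterpart named mapping of each cell type to the one it is
#'   compared against.
#' @return list with `specific` (per cell type) and `ACL_maintained`,
#'   `BCL_maintained`.
#' @export
compare_across_cells <- function(sets,
                                 counterpart = c(AC = "BC", BC = "AC",
                                                 `32E` = "32S",
                                                 `32S` = "32E")) {
  unknown <- setdiff(names(sets), names(counterpart))
  if (length(unknown) > 0)
    stop("unknown cell type key(s): ", paste(unknown, collapse = ", "))
  specific <- lapply(names(sets), function(ct) {
    other <- counterpart[[ct]]
    if (!other %in% names(sets))
      stop("counterpart '", other, "' of '", ct, "' missing from sets")
    setdiff(sets[[ct]], sets[[other]])
  })
  names(specific) <- names(sets)
  acl <- if (all(c("AC", "32E") %in% names(specific)))
    intersect(specific$AC, specific$`32E`) else character()
  bcl <- if (all(c("BC", "32S") %in% names(specific)))
    intersect(specific$BC, specific$`32S`) else character()
  list(specific = specific, ACL_maintained = acl, BCL_maintained = bcl)
}

#' Read / write transcript models as GTF
#'
#' One `exon` feature per exon row with `gene_id` and `transcript_id`
#' attributes (1-based inclusive coordinates).
#'
#' @param tx a `transcript_models` table.
#' @param file path.
#' @export
write_transcripts_gtf <- function(tx, file) {
  gr <- tx_granges(tx)
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$source <- "lineagetx"
  rtracklayer::export(gr, file, format = "gtf")
  invisible(file)
}

#' @rdname write_transcripts_gtf
#' @export
read_transcripts_gtf <- function(file) {
  gr <- rtracklayer::import(file, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  transcript_models(data.frame(
    transcript_id = S4Vectors::mcols(gr)$transcript_id,
    gene_id = S4Vectors::mcols(gr)$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)))
}
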