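#' Pipeline configuration
#'
#' Collects every input path or synthetic-generation block and every
#' threshold of the analysis, with the standard defaults.
#'
#' @param outdir output directory.
#' @param counts,samples paths to a counts TSV and sample sheet TSV
#'   (omit when `synthetic` is given).
#' @param synthetic list with optional `design` ([study_design()]) and
#'   `effects` ([effect_config()]); presence switches the pipeline to
#'   generated data with planted truth.
#' @param contrasts character vector of `"A:B"` contrasts.
#' @param fc_min,fdr_max DEG thresholds (fold change >= 2,
#'   FDR < 0.01).
#' @param fpkm_threshold expressed-gene threshold (FPKM >= 1).
#' @param fate_high,fate_negligible transcript-fate thresholds (FPKM).
#' @param r_min coexpression threshold (Pearson r > 0.87).
#' @param tf_fdr_max TF-enrichment cutoff for network membership.
#' @param min_votes lncRNA consensus votes required.
#' @param uhc_k clusters for the sample dendrogram cut.
#' @param acl_k,bcl_k profile groups for maintained-gene clustering.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            counts = NULL, samples = NULL,
                            synthetic = NULL,
                            contrasts = DEFAULT_CONTRASTS,
                            fc_min = 2, fdr_max = 0.01,
                            fpkm_threshold = 1,
                            fate_high = 5, fate_negligible = 1,
                            r_min = 0.87, tf_fdr_max = 0.05,
                            min_votes = 4, uhc_k = 5,
                            acl_k = 4, bcl_k = 3) {
  if (is.null(synthetic) && (is.null(counts) || is.null(samples)))
    stop("config needs either counts+samples paths or a synthetic block")
  for (v in c(fc_min, fdr_max, fpkm_threshold, fate_high,
              fate_negligible, r_min, tf_fdr_max, min_votes, uhc_k))
    if (!is.finite(v)) stop("all thresholds must be finite")
  if (fc_min <= 1) stop("fc_min must be > 1")
  if (fdr_max <= 0 || fdr_max > 1) stop("fdr_max must be in (0, 1]")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full lineage-transcriptome pipeline
#'
#' Executes, in order: synthetic generation (when configured),
#' FPKM quantification and expressed-gene calling, the six
#' differential-expression contrasts, sample-level structure
#' (correlation, hierarchical clustering, PCA), lineage-maintained gene
#' and transcript-fate calling with profile grouping, annotation-term
#' enrichment, the TF motif/coexpression network, and lncRNA +
#' alternative-splicing analysis.  Per-stage tables are written under
#' the output directory and a machine-readable `summary.json` collects
#' set sizes, thresholds and - when planted truth is available -
#' recovery metrics.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return The summary list, invisibly; stage outputs are attached as
#'   attribute `"stages"`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(format(Sys.time(), "%H:%M:%S "),
                                           ...)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  # --- stage: data -----------------------------------------------------
  bundle <- NULL
  if (!is.null(config$synthetic)) {
    say("stage data: generating synthetic bundle")
    design <- config$synthetic$design
    if (is.null(design)) design <- study_design()
    effects <- config$synthetic$effects
    if (is.null(effects)) effects <- effect_config()
    noise <- config$synthetic$noise
    if (is.null(noise)) noise <- TRUE
    bundle <- simulate_bundle(design, effects, noise = noise)
    write_bundle(bundle, file.path(outdir, "bundle"))
    cm <- bundle$counts
  } else {
    say("stage data: reading ", config$counts)
    cm <- read_counts(config$counts, config$samples)
  }
  truth <- bundle$truth

  # --- stage: quantify -------------------------------------------------
  say("stage quantify")
  em <- compute_fpkm(cm)
  write_fpkm(em, file.path(outdir, "fpkm.tsv"))
  sf <- size_factors(cm)
  present <- intersect(CONTRAST_TYPES, unique(cm$samples$cell_type))
  expressed <- lapply(setNames(present, present), function(ct)
    expressed_genes(em, ct, threshold = config$fpkm_threshold))
  universe <- sort(unique(unlist(expressed)))

  # --- stage: de -------------------------------------------------------
  de <- list()
  for (ctr in config$contrasts) {
    say("stage de: ", ctr)
    de[[ctr]] <- de_contrast(cm, ctr, fc_min = config$fc_min,
                             fdr_max = config$fdr_max, sf = sf)
    write_de(de[[ctr]],
             file.path(outdir, paste0("de_", sub(":", "_vs_", ctr),
                                      ".tsv")))
  }

  # --- stage: structure ------------------------------------------------
  say("stage structure")
  struct_samples <- cm$samples$sample_id[cm$samples$cell_type %in% present]
  em_sub <- em
  em_sub$fpkm <- em$fpkm[, struct_samples, drop = FALSE]
  em_sub$samples <- em$samples[match(struct_samples,
                                     em$samples$sample_id), ]
  rr <- correlation_matrix(em_sub, genes = universe)
  uhc <- hierarchical_cluster(rr, k = min(config$uhc_k, ncol(rr)))
  pca <- pca_samples(em_sub, genes = universe)
  write.table(round(rr, 6), file.path(outdir, "correlation.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  writeLines(uhc$newick, file.path(outdir, "dendrogram.nwk"))
  write.table(data.frame(sample_id = rownames(pca$coords),
                         round(pca$coords[, 1:min(4, ncol(pca$coords))], 4)),
              file.path(outdir, "pca.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # --- stage: lineage --------------------------------------------------
  say("stage lineage")
  lm_sets <- fate <- profiles <- NULL
  if (all(c("AC:BC", "32E:32S") %in% names(de))) {
    lm_sets <- lineage_maintained(de[["AC:BC"]], de[["32E:32S"]])
    fate <- classify_transcript_fate(em, de[["AC:BC"]],
                                     high_fpkm = config$fate_high,
                                     negligible_fpkm = config$fate_negligible)
    write.table(fate, file.path(outdir, "fate_labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (nm in names(lm_sets))
      writeLines(lm_sets[[nm]], file.path(outdir, paste0(nm, ".txt")))
    profiles <- list()
    if (length(lm_sets$ACL_maintained) >= config$acl_k)
      profiles$ACL <- cluster_profiles(em, lm_sets$ACL_maintained,
                                       k = config$acl_k)
    if (length(lm_sets$BCL_maintained) >= config$bcl_k)
      profiles$BCL <- cluster_profiles(em, lm_sets$BCL_maintained,
                                       k = config$bcl_k)
  }

  # --- stage: enrichment -----------------------------------------------
  say("stage enrichment")
  enr <- NULL
  annotation <- if (!is.null(bundle)) bundle$annotation else NULL
  if (!is.null(annotation) && !is.null(lm_sets)) {
    enr <- lapply(lm_sets, function(set)
      enrich(intersect(set, universe), annotation, universe))
    write.table(enr$ACL_maintained,
                file.path(outdir, "enrichment_ACL.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(enr$BCL_maintained,
                file.path(outdir, "enrichment_BCL.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- stage: tf network -----------------------------------------------
  say("stage tfnet")
  tfnet <- NULL
  if (!is.null(bundle) && "AC:BC" %in% names(de)) {
    hits <- scan_promoters(bundle$promoters, bundle$motifs)
    tf_ids <- vapply(bundle$motifs, `[[`, "", "tf_id")
    tf_genes <- setNames(truth$tf$gene_id, truth$tf$tf_id)
    up <- intersect(de[["AC:BC"]]$up, universe)
    dn <- intersect(de[["AC:BC"]]$down, universe)
    enr_up <- tf_motif_enrichment(up, hits, universe, tf_ids = tf_ids)
    enr_dn <- tf_motif_enrichment(dn, hits, universe, tf_ids = tf_ids)
    coex <- coexpression_table(em, hits, tf_genes, r_min = config$r_min)
    edges <- unique(rbind(
      build_network(enr_up, hits, coex, fdr_max = config$tf_fdr_max),
      build_network(enr_dn, hits, coex, fdr_max = config$tf_fdr_max)))
    enriched_tfs <- sort(unique(c(
      enr_up$tf_id[enr_up$FDR < config$tf_fdr_max],
      enr_dn$tf_id[enr_dn$FDR < config$tf_fdr_max])))
    write.table(edges, file.path(outdir, "tf_network_edges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_hits_bed(hits, bundle$promoters,
                   file.path(outdir, "motif_hits.bed"))
    tfnet <- list(hits = hits, enr_up = enr_up, enr_dn = enr_dn,
                  coex = coex, edges = edges, enriched_tfs = enriched_tfs)
  }

  # --- stage: lncRNA + splicing ----------------------------------------
  say("stage lnc/AS")
  lncas <- NULL
  if (!is.null(bundle)) {
    tx <- bundle$tx
    is_cand <- tx$truth$transcripts$role %in%
      c("lnc_candidate", "decoy_short", "decoy_single_overlap")
    cand_ids <- tx$truth$transcripts$transcript_id[is_cand]
    cand_tab <- tx$transcripts[tx$transcripts$transcript_id %in% cand_ids, ]
    surv <- filter_candidates(cand_tab, tx$coding)
    surv_tab <- tx$transcripts[tx$transcripts$transcript_id %in% surv, ]
    coding_ids <- tx$truth$transcripts$transcript_id[
      tx$truth$transcripts$coding]
    hex <- build_hexamer_tables(tx$seqs[coding_ids], tx$seqs[surv])
    calls <- call_lncRNAs(surv_tab, tx$coding, tx$seqs, hex,
                          external_votes = tx$external_votes,
                          min_votes = config$min_votes)
    write.table(calls, file.path(outdir, "lncRNA_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    iso_sets <- lapply(setNames(colnames(tx$fpkm), colnames(tx$fpkm)),
                       function(ct)
                         rownames(tx$fpkm)[tx$fpkm[, ct] >=
                                             config$fpkm_threshold])
    events <- list()
    for (ct in names(iso_sets)) {
      keep <- tx$transcripts$transcript_id %in% iso_sets[[ct]]
      ev <- detect_as_events(tx$transcripts[keep, , drop = FALSE])
      if (nrow(ev) > 0) ev$cell_type <- ct
      events[[ct]] <- ev
    }
    events <- do.call(rbind, events)
    write.table(events, file.path(outdir, "as_events.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    iso_cmp <- compare_across_cells(iso_sets)
    lncas <- list(survivors = surv, calls = calls, events = events,
                  iso_sets = iso_sets, iso_cmp = iso_cmp)
  }

  # --- summary ---------------------------------------------------------
  say("writing summary")
  summary <- list(
    thresholds = config[c("fc_min", "fdr_max", "fpkm_threshold",
                          "fate_high", "fate_negligible", "r_min",
                          "tf_fdr_max", "min_votes", "uhc_k")],
    n_genes = nrow(cm$counts), n_samples = ncol(cm$counts),
    n_expressed = vapply(expressed, length, 1L),
    deg_counts = lapply(de, function(d)
      list(up = length(d$up), down = length(d$down))))
  if (!is.null(lm_sets))
    summary$lineage <- list(ACL_maintained = length(lm_sets$ACL_maintained),
                            BCL_maintained = length(lm_sets$BCL_maintained))
  if (!is.null(tfnet))
    summary$tf_network <- list(enriched_tfs = tfnet$enriched_tfs,
                               n_edges = nrow(tfnet$edges))
  if (!is.null(lncas))
    summary$lnc_as <- list(
      n_candidates_surviving = length(lncas$survivors),
      n_lncRNA = sum(lncas$calls$is_lncRNA),
      n_as_events = if (is.null(lncas$events)) 0L else nrow(lncas$events),
      ACL_specific_isoforms = length(lncas$iso_cmp$specific$AC),
      BCL_specific_isoforms = length(lncas$iso_cmp$specific$BC))
  if (!is.null(truth)) {
    jac <- function(a, b) {
      u <- length(union(a, b))
      if (u == 0) return(1)
      length(intersect(a, b)) / u
    }
    g <- truth$genes
    summary$recovery <- list()
    if (!is.null(lm_sets)) {
      summary$recovery$jaccard_ACL <-
        jac(g$gene_id[g$class == "ACL_maintained"], lm_sets$ACL_maintained)
      summary$recovery$jaccard_BCL <-
        jac(g$gene_id[g$class == "BCL_maintained"], lm_sets$BCL_maintained)
    }
    if (!is.null(fate)) {
      fg <- g[g$class %in% c("inherited_asymmetric", "de_novo",
                             "selective_deletion"), ]
      m <- match(fg$gene_id, fate$gene_id)
      summary$recovery$fate_accuracy <-
        mean(!is.na(m) & fate$mechanism[m] == fg$class)
    }
    ct_truth <- em_sub$samples$cell_type
    summary$recovery$uhc_ari <-
      adjusted_rand_index(uhc$labels[em_sub$samples$sample_id], ct_truth)
    within_r <- unlist(lapply(split(em_sub$samples$sample_id, ct_truth),
                              function(ids) {
                                sub <- rr[ids, ids]
                                sub[upper.tri(sub)]
                              }))
    summary$recovery$min_within_celltype_r <- min(within_r)
    if (!is.null(tfnet)) {
      planted_tfs <- sort(truth$tf$tf_id[truth$tf$planted])
      summary$recovery$tf_set_exact <-
        identical(tfnet$enriched_tfs, planted_tfs)
      truth_edges <- paste(truth$tf_targets$tf_id,
                           truth$tf_targets$gene_id)
      got_edges <- paste(tfnet$edges$tf_id, tfnet$edges$gene_id)
      summary$recovery$edge_jaccard <- jac(truth_edges, got_edges)
    }
    if (!is.null(lncas)) {
      tt <- truth$transcripts
      lnc_truth <- tt$transcript_id[tt$role == "lnc_candidate" & !tt$coding]
      called <- lncas$calls$transcript_id[lncas$calls$is_lncRNA]
      summary$recovery$lnc_jaccard <- jac(lnc_truth, called)
      ev <- detect_as_events(bundle$tx$transcripts)
      m <- match(truth$as_genes$gene_id, ev$gene_id)
      summary$recovery$as_type_accuracy <-
        mean(!is.na(m) &
               ev$type[m] == sub("^ir$", "intron_retention",
                                 sub("^es$", "exon_skipping",
                                     truth$as_genes$type)))
    }
  }
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res <- summary
  attr(res, "stages") <- list(counts = cm, em = em, de = de,
                              structure = list(r = rr, uhc = uhc,
                                               pca = pca),
                              lineage = list(sets = lm_sets, fate = fate,
                                             profiles = profiles),
                              enrichment = enr, tfnet = tfnet,
                              lncas = lncas, bundle = bundle)
  invisible(res)
}
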