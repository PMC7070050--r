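# shared fixtures, built in code

# tiny count matrix with explicit numbers for formula-level checks
tiny_cm <- function() {
  counts <- matrix(c(100L, 0L, 50L,
                     200L, 10L, 400L), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  count_matrix(counts,
               lengths = c(g1 = 1000, g2 = 2000, g3 = 500),
               samples = data.frame(sample_id = c("s1", "s2"),
                                    cell_type = c("AC", "BC"),
                                    replicate = c(1, 1)))
}

# reduced synthetic design for module tests (the default design is used
# in the end-to-end acceptance checks)
small_design <- function(seed = 1, n_genes = 800) {
  study_design(n_genes = n_genes, seed = seed)
}

small_effects <- function(...) {
  effect_config(class_sizes = c(ACL_maintained = 40, BCL_maintained = 30,
                                inherited_asymmetric = 24, de_novo = 24,
                                selective_deletion = 24, EMB_like = 18),
                ...)
}

# cache one small noiseless bundle per session: several tests only need
# expected-value profiles
.small_bundle_cache <- new.env()
small_bundle <- function(noise = FALSE, seed = 5) {
  key <- paste0("b", noise, seed)
  if (is.null(.small_bundle_cache[[key]]))
    .small_bundle_cache[[key]] <- simulate_bundle(
      small_design(seed = seed), small_effects(), noise = noise)
  .small_bundle_cache[[key]]
}

# an expression_matrix built directly from an FPKM matrix
fpkm_em <- function(fpkm, cell_types) {
  structure(list(fpkm = fpkm,
                 samples = data.frame(sample_id = colnames(fpkm),
                                      cell_type = cell_types,
                                      replicate = seq_along(cell_types)),
                 method = "fpkm"),
            class = "expression_matrix")
}

# exon-table constructor for AS fixtures: list of c(start, end) pairs
tx_fixture <- function(id, gene, strand, exons, chrom = "chrF") {
  do.call(rbind, lapply(exons, function(e)
    data.frame(transcript_id = id, gene_id = gene, chrom = chrom,
               strand = strand, start = e[1], end = e[2])))
}

# mirror exon coordinates around a fixed point (strand-reversal helper)
mirror_exons <- function(exons, at = 10000) {
  lapply(rev(exons), function(e) c(at - e[2], at - e[1]))
}
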