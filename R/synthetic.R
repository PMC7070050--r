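#' Study design for the synthetic generator
#'
#' Mirrors the profiled cell types of the zygote -> (AC, BC) ->
#' (32E, 32S) design: egg cell and two zygote stages, the two daughter
#' cells, and the embryo proper / suspensor of the 32-cell proembryo,
#' each with replicated bulk samples.
#'
#' @param cell_types ordered cell-type labels.
#' @param replicates replicates per cell type (>= 2).
#' @param n_genes number of genes in the synthetic genome.
#' @param n_tf number of transcription factors with motif matrices.
#' @param n_terms number of annotation terms.
#' @param seed integer seed; fully determines every generated artifact.
#' @return list of class `study_design`.
#' @export
study_design <- function(cell_types = CELL_TYPES, replicates = 3,
                         n_genes = 3000, n_tf = 6, n_terms = 40,
                         seed = 1) {
  if (replicates < 2) stop("replicates_per_type must be >= 2")
  if (length(cell_types) == 0 || anyDuplicated(cell_types))
    stop("cell_types must be non-empty and unique")
  structure(list(cell_types = cell_types, replicates = replicates,
                 n_genes = n_genes, n_tf = n_tf, n_terms = n_terms,
                 seed = seed),
            class = "study_design")
}

#' Planted-effect configuration
#'
#' Parameters of the count model and of every planted gene class.
#' Counts are negative binomial (gamma-Poisson) around expected FPKM
#' profiles: baseline abundance is log-normal, lineage-maintained genes
#' carry a planted `lfc` log2 fold change between the favored and
#' disfavored lineage at both stages, and the three transcript-fate
#' classes follow fixed FPKM profiles (high in the zygote and one
#' daughter for inherited transcripts, and so on).  Size factors are
#' drawn log-uniform to exercise normalization; gene lengths are
#' uniform to exercise FPKM length correction.
#'
#' @param alpha NB dispersion (> 0); see the methods vignette for how
#'   the default was fixed.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline abundance
#'   (relative FPKM scale).
#' @param lfc planted |log2 fold change| of lineage-maintained genes.
#' @param class_sizes named integer vector of planted class sizes.
#' @param acl_groups,bcl_groups,emb_groups number of profile subgroups.
#' @param depth expected fragments per sample before size factors.
#' @param size_factor_range log-uniform range of sample size factors.
#' @param length_range uniform range of gene lengths (nt).
#' @param jitter_sdlog per-gene log-normal jitter multiplying fate-class
#'   profiles.
#' @param fate_fpkm list of per-mechanism FPKM profiles (apical-favored
#'   orientation; the basal-favored version swaps AC/BC and 32E/32S).
#' @return list of class `effect_config`.
#' @export
effect_config <- function(alpha = 0.04,
                          baseline_meanlog = log(100),
                          baseline_sdlog = 1,
                          lfc = 3,
                          class_sizes = c(ACL_maintained = 120,
                                          BCL_maintained = 90,
                                          inherited_asymmetric = 60,
                                          de_novo = 60,
                                          selective_deletion = 60,
                                          EMB_like = 90),
                          acl_groups = 4, bcl_groups = 3, emb_groups = 3,
                          depth = 2e6,
                          size_factor_range = c(0.7, 1.4),
                          length_range = c(500, 5000),
                          jitter_sdlog = 0.25,
                          fate_fpkm = NULL) {
  if (alpha <= 0) stop("dispersion alpha must be positive")
  if (baseline_meanlog <= -Inf || depth <= 0)
    stop("baseline mean and depth must be positive")
  if (is.null(fate_fpkm))
    fate_fpkm <- list(
      inherited_asymmetric =
        c(EC = 8, Zy14 = 20, Zy24 = 50, AC = 40, BC = 0.2,
          `32E` = 0.2, `32S` = 0.2),
      de_novo =
        c(EC = 0.1, Zy14 = 0.1, Zy24 = 0.2, AC = 30, BC = 0.2,
          `32E` = 8, `32S` = 8),
      selective_deletion =
        c(EC = 15, Zy14 = 30, Zy24 = 50, AC = 40, BC = 0.2,
          `32E` = 10, `32S` = 10))
  structure(list(alpha = alpha, baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, lfc = lfc,
                 class_sizes = class_sizes, acl_groups = acl_groups,
                 bcl_groups = bcl_groups, emb_groups = emb_groups,
                 depth = depth, size_factor_range = size_factor_range,
                 length_range = length_range, jitter_sdlog = jitter_sdlog,
                 fate_fpkm = fate_fpkm),
            class = "effect_config")
}

# canonical multiplier profiles over the seven cell types; F is the
# planted fold change between favored and disfavored lineage
class_profiles <- function(fc) {
  F <- fc
  list(
    ACL = list(
      c(EC = 3,   Zy14 = 3,   Zy24 = 3,   AC = 4, BC = 4 / F,
        `32E` = 4, `32S` = 4 / F),
      c(EC = 0.2, Zy14 = 0.5, Zy24 = 1,   AC = 4, BC = 4 / F,
        `32E` = 4, `32S` = 4 / F),
      c(EC = 0.5, Zy14 = 1,   Zy24 = 2,   AC = 6, BC = 6 / F,
        `32E` = 2, `32S` = 2 / F),
      c(EC = 0.2, Zy14 = 0.2, Zy24 = 0.3, AC = 2, BC = 2 / F,
        `32E` = 6, `32S` = 6 / F)),
    BCL = list(
      c(EC = 3,   Zy14 = 3,   Zy24 = 3,   AC = 4 / F, BC = 4,
        `32E` = 4 / F, `32S` = 4),
      c(EC = 0.2, Zy14 = 0.5, Zy24 = 1,   AC = 4 / F, BC = 4,
        `32E` = 4 / F, `32S` = 4),
      c(EC = 0.2, Zy14 = 0.2, Zy24 = 0.3, AC = 2 / F, BC = 2,
        `32E` = 6 / F, `32S` = 6)),
    EMB = list(shape = c(EC = 0.2, Zy14 = 0.5, Zy24 = 1, AC = 2, BC = 2,
                         `32E` = 3, `32S` = 3),
               levels = c(4, 1, 0.25)))
}

# swap apical and basal columns of a named profile
mirror_profile <- function(p) {
  q <- p
  q[c("AC", "BC", "32E", "32S")] <- p[c("BC", "AC", "32S", "32E")]
  q
}

#' Simulate the count matrix with planted truth
#'
#' Draws gene lengths, assigns planted classes, builds expected FPKM
#' profiles per cell type, converts them to expected counts at the
#' configured depth and size factors, and samples NB counts
#' (`noise = FALSE` instead returns rounded expected counts, the
#' noiseless mode used for exact-recovery checks).
#'
#' Planted classes and their canonical profiles:
#' ACL/BCL-maintained genes (up in the favored lineage at both stages,
#' in `acl_groups`/`bcl_groups` temporal subgroups), the three
#' transcript-fate classes, EMB-like genes (lineage-neutral embryo
#' expression in `emb_groups` level subgroups), and null genes.
#' A subset of maintained genes doubles as the planted transcription
#' factors; decoy TFs are null genes.
#'
#' @param design a [study_design()].
#' @param effects an [effect_config()].
#' @param noise sample NB counts (TRUE) or return expected counts
#'   (FALSE).
#' @return list with `counts` (a [count_matrix()]), `truth` (list with
#'   `genes`, `tf`, `tf_targets`), `expected_fpkm` (genes x cell types)
#'   and `size_factors`.
#' @export
simulate_counts <- function(design, effects = effect_config(),
                            noise = TRUE) {
  stopifnot(inherits(design, "study_design"))
  if (effects$alpha <= 0) stop("dispersion alpha must be positive")
  set.seed(design$seed)
  n <- design$n_genes
  types <- design$cell_types
  gene_ids <- sprintf("G%04d", seq_len(n))
  lens <- round(runif(n, effects$length_range[1], effects$length_range[2]))

  cs <- effects$class_sizes
  cls <- rep("null", n); subgroup <- rep(NA_integer_, n)
  lineage <- rep(NA_character_, n)
  cursor <- 0
  take <- function(k) {
    idx <- cursor + seq_len(k); cursor <<- cursor + k
    if (cursor > n) stop("class sizes exceed n_genes")
    idx
  }
  idx_acl <- if (cs[["ACL_maintained"]] > 0) take(cs[["ACL_maintained"]]) else integer()
  idx_bcl <- if (cs[["BCL_maintained"]] > 0) take(cs[["BCL_maintained"]]) else integer()
  idx_inh <- if (cs[["inherited_asymmetric"]] > 0) take(cs[["inherited_asymmetric"]]) else integer()
  idx_dn  <- if (cs[["de_novo"]] > 0) take(cs[["de_novo"]]) else integer()
  idx_sd  <- if (cs[["selective_deletion"]] > 0) take(cs[["selective_deletion"]]) else integer()
  idx_emb <- if (cs[["EMB_like"]] > 0) take(cs[["EMB_like"]]) else integer()

  cls[idx_acl] <- "ACL_maintained"; lineage[idx_acl] <- "ACL"
  subgroup[idx_acl] <- rep(seq_len(effects$acl_groups),
                           length.out = length(idx_acl))
  cls[idx_bcl] <- "BCL_maintained"; lineage[idx_bcl] <- "BCL"
  subgroup[idx_bcl] <- rep(seq_len(effects$bcl_groups),
                           length.out = length(idx_bcl))
  for (fc in list(c("inherited_asymmetric", "idx_inh"),
                  c("de_novo", "idx_dn"),
                  c("selective_deletion", "idx_sd"))) {
    idx <- get(fc[2])
    cls[idx] <- fc[1]
    lineage[idx] <- rep(c("ACL", "BCL"), length.out = length(idx))
  }
  cls[idx_emb] <- "EMB_like"
  subgroup[idx_emb] <- rep(seq_len(effects$emb_groups),
                           length.out = length(idx_emb))

  profs <- class_profiles(2^effects$lfc)
  q <- matrix(0, n, length(types), dimnames = list(gene_ids, types))
  base <- rlnorm(n, effects$baseline_meanlog, effects$baseline_sdlog)
  flat <- setNames(rep(1, length(types)), types)
  for (i in seq_len(n)) {
    p <- switch(cls[i],
      null = flat,
      ACL_maintained = profs$ACL[[subgroup[i]]],
      BCL_maintained = profs$BCL[[subgroup[i]]],
      EMB_like = {
        # narrow abundance jitter so the planted level subgroups stay
        # separable by expression level
        q[i, ] <- exp(effects$baseline_meanlog) * rlnorm(1, 0, 0.15) *
          (profs$EMB$shape * profs$EMB$levels[subgroup[i]])[types]
        NULL
      },
      inherited_asymmetric = ,
      de_novo = ,
      selective_deletion = {
        fp <- effects$fate_fpkm[[cls[i]]]
        if (lineage[i] == "BCL") fp <- mirror_profile(fp)
        q[i, ] <- fp[types] * rlnorm(1, 0, effects$jitter_sdlog)
        NULL
      })
    if (!is.null(p)) q[i, ] <- base[i] * p[types]
  }

  # compositional normalization per cell type so that expected observed
  # FPKM equals the planted profile
  for (t in types) q[, t] <- q[, t] * 1e9 / sum(q[, t] * lens)

  reps <- design$replicates
  sample_ids <- paste0(rep(types, each = reps), "_r", seq_len(reps))
  samples <- data.frame(sample_id = sample_ids,
                        cell_type = rep(types, each = reps),
                        replicate = rep(seq_len(reps), length(types)))
  sfr <- effects$size_factor_range
  sf <- exp(runif(length(sample_ids), log(sfr[1]), log(sfr[2])))
  mu <- q[, samples$cell_type, drop = FALSE] *
    outer(lens, sf * effects$depth) / 1e9
  colnames(mu) <- sample_ids
  counts <- if (noise) {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / effects$alpha),
           n, length(sample_ids), dimnames = dimnames(mu))
  } else {
    round(mu)
  }

  # planted TFs: two per lineage drawn from one maintained subgroup,
  # plus two null-profile decoys
  n_tf <- design$n_tf
  tf_ids <- sprintf("TF%d", seq_len(n_tf))
  pick_first <- function(idx, grp, k, groups_of) {
    cand <- idx[groups_of[idx] == grp]
    cand[seq_len(min(k, length(cand)))]
  }
  planted_tf_genes <- c(
    if (length(idx_acl)) pick_first(idx_acl, 2, 1, subgroup),
    if (length(idx_acl)) pick_first(idx_acl, 4, 1, subgroup),
    if (length(idx_bcl)) pick_first(idx_bcl, 2, 1, subgroup),
    if (length(idx_bcl)) pick_first(idx_bcl, 3, 1, subgroup))
  null_pool <- which(cls == "null")
  n_planted <- min(length(planted_tf_genes), n_tf)
  n_decoy <- n_tf - n_planted
  tf_gene_idx <- c(planted_tf_genes[seq_len(n_planted)],
                   null_pool[seq_len(n_decoy)])
  tf <- data.frame(tf_id = tf_ids,
                   gene_id = gene_ids[tf_gene_idx],
                   planted = c(rep(TRUE, n_planted), rep(FALSE, n_decoy)))
  # targets: other members of the TF's own subgroup (coexpressed by
  # construction)
  tf_targets <- do.call(rbind, lapply(seq_len(nrow(tf)), function(i) {
    if (!tf$planted[i]) return(NULL)
    gi <- tf_gene_idx[i]
    pool <- which(cls == cls[gi] & subgroup == subgroup[gi] &
                    lineage == lineage[gi])
    pool <- setdiff(pool, tf_gene_idx)
    k <- min(25, length(pool))
    data.frame(tf_id = tf$tf_id[i], gene_id = gene_ids[pool[seq_len(k)]])
  }))
  if (is.null(tf_targets))
    tf_targets <- data.frame(tf_id = character(), gene_id = character())

  genes <- data.frame(gene_id = gene_ids, class = cls,
                      subgroup = subgroup, lineage = lineage,
                      length = lens)
  cm <- count_matrix(counts, setNames(lens, gene_ids), samples)
  list(counts = cm,
       truth = list(genes = genes, tf = tf, tf_targets = tf_targets),
       expected_fpkm = q,
       size_factors = setNames(sf, sample_ids))
}

#' Two-group NB simulation for DE calibration and power
#'
#' `n_planted` genes receive a symmetric planted log2 fold change
#' (`+lfc/2` in A, `-lfc/2` in B around the baseline mean); the rest
#' are null.  Used to verify test calibration and the sensitivity /
#' false-discovery behaviour of the DEG caller.
#'
#' @param n_genes,replicates simulation size.
#' @param n_planted number of non-null genes (default 0: pure null).
#' @param lfc planted |log2FC|.
#' @param mu_meanlog,mu_sdlog log-normal baseline count mean
#'   (default: around 100).
#' @param alpha NB dispersion.
#' @param seed integer seed.
#' @return list with `counts` (a [count_matrix()] with cell types
#'   "A"/"B") and `truth` (logical vector: planted gene?).
#' @export
simulate_two_group <- function(n_genes = 5000, replicates = 3,
                               n_planted = 0, lfc = 3,
                               mu_meanlog = log(100), mu_sdlog = 1,
                               alpha = 0.1, seed = 1) {
  if (alpha <= 0) stop("dispersion alpha must be positive")
  if (replicates < 2) stop("replicates must be >= 2")
  set.seed(seed)
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  mu <- rlnorm(n_genes, mu_meanlog, mu_sdlog)
  planted <- seq_len(n_genes) <= n_planted
  sgn <- rep(c(1, -1), length.out = n_planted)
  muA <- mu; muB <- mu
  muA[planted] <- mu[planted] * 2^(sgn * lfc / 2)
  muB[planted] <- mu[planted] * 2^(-sgn * lfc / 2)
  draw <- function(m) matrix(rnbinom(n_genes * replicates,
                                     mu = rep(m, replicates),
                                     size = 1 / alpha),
                             n_genes, replicates)
  counts <- cbind(draw(muA), draw(muB))
  ids <- c(paste0("A_r", seq_len(replicates)),
           paste0("B_r", seq_len(replicates)))
  dimnames(counts) <- list(gene_ids, ids)
  samples <- data.frame(sample_id = ids,
                        cell_type = rep(c("A", "B"), each = replicates),
                        replicate = rep(seq_len(replicates), 2))
  cm <- count_matrix(counts, setNames(rep(1000, n_genes), gene_ids),
                     samples)
  list(counts = cm, truth = setNames(planted, gene_ids))
}

# default 8-nt, non-palindromic TF consensus sequences
default_consensi <- function(n_tf) {
  pool <- c("TGACGTGG", "CACGTGTA", "GGGCCCAT", "AATTGCCG",
            "CCGGAATC", "TTGACCGA", "GAGACGTT", "CTTAGGCA")
  if (n_tf > length(pool)) stop("at most ", length(pool), " default motifs")
  pool[seq_len(n_tf)]
}

rc_string <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate promoters with planted TF binding sites
#'
#' Each gene gets a promoter sequence (gene orientation) whose
#' -500..+100 window exists; each planted TF's consensus is embedded
#' exactly once, inside the window, in each of its planted targets'
#' promoters.  Background sequence is i.i.d. uniform; with
#' `clean_background = TRUE` (default) background is rejection-sampled
#' to be free of exact occurrences of any planted consensus on either
#' strand, so hits are exactly the planted ones.
#'
#' @param design a [study_design()].
#' @param truth truth list from [simulate_counts()] (`tf`,
#'   `tf_targets`).
#' @param promoter_len sequence length (>= 601 so the window exists).
#' @param consensi character vector of consensus sites per TF.
#' @param clean_background reject background windows containing any
#'   planted consensus.
#' @param seed seed (default derived from the design).
#' @return list with `promoters` (list of `seqs`, `table`) and `motifs`
#'   (list of [motif()] objects).
#' @export
simulate_promoters <- function(design, truth, promoter_len = 601,
                               consensi = default_consensi(design$n_tf),
                               clean_background = TRUE,
                               seed = design$seed + 1L) {
  if (promoter_len < 601)
    stop("promoter length must be >= 601 nt so the -500..+100 window exists")
  widths <- nchar(consensi)
  if (any(widths > 601))
    stop("motif longer than the promoter window")
  set.seed(seed)
  gene_ids <- truth$genes$gene_id
  pats <- c(consensi, vapply(consensi, rc_string, ""))
  has_motif <- function(s) any(vapply(pats, function(p)
    grepl(p, s, fixed = TRUE), TRUE))
  seqs <- vapply(gene_ids, function(g) {
    s <- random_dna(promoter_len)
    if (clean_background) {
      tries <- 0
      while (has_motif(s) && tries < 50) {
        s <- random_dna(promoter_len); tries <- tries + 1
      }
    }
    s
  }, "")
  tss_offset <- 501L
  # embed each TF consensus once per planted target, inside the window
  tf_tab <- truth$tf
  for (i in seq_len(nrow(tf_tab))) {
    cons <- consensi[i]
    targets <- truth$tf_targets$gene_id[truth$tf_targets$tf_id ==
                                          tf_tab$tf_id[i]]
    w <- nchar(cons)
    for (g in targets) {
      rel <- sample(seq(-500, 100 - w + 1), 1)
      pos <- tss_offset + rel
      substr(seqs[g], pos, pos + w - 1) <- cons
    }
  }
  strand <- sample(c("+", "-"), length(gene_ids), replace = TRUE)
  tab <- data.frame(gene_id = gene_ids,
                    chrom = paste0("prom_", gene_ids),
                    tss = ifelse(strand == "+", tss_offset,
                                 promoter_len - tss_offset + 1L),
                    strand = strand,
                    tss_offset = tss_offset,
                    seq_length = promoter_len)
  motifs <- lapply(seq_len(nrow(tf_tab)), function(i)
    consensus_motif(tf_tab$tf_id[i], consensi[i]))
  list(promoters = list(seqs = seqs, table = tab), motifs = motifs)
}

# random codon table biased away from uniform (coding-style hexamer
# statistics), stops excluded
biased_codons <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases)[, 3:1], 1,
                  paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  w <- exp(rnorm(length(codons), 0, 0.8))
  setNames(w / sum(w), codons)
}

coding_sequence <- function(len, codon_p) {
  n_codons <- max(110, floor((len - 6) / 3))
  body <- paste(sample(names(codon_p), n_codons, replace = TRUE,
                       prob = codon_p), collapse = "")
  s <- paste0("ATG", body, "TAA")
  if (nchar(s) < len) s <- paste0(s, random_dna(len - nchar(s)))
  substr(s, 1, max(len, nchar(s)))
  s
}

#' Simulate transcript models, sequences and isoform expression
#'
#' Lays out, on one synthetic chromosome: multi-isoform coding genes
#' each carrying exactly one planted alternative-splicing event of a
#' known type; single-isoform coding genes serving as hosts; lncRNA
#' candidates in the sense, antisense and intergenic contexts; and
#' decoy transcripts that the candidate filter must remove (shorter
#' than 200 nt, or single-exon overlapping a same-strand coding exon).
#' Transcript sequences are generated from the planted coding status
#' (long-ORF codon-biased vs uniform random), isoform-level FPKM
#' carries planted lineage-specific isoforms, and two simulated
#' external coding-potential tools vote with a configurable error
#' rate.
#'
#' @param design a [study_design()].
#' @param isoform_spec named counts:
#'   `es`, `alt_donor`, `alt_acceptor`, `ir`, `complex` (AS genes per
#'   type), `lnc_intergenic`, `lnc_antisense`, `lnc_sense`,
#'   `decoy_short`, `decoy_overlap`.
#' @param external_error_rate per-tool probability of a wrong external
#'   vote.
#' @param seed seed (default derived from the design).
#' @return list with `transcripts` (a `transcript_models` table of all
#'   transcripts), `coding` (subset table of coding models), `seqs`
#'   (named character vector), `fpkm` (transcripts x AC/BC/32E/32S),
#'   `external_votes`, and `truth` (data.frames `transcripts`,
#'   `as_genes`).
#' @export
simulate_transcripts <- function(design,
                                 isoform_spec = c(es = 10, alt_donor = 8,
                                                  alt_acceptor = 8, ir = 8,
                                                  complex = 6,
                                                  lnc_intergenic = 10,
                                                  lnc_antisense = 8,
                                                  lnc_sense = 6,
                                                  decoy_short = 5,
                                                  decoy_overlap = 5),
                                 external_error_rate = 0.05,
                                 seed = design$seed + 2L) {
  set.seed(seed)
  exon_rows <- list(); truth_rows <- list(); as_rows <- list()
  seqs <- character(); fpkm_rows <- list()
  cursor <- 1000L
  add_tx <- function(tid, gid, strand, exons, coding, role, context,
                     spec) {
    exon_rows[[length(exon_rows) + 1]] <<- data.frame(
      transcript_id = tid, gene_id = gid, chrom = "chrT",
      strand = strand, start = exons[, 1], end = exons[, 2])
    truth_rows[[length(truth_rows) + 1]] <<- data.frame(
      transcript_id = tid, gene_id = gid, coding = coding, role = role,
      context = context, specificity = spec,
      length = sum(exons[, 2] - exons[, 1] + 1))
  }
  new_chain <- function(at, n_exons) {
    ex_len <- round(runif(n_exons, 100, 250))
    in_len <- round(runif(max(0, n_exons - 1), 100, 200))
    starts <- at + c(0, cumsum(ex_len[-n_exons] + in_len))
    cbind(starts, starts + ex_len - 1)
  }
  as_types <- rep(names(isoform_spec[c("es", "alt_donor", "alt_acceptor",
                                       "ir", "complex")]),
                  isoform_spec[c("es", "alt_donor", "alt_acceptor",
                                 "ir", "complex")])
  spec_cycle <- rep(c("ACL", "BCL", "shared"), length.out = length(as_types))
  for (i in seq_along(as_types)) {
    gid <- sprintf("ASG%03d", i)
    strand <- sample(c("+", "-"), 1)
    A <- new_chain(cursor, 4)
    cursor <- max(A) + round(runif(1, 800, 1500))
    type <- as_types[i]
    delta <- 30L
    B <- switch(type,
      es = A[-2, , drop = FALSE],
      ir = rbind(c(A[1, 1], A[2, 2]), A[3:4, , drop = FALSE]),
      complex = A[c(1, 4), , drop = FALSE],
      alt_donor = {
        B <- A
        if (strand == "+") B[1, 2] <- B[1, 2] + delta   # intron1 5' end
        else B[4, 1] <- B[4, 1] - delta                 # intron3 5' end
        B
      },
      alt_acceptor = {
        B <- A
        if (strand == "+") B[2, 1] <- B[2, 1] - delta   # intron1 3' end
        else B[3, 2] <- B[3, 2] + delta                 # intron3 3' end
        B
      })
    t1 <- paste0(gid, ".1"); t2 <- paste0(gid, ".2")
    add_tx(t1, gid, strand, A, TRUE, "as_isoform", NA, "shared")
    add_tx(t2, gid, strand, B, TRUE, "as_isoform", NA, spec_cycle[i])
    as_rows[[length(as_rows) + 1]] <- data.frame(gene_id = gid,
                                                 type = type)
  }
  # single-isoform coding hosts for sense/antisense/decoy overlaps
  n_hosts <- isoform_spec[["lnc_antisense"]] + isoform_spec[["lnc_sense"]] +
    isoform_spec[["decoy_overlap"]]
  hosts <- character(n_hosts)
  for (i in seq_len(n_hosts)) {
    gid <- sprintf("CODG%03d", i)
    strand <- sample(c("+", "-"), 1)
    ex <- new_chain(cursor, 3)
    cursor <- max(ex) + round(runif(1, 800, 1500))
    add_tx(paste0(gid, ".1"), gid, strand, ex, TRUE, "coding_host", NA,
           "shared")
    hosts[i] <- gid
  }
  exdf <- function() do.call(rbind, exon_rows)
  host_info <- function(gid) {
    ed <- exdf(); sub <- ed[ed$gene_id == gid, ]
    list(strand = sub$strand[1], first = c(sub$start[1], sub$end[1]),
         span = c(min(sub$start), max(sub$end)))
  }
  hi <- 1
  flip <- function(s) if (s == "+") "-" else "+"
  for (i in seq_len(isoform_spec[["lnc_antisense"]])) {
    h <- host_info(hosts[hi]); hi <- hi + 1
    tid <- sprintf("LNCA%03d", i)
    st <- h$first[1] + 10L
    ex <- cbind(st, st + round(runif(1, 250, 500)))
    add_tx(tid, tid, flip(h$strand), ex, FALSE, "lnc_candidate",
           "antisense", "shared")
  }
  for (i in seq_len(isoform_spec[["lnc_sense"]])) {
    h <- host_info(hosts[hi]); hi <- hi + 1
    tid <- sprintf("LNCS%03d", i)
    # two exons, the first overlapping a coding exon on the same strand
    st <- h$first[1] + 20L
    e1 <- c(st, st + 120L)
    e2 <- c(h$span[2] + 200L, h$span[2] + 200L + 180L)
    add_tx(tid, tid, h$strand, rbind(e1, e2), FALSE, "lnc_candidate",
           "sense", "shared")
  }
  for (i in seq_len(isoform_spec[["decoy_overlap"]])) {
    h <- host_info(hosts[hi]); hi <- hi + 1
    tid <- sprintf("DECO%03d", i)
    st <- h$first[1] + 5L
    ex <- cbind(st, st + round(runif(1, 220, 400)))
    add_tx(tid, tid, h$strand, ex, FALSE, "decoy_single_overlap", NA,
           "shared")
  }
  for (i in seq_len(isoform_spec[["lnc_intergenic"]])) {
    tid <- sprintf("LNCI%03d", i)
    strand <- sample(c("+", "-"), 1)
    ex <- new_chain(cursor, 2)
    cursor <- max(ex) + round(runif(1, 800, 1500))
    add_tx(tid, tid, strand, ex, FALSE, "lnc_candidate", "intergenic",
           "shared")
  }
  for (i in seq_len(isoform_spec[["decoy_short"]])) {
    tid <- sprintf("DECS%03d", i)
    strand <- sample(c("+", "-"), 1)
    len <- round(runif(1, 100, 199))
    ex <- cbind(cursor, cursor + len - 1)
    cursor <- max(ex) + round(runif(1, 800, 1500))
    add_tx(tid, tid, strand, ex, FALSE, "decoy_short", "intergenic",
           "shared")
  }
  transcripts <- transcript_models(exdf())
  truth_tx <- do.call(rbind, truth_rows)

  codon_p <- biased_codons()
  lens <- transcript_lengths(transcripts)
  seqs <- vapply(truth_tx$transcript_id, function(tid) {
    len <- unname(lens[tid])
    if (truth_tx$coding[truth_tx$transcript_id == tid])
      coding_sequence(len, codon_p)
    else random_dna(len)
  }, "")

  # isoform expression: first isoforms everywhere, second isoforms
  # lineage-specific where planted
  cell_types <- c("AC", "BC", "32E", "32S")
  fpkm <- matrix(0, nrow(truth_tx), 4,
                 dimnames = list(truth_tx$transcript_id, cell_types))
  for (i in seq_len(nrow(truth_tx))) {
    sp <- truth_tx$specificity[i]
    fpkm[i, ] <- switch(sp,
                        shared = rep(20, 4),
                        ACL = c(10, 0, 10, 0),
                        BCL = c(0, 10, 0, 10))
  }
  cand <- truth_tx$transcript_id[truth_tx$role %in%
                                   c("lnc_candidate", "decoy_short",
                                     "decoy_single_overlap")]
  ext <- data.frame(transcript_id = cand)
  status <- !truth_tx$coding[match(cand, truth_tx$transcript_id)]
  for (toolname in c("ext_tool1", "ext_tool2")) {
    wrong <- runif(length(cand)) < external_error_rate
    ext[[toolname]] <- xor(status, wrong)
  }
  coding_tab <- transcripts[transcripts$transcript_id %in%
                              truth_tx$transcript_id[truth_tx$coding], ,
                            drop = FALSE]
  list(transcripts = transcripts, coding = coding_tab, seqs = seqs,
       fpkm = fpkm, external_votes = ext,
       truth = list(transcripts = truth_tx,
                    as_genes = do.call(rbind, as_rows)))
}

#' Simulate a gene-to-term annotation map
#'
#' A few planted terms are loaded with members of the planted
#' lineage-maintained classes (so enrichment finds them); the rest have
#' random membership.
#'
#' @param design a [study_design()].
#' @param truth truth list from [simulate_counts()].
#' @param seed seed (default derived from the design).
#' @return list with `annotation` (data.frame `gene_id`, `term_id`) and
#'   `enriched_terms` (character vector of planted term ids).
#' @export
simulate_annotation <- function(design, truth, seed = design$seed + 3L) {
  set.seed(seed)
  genes <- truth$genes
  rows <- list()
  planted <- c(TERM_ACL = "ACL_maintained", TERM_BCL = "BCL_maintained",
               TERM_DENOVO = "de_novo")
  for (tm in names(planted)) {
    members <- genes$gene_id[genes$class == planted[[tm]]]
    members <- members[runif(length(members)) < 0.7]
    extra <- sample(genes$gene_id[genes$class == "null"],
                    min(15, sum(genes$class == "null")))
    rows[[tm]] <- data.frame(gene_id = c(members, extra), term_id = tm)
  }
  n_random <- max(0, design$n_terms - length(planted))
  for (i in seq_len(n_random)) {
    tm <- sprintf("TERM%03d", i)
    k <- 5 + stats::rpois(1, 20)
    rows[[tm]] <- data.frame(gene_id = sample(genes$gene_id, k),
                             term_id = tm)
  }
  list(annotation = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       enriched_terms = names(planted))
}

#' Generate the full synthetic study bundle
#'
#' Runs every generator under seeds derived from the design seed:
#' counts with planted truth, promoters and motifs, transcript models
#' with sequences and isoform expression, and the annotation map.
#'
#' @param design a [study_design()].
#' @param effects an [effect_config()].
#' @param noise see [simulate_counts()].
#' @param ... passed on to [simulate_transcripts()] and
#'   [simulate_promoters()] (e.g. `clean_background`,
#'   `external_error_rate`).
#' @return list of class `synthetic_bundle` with elements `design`,
#'   `effects`, `counts`, `expected_fpkm`, `promoters`, `motifs`,
#'   `tx` (transcript sub-bundle) , `annotation`, `truth`.
#' @export
simulate_bundle <- function(design = study_design(),
                            effects = effect_config(), noise = TRUE,
                            ...) {
  dots <- list(...)
  cnt <- simulate_counts(design, effects, noise = noise)
  prom_args <- dots[names(dots) %in%
                      c("promoter_len", "consensi", "clean_background")]
  prom <- do.call(simulate_promoters,
                  c(list(design = design, truth = cnt$truth), prom_args))
  tx_args <- dots[names(dots) %in%
                    c("isoform_spec", "external_error_rate")]
  tx <- do.call(simulate_transcripts, c(list(design = design), tx_args))
  ann <- simulate_annotation(design, cnt$truth)
  truth <- c(cnt$truth, tx$truth, list(enriched_terms = ann$enriched_terms))
  structure(list(design = design, effects = effects,
                 counts = cnt$counts, expected_fpkm = cnt$expected_fpkm,
                 size_factors = cnt$size_factors,
                 promoters = prom$promoters, motifs = prom$motifs,
                 tx = tx, annotation = ann$annotation, truth = truth),
            class = "synthetic_bundle")
}

#' Serialize a synthetic bundle to standard file formats
#'
#' Counts and sample sheet as TSV, promoters as FASTA plus a BED6 TSS
#' table (0-based half-open), motifs in JASPAR-style text, transcripts
#' as GTF (1-based inclusive), transcript sequences as FASTA,
#' annotation map / truth tables / external votes as TSV.
#'
#' @param bundle a [simulate_bundle()] result.
#' @param outdir output directory (created if missing).
#' @return The output directory, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  write_counts(bundle$counts, p("counts.tsv"), p("samples.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(bundle$promoters$seqs),
    p("promoters.fasta"))
  tab <- bundle$promoters$table
  bed <- data.frame(chrom = tab$chrom, start = tab$tss - 1L,
                    end = tab$tss, name = tab$gene_id, score = 0,
                    strand = tab$strand)
  write.table(bed, p("tss.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_motifs(bundle$motifs, p("motifs.txt"))
  write_transcripts_gtf(bundle$tx$transcripts, p("transcripts.gtf"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(bundle$tx$seqs),
                              p("transcript_seqs.fasta"))
  write.table(bundle$tx$fpkm, p("transcript_fpkm.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  write.table(bundle$tx$external_votes, p("external_votes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$annotation, p("annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$truth$genes, p("truth_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$truth$tf_targets, p("truth_tf_targets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$truth$transcripts, p("truth_transcripts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
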