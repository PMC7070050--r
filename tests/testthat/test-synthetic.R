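test_that("the generator is deterministic given the seed", {
  d <- small_design(seed = 17)
  b1 <- simulate_bundle(d, small_effects())
  b2 <- simulate_bundle(d, small_effects())
  expect_identical(b1$counts$counts, b2$counts$counts)
  expect_identical(b1$promoters$seqs, b2$promoters$seqs)
  expect_identical(b1$tx$seqs, b2$tx$seqs)
  expect_identical(b1$annotation, b2$annotation)
  # serialized outputs are byte-identical too
  o1 <- tempfile(); o2 <- tempfile()
  write_bundle(b1, o1); write_bundle(b2, o2)
  for (f in list.files(o1)) {
    expect_identical(readBin(file.path(o1, f), "raw", 2e6),
                     readBin(file.path(o2, f), "raw", 2e6),
                     info = f)
  }
  # a different seed changes the data
  b3 <- simulate_bundle(small_design(seed = 18), small_effects())
  expect_false(identical(b1$counts$counts, b3$counts$counts))
})

test_that("invalid designs and effect configurations are rejected", {
  expect_error(study_design(replicates = 1), "replicates")
  expect_error(study_design(cell_types = character()), "cell_types")
  expect_error(study_design(cell_types = c("A", "A", "B")), "cell_types")
  expect_error(effect_config(alpha = 0), "positive")
  expect_error(effect_config(alpha = -1), "positive")
  expect_error(simulate_promoters(small_design(), small_bundle()$truth,
                                  promoter_len = 400), "601")
})

test_that("counts follow the NB mean-variance law var = mu + alpha mu^2", {
  sim <- simulate_two_group(n_genes = 5000, replicates = 6, alpha = 0.15,
                            seed = 23)
  counts <- sim$counts$counts[, 1:6]
  mu_hat <- rowMeans(counts)
  v_hat <- apply(counts, 1, var)
  keep <- mu_hat > 20
  ratio <- mean(v_hat[keep]) / mean(mu_hat[keep] + 0.15 * mu_hat[keep]^2)
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("planted maintained genes separate the daughters by the configured effect", {
  # expected-value oracle: group means of apical-maintained genes in AC
  # exceed BC by at least 4-fold under the default 8-fold planting
  b <- small_bundle(noise = TRUE, seed = 5)
  g <- b$truth$genes
  em <- compute_fpkm(b$counts)
  gm <- group_means(em, c("AC", "BC"))
  acl <- g$gene_id[g$class == "ACL_maintained"]
  expect_gte(mean(gm[acl, "AC"]) / mean(gm[acl, "BC"]), 4)
  # and the planted expected profiles carry the exact configured ratio
  q <- b$expected_fpkm
  rat <- q[acl, "AC"] / q[acl, "BC"]
  expect_true(all(abs(log2(rat) - 3) < 0.2))
})

test_that("a null effect configuration produces no planted signal", {
  d <- small_design(seed = 30, n_genes = 400)
  eff <- effect_config(class_sizes = c(ACL_maintained = 0,
                                       BCL_maintained = 0,
                                       inherited_asymmetric = 0,
                                       de_novo = 0,
                                       selective_deletion = 0,
                                       EMB_like = 0))
  sim <- simulate_counts(d, eff)
  expect_true(all(sim$truth$genes$class == "null"))
  de <- de_contrast(sim$counts, "AC:BC")
  # DE recovery is at (or below) the nominal false-positive level
  expect_lte(length(union(de$up, de$down)), 0.02 * 400)
})

test_that("every planted truth class is recoverable from noiseless profiles", {
  b <- small_bundle(noise = FALSE, seed = 5)
  q <- b$expected_fpkm
  g <- b$truth$genes
  up1 <- q[, "AC"] / q[, "BC"] >= 2
  up32 <- q[, "32E"] / q[, "32S"] >= 2
  acl_rule <- rownames(q)[up1 & up32]
  expect_setequal(acl_rule, g$gene_id[g$class == "ACL_maintained"])
  # fate rules on expected profiles recover the fate classes exactly
  for (cls in c("inherited_asymmetric", "de_novo", "selective_deletion")) {
    ids <- g$gene_id[g$class == cls]
    zy <- q[ids, "Zy24"]
    fav <- g$lineage[match(ids, g$gene_id)]
    dd <- ifelse(fav == "ACL", q[ids, "AC"], q[ids, "BC"])
    oo <- ifelse(fav == "ACL", q[ids, "BC"], q[ids, "AC"])
    late <- pmax(q[ids, "32E"], q[ids, "32S"])
    ok <- switch(cls,
      inherited_asymmetric = zy >= 5 & late < 1,
      de_novo = zy < 1 & dd >= 5,
      selective_deletion = zy >= 5 & dd >= 5 & oo < 1 & late >= 1)
    expect_true(all(ok), info = cls)
  }
})

test_that("every planted motif occurs in each target promoter window", {
  b <- small_bundle(noise = FALSE, seed = 5)
  hits <- scan_promoters(b$promoters, b$motifs)
  planted <- b$truth$tf_targets
  key_hits <- unique(paste(hits$tf_id, hits$gene_id))
  expect_true(all(paste(planted$tf_id, planted$gene_id) %in% key_hits))
  # clean background: hits are exactly the planted pairs
  expect_setequal(key_hits, paste(planted$tf_id, planted$gene_id))
})

test_that("background motif hits match the closed-form expectation without cleaning", {
  # 6-nt consensus, no planted targets: per window and strand the
  # expected number of exact matches is (601 - 5) * (1/4)^6
  n <- 4000
  genes <- data.frame(gene_id = sprintf("g%05d", 1:n))
  truth <- list(genes = genes,
                tf = data.frame(tf_id = character(),
                                gene_id = character(),
                                planted = logical()),
                tf_targets = data.frame(tf_id = character(),
                                        gene_id = character()))
  d <- study_design(n_genes = n, seed = 77)
  pr <- simulate_promoters(d, truth, consensi = character(),
                           clean_background = FALSE)
  mt <- consensus_motif("T6", "TGACGT", dominant = 0.97)
  hits <- scan_promoters(pr$promoters, list(mt))
  rate <- nrow(hits) / n / 2          # per window per strand
  expected <- (601 - 5) * (1 / 4)^6
  expect_lt(abs(rate - expected) / expected, 0.15)
})

test_that("transcript truth plants the declared AS types and contexts", {
  b <- small_bundle(noise = FALSE, seed = 5)
  tx <- b$tx
  ev <- detect_as_events(tx$transcripts)
  m <- match(tx$truth$as_genes$gene_id, ev$gene_id)
  expect_false(any(is.na(m)))
  want <- sub("^es$", "exon_skipping",
              sub("^ir$", "intron_retention", tx$truth$as_genes$type))
  expect_equal(ev$type[m], want)
  # planted contexts match the classifier
  tt <- tx$truth$transcripts
  cand <- tt[tt$role == "lnc_candidate", ]
  ctx <- classify_context(
    tx$transcripts[tx$transcripts$transcript_id %in% cand$transcript_id, ],
    tx$coding)
  expect_equal(ctx$context[match(cand$transcript_id, ctx$transcript_id)],
               cand$context)
  # decoys are planted to fail the candidate filter
  decoys <- tt$transcript_id[grepl("^DEC", tt$transcript_id)]
  kept <- filter_candidates(
    tx$transcripts[tx$transcripts$transcript_id %in%
                     c(decoys, cand$transcript_id), ], tx$coding)
  expect_length(intersect(kept, decoys), 0)
  expect_setequal(kept, cand$transcript_id)
})
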