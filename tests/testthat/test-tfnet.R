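test_that("promoter windows follow the -500..+100 convention on both strands", {
  expect_equal(promoter_window(1000, "+"), c(500, 1100))
  expect_equal(promoter_window(1000, "-"), c(900, 1500))
  expect_equal(promoter_window(300, "+"), c(1, 400))    # clipped at 1
  expect_error(promoter_window(1000, "*"), "strand")
  expect_error(promoter_window(0, "+"), "tss")
})

# one-promoter fixture: 601-nt window with a motif planted at a known
# position relative to the TSS (offset 501)
planted_promoter <- function(consensus, rel, seed = 21) {
  set.seed(seed)
  len <- 601
  pats <- c(consensus,
            chartr("ACGT", "TGCA",
                   paste(rev(strsplit(consensus, "")[[1]]), collapse = "")))
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    if (!any(vapply(pats, grepl, TRUE, s, fixed = TRUE))) break
  }
  pos <- 501 + rel
  substr(s, pos, pos + nchar(consensus) - 1) <- consensus
  list(seqs = setNames(s, "gX"),
       table = data.frame(gene_id = "gX", chrom = "prom_gX", tss = 501,
                          strand = "+", tss_offset = 501,
                          seq_length = len))
}

test_that("the scan finds a planted consensus exactly once at its position", {
  prom <- planted_promoter("TGACGTGG", rel = -200)
  hits <- scan_promoters(prom, list(consensus_motif("TF1", "TGACGTGG")))
  fwd <- hits[hits$strand == "+", ]
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$rel_pos, -200)
  expect_equal(fwd$gene_id, "gX")
  # non-palindromic strict-threshold motif: no reverse-strand hit
  expect_equal(nrow(hits[hits$strand == "-", ]), 0)
})

test_that("a palindromic motif hits both strands at the same position", {
  prom <- planted_promoter("TGACGTCA", rel = 40)   # reverse complement of itself
  hits <- scan_promoters(prom, list(consensus_motif("TFP", "TGACGTCA")))
  expect_setequal(unique(hits$strand), c("-", "+"))
  expect_equal(unique(hits$rel_pos), 40)
})

test_that("scan results depend only on positions relative to the TSS", {
  prom <- planted_promoter("TGACGTGG", rel = -123)
  # pad 50 nt upstream and shift the TSS offset accordingly
  prom2 <- prom
  set.seed(1)
  pad <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
               collapse = "")
  prom2$seqs[] <- paste0(pad, prom$seqs)
  prom2$table$tss_offset <- 551
  prom2$table$seq_length <- 651
  m <- list(consensus_motif("TF1", "TGACGTGG"))
  h1 <- scan_promoters(prom, m)
  h2 <- scan_promoters(prom2, m)
  expect_equal(h1[, c("tf_id", "rel_pos", "strand", "score")],
               h2[, c("tf_id", "rel_pos", "strand", "score")])
})

test_that("an unattainable threshold yields zero hits (exhaustive max-score oracle)", {
  prom <- planted_promoter("GGGCCCAT", rel = 0)
  mt <- consensus_motif("TF1", "AATTGCCG")   # not planted
  # brute-force sliding-window max score over both strands
  win <- substr(prom$seqs, 1, 601)
  base_idx <- match(strsplit(win, "")[[1]], c("A", "C", "G", "T"))
  max_sc <- -Inf
  for (lo in list(mt$logodds,
                  mt$logodds[c("T", "G", "C", "A"), 8:1])) {
    rownames(lo) <- c("A", "C", "G", "T")
    for (p in 1:(601 - 7)) {
      sc <- sum(lo[cbind(base_idx[p:(p + 7)], 1:8)])
      max_sc <- max(max_sc, sc)
    }
  }
  expect_lt(max_sc, mt$max_score)    # consensus absent by construction
  mt_strict <- mt
  mt_strict$threshold <- mt$max_score
  expect_equal(nrow(scan_promoters(prom, list(mt_strict))), 0)
  # at a threshold just below the oracle's max the scan finds that site
  mt_loose <- mt
  mt_loose$threshold <- max_sc - 1e-9
  expect_gte(nrow(scan_promoters(prom, list(mt_loose))), 1)
})

test_that("windows outside the provided sequence are rejected by name", {
  prom <- planted_promoter("TGACGTGG", rel = 0)
  prom_bad <- prom
  prom_bad$table$tss_offset <- 400   # window would start at -100
  expect_error(scan_promoters(prom_bad,
                              list(consensus_motif("T", "ACGTACGT"))),
               "gX")
  expect_error(scan_promoters(prom,
                              list(consensus_motif("T",
                                                   strrep("ACGT", 200)))),
               "longer than")
})

test_that("TF motif enrichment handles zero hits, saturation and a planted signal", {
  universe <- sprintf("g%03d", 1:200)
  deg <- universe[1:40]
  hits <- data.frame(tf_id = "TFA",
                     gene_id = c(universe[1:30], universe[101:110]),
                     rel_pos = 0L, strand = "+", score = 1, width = 8)
  res <- tf_motif_enrichment(deg, hits, universe,
                             tf_ids = c("TFA", "TFZERO"))
  expect_equal(res$tf_id[1], "TFA")
  expect_lt(res$FDR[1], 0.05)
  expect_equal(res$p[res$tf_id == "TFZERO"], 1)
  # all genes hit (K = N) -> p = 1
  hits_all <- data.frame(tf_id = "TFALL", gene_id = universe,
                         rel_pos = 0L, strand = "+", score = 1, width = 8)
  res_all <- tf_motif_enrichment(deg, hits_all, universe,
                                 tf_ids = "TFALL")
  expect_equal(res_all$p, 1)
  expect_error(tf_motif_enrichment(c(deg, "nope"), hits, universe),
               "universe")
})

test_that("the coexpression filter applies Pearson r > 0.87 strictly", {
  expect_true(coexpression_filter(c(1, 2, 3, 4, 5),
                                  c(2, 4, 6, 8, 10))$pass)   # r = 1
  rev_ <- coexpression_filter(c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1))
  expect_equal(rev_$r, -1)
  expect_false(rev_$pass)
  # hand-computed Pearson for (1..5) vs (1,2,3,4,10)
  x <- 1:5; y <- c(1, 2, 3, 4, 10)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- coexpression_filter(x, y)
  expect_equal(got$r, r_hand)
  expect_equal(got$pass, r_hand > 0.87)
  flat <- coexpression_filter(c(1, 1, 1), c(1, 2, 3))
  expect_false(flat$pass)
  expect_equal(flat$reason, "undefined correlation")
})

test_that("network edges require enrichment, a hit and coexpression jointly", {
  enriched <- data.frame(tf_id = c("TF1", "TF2"), FDR = c(0.001, 0.5))
  hits <- data.frame(tf_id = c("TF1", "TF1", "TF2"),
                     gene_id = c("gA", "gB", "gC"),
                     rel_pos = 0L, strand = "+", score = 1, width = 8)
  coexpr <- data.frame(tf_id = c("TF1", "TF1", "TF2"),
                       gene_id = c("gA", "gB", "gC"),
                       r = c(0.99, -0.8, 0.99),
                       pass = c(TRUE, FALSE, TRUE))
  net <- build_network(enriched, hits, coexpr)
  expect_equal(net$gene_id, "gA")        # TF2 not enriched, gB anti-correlated
  # dropping the coexpression requirement can only add edges
  coexpr_all <- coexpr; coexpr_all$pass <- TRUE
  net_all <- build_network(enriched, hits, coexpr_all)
  expect_true(all(paste(net$tf_id, net$gene_id) %in%
                    paste(net_all$tf_id, net_all$gene_id)))
  # empty enriched set -> empty network
  none <- data.frame(tf_id = character(), FDR = numeric())
  expect_equal(nrow(build_network(none, hits, coexpr)), 0)
})

test_that("motif matrices round-trip through the JASPAR-style text format", {
  mts <- list(consensus_motif("TF1", "TGACGTGG"),
              consensus_motif("TF2", "CACGTGTA"))
  f <- tempfile(fileext = ".txt")
  write_motifs(mts, f)
  back <- read_motifs(f)
  expect_equal(vapply(back, `[[`, "", "tf_id"), c("TF1", "TF2"))
  expect_equal(back[[1]]$consensus, "TGACGTGG")
  expect_equal(back[[1]]$prob, mts[[1]]$prob, tolerance = 1e-5)
})
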