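test_that("the candidate filter removes short and single-exon sense-overlapping transcripts", {
  coding <- tx_fixture("cod.1", "COD", "+", list(c(1000, 1400),
                                                 c(1600, 2000)))
  cand <- rbind(
    tx_fixture("short1", "short1", "+", list(c(5000, 5149))),     # 150 nt
    tx_fixture("short2", "short2", "-", list(c(6000, 6180))),     # 181 nt
    tx_fixture("ovl1", "ovl1", "+", list(c(1100, 1500))),         # 1-exon sense overlap
    tx_fixture("ok1", "ok1", "+", list(c(8000, 8400), c(8600, 9100))),
    tx_fixture("ok2", "ok2", "-", list(c(1100, 1500))),           # antisense survives
    tx_fixture("ok3", "ok3", "+", list(c(1100, 1300), c(2200, 2400))))
  kept <- filter_candidates(cand, coding)
  expect_equal(kept, c("ok1", "ok2", "ok3"))
  # multi-exon sense-overlapping candidates are retained (ok3)
  expect_true("ok3" %in% kept)
  expect_error(filter_candidates(
    tx_fixture("bad", "bad", "+", list(c(100, 50))), coding), "malformed")
})

test_that("context classes separate sense, antisense and intergenic candidates", {
  coding <- tx_fixture("cod.1", "COD", "+", list(c(1000, 1400),
                                                 c(1600, 2000)))
  cand <- rbind(
    tx_fixture("s", "s", "+", list(c(1100, 1300), c(2200, 2400))),
    tx_fixture("a", "a", "-", list(c(1200, 1700))),
    tx_fixture("i", "i", "+", list(c(9000, 9500))))
  ctx <- classify_context(cand, coding)
  got <- setNames(ctx$context, ctx$transcript_id)
  expect_equal(got[c("a", "i", "s")],
               c(a = "antisense", i = "intergenic", s = "sense"))
  # with no coding annotation everything is intergenic
  ctx0 <- classify_context(cand, coding[0, ])
  expect_true(all(ctx0$context == "intergenic"))
})

test_that("the consensus vote accepts exactly the >= 4-of-5 vote vectors", {
  expect_true(vote_lncRNA(c(TRUE, TRUE, TRUE, TRUE, FALSE)))
  expect_false(vote_lncRNA(c(TRUE, TRUE, TRUE, FALSE, FALSE)))
  expect_error(vote_lncRNA(c(TRUE, TRUE)), "5 votes")
  # exhaustive 2^5 enumeration against the counting oracle
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  accepted <- apply(grid, 1, function(v) vote_lncRNA(as.logical(v)))
  expect_equal(sum(accepted), choose(5, 4) + choose(5, 5))  # 6 vectors
  expect_equal(accepted, rowSums(grid) >= 4)
})

test_that("the ORF scorer thresholds at 100 codons and matches a naive ORF oracle", {
  set.seed(41)
  # 133-codon ORF embedded in random sequence -> coding vote
  body <- paste(sample(setdiff(
    apply(expand.grid(b1 = c("A", "C", "G", "T"), b2 = c("A", "C", "G", "T"),
                      b3 = c("A", "C", "G", "T")), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA")), 132, replace = TRUE), collapse = "")
  seqc <- paste0("CC", "ATG", body, "TAA", "GG")
  expect_gte(longest_orf(seqc), 133)
  expect_false(orf_scorer(seqc))
  # naive single-strand regex oracle on random sequences
  naive_orf <- function(s) {
    best <- 0
    for (str in c(s, chartr("ACGT", "TGCA",
                            paste(rev(strsplit(s, "")[[1]]),
                                  collapse = "")))) {
      n <- nchar(str)
      for (off in 0:2) {
        cods <- substring(str, seq(1 + off, n - 2, 3), seq(3 + off, n, 3))
        j <- 1
        while (j <= length(cods)) {
          if (cods[j] == "ATG") {
            stops <- which(cods %in% c("TAA", "TAG", "TGA") &
                             seq_along(cods) > j)
            if (length(stops) > 0) {
              best <- max(best, stops[1] - j)
              j <- stops[1]
            }
          }
          j <- j + 1
        }
      }
    }
    best
  }
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
    expect_equal(longest_orf(s), naive_orf(s))
  }
  expect_error(longest_orf(""), "empty")
})

test_that("stop-density and hexamer scorers separate coding-like from random sequence", {
  expect_true(stop_density_scorer(strrep("TAA", 60)))
  set.seed(42)
  nonstop <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T"))[, 3:1], 1,
                           paste, collapse = ""),
                     c("TAA", "TAG", "TGA"))
  wts <- exp(rnorm(length(nonstop), 0, 0.8))
  coding_like <- replicate(30, paste0(
    "ATG", paste(sample(nonstop, 150, replace = TRUE,
                        prob = wts / sum(wts)), collapse = ""), "TAA"))
  random_seqs <- replicate(30, paste(sample(c("A", "C", "G", "T"), 456,
                                            replace = TRUE),
                                     collapse = ""))
  expect_false(stop_density_scorer(coding_like[1]))
  tabs <- build_hexamer_tables(coding_like[1:20], random_seqs[1:20])
  # held-out sequences are classified by the hexamer log-ratio
  cod_votes <- vapply(coding_like[21:30], hexamer_scorer, TRUE,
                      tables = tabs)
  rnd_votes <- vapply(random_seqs[21:30], hexamer_scorer, TRUE,
                      tables = tabs)
  expect_lte(mean(cod_votes), 0.2)   # coding mostly voted coding
  expect_gte(mean(rnd_votes), 0.8)   # random mostly voted noncoding
})

test_that("pairwise exon-chain comparison classifies the basic splice patterns", {
  A <- tx_fixture("A", "g", "+", list(c(1, 100), c(200, 300), c(400, 500)))
  B <- tx_fixture("B", "g", "+", list(c(1, 100), c(400, 500)))
  ev <- detect_as_events(rbind(A, B))
  expect_equal(ev$type, "exon_skipping")
  expect_equal(c(ev$region_start, ev$region_end), c(200, 300))

  A2 <- tx_fixture("A", "g", "+", list(c(1, 100), c(200, 300)))
  B2 <- tx_fixture("B", "g", "+", list(c(1, 300)))
  expect_equal(detect_as_events(rbind(A2, B2))$type, "intron_retention")

  B3 <- tx_fixture("B", "g", "+", list(c(1, 120), c(200, 300)))
  ev3 <- detect_as_events(rbind(A2, B3))
  expect_equal(ev3$type, "alt_donor")      # intron 5' boundary moved
  B4 <- tx_fixture("B", "g", "+", list(c(1, 100), c(180, 300)))
  expect_equal(detect_as_events(rbind(A2, B4))$type, "alt_acceptor")

  # two exons lost at once does not match a basic pattern
  A5 <- tx_fixture("A", "g", "+", list(c(1, 100), c(200, 300),
                                       c(400, 500), c(600, 700)))
  B5 <- tx_fixture("B", "g", "+", list(c(1, 100), c(600, 700)))
  expect_equal(detect_as_events(rbind(A5, B5))$type, "complex")

  # strand disagreement within a gene is rejected
  Bx <- tx_fixture("B", "g", "-", list(c(1, 100), c(400, 500)))
  expect_error(detect_as_events(rbind(A, Bx)), "strand")
})

test_that("AS classification ignores isoform order and mirrors donor/acceptor under strand flips", {
  ex_a <- list(c(1000, 1100), c(1200, 1300))
  ex_b <- list(c(1000, 1120), c(1200, 1300))
  A <- tx_fixture("A", "g", "+", ex_a)
  B <- tx_fixture("B", "g", "+", ex_b)
  expect_equal(detect_as_events(rbind(A, B))$type,
               detect_as_events(rbind(B, A))$type)
  # mirrored coordinates on the - strand swap donor and acceptor
  Am <- tx_fixture("A", "g", "-", mirror_exons(ex_a))
  Bm <- tx_fixture("B", "g", "-", mirror_exons(ex_b))
  t_plus <- detect_as_events(rbind(A, B))$type
  t_minus <- detect_as_events(rbind(Am, Bm))$type
  expect_equal(t_plus, "alt_donor")
  expect_equal(t_minus, "alt_donor")   # mirrored genome + flipped strand
  # same coordinates, opposite strand: the labels swap
  Ao <- tx_fixture("A", "g", "-", ex_a)
  Bo <- tx_fixture("B", "g", "-", ex_b)
  expect_equal(detect_as_events(rbind(Ao, Bo))$type, "alt_acceptor")
  # the expression filter drops sub-threshold isoforms
  ev <- detect_as_events(rbind(A, B), fpkm = c(A = 5, B = 0.2))
  expect_equal(nrow(ev), 0)
})

test_that("isoform comparison across cell types finds specific and maintained isoforms", {
  sets <- list(AC = c("x", "y"), BC = c("y", "z"),
               `32E` = c("x", "w"), `32S` = c("z", "w"))
  cmp <- compare_across_cells(sets)
  expect_equal(cmp$specific$AC, "x")
  expect_equal(cmp$specific$BC, "z")
  expect_equal(cmp$ACL_maintained, "x")
  expect_equal(cmp$BCL_maintained, "z")
  # identical sets -> nothing specific
  cmp0 <- compare_across_cells(list(AC = c("x"), BC = c("x")))
  expect_length(cmp0$specific$AC, 0)
  expect_error(compare_across_cells(list(XX = "x")), "unknown cell type")
})

test_that("transcript models round-trip through GTF", {
  tx <- transcript_models(rbind(
    tx_fixture("t1.1", "g1", "+", list(c(100, 200), c(300, 400))),
    tx_fixture("t2.1", "g2", "-", list(c(1000, 1500)))))
  f <- tempfile(fileext = ".gtf")
  write_transcripts_gtf(tx, f)
  back <- read_transcripts_gtf(f)
  back <- back[order(back$transcript_id, back$start), ]
  expect_equal(back$start, tx$start)
  expect_equal(back$end, tx$end)
  expect_equal(back$strand, tx$strand)
  expect_equal(back$transcript_id, tx$transcript_id)
})
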