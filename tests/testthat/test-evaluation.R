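ev_tree <- function() toy_tree()  # root-p-f-{g1:{s1,s2},g2:{s3}}, st1<s1

ev_truth <- function() data.frame(
  seq_id = c("c1", "c2", "c3", "c4"),
  taxon_id = c("s1", "s1", "s2", "s3"),
  length = c(4000, 4000, 2000, 10000), stringsAsFactors = FALSE)

test_that("precision/recall are bp-weighted with rank projection", {
  tr <- ev_tree(); truth <- ev_truth()
  perfect <- truth[, c("seq_id", "taxon_id")]
  pr <- precision_recall(perfect, truth, tr, "species")
  expect_equal(pr$precision, 1); expect_equal(pr$recall, 1)
  none <- data.frame(seq_id = truth$seq_id, taxon_id = NA_character_)
  pr0 <- precision_recall(none, truth, tr, "species")
  expect_true(is.na(pr0$precision)); expect_equal(pr0$recall, 0)
  # 8 kb correct, 2 kb wrong, 10 kb unassigned of 20 kb total
  pred <- data.frame(seq_id = c("c1", "c2", "c3", "c4"),
                     taxon_id = c("s1", "s1", "s1", NA))
  pr2 <- precision_recall(pred, truth, tr, "species")
  expect_equal(pr2$precision, 0.8)
  expect_equal(pr2$recall, 0.4)
  # a strain-level prediction lifts to its species; genus-level prediction
  # counts as unassigned at species rank
  deep <- data.frame(seq_id = c("c1", "c2"), taxon_id = c("st1", "g1"))
  pr3 <- precision_recall(deep, truth, tr, "species")
  expect_equal(pr3$assigned_bp, 4000)
  expect_equal(pr3$correct_bp, 4000)
})

test_that("precision/recall invariant to order and to splitting sequences", {
  tr <- ev_tree(); truth <- ev_truth()
  pred <- data.frame(seq_id = c("c1", "c2", "c3", "c4"),
                     taxon_id = c("s1", "s2", "s2", "s3"))
  a <- precision_recall(pred, truth, tr, "genus")
  sh <- sample(nrow(pred))
  b <- precision_recall(pred[sh, ], truth[sample(4), ], tr, "genus")
  expect_equal(a, b)
  # split c4 into two 5 kb halves with the same labels
  truth2 <- rbind(truth[1:3, ],
                  data.frame(seq_id = c("c4a", "c4b"), taxon_id = "s3",
                             length = 5000))
  pred2 <- rbind(pred[1:3, ],
                 data.frame(seq_id = c("c4a", "c4b"), taxon_id = "s3"))
  expect_equal(precision_recall(pred2, truth2, tr, "genus"), a)
})

test_that("corrected measures credit consistently mislabeled bins", {
  tr <- ev_tree(); truth <- ev_truth()
  # labels permuted among bins: corrected measures are perfect
  perm <- data.frame(seq_id = c("c1", "c2", "c3", "c4"),
                     taxon_id = c("s2", "s2", "s3", "s1"))
  cr <- corrected_precision_recall(perm, truth, tr, "species")
  expect_equal(cr$precision, 1)
  expect_equal(cr$recall, 1)
  expect_lt(precision_recall(perm, truth, tr, "species")$precision, 1)
  empty <- data.frame(seq_id = character(0), taxon_id = character(0))
  expect_equal(corrected_precision_recall(empty, truth, tr,
                                          "species")$recall, 0)
})

test_that("exact matching equals the exhaustive oracle on small cases", {
  set.seed(404)
  for (rep in 1:60) {
    nr <- sample(1:5, 1); nc <- sample(1:5, 1)
    W <- matrix(sample(0:20, nr * nc, TRUE), nr, nc)
    expect_equal(match_bins(W)$weight, oracle_match_weight(W))
  }
  # the case where greedy matching would under-credit
  W <- rbind(c(5, 9), c(0, 5))
  expect_equal(match_bins(W)$weight, 10)
})

test_that("corrected measures never fall below plain measures", {
  tr <- ev_tree()
  set.seed(505)
  for (rep in 1:30) {
    n <- 12
    truth <- data.frame(seq_id = paste0("c", 1:n),
                        taxon_id = sample(c("s1", "s2", "s3"), n, TRUE),
                        length = sample(1e3:1e4, n),
                        stringsAsFactors = FALSE)
    pred <- data.frame(seq_id = truth$seq_id,
                       taxon_id = sample(c("s1", "s2", "s3", "g1", NA),
                                         n, TRUE))
    for (rk in c("genus", "species")) {
      pr <- precision_recall(pred, truth, tr, rk)
      cr <- corrected_precision_recall(pred, truth, tr, rk)
      if (!is.na(pr$precision))
        expect_gte(cr$precision + 1e-12, pr$precision)
      expect_gte(cr$recall + 1e-12, pr$recall)
    }
  }
})

test_that("false-taxon counting equals a set difference", {
  tr <- ev_tree(); truth <- ev_truth()
  within <- data.frame(seq_id = "c1", taxon_id = "s2")
  expect_equal(count_false_taxa(within, truth, tr, "species"), 0L)
  invented <- data.frame(seq_id = c("c1", "c2"), taxon_id = c("s1", "s3"))
  truth13 <- truth[truth$seq_id %in% c("c1", "c2"), ]
  # s3 is a real taxon of the tree but absent from this truth subset
  expect_equal(count_false_taxa(invented, truth13, tr, "species"), 1L)
  set.seed(42)
  for (rep in 1:20) {
    pred <- data.frame(seq_id = truth$seq_id,
                       taxon_id = sample(c("s1", "s2", "s3", NA), 4, TRUE))
    got <- count_false_taxa(pred, truth, tr, "species")
    p <- project_to_rank(tr, pred$taxon_id, "species")
    t <- project_to_rank(tr, truth$taxon_id, "species")
    expect_equal(got, length(setdiff(unique(p[!is.na(p)]), unique(t))))
  }
})

test_that("contig chunking follows the 10 kb / 2 kb rule", {
  mkseq <- function(n) paste(rep("ACGT", ceiling(n / 4)), collapse = "") |>
    substr(1, n)
  contigs <- c(exact = mkseq(10000), short = mkseq(9999),
               rem = mkseq(11000))
  ch <- chunk_contigs(contigs)
  expect_false(any(grepl("^short", names(ch$chunks))))   # dropped
  expect_equal(sum(ch$map$contig_id == "exact"), 5L)
  expect_true(all(nchar(ch$chunks[ch$map$contig_id == "exact"]) == 2000))
  rem <- ch$map[ch$map$contig_id == "rem", ]
  expect_equal(nrow(rem), 5L)
  expect_equal(rem$end[5] - rem$start[5], 3000)           # merged remainder
  expect_equal(paste(ch$chunks[rem$chunk_id], collapse = ""),
               contigs[["rem"]])
})

test_that("scaffold-contig agreement counts only comparable contigs", {
  tr <- ev_tree()
  smap <- data.frame(scaffold_id = c("sc1", "sc1", "sc2"),
                     contig_id = c("c1", "c2", "c3"),
                     stringsAsFactors = FALSE)
  lens <- c(c1 = 4000, c2 = 4000, c3 = 4000)
  cp <- data.frame(seq_id = c("c1", "c2", "c3"),
                   taxon_id = c("s1", "s2", "s3"))
  sp_same <- data.frame(seq_id = c("sc1", "sc2"), taxon_id = c("s1", "s3"))
  ag <- scaffold_contig_agreement(cp, sp_same, smap, tr, "species", lens)
  expect_equal(ag$pct_agreement, 100 * 2 / 3)
  expect_equal(ag$kb_agreement, 8)
  # unassigned contig is excluded from numerator and denominator
  cp2 <- cp; cp2$taxon_id[2] <- NA
  ag2 <- scaffold_contig_agreement(cp2, sp_same, smap, tr, "species", lens)
  expect_equal(ag2$comparable, 2L)
  expect_equal(ag2$pct_agreement, 100)
  # identical assignments agree everywhere
  sp_id <- data.frame(seq_id = c("sc1", "sc2"), taxon_id = c("g1", "s3"))
  cp3 <- data.frame(seq_id = c("c1", "c2", "c3"),
                    taxon_id = c("s1", "s1", "s3"))
  ag3 <- scaffold_contig_agreement(cp3, sp_id, smap, tr, "genus", lens)
  expect_equal(ag3$pct_agreement, 100)
  expect_equal(ag3$kb_agreement, 12)
})

test_that("the per-rank report assembles all measures", {
  tr <- ev_tree(); truth <- ev_truth()
  pred <- truth[, c("seq_id", "taxon_id")]
  rep1 <- evaluate_binning(pred, truth, tr)
  expect_equal(nrow(rep1), 6L)
  expect_true(all(rep1$precision[rep1$rank %in%
                                   c("family", "genus", "species")] == 1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(rep1, f)
  back <- read.table(f, sep = "\t", header = TRUE)
  expect_equal(nrow(back), 6L)
})
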