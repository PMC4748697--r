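test_that("six-frame translation matches an independent codon table", {
  expect_equal(unname(six_frame_translate("ATG")["f0"]), "M")
  expect_equal(unname(six_frame_translate("")), rep("", 6))
  set.seed(66)
  for (rep in 1:10) {
    s <- random_dna(300, p_non_acgt = 0)
    tr <- six_frame_translate(s)
    rc <- oracle_revcomp(s)
    expect_equal(unname(tr["f0"]), oracle_translate(s))
    expect_equal(unname(tr["f1"]), oracle_translate(substr(s, 2, 300)))
    expect_equal(unname(tr["f2"]), oracle_translate(substr(s, 3, 300)))
    expect_equal(unname(tr["r0"]), oracle_translate(rc))
    expect_equal(unname(tr["r1"]), oracle_translate(substr(rc, 2, 300)))
    expect_equal(unname(tr["r2"]), oracle_translate(substr(rc, 3, 300)))
  }
})

test_that("marker hits are validated and extracted with orientation", {
  contigs <- c(c1 = paste(rep("ACGT", 250), collapse = ""))
  hits <- data.frame(contig_id = c("c1", "c1", "c2"),
                     start = c(0L, 900L, 0L),
                     end = c(90L, 1100L, 50L),
                     gene = "geneA", strand = "+", frame = 0L,
                     stringsAsFactors = FALSE)
  expect_warning(expect_warning(ok <- detect_markers(contigs, hits),
                                "unknown"), "out-of-bounds")
  expect_equal(nrow(ok), 1L)
  expect_equal(nchar(ok$seq), 90L)
  expect_equal(ok$seq, substr(contigs[["c1"]], 1, 90))
  # reverse-strand hit equals reverse complement of the interval
  hits2 <- data.frame(contig_id = "c1", start = 10L, end = 40L,
                      gene = "g", strand = "-", frame = 0L)
  got <- detect_markers(contigs, hits2)$seq
  expect_equal(got, oracle_revcomp(substr(contigs[["c1"]], 11, 40)))
})

test_that("naive Bayes log-likelihoods match a hand multinomial model", {
  seqs <- c("AAAAAAAA", "AAAAAAGA", "GGGGGGGG", "GGGGGAGG")
  taxa <- c("tA", "tA", "tG", "tG")
  m <- train_nbc(seqs, taxa, k = 1L, pseudocount = 1)
  # taxon tA: counts A=15, G=1 (k=1 over 16 windows); +1 pseudocount
  pa <- (c(15, 0, 1, 0) + 1) / 20
  expect_equal(unname(m$logp["tA", ]), log(pa))
  q <- count_kmers("AAGA", 1L)
  ll <- m$logp %*% as.numeric(q)
  byhand_tA <- sum(as.numeric(q) * log(pa))
  expect_equal(unname(ll["tA", 1]), byhand_tA)
  expect_error(train_nbc(character(0), character(0)), "length")
})

test_that("bootstrap assignment is confident, calibrated and seeded", {
  set.seed(77)
  mkseq <- function(p_a, n = 400) paste(
    sample(c("A", "G"), n, TRUE, prob = c(p_a, 1 - p_a)), collapse = "")
  train <- c(replicate(5, mkseq(0.9)), replicate(5, mkseq(0.1)))
  m <- train_nbc(train, rep(c("tA", "tG"), each = 5), k = 2L)
  sure <- assign_marker(m, mkseq(0.9), n_bootstrap = 100, seed = 1)
  expect_equal(sure$taxon_id, "tA")
  expect_equal(sure$confidence, 1)
  # equidistant query between two exactly mirrored models (class tG's
  # training data is class tA's with A and G swapped): confidence ~ 0.5
  seqsA <- replicate(5, mkseq(0.9))
  msym <- train_nbc(c(seqsA, chartr("AG", "GA", seqsA)),
                    rep(c("tA", "tG"), each = 5), k = 1L)
  amb <- assign_marker(msym, strrep("AG", 200), n_bootstrap = 1000,
                       seed = 2)
  expect_gt(amb$confidence, 0.35)
  expect_lt(amb$confidence, 0.65)
  r1 <- assign_marker(m, mkseq(0.7), n_bootstrap = 200, seed = 3)
  r2 <- assign_marker(m, mkseq(0.7), n_bootstrap = 200, seed = 3)
  expect_identical(r1, r2)
  none <- assign_marker(m, "NNNNNN", seed = 1)
  expect_true(is.na(none$taxon_id))
  expect_equal(none$confidence, 0)
})

test_that("posterior argmax recovers the generating taxon on the toy", {
  set.seed(88)
  mkseq <- function(p_a, n) paste(
    sample(c("A", "G"), n, TRUE, prob = c(p_a, 1 - p_a)), collapse = "")
  m <- train_nbc(c(replicate(5, mkseq(0.8, 1000)),
                   replicate(5, mkseq(0.2, 1000))),
                 rep(c("tA", "tG"), each = 5), k = 2L)
  hits <- vapply(1:200, function(i)
    assign_marker(m, mkseq(0.8, 200), n_bootstrap = 10)$taxon_id, "")
  expect_gte(mean(hits == "tA"), 0.99)
})

test_that("fragment consensus follows the retained-set rule", {
  tr <- toy_tree()
  single <- assign_fragment(
    data.frame(taxon_id = "s1", confidence = 0.9), tr, 0.1)
  expect_equal(single, list(taxon_id = "s1", confidence = 0.9))
  # genus + its species both retained -> species wins, min confidence
  two <- assign_fragment(
    data.frame(taxon_id = c("g1", "s1"), confidence = c(0.90, 0.88)),
    tr, 0.1)
  expect_equal(two, list(taxon_id = "s1", confidence = 0.88))
  # sibling species conflict -> LCA fallback at their genus
  sib <- assign_fragment(
    data.frame(taxon_id = c("s1", "s2"), confidence = c(0.90, 0.89)),
    tr, 0.1)
  expect_equal(sib, list(taxon_id = "g1", confidence = 0.89))
  # low-confidence conflicting hit is dropped by the hcs filter
  filt <- assign_fragment(
    data.frame(taxon_id = c("s1", "s3"), confidence = c(0.95, 0.5)),
    tr, 0.1)
  expect_equal(filt$taxon_id, "s1")
})

test_that("fragment consensus is order-invariant and matches a brute force", {
  tr <- toy_tree()
  # independent re-statement of the rule via explicit root paths
  brute <- function(a, thr) {
    keep <- a[a$confidence >= max(a$confidence) * (1 - thr), , drop = FALSE]
    taxa <- unique(keep$taxon_id)
    dom <- Filter(function(t)
      all(vapply(taxa, function(o) o %in% tax_path(tr, t), logical(1))),
      taxa)
    t <- if (length(dom) > 0)
      dom[[which.max(vapply(dom, function(d) tr$depth[[d]], 1L))]]
    else oracle_lca(tr, taxa)
    list(taxon_id = t, confidence = min(keep$confidence))
  }
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(1:5, 1)
    a <- data.frame(taxon_id = sample(tr$ids[-1], n, replace = TRUE),
                    confidence = round(stats::runif(n), 2))
    r1 <- assign_fragment(a, tr, 0.1)
    r2 <- assign_fragment(a[sample.int(n), , drop = FALSE], tr, 0.1)
    expect_identical(r1, r2)
    expect_equal(r1, brute(a, 0.1))
    hcs <- max(a$confidence)
    kept <- a$confidence >= hcs * 0.9
    expect_lte(r1$confidence, min(a$confidence[kept]) + 1e-12)
    expect_true(any(vapply(a$taxon_id[kept], function(t)
      is_on_path(tr, r1$taxon_id, t), logical(1))))
  }
})

test_that("domtblout adapter extracts names, scores and envelopes", {
  f <- withr::local_tempfile()
  writeLines(c(
    "# comment line",
    paste("c1_f0 - 120 rpL2 PF00181.1 90 1e-30 100.2 0.1 1 1 1e-31",
          "1e-30 99.9 0.1 5 88 4 90 2 95 0.9 -")), f)
  df <- read_domtblout(f)
  expect_equal(df$target, "c1_f0")
  expect_equal(df$query, "rpL2")
  expect_equal(df$score, 99.9)
  expect_equal(df$env_from, 2L)
  expect_equal(df$env_to, 95L)
})
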