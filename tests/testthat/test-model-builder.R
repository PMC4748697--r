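# taxonomy used throughout: root - p - f - g (genus) - s1..s3 (species),
# plus a second genus g2/s4 for reference-count cases
mb_tree <- function() {
  taxonomy(data.frame(
    taxon_id = c("root", "p", "f", "g", "s1", "s2", "s3", "s5",
                 "g2", "s4"),
    parent_id = c("root", "root", "p", "f", "g", "g", "g", "g",
                  "f", "g2"),
    rank = c("no rank", "phylum", "family", "genus", "species", "species",
             "species", "species", "genus", "species")))
}

cat_of <- function(...) reference_catalog(data.frame(taxon_id = names(c(...)),
                                                     bp = unname(c(...))))

test_that("modelability applies the printed bp thresholds", {
  tr <- mb_tree()
  p <- selection_params()
  cat1 <- cat_of(c(s1 = 350e3, s2 = 320e3, s3 = 310e3, s4 = 400e3))
  # species: 150 kb sample + 350 kb reference -> modelable
  expect_true(is_modelable("s1", 150e3, cat1, tr, p))
  # species with only 100 kb reference -> not modelable
  expect_false(is_modelable("s1", 150e3, cat_of(c(s1 = 100e3)), tr, p))
  # below the 100 kb sample floor -> never modelable
  expect_false(is_modelable("s1", 50e3, cat1, tr, p))
  # genus needs minGenomesWgs qualifying species
  expect_true(is_modelable("g", 150e3, cat1, tr, p))    # s1,s2,s3 qualify
  expect_false(is_modelable("g2", 150e3, cat1, tr, p))  # 1 species < 3
  p1 <- selection_params(minGenomesWgs = 1)
  expect_true(is_modelable("g2", 150e3, cat1, tr, p1))
})

test_that("step 6 moves assignments to the nearest modelable ancestor", {
  tr <- mb_tree()
  p <- selection_params()
  # s1 has no reference; s2, s3, s5 qualify so genus g remains modelable
  cat1 <- cat_of(c(s2 = 350e3, s3 = 320e3, s5 = 310e3, s4 = 400e3))
  a <- data.frame(seq_id = c("c1", "c2", "c3"),
                  taxon_id = c("s1", "s2", "s3"),
                  confidence = 1, stringsAsFactors = FALSE)
  lens <- c(c1 = 150e3, c2 = 150e3, c3 = 150e3)
  sel <- select_modelable_taxa(a, cat1, tr, p, lens)
  # s1 has no reference -> its contig moves to genus g (which qualifies)
  expect_equal(sel$assignments$taxon_id, c("g", "s2", "s3"))
  expect_setequal(sel$modelable, c("g", "s2", "s3"))
  # total assigned bp conserved
  expect_equal(sum(lens[sel$assignments$seq_id[!is.na(sel$assignments$taxon_id)]]),
               sum(lens))
  # nothing modelable anywhere -> configuration error
  expect_error(
    select_modelable_taxa(a, cat_of(c(s4 = 1e3)), tr, p, lens),
    "configuration error")
})

test_that("step 7 prunes least-abundant leaves into retained ancestors", {
  tr <- mb_tree()
  a <- data.frame(seq_id = c("c1", "c2", "c3"),
                  taxon_id = c("s1", "s2", "s3"),
                  confidence = 1, stringsAsFactors = FALSE)
  lens <- c(c1 = 10e3, c2 = 20e3, c3 = 30e3)
  pr <- prune_to_max_leaves(a, tr, selection_params(maxLeafClades = 2),
                            lens)
  # 10 kb leaf removed; its bp joins the nearest ancestor with data (g)
  expect_setequal(pr$leaves, c("g", "s2", "s3")[c(2, 3)])
  expect_equal(pr$assignments$taxon_id[1], "g")
  expect_equal(sum(lens), sum(lens[pr$assignments$seq_id]))
  # no pruning when under the cap
  pr2 <- prune_to_max_leaves(a, tr, selection_params(maxLeafClades = 3),
                             lens)
  expect_identical(pr2$assignments$taxon_id, a$taxon_id)
  # maxLeafClades = 1: everything collapses onto one lineage node
  pr1 <- prune_to_max_leaves(a, tr, selection_params(maxLeafClades = 1),
                             lens)
  expect_equal(length(pr1$leaves), 1L)
  expect_equal(sum(lens), sum(lens[pr1$assignments$seq_id]))
})

test_that("pruning is deterministic and bp-conserving on random inputs", {
  set.seed(202)
  for (rep in 1:10) {
    tr <- random_tree(25)
    n <- 20
    a <- data.frame(seq_id = paste0("c", 1:n),
                    taxon_id = sample(tr$ids, n, replace = TRUE),
                    confidence = 1, stringsAsFactors = FALSE)
    lens <- stats::setNames(sample(1e3:5e4, n), a$seq_id)
    p <- selection_params(maxLeafClades = 3)
    r1 <- prune_to_max_leaves(a, tr, p, lens)
    r2 <- prune_to_max_leaves(a, tr, p, lens)
    expect_identical(r1, r2)
    expect_lte(length(r1$leaves), 3L)
    expect_equal(sum(lens[r1$assignments$seq_id]), sum(lens))
  }
})

test_that("balancing caps per-leaf training data with the stated ordering", {
  tr <- mb_tree()
  p <- selection_params(maxSSDfileSize = 400e3)
  # 600 kb of equal-confidence contigs: longest kept up to the cap
  a <- data.frame(seq_id = paste0("c", 1:6), taxon_id = "s1",
                  confidence = 0.9, stringsAsFactors = FALSE)
  lens <- stats::setNames(c(150e3, 140e3, 120e3, 90e3, 60e3, 40e3),
                          a$seq_id)
  ms <- balance_training_data(a, tr, p, lens)
  # 150 + 140 = 290 kb kept; adding the 120 kb contig would exceed the cap
  expect_setequal(ms$training$seq_id, c("c1", "c2"))
  expect_lte(sum(ms$training$length), 400e3)
  # under the cap: everything kept
  small <- a[1:2, ]
  ms2 <- balance_training_data(small, tr, p,
                               stats::setNames(c(60e3, 60e3), small$seq_id))
  expect_equal(nrow(ms2$training), 2L)
  # tie-break: same confidence, lengths 5 kb/3 kb, cap 5 kb -> 5 kb kept
  tie <- data.frame(seq_id = c("a", "b"), taxon_id = "s1",
                    confidence = 0.5, stringsAsFactors = FALSE)
  ms3 <- balance_training_data(tie, tr, selection_params(maxSSDfileSize = 5e3),
                               c(a = 5e3, b = 3e3))
  expect_equal(ms3$training$seq_id, "a")
  # confidence outranks length
  conf <- data.frame(seq_id = c("lo", "hi"), taxon_id = "s1",
                     confidence = c(0.4, 0.9), stringsAsFactors = FALSE)
  ms4 <- balance_training_data(conf, tr, selection_params(maxSSDfileSize = 4e3),
                               c(lo = 4e3, hi = 2e3))
  expect_equal(ms4$training$seq_id, "hi")
  # a single oversized contig is kept alone
  big <- data.frame(seq_id = "huge", taxon_id = "s1", confidence = 1,
                    stringsAsFactors = FALSE)
  ms5 <- balance_training_data(big, tr, selection_params(maxSSDfileSize = 1e3),
                               c(huge = 5e4))
  expect_equal(ms5$training$seq_id, "huge")
})

test_that("model spec leaves are non-ancestral and internal data excluded", {
  tr <- mb_tree()
  a <- data.frame(seq_id = c("c1", "c2", "c3"),
                  taxon_id = c("g", "s1", "s4"),
                  confidence = 1, stringsAsFactors = FALSE)
  lens <- c(c1 = 5e4, c2 = 5e4, c3 = 5e4)
  ms <- balance_training_data(a, tr, selection_params(), lens)
  expect_setequal(ms$leaves, c("s1", "s4"))      # g is internal over s1
  expect_false("c1" %in% ms$training$seq_id)     # internal data not training
  for (l1 in ms$leaves) for (l2 in setdiff(ms$leaves, l1))
    expect_false(is_on_path(tr, l1, l2))
})
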