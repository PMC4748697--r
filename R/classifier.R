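# Phase 2: top-down hierarchical composition classifier over the
# restricted taxonomy (model leaves + their ancestors).  Each internal
# node with two or more children carries a regularized multinomial linear
# model over multi-k k-mer frequency profiles; prediction descends from
# the root and may stop at an internal node when the winning margin is
# below the node's calibrated threshold.

#' Restricted taxonomy over a leaf set
#'
#' @param tree A [taxonomy()] object.
#' @param leaves Modeled leaf taxa (mutually non-ancestral).
#' @return List: `nodes`, `root`, `leaves`, `children` (restricted
#'   children per node), `leaf_under` (node -> leaves in its subtree).
#' @export
restricted_taxonomy <- function(tree, leaves) {
  leaves <- as.character(leaves)
  .check_taxa(tree, leaves)
  paths <- lapply(leaves, tax_path, tree = tree)
  nodes <- unique(unlist(paths))
  children <- stats::setNames(vector("list", length(nodes)), nodes)
  leaf_under <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(leaves)) {
    p <- paths[[i]]
    for (j in seq_along(p)) {
      leaf_under[[p[j]]] <- union(leaf_under[[p[j]]], leaves[i])
      if (j < length(p))
        children[[p[j]]] <- union(children[[p[j]]], p[j + 1L])
    }
  }
  list(nodes = nodes, root = tree$root, leaves = leaves,
       children = children, leaf_under = leaf_under)
}

# non-overlapping fragment windows; sequences shorter than fragment_len
# are kept whole when at least half a fragment long
.fragment_seqs <- function(seqs, fragment_len) {
  out <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n < fragment_len) {
      if (n >= fragment_len / 2) out <- c(out, s)
      next
    }
    starts <- seq(1L, n - fragment_len + 1L, by = fragment_len)
    out <- c(out, substring(s, starts, starts + fragment_len - 1L))
  }
  out
}

.softmax <- function(scores) {
  e <- exp(scores - apply(scores, 1L, max))
  e / rowSums(e)
}

# fit one node: regularized multinomial linear model, classes balanced by
# down-sampling, 10% held out for margin calibration
.fit_node <- function(frags_by_child, K, holdout, stop_quantile,
                      lambda = 1e-3) {
  sizes <- lengths(frags_by_child)
  nmin <- min(sizes)
  train_x <- list(); train_y <- character(0)
  held_x <- list(); held_y <- character(0)
  for (ch in names(frags_by_child)) {
    f <- frags_by_child[[ch]]
    if (length(f) > nmin) f <- sample(f, nmin)
    nh <- max(1L, floor(length(f) * holdout))
    if (length(f) - nh < 2L) nh <- 0L
    hold_ix <- if (nh > 0L) sample(seq_along(f), nh) else integer(0)
    tr <- if (nh > 0L) f[-hold_ix] else f
    train_x[[ch]] <- kmer_profile_matrix(tr, K = K)
    train_y <- c(train_y, rep(ch, length(tr)))
    if (nh > 0L) {
      held_x[[ch]] <- kmer_profile_matrix(f[hold_ix], K = K)
      held_y <- c(held_y, rep(ch, nh))
    }
  }
  x <- do.call(rbind, train_x)
  y <- factor(train_y, levels = names(frags_by_child))
  fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = 0,
                        lambda = c(0.1, 0.01, lambda))
  co <- glmnet::coef.glmnet(fit, s = lambda)
  W <- vapply(names(frags_by_child),
              function(ch) as.numeric(co[[ch]]),
              numeric(ncol(x) + 1L))
  threshold <- 0
  if (stop_quantile > 0 && length(held_y) > 0L) {
    hx <- do.call(rbind, held_x)
    pr <- .softmax(cbind(1, hx) %*% W)
    win <- max.col(pr, ties.method = "first")
    margin <- pr[cbind(seq_len(nrow(pr)), win)] -
      apply(pr, 1L, function(r) sort(r, decreasing = TRUE)[2L])
    correct <- colnames(W)[win] == held_y
    if (any(correct))
      threshold <- stats::quantile(margin[correct], stop_quantile,
                                   names = FALSE)
  }
  list(W = W, threshold = threshold)
}

#' Train the hierarchical binning classifier
#'
#' For every internal node of the restricted taxonomy with two or more
#' children, a linear multinomial model separates the children using
#' fixed-length fragments drawn from the sample-derived training contigs
#' and the reference sequences of each child's subtree. Classes are
#' balanced by down-sampling to the smallest child; a held-out fraction
#' calibrates the per-node early-stopping margin threshold. Deterministic
#' under `seed`.
#'
#' @param model_spec A `model_spec` from [balance_training_data()].
#' @param contigs Named character vector of sample contigs.
#' @param catalog A [reference_catalog()] whose `ref_seqs` supply
#'   reference training sequences.
#' @param tree A [taxonomy()] object.
#' @param K k-mer lengths of the composition profile (default 4, 5, 6).
#' @param fragment_len Training fragment length in bp (default 1,000).
#' @param min_seq_len `minSeqLen`: shorter query sequences are left
#'   unassigned (default 1,000).
#' @param max_frags_per_class Per-node cap on fragments per child class.
#' @param holdout Held-out fraction for margin calibration (default 0.1).
#' @param stop_quantile Early-stopping calibration: 0 (the default)
#'   disables early stopping; a positive value sets each node's threshold
#'   to that quantile of the correct held-out margins, so prediction
#'   stops at the node when the winning margin falls below it.
#' @param seed RNG seed.
#' @return A `hier_model` object.
#' @export
train_hierarchical <- function(model_spec, contigs, catalog, tree,
                               K = c(4L, 5L, 6L), fragment_len = 1000L,
                               min_seq_len = 1000L,
                               max_frags_per_class = 300L,
                               holdout = 0.1, stop_quantile = 0,
                               seed = NULL) {
  stopifnot(inherits(model_spec, "model_spec"))
  if (length(model_spec$leaves) < 2L)
    stop("need at least two leaf taxa to train")
  if (!is.null(seed)) set.seed(seed)
  rt <- restricted_taxonomy(tree, model_spec$leaves)

  frags_by_leaf <- list()
  for (lf in model_spec$leaves) {
    ids <- model_spec$training$seq_id[model_spec$training$taxon_id == lf]
    seqs <- unname(contigs[intersect(ids, names(contigs))])
    for (t in intersect(tax_descendants(tree, lf),
                        names(catalog$ref_seqs)))
      seqs <- c(seqs, catalog$ref_seqs[[t]])
    fr <- .fragment_seqs(seqs, fragment_len)
    if (length(fr) == 0L)
      stop("leaf taxon ", lf, " has no training fragments ",
           "(configuration error)")
    frags_by_leaf[[lf]] <- fr
  }

  nodes <- list()
  for (nd in rt$nodes) {
    ch <- rt$children[[nd]]
    if (length(ch) < 2L) next
    fbc <- stats::setNames(lapply(ch, function(c1) {
      pool <- unlist(frags_by_leaf[rt$leaf_under[[c1]]], use.names = FALSE)
      if (length(pool) > max_frags_per_class)
        pool <- sample(pool, max_frags_per_class)
      pool
    }), ch)
    nodes[[nd]] <- .fit_node(fbc, K, holdout, stop_quantile)
    nodes[[nd]]$children <- ch
  }
  structure(list(restricted = rt, nodes = nodes, K = as.integer(K),
                 fragment_len = as.integer(fragment_len),
                 min_seq_len = as.integer(min_seq_len)),
            class = "hier_model")
}

#' @export
print.hier_model <- function(x, ...) {
  cat("hierarchical composition classifier:",
      length(x$restricted$leaves), "leaf taxa,",
      length(x$nodes), "decision nodes, K =",
      paste(x$K, collapse = ","), "\n")
  invisible(x)
}

#' Classify one sequence
#'
#' Root-to-leaf descent choosing the best child at each decision node;
#' stops early (returning the internal node) when the winning margin is
#' below the node threshold. Sequences shorter than `minSeqLen` are
#' unassigned. The output taxon is always a node of the learned
#' restricted taxonomy.
#'
#' @param model A `hier_model`.
#' @param dna Query sequence.
#' @return List with `taxon_id` (`NA` if unassigned) and `confidence`
#'   (minimum winning-class probability along the path).
#' @export
predict_taxon <- function(model, dna) {
  if (nchar(dna) < model$min_seq_len)
    return(list(taxon_id = NA_character_, confidence = 0))
  x <- matrix(kmer_profile(dna, K = model$K), nrow = 1L)
  cur <- model$restricted$root
  conf <- 1
  repeat {
    ch <- model$restricted$children[[cur]]
    if (length(ch) == 0L) break                 # leaf
    if (length(ch) == 1L) { cur <- ch; next }   # pass-through
    nodemod <- model$nodes[[cur]]
    pr <- .softmax(cbind(1, x) %*% nodemod$W)[1L, ]
    ord <- order(pr, decreasing = TRUE)
    margin <- pr[ord[1L]] - pr[ord[2L]]
    if (margin < nodemod$threshold) break       # stop at internal node
    conf <- min(conf, pr[ord[1L]])
    cur <- nodemod$children[ord[1L]]
  }
  list(taxon_id = cur, confidence = conf)
}

#' Bin a whole sample
#'
#' Classifies every contig with [predict_taxon()]; optionally applies a
#' final scaffold-consistency pass.
#'
#' @param model A `hier_model`.
#' @param contigs Named character vector of contigs.
#' @param scaffold_map Optional scaffold map `data.frame`.
#' @param tree Taxonomy (required for the scaffold pass).
#' @param params [consensus_params()] for the scaffold pass.
#' @return Assignment `data.frame`: `seq_id`, `taxon_id`, `confidence`
#'   (one row per input contig, unassigned rows included).
#' @export
bin_sample <- function(model, contigs, scaffold_map = NULL, tree = NULL,
                       params = consensus_params()) {
  contigs <- .named_chr(contigs)
  res <- lapply(contigs, predict_taxon, model = model)
  out <- data.frame(seq_id = names(contigs),
                    taxon_id = vapply(res, `[[`, "", "taxon_id"),
                    confidence = vapply(res, `[[`, 0, "confidence"),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(scaffold_map) && !is.null(tree) && params$enabled &&
      nrow(out) > 0L)
    out <- scaffold_consensus(out, scaffold_map, tree, params,
                              stats::setNames(nchar(contigs),
                                              names(contigs)))
  out
}

#' Persist a trained model as a plain-text directory
#'
#' Writes a manifest (`manifest.yaml`), the restricted taxonomy
#' (`taxonomy.tsv`: node, parent-within-restricted-tree) and one weight
#' TSV per decision node.
#'
#' @param model A `hier_model`.
#' @param dir Output directory.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rt <- model$restricted
  edges <- do.call(rbind, lapply(rt$nodes, function(nd) {
    ch <- rt$children[[nd]]
    if (length(ch) == 0L) NULL
    else data.frame(parent = nd, child = ch, stringsAsFactors = FALSE)
  }))
  utils::write.table(edges, file.path(dir, "taxonomy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  nodefiles <- character(0)
  for (nd in names(model$nodes)) {
    fn <- paste0("node_", gsub("[^A-Za-z0-9_.-]", "_", nd), ".tsv")
    W <- model$nodes[[nd]]$W
    utils::write.table(W, file.path(dir, fn), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    nodefiles[nd] <- fn
  }
  yaml::write_yaml(list(
    K = model$K, fragment_len = model$fragment_len,
    min_seq_len = model$min_seq_len, root = rt$root,
    leaves = rt$leaves,
    nodes = lapply(names(model$nodes), function(nd) list(
      id = nd, file = unname(nodefiles[nd]),
      children = model$nodes[[nd]]$children,
      threshold = model$nodes[[nd]]$threshold))),
    file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Load a model persisted with [save_model()]
#'
#' @param dir Model directory.
#' @return A `hier_model`.
#' @export
load_model <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  edges <- utils::read.table(file.path(dir, "taxonomy.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  nodes_all <- unique(c(edges$parent, edges$child))
  children <- stats::setNames(vector("list", length(nodes_all)), nodes_all)
  for (p in unique(edges$parent))
    children[[p]] <- edges$child[edges$parent == p]
  leaves <- unlist(man$leaves)
  leaf_under <- stats::setNames(vector("list", length(nodes_all)),
                                nodes_all)
  desc_leaves <- function(nd) {
    ch <- children[[nd]]
    if (length(ch) == 0L) return(nd)
    unlist(lapply(ch, desc_leaves))
  }
  for (nd in nodes_all) leaf_under[[nd]] <- intersect(desc_leaves(nd),
                                                      leaves)
  nodes <- list()
  for (nd in man$nodes) {
    W <- as.matrix(utils::read.table(file.path(dir, nd$file), sep = "\t",
                                     header = TRUE, check.names = FALSE))
    nodes[[nd$id]] <- list(W = W, threshold = nd$threshold,
                           children = unlist(nd$children))
  }
  structure(list(
    restricted = list(nodes = nodes_all, root = man$root, leaves = leaves,
                      children = children, leaf_under = leaf_under),
    nodes = nodes, K = unlist(man$K),
    fragment_len = man$fragment_len, min_seq_len = man$min_seq_len),
    class = "hier_model")
}
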