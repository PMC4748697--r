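# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# naive sliding-window dictionary k-mer counter (substring + tabulate)
naive_kmer_counts <- function(s, k) {
  n <- nchar(s)
  counts <- integer(4^k)
  if (n < k) return(counts)
  w <- substring(s, 1:(n - k + 1), k:n)
  w <- toupper(w)
  valid <- !grepl("[^ACGT]", w)
  for (win in w[valid]) {
    d <- match(strsplit(win, "")[[1]], c("A", "T", "G", "C")) - 1L
    ix <- sum(d * 4^((k - 1):0)) + 1L
    counts[ix] <- counts[ix] + 1L
  }
  counts
}

random_dna <- function(n, p_non_acgt = 0.05) {
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(rep((1 - p_non_acgt) / 4, 4), p_non_acgt)),
        collapse = "")
}

# independent codon table (standard genetic code), built by hand
oracle_translate <- function(dna) {
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- as.vector(outer(outer(bases, bases, paste0), bases,
                            paste0))
  # outer ordering: first index varies fastest; rebuild explicitly
  codons <- character(64); i <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    i <- i + 1L; codons[i] <- paste0(b1, b2, b3)
  }
  tab <- stats::setNames(aas, codons)
  n <- (nchar(dna) %/% 3L) * 3L
  if (n == 0L) return("")
  cods <- substring(toupper(dna), seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- tab[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

oracle_revcomp <- function(dna) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(dna, "")[[1]]), collapse = ""))
}

# random taxonomy: node i's parent drawn among nodes 1..i-1, ranks
# assigned from depth so root-to-leaf rank order is non-increasing
random_tree <- function(n_nodes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- paste0("n", seq_len(n_nodes))
  parent <- c("n1", ids[vapply(2:n_nodes, function(i)
    sample.int(i - 1L, 1L), 1L)])
  depth <- integer(n_nodes)
  for (i in 2:n_nodes) depth[i] <- depth[match(parent[i], ids)] + 1L
  rank <- ifelse(depth == 0L, "no rank",
                 TAXONOMY_RANKS[pmin(depth, length(TAXONOMY_RANKS))])
  rank[stats::runif(n_nodes) < 0.2 & depth > 0L] <- "no rank"
  taxonomy(data.frame(taxon_id = ids, parent_id = parent, rank = rank))
}

# brute-force LCA: deepest node in the intersection of root paths
oracle_lca <- function(tree, taxa) {
  paths <- lapply(taxa, tax_path, tree = tree)
  common <- Reduce(intersect, paths)
  common[which.max(tree$depth[common])]
}

# exhaustive max-weight one-to-one matching: recursively try every
# (row -> column or unmatched) assignment
oracle_match_weight <- function(W) {
  nr <- nrow(W); nc <- ncol(W)
  if (nr == 0L || nc == 0L) return(0)
  rec <- function(i, used, acc) {
    if (i > nr) return(acc)
    best <- rec(i + 1L, used, acc)        # leave row i unmatched
    for (j in seq_len(nc))
      if (!used[j])
        best <- max(best, rec(i + 1L, replace(used, j, TRUE),
                              acc + W[i, j]))
    best
  }
  rec(1L, logical(nc), 0)
}

# small fixed taxonomy: root - phylum - family - 2 genera - species/strain
toy_tree <- function() {
  taxonomy(data.frame(
    taxon_id = c("root", "p", "f", "g1", "g2", "s1", "s2", "s3", "st1"),
    parent_id = c("root", "root", "p", "f", "f", "g1", "g1", "g2", "s1"),
    rank = c("no rank", "phylum", "family", "genus", "genus",
             "species", "species", "species", "strain")))
}

# cached default synthetic community + pipeline runs (built once per
# test session; used by the conservation and recovery tests)
.cache <- new.env(parent = emptyenv())
cached_community <- function(scenario = leave_out_scenario()) {
  key <- paste0("comm_", scenario$rs, "_", scenario$mg)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- generate_community(community_spec(), scenario)
  .cache[[key]]
}
cached_pipeline <- function(scenario = leave_out_scenario()) {
  key <- paste0("pipe_", scenario$rs, "_", scenario$mg)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- suppressWarnings(
      run_pipeline(cached_community(scenario), default_config()))
  .cache[[key]]
}
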