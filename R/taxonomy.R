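# Rank-annotated taxonomy tree: every assignment in the pipeline is a node
# identifier in this structure.

#' Named taxonomic ranks, highest first
#'
#' Rank queries operate on these eight named ranks; nodes with any other
#' rank label are stored as `"no rank"` and are transparent to rank-based
#' operations (walked through upward).
#'
#' @export
TAXONOMY_RANKS <- c("superkingdom", "phylum", "class", "order",
                    "family", "genus", "species", "strain")

#' Numeric position of a rank label (1 = superkingdom)
#'
#' @param rank Rank label(s).
#' @return Integer index into [TAXONOMY_RANKS]; `NA` for `"no rank"` or
#'   unknown labels.
#' @export
rank_index <- function(rank) match(rank, TAXONOMY_RANKS)

#' Build a taxonomy tree from a node table
#'
#' @param nodes `data.frame` with columns `taxon_id`, `parent_id`, `rank`,
#'   and optionally `name`. The root is the node whose parent is itself,
#'   empty, or `NA`. Taxon ids are opaque strings.
#' @return An object of class `taxonomy`.
#' @export
taxonomy <- function(nodes) {
  stopifnot(all(c("taxon_id", "parent_id", "rank") %in% names(nodes)))
  id <- as.character(nodes$taxon_id)
  if (anyDuplicated(id)) stop("duplicated taxon ids")
  parent <- as.character(nodes$parent_id)
  parent[is.na(parent) | parent == ""] <- id[is.na(parent) | parent == ""]
  rank <- as.character(nodes$rank)
  rank[is.na(rank) | !(rank %in% TAXONOMY_RANKS)] <- "no rank"
  nm <- if ("name" %in% names(nodes)) as.character(nodes$name) else id
  names(parent) <- names(rank) <- names(nm) <- id

  root <- id[parent == id]
  if (length(root) != 1L)
    stop("taxonomy must have exactly one root, found ", length(root))
  dangling <- setdiff(parent, id)
  if (length(dangling) > 0L)
    stop("dangling parent reference(s): ", paste(dangling, collapse = ", "))

  # depth by walking parent links; > n steps means a cycle
  n <- length(id)
  depth <- stats::setNames(rep(NA_integer_, n), id)
  for (x in id) {
    cur <- x; steps <- 0L
    while (cur != root) {
      cur <- parent[[cur]]
      steps <- steps + 1L
      if (steps > n) stop("cycle detected involving taxon ", x)
    }
    depth[[x]] <- steps
  }
  structure(list(ids = id, parent = parent, rank = rank, name = nm,
                 root = root, depth = depth),
            class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("taxonomy tree:", length(x$ids), "nodes, root", x$root, "\n")
  tb <- table(x$rank)
  cat("  ranks:", paste(names(tb), tb, sep = ":", collapse = " "), "\n")
  invisible(x)
}

.check_taxa <- function(tree, taxa) {
  bad <- setdiff(as.character(taxa), tree$ids)
  if (length(bad) > 0L)
    stop("unknown taxon id(s): ", paste(bad, collapse = ", "))
}

#' Load a taxonomy from NCBI taxdump or plain TSV
#'
#' Accepts either the NCBI `nodes.dmp`/`names.dmp` dialect
#' (`\\t|\\t`-delimited) or a headerless 4-column TSV
#' (`taxon_id`, `parent_id`, `rank`, `name`). Ranks outside
#' [TAXONOMY_RANKS] are stored as `"no rank"`.
#'
#' @param nodes_path Path to `nodes.dmp` or the TSV.
#' @param names_path Optional path to `names.dmp` (scientific names).
#' @param format `"auto"`, `"taxdump"` or `"tsv"`.
#' @return A [taxonomy()] object.
#' @export
load_taxonomy <- function(nodes_path, names_path = NULL,
                          format = c("auto", "taxdump", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(nodes_path)
  lines <- lines[nzchar(lines)]
  if (format == "auto")
    format <- if (any(grepl("\t|\t", lines[1], fixed = TRUE))) "taxdump" else "tsv"
  if (format == "taxdump") {
    fields <- strsplit(sub("\t\\|$", "", lines), "\t\\|\t")
    nodes <- data.frame(
      taxon_id  = vapply(fields, `[`, "", 1L),
      parent_id = vapply(fields, `[`, "", 2L),
      rank      = vapply(fields, `[`, "", 3L),
      stringsAsFactors = FALSE)
    if (!is.null(names_path)) {
      nl <- readLines(names_path)
      nf <- strsplit(sub("\t\\|$", "", nl[nzchar(nl)]), "\t\\|\t")
      cls <- vapply(nf, function(f) if (length(f) >= 4L) f[4L] else "", "")
      keep <- cls == "scientific name"
      nm <- stats::setNames(vapply(nf[keep], `[`, "", 2L),
                            vapply(nf[keep], `[`, "", 1L))
      nodes$name <- unname(nm[nodes$taxon_id])
    }
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nodes <- data.frame(
      taxon_id  = vapply(fields, `[`, "", 1L),
      parent_id = vapply(fields, `[`, "", 2L),
      rank      = vapply(fields, `[`, "", 3L),
      name      = vapply(fields, function(f)
        if (length(f) >= 4L) f[4L] else NA_character_, ""),
      stringsAsFactors = FALSE)
  }
  taxonomy(nodes)
}

#' Write a taxonomy as 4-column TSV
#'
#' @param tree A [taxonomy()] object.
#' @param path Output file.
#' @export
write_taxonomy_tsv <- function(tree, path) {
  utils::write.table(
    data.frame(tree$ids, tree$parent[tree$ids], tree$rank[tree$ids],
               tree$name[tree$ids]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Root-to-node path
#'
#' @param tree A [taxonomy()] object.
#' @param taxon Taxon id.
#' @return Character vector of taxon ids from the root down to `taxon`.
#' @export
tax_path <- function(tree, taxon) {
  .check_taxa(tree, taxon)
  taxon <- as.character(taxon)
  path <- character(tree$depth[[taxon]] + 1L)
  cur <- taxon
  for (i in length(path):1L) {
    path[i] <- cur
    cur <- tree$parent[[cur]]
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' @param tree A [taxonomy()] object.
#' @param taxa Non-empty vector of taxon ids.
#' @return The deepest node that is an ancestor-or-self of every input.
#' @export
lca <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  stopifnot(length(taxa) >= 1L)
  .check_taxa(tree, taxa)
  common <- tax_path(tree, taxa[1L])
  for (t in taxa[-1L]) {
    p <- tax_path(tree, t)
    n <- min(length(common), length(p))
    eq <- common[seq_len(n)] == p[seq_len(n)]
    common <- common[seq_len(if (all(eq)) n else min(which(!eq)) - 1L)]
  }
  common[length(common)]
}

#' Is `candidate` on the root-to-`lower` path?
#'
#' @param tree A [taxonomy()] object.
#' @param candidate,lower Taxon ids.
#' @return `TRUE` iff `candidate` is an ancestor-or-self of `lower`.
#' @export
is_on_path <- function(tree, candidate, lower) {
  .check_taxa(tree, c(candidate, lower))
  cur <- as.character(lower); candidate <- as.character(candidate)
  repeat {
    if (cur == candidate) return(TRUE)
    if (cur == tree$root) return(FALSE)
    cur <- tree$parent[[cur]]
  }
}

#' Nearest self-or-ancestor at a named rank at or above a cut
#'
#' Walks upward from `taxon` (through `"no rank"` nodes) and returns the
#' first node whose named rank is at or above `cut`; assignments deeper
#' than the configured lowest rank are lifted this way. The root is a
#' fixed point.
#'
#' @param tree A [taxonomy()] object.
#' @param taxon Taxon id.
#' @param cut Rank label from [TAXONOMY_RANKS] (the lowest permitted rank).
#' @return Taxon id at or above `cut`.
#' @export
truncate_to_rank <- function(tree, taxon, cut) {
  ci <- rank_index(cut)
  if (is.na(ci)) stop("unknown rank: ", cut)
  .check_taxa(tree, taxon)
  cur <- as.character(taxon)
  repeat {
    ri <- rank_index(tree$rank[[cur]])
    if (!is.na(ri) && ri <= ci) return(cur)
    if (cur == tree$root) {
      if (!is.na(ri) && ri > ci)
        stop("no ancestor of ", taxon, " at or above rank ", cut)
      return(cur)
    }
    cur <- tree$parent[[cur]]
  }
}

#' Self-or-ancestor of a taxon at an exact named rank
#'
#' @param tree A [taxonomy()] object.
#' @param taxon Taxon id.
#' @param rank Rank label.
#' @return The taxon id on the root path whose rank equals `rank`, or `NA`
#'   if the lineage has no node at that rank.
#' @export
ancestor_at_rank <- function(tree, taxon, rank) {
  .check_taxa(tree, taxon)
  for (node in rev(tax_path(tree, taxon)))
    if (tree$rank[[node]] == rank) return(node)
  NA_character_
}

#' Children map of a taxonomy
#'
#' @param tree A [taxonomy()] object.
#' @return Named list: taxon id -> character vector of child ids.
#' @export
tax_children <- function(tree) {
  kids <- split(tree$ids[tree$ids != tree$root],
                tree$parent[tree$ids[tree$ids != tree$root]])
  out <- stats::setNames(vector("list", length(tree$ids)), tree$ids)
  out[names(kids)] <- kids
  out
}

#' Descendant taxa (including self)
#'
#' @param tree A [taxonomy()] object.
#' @param taxon Taxon id.
#' @return Character vector of all nodes in the subtree rooted at `taxon`.
#' @export
tax_descendants <- function(tree, taxon) {
  .check_taxa(tree, taxon)
  kids <- tax_children(tree)
  out <- character(0)
  queue <- as.character(taxon)
  while (length(queue) > 0L) {
    cur <- queue[1L]; queue <- queue[-1L]
    out <- c(out, cur)
    queue <- c(queue, kids[[cur]])
  }
  out
}
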