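# Scaffold-consistency correction and propagation, plus rank truncation.
# All contigs of a scaffold originate from one strain, so their
# assignments are made consistent and unassigned contigs can inherit the
# scaffold consensus.

#' Consensus parameters for the scaffold step
#'
#' @param agThreshold Fraction of a scaffold's assigned contigs that must
#'   support the consensus taxon (default 0.3).
#' @param assignedPartThreshold Minimum assigned fraction of scaffold bp
#'   required before unassigned contigs inherit the consensus
#'   (default 0.5).
#' @param enabled Whether the scaffold step runs at all
#'   (`placeContigsFromTheSameScaffold`).
#' @return List of class `consensus_params`.
#' @export
consensus_params <- function(agThreshold = 0.3,
                             assignedPartThreshold = 0.5,
                             enabled = TRUE) {
  stopifnot(agThreshold >= 0, agThreshold <= 1,
            assignedPartThreshold >= 0, assignedPartThreshold <= 1)
  structure(list(agThreshold = agThreshold,
                 assignedPartThreshold = assignedPartThreshold,
                 enabled = enabled),
            class = "consensus_params")
}

#' Read a scaffold map TSV
#'
#' Two columns, `scaffold_id` and `contig_id`, one row per contig.
#'
#' @param path TSV file.
#' @return `data.frame` with `scaffold_id`, `contig_id`.
#' @export
read_scaffold_map <- function(path) {
  first <- readLines(path, n = 1L)
  hdr <- grepl("^scaffold_id\t", first)
  df <- utils::read.table(path, sep = "\t", header = hdr,
                          stringsAsFactors = FALSE)
  if (!hdr) names(df) <- c("scaffold_id", "contig_id")
  df$scaffold_id <- as.character(df$scaffold_id)
  df$contig_id <- as.character(df$contig_id)
  df
}

# consensus taxon c for one scaffold's assigned contigs:
# lc = deepest supported assigned taxon (bp-weighted across lineages when
# assignments do not share a single root path), c = lowest node on
# root->lc with support >= agThreshold * n, support counting contigs
# assigned on the c->lc subpath.
.scaffold_consensus_taxon <- function(taxa, lengths, tree, agThreshold) {
  n <- length(taxa)
  stopifnot(n >= 1L)
  utaxa <- unique(taxa)
  deepest <- utaxa[tree$depth[utaxa] == max(tree$depth[utaxa])]
  if (length(deepest) > 1L) {
    on_path_stats <- function(cand) {
      onp <- vapply(taxa, function(t) is_on_path(tree, t, cand), logical(1))
      c(bp = sum(lengths[onp]), k = sum(onp))
    }
    st <- vapply(deepest, on_path_stats, numeric(2))
    ord <- order(-st["bp", ], -st["k", ], deepest)
    lc <- deepest[ord[1L]]
  } else lc <- deepest
  path <- tax_path(tree, lc)
  for (i in length(path):1L) {
    sub <- path[i:length(path)]
    support <- sum(taxa %in% sub)
    if (support >= agThreshold * n) return(path[i])
  }
  tree$root
}

#' Correct the assignments of one scaffold
#'
#' Reassigns every assigned contig of the scaffold to the lowest taxon `c`
#' on the path from the root to the deepest supported assignment `lc` such
#' that at least `agThreshold * n` of the `n` assigned contigs are
#' assigned on the `c`-to-`lc` subpath. Confidences are preserved.
#'
#' @param assignments `data.frame` with `seq_id`, `taxon_id`,
#'   `confidence` (`NA` taxon = unassigned); may cover many scaffolds.
#' @param contig_ids Contigs belonging to this scaffold.
#' @param tree A [taxonomy()] object.
#' @param params [consensus_params()].
#' @param lengths Named vector of contig lengths in bp.
#' @return List with the corrected `assignments` and the consensus taxon
#'   `c` (`NA` when the scaffold has no assigned contig).
#' @export
correct_scaffold <- function(assignments, contig_ids, tree, params,
                             lengths) {
  rows <- which(assignments$seq_id %in% contig_ids &
                  !is.na(assignments$taxon_id))
  if (length(rows) == 0L)
    return(list(assignments = assignments, taxon = NA_character_))
  cc <- .scaffold_consensus_taxon(assignments$taxon_id[rows],
                                  lengths[assignments$seq_id[rows]],
                                  tree, params$agThreshold)
  assignments$taxon_id[rows] <- cc
  list(assignments = assignments, taxon = cc)
}

#' Propagate the scaffold consensus to unassigned contigs
#'
#' When the assigned fraction of the scaffold's bp (`al / l`) reaches
#' `assignedPartThreshold`, every unassigned contig of the scaffold is
#' assigned the consensus taxon `c` with confidence equal to the minimum
#' confidence among the scaffold's assigned contigs.
#'
#' @inheritParams correct_scaffold
#' @param taxon Consensus taxon `c` from [correct_scaffold()].
#' @return Updated assignments.
#' @export
propagate_unassigned <- function(assignments, contig_ids, taxon, tree,
                                 params, lengths) {
  if (is.na(taxon)) return(assignments)
  rows <- which(assignments$seq_id %in% contig_ids)
  assigned <- rows[!is.na(assignments$taxon_id[rows])]
  unassigned <- setdiff(rows, assigned)
  if (length(unassigned) == 0L) return(assignments)
  l <- sum(lengths[contig_ids])
  al <- sum(lengths[assignments$seq_id[assigned]])
  if (al / l >= params$assignedPartThreshold) {
    assignments$taxon_id[unassigned] <- taxon
    assignments$confidence[unassigned] <-
      min(assignments$confidence[assigned])
  }
  assignments
}

#' Scaffold-consistency pass over all scaffolds
#'
#' Applies [correct_scaffold()] then [propagate_unassigned()] to every
#' scaffold of the map. Contigs absent from the map are singleton
#' scaffolds (a no-op). Contigs in the map but absent from `assignments`
#' are added as unassigned rows first, so propagation can reach them.
#'
#' @inheritParams correct_scaffold
#' @param scaffold_map `data.frame` with `scaffold_id`, `contig_id`.
#' @return Updated assignments `data.frame`.
#' @export
scaffold_consensus <- function(assignments, scaffold_map, tree, params,
                               lengths) {
  if (!params$enabled) return(assignments)
  missing <- setdiff(scaffold_map$contig_id, assignments$seq_id)
  if (length(missing) > 0L)
    assignments <- rbind(assignments,
                         data.frame(seq_id = missing,
                                    taxon_id = NA_character_,
                                    confidence = 0,
                                    stringsAsFactors = FALSE))
  for (sc in unique(scaffold_map$scaffold_id)) {
    ids <- scaffold_map$contig_id[scaffold_map$scaffold_id == sc]
    res <- correct_scaffold(assignments, ids, tree, params, lengths)
    assignments <- propagate_unassigned(res$assignments, ids, res$taxon,
                                        tree, params, lengths)
  }
  assignments
}

#' Truncate assignments to the configured lowest rank
#'
#' Assignments deeper than `cut` (`rankIdCut`) are lifted to the nearest
#' ancestor at or above that rank via [truncate_to_rank()].
#'
#' @param assignments Assignment `data.frame`.
#' @param tree A [taxonomy()] object.
#' @param cut Rank label.
#' @return Updated assignments.
#' @export
truncate_assignments <- function(assignments, tree, cut) {
  ok <- !is.na(assignments$taxon_id)
  if (any(ok)) {
    ut <- unique(assignments$taxon_id[ok])
    map <- stats::setNames(
      vapply(ut, function(t) truncate_to_rank(tree, t, cut), character(1)),
      ut)
    assignments$taxon_id[ok] <- unname(map[assignments$taxon_id[ok]])
  }
  assignments
}
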