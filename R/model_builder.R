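# Steps 6-7 and training-data balancing: which taxa get their own model,
# and which sample-derived contigs train them.

#' Selection parameters for taxon modeling
#'
#' @param minBpToModel Minimum sample-derived bp for a taxon to be
#'   modeled (default 100,000).
#' @param minBpPerSpecies Minimum reference bp per species
#'   (default 300,000).
#' @param minGenomesWgs Number of distinct qualifying descendant species a
#'   higher-ranking taxon needs (default 3; 1 is the permissive
#'   alternative).
#' @param maxLeafClades Maximum number of modeled leaf taxa (default 50).
#' @param maxSSDfileSize Per-leaf cap on sample-derived training bp
#'   (default 400,000); set very large to disable balancing.
#' @return List of class `selection_params`.
#' @export
selection_params <- function(minBpToModel = 1e5,
                             minBpPerSpecies = 3e5,
                             minGenomesWgs = 3L,
                             maxLeafClades = 50L,
                             maxSSDfileSize = 4e5) {
  stopifnot(minBpToModel > 0, minBpPerSpecies > 0, minGenomesWgs >= 1,
            maxLeafClades >= 1, maxSSDfileSize > 0)
  structure(list(minBpToModel = minBpToModel,
                 minBpPerSpecies = minBpPerSpecies,
                 minGenomesWgs = as.integer(minGenomesWgs),
                 maxLeafClades = as.integer(maxLeafClades),
                 maxSSDfileSize = maxSSDfileSize),
            class = "selection_params")
}

#' Reference sequence catalog
#'
#' @param bp_table `data.frame` with `taxon_id` and `bp` of reference
#'   sequence available per taxon.
#' @param ref_seqs Optional named list: taxon id -> character vector of
#'   reference sequences (used for classifier training).
#' @return List of class `reference_catalog`.
#' @export
reference_catalog <- function(bp_table, ref_seqs = NULL) {
  stopifnot(all(c("taxon_id", "bp") %in% names(bp_table)),
            all(bp_table$bp >= 0))
  bp_table$taxon_id <- as.character(bp_table$taxon_id)
  structure(list(bp = stats::setNames(bp_table$bp, bp_table$taxon_id),
                 ref_seqs = ref_seqs),
            class = "reference_catalog")
}

#' Read a reference catalog TSV (`taxon_id`, `bp`)
#'
#' @param path TSV file.
#' @return A [reference_catalog()].
#' @export
read_reference_catalog <- function(path) {
  first <- readLines(path, n = 1L)
  hdr <- grepl("^taxon_id\t", first)
  df <- utils::read.table(path, sep = "\t", header = hdr,
                          stringsAsFactors = FALSE)
  if (!hdr) names(df) <- c("taxon_id", "bp")
  reference_catalog(df)
}

# reference bp of a species-level taxon, summed over its subtree
.species_ref_bp <- function(catalog, tree, species) {
  sum(catalog$bp[intersect(tax_descendants(tree, species),
                           names(catalog$bp))])
}

# distinct descendant species of `taxon` with >= minBp reference each
.qualifying_species <- function(catalog, tree, taxon, minBp) {
  desc <- tax_descendants(tree, taxon)
  species <- desc[tree$rank[desc] == "species"]
  species[vapply(species, function(s)
    .species_ref_bp(catalog, tree, s) >= minBp, logical(1))]
}

#' Can a taxon be modeled?
#'
#' A taxon is modelable iff it has at least `minBpToModel` of
#' sample-derived data and, at species rank (or below), at least
#' `minBpPerSpecies` of reference sequence, or, at higher ranks, at least
#' `minGenomesWgs` distinct descendant species each with
#' `minBpPerSpecies` of reference.
#'
#' @param taxon Taxon id.
#' @param sample_bp Sample-derived bp identified for the taxon.
#' @param catalog A [reference_catalog()].
#' @param tree A [taxonomy()] object.
#' @param params [selection_params()].
#' @return Logical.
#' @export
is_modelable <- function(taxon, sample_bp, catalog, tree, params) {
  if (sample_bp < params$minBpToModel) return(FALSE)
  ri <- rank_index(tree$rank[[taxon]])
  if (!is.na(ri) && ri >= rank_index("species")) {
    sp <- if (tree$rank[[taxon]] == "species") taxon
          else ancestor_at_rank(tree, taxon, "species")
    if (is.na(sp)) return(FALSE)
    .species_ref_bp(catalog, tree, sp) >= params$minBpPerSpecies
  } else {
    length(.qualifying_species(catalog, tree, taxon,
                               params$minBpPerSpecies)) >=
      params$minGenomesWgs
  }
}

.bp_by_taxon <- function(assignments, lengths) {
  a <- assignments[!is.na(assignments$taxon_id), , drop = FALSE]
  if (nrow(a) == 0L) return(stats::setNames(numeric(0), character(0)))
  tapply(lengths[a$seq_id], a$taxon_id, sum)
}

#' Step 6: move assignments onto modelable taxa
#'
#' Iterates deepest-first: assignments at a taxon that is not modelable
#' (given the sample bp accumulated there so far) move to its parent,
#' until every assigned taxon is modelable. Sample bp moved up from
#' descendants counts toward the ancestor's own threshold.
#'
#' @param assignments Assignment `data.frame` (after rank truncation).
#' @param catalog A [reference_catalog()].
#' @param tree A [taxonomy()] object.
#' @param params [selection_params()].
#' @param lengths Named contig lengths in bp.
#' @return List: `assignments` (reassigned) and `modelable` (character
#'   vector of taxa carrying data, all modelable).
#' @export
select_modelable_taxa <- function(assignments, catalog, tree, params,
                                  lengths) {
  repeat {
    bp <- .bp_by_taxon(assignments, lengths)
    if (length(bp) == 0L)
      return(list(assignments = assignments, modelable = character(0)))
    taxa <- setdiff(names(bp)[order(-tree$depth[names(bp)])], tree$root)
    moved <- FALSE
    for (t in taxa) {
      bp_now <- .bp_by_taxon(assignments, lengths)  # includes accumulation
      if (!(t %in% names(bp_now))) next
      if (!is_modelable(t, bp_now[[t]], catalog, tree, params)) {
        rows <- which(!is.na(assignments$taxon_id) &
                        assignments$taxon_id == t)
        assignments$taxon_id[rows] <- tree$parent[[t]]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  # residual bp that cannot support any model accumulates at the root;
  # the root only counts as modelable if it passes the test itself
  bp <- .bp_by_taxon(assignments, lengths)
  modelable <- names(bp)[vapply(names(bp), function(t)
    is_modelable(t, bp[[t]], catalog, tree, params), logical(1))]
  if (length(modelable) == 0L)
    stop("no modelable taxon, not even the root: ",
         "check reference catalog and thresholds (configuration error)")
  list(assignments = assignments, modelable = modelable)
}

# taxa carrying data with no strict descendant carrying data
.leaf_taxa <- function(tree, taxa_with_data) {
  taxa_with_data[vapply(taxa_with_data, function(t)
    !any(vapply(setdiff(taxa_with_data, t), function(o)
      is_on_path(tree, t, o), logical(1))), logical(1))]
}

#' Step 7: prune to the most abundant leaf taxa
#'
#' While more than `maxLeafClades` leaf taxa carry data, the least
#' abundant leaf (minimum assigned bp; ties broken by deeper rank, then
#' lexicographic id) is removed and its sequences are reassigned to the
#' closest ancestor that carries data (or, failing that, its parent).
#'
#' @inheritParams select_modelable_taxa
#' @return List: `assignments` and `leaves` (final leaf taxon set).
#' @export
prune_to_max_leaves <- function(assignments, tree, params, lengths) {
  guard <- length(tree$ids) * (max(tree$depth) + 1L)
  repeat {
    bp <- .bp_by_taxon(assignments, lengths)
    withdata <- names(bp)
    leaves <- .leaf_taxa(tree, withdata)
    if (length(leaves) <= params$maxLeafClades) break
    lbp <- bp[leaves]
    ord <- order(lbp, -tree$depth[leaves], leaves)
    victim <- leaves[ord[1L]]
    anc <- rev(tax_path(tree, victim))[-1L]   # strict ancestors, deep first
    target <- c(intersect(anc, setdiff(withdata, victim)), anc)[1L]
    rows <- which(!is.na(assignments$taxon_id) &
                    assignments$taxon_id == victim)
    assignments$taxon_id[rows] <- target
    guard <- guard - 1L
    if (guard <= 0L) stop("pruning failed to terminate")
  }
  list(assignments = assignments,
       leaves = .leaf_taxa(tree, names(.bp_by_taxon(assignments, lengths))))
}

#' Balance sample-derived training data per leaf taxon
#'
#' For every leaf taxon, contigs are accepted in order of decreasing
#' confidence, then decreasing length, until adding the next contig would
#' exceed `maxSSDfileSize`; a single contig larger than the cap is kept
#' alone. Data assigned to internal taxa (ancestors of another data
#' taxon) is not leaf training data and is excluded.
#'
#' @inheritParams select_modelable_taxa
#' @return A `model_spec`: list with `leaves`, `training` (`data.frame`
#'   `seq_id`, `taxon_id`, `confidence`, `length`) and `assignments`
#'   (the full phase-1 assignments the spec was built from).
#' @export
balance_training_data <- function(assignments, tree, params, lengths) {
  bp <- .bp_by_taxon(assignments, lengths)
  leaves <- .leaf_taxa(tree, names(bp))
  keep <- list()
  for (lf in leaves) {
    rows <- assignments[!is.na(assignments$taxon_id) &
                          assignments$taxon_id == lf, , drop = FALSE]
    rows$length <- unname(lengths[rows$seq_id])
    rows <- rows[order(-rows$confidence, -rows$length, rows$seq_id), ,
                 drop = FALSE]
    total <- 0
    sel <- logical(nrow(rows))
    for (i in seq_len(nrow(rows))) {
      if (i == 1L && rows$length[1L] > params$maxSSDfileSize) {
        sel[1L] <- TRUE
        break
      }
      if (total + rows$length[i] > params$maxSSDfileSize) break
      sel[i] <- TRUE
      total <- total + rows$length[i]
    }
    keep[[lf]] <- rows[sel, , drop = FALSE]
  }
  training <- do.call(rbind, c(keep, list(make.row.names = FALSE)))
  if (is.null(training))
    training <- data.frame(seq_id = character(0), taxon_id = character(0),
                           confidence = numeric(0), length = numeric(0))
  structure(list(leaves = leaves, training = training,
                 assignments = assignments),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model spec:", length(x$leaves), "leaf taxa,",
      nrow(x$training), "training contigs,",
      sum(x$training$length), "bp sample-derived training data\n")
  invisible(x)
}

#' Write a model spec as a manifest TSV plus per-leaf FASTA
#'
#' @param model_spec A `model_spec`.
#' @param contigs Named character vector of contig sequences.
#' @param dir Output directory (created if needed).
#' @export
write_model_spec <- function(model_spec, contigs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(model_spec$training,
                     file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (lf in model_spec$leaves) {
    ids <- model_spec$training$seq_id[model_spec$training$taxon_id == lf]
    if (length(ids) == 0L) next
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(contigs[ids]),
      file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", lf), ".fna")))
  }
  invisible(dir)
}
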