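# Binning evaluation: per-rank bp-weighted precision/recall, their
# bin-identity-free "corrected" variants, false-taxon counts, contig
# chunking and scaffold-contig agreement.

#' Project assignments to a named rank
#'
#' Taxa deeper than the rank are lifted to their ancestor at that rank;
#' taxa whose lineage has no node at the rank (including assignments above
#' it) project to `NA`.
#'
#' @param tree A [taxonomy()] object.
#' @param taxa Character vector of taxon ids (`NA` allowed).
#' @param rank Rank label.
#' @return Character vector of rank-level taxa (`NA` where undefined).
#' @export
project_to_rank <- function(tree, taxa, rank) {
  ut <- unique(taxa[!is.na(taxa)])
  if (length(ut) == 0L) return(rep(NA_character_, length(taxa)))
  map <- stats::setNames(
    vapply(ut, function(t) ancestor_at_rank(tree, t, rank), character(1)),
    ut)
  out <- rep(NA_character_, length(taxa))
  ok <- !is.na(taxa)
  out[ok] <- unname(map[taxa[ok]])
  out
}

.eval_frame <- function(pred, truth, tree, rank) {
  m <- merge(truth, pred, by = "seq_id", all.x = TRUE,
             suffixes = c("_true", "_pred"))
  m$true_rank <- project_to_rank(tree, m$taxon_id_true, rank)
  m$pred_rank <- project_to_rank(tree, m$taxon_id_pred, rank)
  m[!is.na(m$true_rank), , drop = FALSE]   # truth lineage must have the rank
}

#' bp-weighted precision and recall at a rank
#'
#' Precision is correctly labeled assigned bp over assigned bp at the
#' rank; recall is correctly labeled bp over total truth bp at the rank.
#' Sequences whose predicted lineage lacks the rank count as unassigned;
#' sequences whose true lineage lacks it are excluded.
#'
#' @param pred Assignment `data.frame` (`seq_id`, `taxon_id`, ...).
#' @param truth Truth `data.frame` (`seq_id`, `taxon_id`, `length`).
#' @param tree A [taxonomy()] object.
#' @param rank Rank label.
#' @return List: `precision` (`NA` when nothing is assigned), `recall`,
#'   `assigned_bp`, `correct_bp`, `total_bp`.
#' @export
precision_recall <- function(pred, truth, tree, rank) {
  m <- .eval_frame(pred, truth, tree, rank)
  total <- sum(m$length)
  assigned <- !is.na(m$pred_rank)
  correct <- assigned & m$pred_rank == m$true_rank
  list(precision = if (sum(m$length[assigned]) > 0)
         sum(m$length[correct]) / sum(m$length[assigned]) else NA_real_,
       recall = if (total > 0) sum(m$length[correct]) / total else NA_real_,
       assigned_bp = sum(m$length[assigned]),
       correct_bp = sum(m$length[correct]),
       total_bp = total)
}

#' Maximum-weight one-to-one matching of bins to taxa
#'
#' Exact subset dynamic program over the smaller side of the overlap
#' matrix (used whenever that side has at most `max_exact_dim` entries);
#' beyond that a greedy descending-weight matching is used, which this
#' package's community sizes never reach.
#'
#' @param overlap Numeric matrix of shared bp, bins x taxa.
#' @param max_exact_dim Largest dimension solved exactly.
#' @return List with `weight`, the maximal total shared bp over all
#'   one-to-one bin-taxon matchings.
#' @export
match_bins <- function(overlap, max_exact_dim = 16L) {
  if (length(overlap) == 0L || nrow(overlap) == 0L || ncol(overlap) == 0L)
    return(list(weight = 0, pairs = NULL))
  transposed <- ncol(overlap) > nrow(overlap)
  W <- if (transposed) t(overlap) else overlap
  m <- ncol(W)
  if (m <= max_exact_dim) {
    nS <- bitwShiftL(1L, m)
    dp <- rep(0, nS)
    for (i in seq_len(nrow(W))) {
      new <- dp
      for (j in seq_len(m)) {
        bit <- bitwShiftL(1L, j - 1L)
        S <- which(bitwAnd(seq_len(nS) - 1L, bit) > 0L)
        cand <- dp[S - bit] + W[i, j]
        new[S] <- pmax(new[S], cand)
      }
      dp <- new
    }
    weight <- max(dp)
  } else {
    ord <- order(-as.vector(W))
    used_r <- logical(nrow(W)); used_c <- logical(m)
    weight <- 0
    for (ix in ord) {
      if (W[ix] <= 0) break
      r <- (ix - 1L) %% nrow(W) + 1L
      cc <- (ix - 1L) %/% nrow(W) + 1L
      if (!used_r[r] && !used_c[cc]) {
        used_r[r] <- used_c[cc] <- TRUE
        weight <- weight + W[ix]
      }
    }
  }
  list(weight = weight)
}

#' Corrected (bin-identity-free) precision and recall
#'
#' Credits consistent-but-mislabeled bins: predicted rank-level bins are
#' matched one-to-one to true rank-level taxa by maximising the total
#' shared bp; bp inside matched pairs counts as consistent, and
#' precision/recall are computed on consistent bp as in
#' [precision_recall()].
#'
#' @inheritParams precision_recall
#' @return List: `precision`, `recall`, `consistent_bp`, `assigned_bp`,
#'   `total_bp`.
#' @export
corrected_precision_recall <- function(pred, truth, tree, rank) {
  m <- .eval_frame(pred, truth, tree, rank)
  total <- sum(m$length)
  a <- m[!is.na(m$pred_rank), , drop = FALSE]
  if (nrow(a) == 0L)
    return(list(precision = NA_real_, recall = if (total > 0) 0 else NA_real_,
                consistent_bp = 0, assigned_bp = 0, total_bp = total))
  overlap <- tapply(a$length, list(a$pred_rank, a$true_rank), sum,
                    default = 0)
  overlap <- matrix(overlap, nrow = dim(overlap)[1L],
                    dimnames = dimnames(overlap))
  consistent <- match_bins(overlap)$weight
  assigned <- sum(a$length)
  list(precision = consistent / assigned,
       recall = consistent / total,
       consistent_bp = consistent, assigned_bp = assigned,
       total_bp = total)
}

#' Count predicted taxa absent from the truth at a rank
#'
#' @inheritParams precision_recall
#' @return Number of predicted rank-level taxa receiving more than 0 bp
#'   that are not in the truth's rank-level taxon set.
#' @export
count_false_taxa <- function(pred, truth, tree, rank) {
  m <- .eval_frame(pred, truth, tree, rank)
  length(setdiff(unique(m$pred_rank[!is.na(m$pred_rank)]),
                 unique(m$true_rank)))
}

#' Chunk long contigs into fixed-size pieces
#'
#' Contigs shorter than `min_len` are dropped; the rest are cut into
#' consecutive `chunk`-sized pieces, with the trailing remainder merged
#' into the final chunk. Used to compare assignment consistency on
#' equal-sized sequences.
#'
#' @param contigs Named character vector of contigs.
#' @param min_len Minimum contig length to keep (default 10,000).
#' @param chunk Chunk size in bp (default 2,000).
#' @return List: `chunks` (named character vector) and `map`
#'   (`data.frame` `chunk_id`, `contig_id`, `start`, `end`; 0-based
#'   half-open).
#' @export
chunk_contigs <- function(contigs, min_len = 10000L, chunk = 2000L) {
  contigs <- .named_chr(contigs)
  keep <- nchar(contigs) >= min_len
  contigs <- contigs[keep]
  chunks <- character(0); map <- list()
  for (id in names(contigs)) {
    n <- nchar(contigs[[id]])
    k <- max(1L, n %/% chunk)
    starts <- (seq_len(k) - 1L) * chunk
    ends <- c(starts[-1L], n)
    cid <- paste0(id, ".", seq_len(k))
    pieces <- substring(contigs[[id]], starts + 1L, ends)
    names(pieces) <- cid
    chunks <- c(chunks, pieces)
    map[[id]] <- data.frame(chunk_id = cid, contig_id = id,
                            start = starts, end = ends,
                            stringsAsFactors = FALSE)
  }
  list(chunks = chunks,
       map = if (length(map) > 0L)
         do.call(rbind, c(map, list(make.row.names = FALSE)))
       else data.frame(chunk_id = character(0), contig_id = character(0),
                       start = integer(0), end = integer(0)))
}

#' Scaffold-contig assignment agreement at a rank
#'
#' For every contig with both a contig-level and (via its scaffold) a
#' scaffold-level assignment at the rank, the two rank-projected taxa are
#' compared; contigs with fewer than two assignments at the rank are not
#' considered. `% agreement` is the percentage of comparable contigs that
#' agree; `kb agreement` is the summed length of agreeing contigs in kb.
#'
#' @param contig_pred Per-contig assignment `data.frame`.
#' @param scaffold_pred Per-scaffold assignment `data.frame` (`seq_id` =
#'   scaffold id).
#' @param scaffold_map `data.frame` `scaffold_id`, `contig_id`.
#' @param tree A [taxonomy()] object.
#' @param rank Rank label.
#' @param lengths Named contig lengths in bp.
#' @return List: `pct_agreement` (`NA` if no comparable contig),
#'   `kb_agreement`, `comparable` (contig count), `comparable_kb`.
#' @export
scaffold_contig_agreement <- function(contig_pred, scaffold_pred,
                                      scaffold_map, tree, rank, lengths) {
  cp <- stats::setNames(project_to_rank(tree, contig_pred$taxon_id, rank),
                        contig_pred$seq_id)
  sp <- stats::setNames(project_to_rank(tree, scaffold_pred$taxon_id, rank),
                        scaffold_pred$seq_id)
  ctg <- scaffold_map$contig_id
  c_tax <- cp[ctg]
  s_tax <- sp[scaffold_map$scaffold_id]
  comparable <- !is.na(c_tax) & !is.na(s_tax)
  agree <- comparable & c_tax == s_tax
  list(pct_agreement = if (sum(comparable) > 0)
         100 * sum(agree) / sum(comparable) else NA_real_,
       kb_agreement = sum(lengths[ctg[agree]]) / 1000,
       comparable = sum(comparable),
       comparable_kb = sum(lengths[ctg[comparable]]) / 1000)
}

#' Per-rank evaluation report
#'
#' @inheritParams precision_recall
#' @param ranks Rank labels to report (default phylum..species).
#' @param scaffold_pred,scaffold_map Optional scaffold-level assignments
#'   and map for the agreement columns.
#' @return `data.frame` of class `eval_report`, one row per rank.
#' @export
evaluate_binning <- function(pred, truth, tree,
                             ranks = c("phylum", "class", "order",
                                       "family", "genus", "species"),
                             scaffold_pred = NULL, scaffold_map = NULL) {
  lengths <- stats::setNames(truth$length, truth$seq_id)
  rows <- lapply(ranks, function(rk) {
    pr <- precision_recall(pred, truth, tree, rk)
    cr <- corrected_precision_recall(pred, truth, tree, rk)
    row <- data.frame(rank = rk, precision = pr$precision,
                      recall = pr$recall,
                      corrected_precision = cr$precision,
                      corrected_recall = cr$recall,
                      assigned_bp = pr$assigned_bp,
                      false_taxa = count_false_taxa(pred, truth, tree, rk),
                      stringsAsFactors = FALSE)
    if (!is.null(scaffold_pred) && !is.null(scaffold_map)) {
      ag <- scaffold_contig_agreement(pred, scaffold_pred, scaffold_map,
                                      tree, rk, lengths)
      row$pct_agreement <- ag$pct_agreement
      row$kb_agreement <- ag$kb_agreement
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("eval_report", class(out))
  out
}

#' Write an evaluation report as TSV
#'
#' @param report An `eval_report`.
#' @param path Output file.
#' @export
write_eval_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
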