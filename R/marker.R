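# Phase 1 core: marker-gene regions -> bootstrap-confidence naive Bayes
# taxon assignment -> one consensus assignment per fragment.

#' Six-frame translation
#'
#' Translates the three forward frames and the three frames of the reverse
#' complement with the standard genetic code. Stop codons are `*`,
#' ambiguous codons `X`, trailing partial codons are dropped.
#'
#' @param dna A DNA string.
#' @return Character vector of six protein strings, named
#'   `f0, f1, f2, r0, r1, r2`.
#' @export
six_frame_translate <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L)
  tr1 <- function(s, off) {
    n <- nchar(s) - off
    len <- (n %/% 3L) * 3L
    if (len <= 0L) return("")
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, off + 1L, off + len)),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  rc <- if (nchar(dna) > 0L)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  else ""
  out <- c(tr1(dna, 0L), tr1(dna, 1L), tr1(dna, 2L),
           tr1(rc, 0L), tr1(rc, 1L), tr1(rc, 2L))
  names(out) <- c("f0", "f1", "f2", "r0", "r1", "r2")
  out
}

#' Read a marker-hit TSV
#'
#' Columns `contig_id`, `start`, `end`, `gene`, `strand`, `frame` with
#' 0-based half-open coordinates; a header line is detected and skipped.
#'
#' @param path TSV file.
#' @return `data.frame` of hits.
#' @export
read_marker_hits <- function(path) {
  first <- readLines(path, n = 1L)
  hdr <- grepl("^contig_id\t", first)
  df <- utils::read.table(path, sep = "\t", header = hdr,
                          stringsAsFactors = FALSE)
  if (!hdr) names(df) <- c("contig_id", "start", "end",
                           "gene", "strand", "frame")[seq_len(ncol(df))]
  df$contig_id <- as.character(df$contig_id)
  df
}

#' Validate marker hits and extract their DNA
#'
#' Marker detection itself (HMM profile search) is external; this takes
#' precomputed hit regions, rejects out-of-bounds or unknown-contig hits
#' with a warning, and extracts the hit subsequence
#' (reverse-complemented for `-` strand hits).
#'
#' @param contigs Named character vector (or `DNAStringSet`) of contigs.
#' @param hits `data.frame` as returned by [read_marker_hits()].
#' @return The accepted hits with an added `seq` column.
#' @export
detect_markers <- function(contigs, hits) {
  contigs <- .named_chr(contigs)
  stopifnot(!is.null(names(contigs)))
  known <- hits$contig_id %in% names(contigs)
  if (any(!known))
    warning(sum(!known), " hit(s) on unknown contigs rejected")
  hits <- hits[known, , drop = FALSE]
  len <- nchar(contigs[hits$contig_id])
  ok <- hits$start >= 0 & hits$start < hits$end & hits$end <= len
  if (any(!ok))
    warning(sum(!ok), " out-of-bounds hit(s) rejected")
  hits <- hits[ok, , drop = FALSE]
  if (nrow(hits) == 0L) { hits$seq <- character(0); return(hits) }
  seqs <- substr(contigs[hits$contig_id], hits$start + 1L, hits$end)
  rev <- which(hits$strand == "-")
  for (i in rev)
    seqs[i] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seqs[i])))
  hits$seq <- unname(seqs)
  rownames(hits) <- NULL
  hits
}

#' Train the marker naive Bayes classifier
#'
#' Multinomial model over k-mer counts per taxon with additive smoothing
#' and a uniform prior.
#'
#' @param seqs Character vector of labeled marker sequences.
#' @param taxa Taxon id per sequence.
#' @param k k-mer length of the marker classifier (default 8).
#' @param pseudocount Additive smoothing constant.
#' @return An `nbc_model` object.
#' @export
train_nbc <- function(seqs, taxa, k = 8L, pseudocount = 1) {
  stopifnot(length(seqs) == length(taxa), length(seqs) > 0L)
  taxa <- as.character(taxa)
  classes <- sort(unique(taxa))
  if (any(is.na(taxa) | taxa == ""))
    stop("every training sequence needs a taxon label")
  logp <- matrix(0, nrow = length(classes), ncol = 4^k,
                 dimnames = list(classes, NULL))
  for (cl in classes) {
    counts <- numeric(4^k)
    for (s in seqs[taxa == cl])
      counts <- counts + as.numeric(count_kmers(s, k))
    if (sum(counts) == 0)
      stop("taxon ", cl, " has no countable k-mers (configuration error)")
    p <- (counts + pseudocount) / sum(counts + pseudocount)
    logp[cl, ] <- log(p)
  }
  structure(list(k = as.integer(k), taxa = classes, logp = logp,
                 pseudocount = pseudocount),
            class = "nbc_model")
}

#' @export
print.nbc_model <- function(x, ...) {
  cat("naive Bayes marker classifier: k =", x$k, ",",
      length(x$taxa), "taxa\n")
  invisible(x)
}

#' Assign one marker sequence with bootstrap confidence
#'
#' The taxon is the posterior argmax on the full k-mer count vector; the
#' confidence is the fraction of bootstrap resamples (multinomial
#' resampling of the count vector at its observed total) whose argmax
#' agrees with the full-data argmax.
#'
#' @param model An `nbc_model`.
#' @param dna Marker DNA sequence.
#' @param n_bootstrap Number of bootstrap resamples.
#' @param seed Optional RNG seed for reproducible confidences.
#' @return List with `taxon_id` (`NA` if the sequence has no valid k-mer
#'   window) and `confidence` in `[0, 1]`.
#' @export
assign_marker <- function(model, dna, n_bootstrap = 100L, seed = NULL) {
  stopifnot(inherits(model, "nbc_model"), nchar(dna) > 0L)
  if (!is.null(seed)) set.seed(seed)
  counts <- count_kmers(dna, model$k)
  nz <- which(counts > 0L)
  if (length(nz) == 0L)
    return(list(taxon_id = NA_character_, confidence = 0))
  ll <- model$logp[, nz, drop = FALSE] %*% as.numeric(counts[nz])
  win <- which.max(ll)
  total <- sum(counts[nz])
  boot <- stats::rmultinom(n_bootstrap, total, counts[nz] / total)
  bll <- model$logp[, nz, drop = FALSE] %*% boot
  winners <- max.col(t(bll), ties.method = "first")
  list(taxon_id = model$taxa[win],
       confidence = mean(winners == win))
}

#' Assign a table of marker hits
#'
#' @param model An `nbc_model`.
#' @param hits Hits with a `seq` column ([detect_markers()]).
#' @param n_bootstrap Bootstrap resamples per hit.
#' @param seed RNG seed (one stream over all hits).
#' @return `data.frame`: `contig_id`, `gene`, `taxon_id`, `confidence`.
#' @export
assign_markers <- function(model, hits, n_bootstrap = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(seq_len(nrow(hits)), function(i)
    assign_marker(model, hits$seq[i], n_bootstrap = n_bootstrap))
  data.frame(contig_id = hits$contig_id,
             gene = hits$gene,
             taxon_id = vapply(res, `[[`, "", "taxon_id"),
             confidence = vapply(res, `[[`, 0, "confidence"),
             stringsAsFactors = FALSE)
}

#' Combine per-marker assignments into one fragment assignment
#'
#' Retains assignments with confidence at least `hcs * (1 - threshold)`
#' where `hcs` is the highest confidence on the fragment, then assigns the
#' lowest retained taxon `t` such that every retained assignment is `t` or
#' an ancestor of `t`. When no retained taxon dominates (assignments on
#' diverging lineages), the fragment falls back to the LCA of the retained
#' taxa. The fragment confidence is the smallest retained confidence.
#'
#' @param assignments `data.frame` with `taxon_id`, `confidence` for the
#'   markers of one fragment (rows with `NA` taxon are ignored).
#' @param tree A [taxonomy()] object.
#' @param threshold `candidatePlTopPercentThreshold` (default 0.1).
#' @return List with `taxon_id` and `confidence`.
#' @export
assign_fragment <- function(assignments, tree, threshold = 0.1) {
  a <- assignments[!is.na(assignments$taxon_id), , drop = FALSE]
  if (nrow(a) == 0L)
    return(list(taxon_id = NA_character_, confidence = 0))
  hcs <- max(a$confidence)
  keep <- a[a$confidence >= hcs * (1 - threshold), , drop = FALSE]
  taxa <- unique(keep$taxon_id)
  dominated <- vapply(taxa, function(t)
    all(vapply(taxa, function(o) is_on_path(tree, o, t), logical(1))),
    logical(1))
  if (any(dominated)) {
    cand <- taxa[dominated]
    t <- cand[which.max(tree$depth[cand])]
  } else {
    t <- lca(tree, taxa)
  }
  list(taxon_id = t, confidence = min(keep$confidence))
}

#' Fragment assignments for all contigs with marker hits
#'
#' @param marker_assignments Output of [assign_markers()].
#' @param tree A [taxonomy()] object.
#' @inheritParams assign_fragment
#' @return `data.frame`: `seq_id`, `taxon_id`, `confidence` (one row per
#'   contig that carries at least one assigned marker).
#' @export
assign_fragments <- function(marker_assignments, tree, threshold = 0.1) {
  parts <- split(marker_assignments,
                 marker_assignments$contig_id)
  res <- lapply(parts, assign_fragment, tree = tree, threshold = threshold)
  data.frame(seq_id = names(parts),
             taxon_id = vapply(res, `[[`, "", "taxon_id"),
             confidence = vapply(res, `[[`, 0, "confidence"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Minimal HMMER3 domtblout parser
#'
#' Returns one row per domain hit with the target/query names, envelope
#' coordinates (in the coordinate system of the searched sequence, i.e.
#' protein space for translated searches) and the domain bit score.
#' Mapping translated-frame coordinates back onto contig DNA depends on
#' how the six-frame sequences were named and is left to the caller.
#'
#' @param path domtblout file.
#' @return `data.frame`: `target`, `tlen`, `query`, `score`, `env_from`,
#'   `env_to`.
#' @export
read_domtblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "[[:space:]]+")
  data.frame(
    target   = vapply(fields, `[`, "", 1L),
    tlen     = as.integer(vapply(fields, `[`, "", 3L)),
    query    = vapply(fields, `[`, "", 4L),
    score    = as.numeric(vapply(fields, `[`, "", 14L)),
    env_from = as.integer(vapply(fields, `[`, "", 20L)),
    env_to   = as.integer(vapply(fields, `[`, "", 21L)),
    stringsAsFactors = FALSE)
}
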