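# Multi-k rolling-index k-mer counting: the composition feature core.

DIGIT_A <- 0L; DIGIT_T <- 1L; DIGIT_G <- 2L; DIGIT_C <- 3L
SENTINEL <- 4L

.encode_map <- local({
  m <- rep(SENTINEL, 256L)
  m[utf8ToInt("A") + 1L] <- DIGIT_A; m[utf8ToInt("a") + 1L] <- DIGIT_A
  m[utf8ToInt("T") + 1L] <- DIGIT_T; m[utf8ToInt("t") + 1L] <- DIGIT_T
  m[utf8ToInt("G") + 1L] <- DIGIT_G; m[utf8ToInt("g") + 1L] <- DIGIT_G
  m[utf8ToInt("C") + 1L] <- DIGIT_C; m[utf8ToInt("c") + 1L] <- DIGIT_C
  m
})

#' Encode a DNA string as base-4 digits
#'
#' Maps `A -> 0`, `T -> 1`, `G -> 2`, `C -> 3` (case-insensitive); every
#' other character (`N`, IUPAC ambiguity codes, gaps, ...) becomes the
#' sentinel value 4. Windows containing a sentinel are skipped by the
#' counting routines.
#'
#' @param dna A single character string.
#' @return Integer vector of digits, one per input character.
#' @examples
#' encode_dna("ATGCATG")  # 0 1 2 3 0 1 2
#' @export
encode_dna <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L)
  if (nchar(dna) == 0L) return(integer(0))
  .encode_map[utf8ToInt(dna) + 1L]
}

.as_digits <- function(x) {
  if (is.character(x)) encode_dna(x) else as.integer(x)
}

#' Base-4 index of the k-mer starting at a position
#'
#' Computes `a[start]*4^(k-1) + ... + a[start+k-1]*4^0` for the digit
#' encoding of `x`. This is the index of the first window from which the
#' rolling update proceeds.
#'
#' @param x DNA string or digit vector from [encode_dna()].
#' @param start 0-based start position of the window.
#' @param k Window length.
#' @return Integer index in `[0, 4^k)`.
#' @examples
#' first_index("ATGCATG", 0, 2)  # 1 (AT)
#' first_index("ATGCATG", 3, 2)  # 12 (CA)
#' @export
first_index <- function(x, start, k) {
  a <- .as_digits(x)
  stopifnot(k >= 1, start >= 0)
  if (start + k > length(a))
    stop("window [", start, ", ", start + k, ") out of bounds")
  w <- a[(start + 1L):(start + k)]
  if (any(w >= SENTINEL))
    stop("window contains a non-ACGT character")
  sum(w * 4^((k - 1L):0L))
}

#' Rolling window indices for one k
#'
#' Returns the base-4 index of every length-`k` window of the sequence,
#' computed with the rolling update
#' `index[i+1] = (index[i] - a[i]*4^(k-1)) * 4 + a[i+k]`.
#' Windows covering a non-ACGT character are `NA`.
#'
#' @inheritParams first_index
#' @return Integer vector of length `max(0, n - k + 1)`.
#' @export
rolling_indices <- function(x, k) {
  cpp_rolling_indices(.as_digits(x), as.integer(k))
}

#' Count k-mers of one length
#'
#' One O(n) pass with the rolling index; memory O(4^k). Sequences shorter
#' than `k` yield all-zero counts. Only the forward strand is counted.
#'
#' @inheritParams first_index
#' @param k k-mer length (1..12).
#' @return Integer vector of length `4^k` with attribute `k`; entry `j+1`
#'   is the count of the k-mer whose base-4 encoding is `j`.
#' @examples
#' cc <- count_kmers("ATGCATG", 2)
#' which(cc > 0) - 1L  # indices 1 (AT), 6 (TG), 11 (GC), 12 (CA)
#' @export
count_kmers <- function(x, k) {
  k <- as.integer(k)
  stopifnot(length(k) == 1L, k >= 1L)
  counts <- cpp_multi_kmer_counts(.as_digits(x), k)[[1L]]
  attr(counts, "k") <- k
  counts
}

#' Count k-mers of several consecutive lengths in one pass
#'
#' Maintains the rolling index of the longest window; the index of every
#' shorter prefix k-mer is obtained from it by a right shift, so all k are
#' counted simultaneously. Results are identical to independent
#' [count_kmers()] runs for each k.
#'
#' @inheritParams first_index
#' @param K Integer vector of k values (default `c(4, 5, 6)`).
#' @return Named list (`"k4"`, `"k5"`, ...) of count vectors as in
#'   [count_kmers()].
#' @export
count_multi_k <- function(x, K = c(4L, 5L, 6L)) {
  K <- as.integer(K)
  stopifnot(length(K) >= 1L)
  res <- cpp_multi_kmer_counts(.as_digits(x), K)
  names(res) <- paste0("k", K)
  for (j in seq_along(K)) attr(res[[j]], "k") <- K[j]
  res
}

#' Multi-k composition profile of a sequence
#'
#' Concatenates the per-k count blocks; with `normalize = TRUE` each block
#' is divided by its sum (all-zero blocks stay zero), giving per-k
#' frequency vectors — the feature representation used by the binning
#' classifier.
#'
#' @inheritParams count_multi_k
#' @param normalize Divide each per-k block by its total.
#' @return Numeric vector of length `sum(4^K)` with attribute `K`.
#' @export
kmer_profile <- function(x, K = c(4L, 5L, 6L), normalize = TRUE) {
  blocks <- count_multi_k(x, K)
  v <- unlist(lapply(blocks, function(b) {
    b <- as.numeric(b)
    if (normalize) {
      s <- sum(b)
      if (s > 0) b <- b / s
    }
    b
  }), use.names = FALSE)
  attr(v, "K") <- as.integer(K)
  v
}

#' Multi-k profiles for many sequences
#'
#' @param seqs Character vector (or `Biostrings::DNAStringSet`) of
#'   sequences.
#' @inheritParams kmer_profile
#' @return Numeric matrix, one row per sequence.
#' @export
kmer_profile_matrix <- function(seqs, K = c(4L, 5L, 6L), normalize = TRUE) {
  seqs <- .named_chr(seqs)
  m <- matrix(0, nrow = length(seqs), ncol = sum(4^as.integer(K)))
  for (i in seq_along(seqs))
    m[i, ] <- kmer_profile(seqs[[i]], K = K, normalize = normalize)
  rownames(m) <- names(seqs)
  m
}

#' Decode a base-4 k-mer index back to its DNA string
#'
#' @param index Integer index in `[0, 4^k)` (vectorised).
#' @param k k-mer length.
#' @return Character vector of k-mers.
#' @export
kmer_index_to_string <- function(index, k) {
  bases <- c("A", "T", "G", "C")
  vapply(index, function(ix) {
    d <- integer(k)
    for (p in k:1) { d[p] <- ix %% 4L; ix <- ix %/% 4L }
    paste(bases[d + 1L], collapse = "")
  }, character(1))
}

#' Write k-mer counts as TSV
#'
#' Two columns: k-mer string and count, one row per k-mer with a nonzero
#' count (or all k-mers when `all = TRUE`).
#'
#' @param counts Count vector from [count_kmers()].
#' @param path Output file.
#' @param all Also write zero counts.
#' @export
write_kmer_counts <- function(counts, path, all = FALSE) {
  k <- attr(counts, "k")
  stopifnot(!is.null(k))
  ix <- if (all) seq_along(counts) - 1L else which(counts > 0L) - 1L
  df <- data.frame(kmer = kmer_index_to_string(ix, k),
                   count = as.integer(counts[ix + 1L]))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(df)
}
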