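DNA_BASES <- c("A", "C", "G", "T")

#' All DNA k-mers of length k in lexicographic order
#' @param k word length (>= 1).
#' @return character vector of length `4^k`.
#' @export
all_kmers <- function(k) {
  stopifnot(length(k) == 1L, k >= 1)
  out <- ""
  for (i in seq_len(k)) out <- paste0(rep(out, each = 4L), DNA_BASES)
  out
}

#' Reverse complement of DNA strings
#'
#' Complements (A<->T, C<->G) then reverses. An involution:
#' `revcomp(revcomp(x)) == x`.
#'
#' @param x character vector of DNA strings.
#' @return character vector, same lengths.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", toupper(x))
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

#' Canonical form of a k-mer under reverse complementation
#'
#' The lexicographically smaller of the k-mer and its reverse complement,
#' so a k-mer and its reverse complement share one representative
#' (strand-invariant counting).
#'
#' @param x character vector of k-mers.
#' @return character vector of canonical representatives.
#' @export
canonical_kmer <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

#' Number of canonical k-mer classes
#'
#' Closed form: `2^(2k-1)` for odd k (no k-mer is its own reverse
#' complement), `2^(2k-1) + 2^(k-1)` for even k (palindromic k-mers are
#' singleton classes). k = 2 gives 10 classes from the 16 basic 2-mers.
#'
#' @param k word length (>= 1); vectorized.
#' @return integer count(s) of canonical classes.
#' @export
count_canonical <- function(k) {
  if (any(k < 1) || any(k != as.integer(k))) stop("k must be a positive integer")
  ifelse(k %% 2 == 1, 2^(2 * k - 1), 2^(2 * k - 1) + 2^(k - 1))
}

seq_windows <- function(s, k) {
  L <- nchar(s)
  if (L < k) stop("sequence of length ", L, " is shorter than k = ", k)
  substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
}

one_seq <- function(seq) {
  s <- if (inherits(seq, "seq_set")) {
    if (length(seq) != 1L) stop("expected a single sequence")
    seq[[1]]
  } else {
    as.character(seq)
  }
  s <- toupper(s)
  validate_residues(s, "aptamer", "dna")
  s
}

#' Cumulative k-mer frequency vector of a DNA sequence
#'
#' Concatenates one block per k = 1..kmax. Block k has `4^k` entries in
#' lexicographic order; each entry is the count of that k-mer among the
#' L-k+1 sliding windows divided by L-k+1, so every block sums to 1.
#' Total dimension is `sum(4^(1:kmax))`: 84 for kmax = 3, 340 for
#' kmax = 4. Labels are `k<k>_<kmer>`.
#'
#' @param seq DNA string or single-sequence [seq_set()].
#' @param kmax largest word length (>= 1); sequence must be at least this long.
#' @return named numeric feature vector.
#' @export
kmer_vector <- function(seq, kmax = 3L) {
  s <- one_seq(seq)
  if (nchar(s) < kmax) {
    stop("sequence length ", nchar(s), " < kmax = ", kmax)
  }
  blocks <- lapply(seq_len(kmax), function(k) {
    lv <- all_kmers(k)
    w <- seq_windows(s, k)
    cnt <- table(factor(w, levels = lv))
    v <- as.numeric(cnt) / length(w)
    names(v) <- paste0("k", k, "_", lv)
    v
  })
  unlist(blocks)
}

#' Cumulative reverse-complement canonical k-mer frequency vector
#'
#' As [kmer_vector()], but each window is first mapped to its canonical
#' form ([canonical_kmer()]), and block k has [count_canonical()]`(k)`
#' entries labeled by the canonical representatives in lexicographic
#' order. Dimension `sum(count_canonical(1:kmax))`: 44 for kmax = 3, 180
#' for kmax = 4. Strand-invariant: a sequence and its reverse complement
#' encode identically. Labels are `rc<k>_<kmer>`.
#'
#' @inheritParams kmer_vector
#' @return named numeric feature vector.
#' @export
revc_kmer_vector <- function(seq, kmax = 3L) {
  s <- one_seq(seq)
  if (nchar(s) < kmax) {
    stop("sequence length ", nchar(s), " < kmax = ", kmax)
  }
  blocks <- lapply(seq_len(kmax), function(k) {
    lv <- sort(unique(canonical_kmer(all_kmers(k))))
    w <- canonical_kmer(seq_windows(s, k))
    cnt <- table(factor(w, levels = lv))
    v <- as.numeric(cnt) / length(w)
    names(v) <- paste0("rc", k, "_", lv)
    v
  })
  unlist(blocks)
}

#' Encode a set of aptamers as a feature matrix
#'
#' @param seqs DNA [seq_set()].
#' @param kmax largest word length.
#' @param mode `"plain"` for [kmer_vector()], `"revc"` for
#'   [revc_kmer_vector()].
#' @return numeric matrix, one row per sequence, feature labels as columns.
#' @export
encode_aptamers <- function(seqs, kmax = 3L, mode = c("plain", "revc")) {
  mode <- match.arg(mode)
  f <- if (mode == "plain") kmer_vector else revc_kmer_vector
  rows <- lapply(seq_along(seqs), function(i) {
    tryCatch(f(seqs[[i]], kmax),
             error = function(e) stop("aptamer '", names(seqs)[i], "': ",
                                      conditionMessage(e), call. = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(seqs)
  out
}
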