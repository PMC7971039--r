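# Independent oracles, deliberately implemented apart from the package code.

# reverse complement via Biostrings when available, else a lookup-table
# implementation distinct from the package's chartr-based one
oracle_revcomp <- function(x) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  } else {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    vapply(strsplit(x, ""), function(ch) {
      paste(comp[rev(ch)], collapse = "")
    }, "")
  }
}

# exhaustive canonical-class count: canonicalize every 4^k string
oracle_count_canonical <- function(k) {
  bases <- c("A", "C", "G", "T")
  kmers <- do.call(paste0, rev(expand.grid(rep(list(bases), k),
                                           stringsAsFactors = FALSE)))
  rc <- oracle_revcomp(kmers)
  length(unique(pmin(kmers, rc)))
}

# brute-force k nearest neighbours by explicit loops; ties by lower index
oracle_knn <- function(x, i, k) {
  n <- nrow(x)
  d <- rep(Inf, n)
  for (j in seq_len(n)) {
    if (j != i) d[j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  }
  order(d, seq_len(n))[seq_len(k)]
}

# brute-force NCL removal set A1 (ENN-flagged majority) plus A2 (majority
# neighbours of misclassified minority points), on unscaled coordinates
oracle_ncl_removed <- function(x, y, k = 3) {
  n <- nrow(x)
  minority <- if (sum(y == 1) <= sum(y == 0)) 1 else 0
  flagged <- logical(n)
  nbs <- vector("list", n)
  for (i in seq_len(n)) {
    nbs[[i]] <- oracle_knn(x, i, k)
    flagged[i] <- sum(y[nbs[[i]]] != y[i]) > k / 2
  }
  a1 <- which(flagged & y != minority)
  a2 <- integer()
  for (i in which(flagged & y == minority)) {
    a2 <- c(a2, nbs[[i]][y[nbs[[i]]] != minority])
  }
  sort(unique(c(a1, a2)))
}

random_protein <- function(n, len = 60) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(aa, len, replace = TRUE), collapse = "")
  }, "")
}

random_dna <- function(n, len = 30) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

# small well-separated two-cluster feature set
toy_clusters <- function(n_min = 10, n_maj = 30, sep = 6, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_min * 2, 0, 0.4), n_min),
             matrix(rnorm(n_maj * 2, sep, 0.4), n_maj))
  colnames(x) <- c("u", "v")
  list(x = x, y = rep(c(1L, 0L), c(n_min, n_maj)))
}

# linearly separable toy with labelled test split
toy_separable <- function(n = 200, p = 5, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n)
  colnames(x) <- paste0("f", seq_len(p))
  y <- as.integer(x[, 1] + x[, 2] > 0)
  x[y == 1, 1] <- x[y == 1, 1] + 2.5
  x[y == 0, 1] <- x[y == 0, 1] - 2.5
  list(x = x, y = y)
}

tiny_dataset <- function(n_pairs = 6, apt_len = 12, prot_len = 40, seed = 5) {
  set.seed(seed)
  apt <- random_dna(n_pairs, apt_len)
  names(apt) <- sprintf("a%d", seq_len(n_pairs))
  prot <- random_protein(n_pairs, prot_len)
  names(prot) <- sprintf("p%d", seq_len(n_pairs))
  interaction_dataset(
    data.frame(aptamer_id = names(apt), protein_id = names(prot),
               label = rep_len(c(1L, 0L), n_pairs)),
    seq_set(apt, "dna"), seq_set(prot, "protein"))
}
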