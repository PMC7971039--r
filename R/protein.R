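protein_chars <- function(seq, id = "protein") {
  s <- if (inherits(seq, "seq_set")) seq[[1]] else toupper(as.character(seq))
  validate_residues(s, id, "protein")
  strsplit(s, "")[[1]]
}

#' Amino acid composition (AAC) of a protein
#'
#' 20 residue frequencies f(t) = N(t)/N in the fixed order
#' ACDEFGHIKLMNPQRSTVWY; sums to 1.
#'
#' @param seq protein string or single-sequence [seq_set()].
#' @return named numeric vector of length 20 (`f_A` ... `f_Y`).
#' @export
aac_vector <- function(seq) {
  chars <- protein_chars(seq)
  v <- as.numeric(table(factor(chars, levels = AA_ORDER))) / length(chars)
  names(v) <- paste0("f", AA_ORDER)
  v
}

#' Sequence-order correlation factor at a given lag
#'
#' The lag-d tier averages, over all residue pairs d apart, the squared
#' property differences across the group's three standardized scales:
#' theta_d = mean_i Theta(R_i, R_(i+d)) with
#' Theta(Ri, Rj) = mean over the 3 properties of (H(Rj) - H(Ri))^2.
#' Non-negative; zero for homopolymers.
#'
#' @param seq protein string or single-sequence [seq_set()].
#' @param lag tier (1 <= lag < sequence length).
#' @param group_values 20 x 3 matrix of *standardized* property values
#'   (rows in ACDEFGHIKLMNPQRSTVWY order).
#' @return scalar correlation factor.
#' @export
theta_tier <- function(seq, lag, group_values) {
  chars <- protein_chars(seq)
  L <- length(chars)
  if (lag < 1 || lag >= L) {
    stop("lag must satisfy 1 <= lag < L (lag = ", lag, ", L = ", L, ")")
  }
  stopifnot(is.matrix(group_values), nrow(group_values) == 20L,
            ncol(group_values) == 3L)
  idx <- match(chars, AA_ORDER)
  d <- group_values[idx[(1 + lag):L], , drop = FALSE] -
       group_values[idx[1:(L - lag)], , drop = FALSE]
  mean(rowMeans(d^2))
}

group_matrix <- function(table, group) {
  if (!table$standardized) table <- standardize_properties(table)
  props <- table$groups[[group]]
  if (is.null(props)) stop("unknown property group '", group, "'")
  table$values[, props, drop = FALSE]
}

#' Pseudo amino acid composition (PseAAC) of a protein
#'
#' A (20 + lambda)-dimensional descriptor: the 20 residue frequencies and
#' lambda sequence-order correlation tiers ([theta_tier()]) computed from
#' one standardized 3-property group, combined as
#' X_u = f_u / (1 + w * sum(theta)) for u <= 20 and
#' X_u = w * theta_(u-20) / (1 + w * sum(theta)) above, so the vector
#' sums to 1. As w -> 0 the first 20 components reduce to [aac_vector()].
#'
#' @param seq protein string or single-sequence [seq_set()].
#' @param group group name (e.g. `"A"`) in `table$groups`.
#' @param lambda number of correlation tiers (default 30); must be < L.
#' @param omega sequence-order weight factor (default 0.05).
#' @param table a [load_property_table()]; standardized internally.
#' @param id protein id used in error messages.
#' @return named numeric vector of length `20 + lambda`.
#' @export
pseaac_vector <- function(seq, group = "A", lambda = 30L, omega = 0.05,
                          table = load_property_table(), id = "protein") {
  stopifnot(lambda >= 1, omega > 0)
  chars <- protein_chars(seq, id)
  L <- length(chars)
  if (L <= lambda) {
    stop("protein '", id, "': length L = ", L,
         " must exceed lambda = ", lambda)
  }
  gv <- group_matrix(table, group)
  f <- as.numeric(table(factor(chars, levels = AA_ORDER))) / L
  idx <- match(chars, AA_ORDER)
  theta <- vapply(seq_len(lambda), function(lag) {
    d <- gv[idx[(1 + lag):L], , drop = FALSE] - gv[idx[1:(L - lag)], , drop = FALSE]
    mean(rowMeans(d^2))
  }, 0)
  denom <- sum(f) + omega * sum(theta)
  v <- c(f / denom, omega * theta / denom)
  names(v) <- c(paste0("f", AA_ORDER), paste0("th", seq_len(lambda)))
  v
}

#' Encode proteins as PseAAC blocks over property groups
#'
#' @param seqs protein [seq_set()].
#' @param groups property-group names, kept in the table's A..H order.
#' @inheritParams pseaac_vector
#' @return numeric matrix, one row per protein; 20 + lambda columns per
#'   group, labels prefixed by the group name (e.g. `A_fA`, `A_th1`).
#' @export
encode_proteins <- function(seqs, groups = "A", lambda = 30L, omega = 0.05,
                            table = load_property_table()) {
  if (!table$standardized) table <- standardize_properties(table)
  groups <- names(table$groups)[names(table$groups) %in% groups]
  if (!length(groups)) stop("no valid property groups selected")
  rows <- lapply(seq_along(seqs), function(i) {
    unlist(lapply(groups, function(g) {
      v <- pseaac_vector(seqs[[i]], g, lambda, omega, table, id = names(seqs)[i])
      names(v) <- paste0(g, "_", names(v))
      v
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(seqs)
  out
}

#' Assemble the pairwise feature matrix
#'
#' One row per aptamer-protein pair: the aptamer k-mer block
#' ([encode_aptamers()]) followed by one (20 + lambda)-column PseAAC
#' block per selected property group in the table's A..H order. With the
#' defaults of kmax = 3 plain k-mers, lambda = 30 and all eight groups
#' the matrix has 84 + 8 x 50 = 484 feature columns; the
#' reverse-complement variant gives 44 + 400 = 444.
#'
#' @param dataset an [interaction_dataset()].
#' @param kmax largest aptamer word length (default 3).
#' @param mode `"plain"` or `"revc"` aptamer encoding.
#' @param groups protein property groups to include (default all eight).
#' @inheritParams pseaac_vector
#' @return a `feature_matrix`: list with `x` (numeric matrix, named
#'   columns), `y` (integer 0/1 labels) and `pair_id`.
#' @export
build_feature_matrix <- function(dataset, kmax = 3L,
                                 mode = c("plain", "revc"),
                                 groups = LETTERS[1:8],
                                 lambda = 30L, omega = 0.05,
                                 table = load_property_table()) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "interaction_dataset"))
  apt <- encode_aptamers(dataset$aptamers, kmax, mode)
  prot <- encode_proteins(dataset$proteins, groups, lambda, omega, table)
  p <- dataset$pairs
  x <- cbind(apt[p$aptamer_id, , drop = FALSE],
             prot[p$protein_id, , drop = FALSE])
  rownames(x) <- paste(p$aptamer_id, p$protein_id, sep = ":")
  feature_matrix(x, p$label, rownames(x))
}

#' Construct a feature_matrix container
#'
#' @param x numeric matrix with unique column names.
#' @param y binary labels (0/1), one per row.
#' @param pair_id row identifiers.
#' @return a `feature_matrix` object.
#' @export
feature_matrix <- function(x, y, pair_id = rownames(x)) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (is.null(colnames(x)) || anyDuplicated(colnames(x))) {
    stop("feature matrix needs unique column names")
  }
  if (any(!is.finite(x))) stop("non-finite feature values")
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  if (is.null(pair_id)) pair_id <- as.character(seq_len(nrow(x)))
  structure(list(x = x, y = y, pair_id = as.character(pair_id)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$x), "samples x", ncol(x$x), "features (",
      sum(x$y == 1), "positive /", sum(x$y == 0), "negative )\n")
  invisible(x)
}

#' Write / read a feature matrix as CSV
#'
#' Columns: `pair_id`, the named features, `label`.
#'
#' @param fm a [feature_matrix()].
#' @param path CSV file.
#' @return `path` (write) or a `feature_matrix` (read).
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(pair_id = fm$pair_id, fm$x, label = fm$y,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("pair_id", "label") %in% names(df)))
  feats <- setdiff(names(df), c("pair_id", "label"))
  x <- as.matrix(df[feats])
  rownames(x) <- df$pair_id
  feature_matrix(x, df$label, df$pair_id)
}
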