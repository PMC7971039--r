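#' @useDynLib aptaml, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict rnorm runif rbinom rpois sd var dist optim dpois
#' @importFrom utils head read.csv write.csv
"_PACKAGE"

ALPHABETS <- list(
  dna        = c("A", "C", "G", "T"),
  rna        = c("A", "C", "G", "U"),
  nucleotide = c("A", "C", "G", "T", "U"), # mixed DNA/RNA input
  protein    = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
)

#' Construct a validated sequence set
#'
#' A `seq_set` is a named character vector of residue strings plus an
#' `alphabet` attribute (`"dna"`, `"rna"` or `"protein"`). All exported I/O
#' and encoder functions consume and produce this class.
#'
#' @param x named character vector of sequences (names are ids).
#' @param alphabet one of `"dna"`, `"rna"`, `"nucleotide"` (mixed
#'   DNA/RNA, as aptamer collections often are), `"protein"`.
#' @return a `seq_set` object.
#' @export
seq_set <- function(x, alphabet = c("dna", "rna", "nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (length(x) == 0L) stop("empty sequence set")
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids))) stop("every sequence needs a non-empty id")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  x[] <- toupper(x)
  for (i in seq_along(x)) validate_residues(x[[i]], ids[[i]], alphabet)
  structure(x, class = "seq_set", alphabet = alphabet)
}

validate_residues <- function(residues, id, alphabet) {
  if (!nzchar(residues)) stop("sequence '", id, "' is empty")
  ok <- ALPHABETS[[alphabet]]
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!chars %in% ok)
  if (length(bad)) {
    stop("sequence '", id, "': invalid ", alphabet, " residue '",
         chars[bad[1]], "' at position ", bad[1])
  }
  invisible(TRUE)
}

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set of", length(x), attr(x, "alphabet"), "sequence(s)\n")
  n <- min(length(x), 6L)
  for (i in seq_len(n)) {
    s <- x[[i]]
    cat(sprintf("  %s  [%d] %s%s\n", names(x)[i], nchar(s),
                substr(s, 1, 40), if (nchar(s) > 40) "..." else ""))
  }
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

#' Read a FASTA file
#'
#' Ids are taken from the header token before the first whitespace;
#' duplicate ids are rejected. Lowercase residues are uppercased. RNA
#' records keep their U residues -- conversion to DNA is explicit via
#' [rna_to_dna()].
#'
#' @param path FASTA file.
#' @param alphabet `"dna"`, `"rna"`, `"nucleotide"` or `"protein"`;
#'   residues are validated against it and an error names the offending
#'   id and position.
#' @return a [seq_set()].
#' @export
read_fasta <- function(path, alphabet = c("dna", "rna", "nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stop("FASTA parse error: file '", path, "' has no records")
  ids <- character()
  seqs <- character()
  cur <- NULL
  for (ln in keep) {
    line <- trimws(lines[ln])
    if (startsWith(line, ">")) {
      header <- sub("^>", "", line)
      id <- strsplit(trimws(header), "\\s+")[[1]][1]
      if (is.na(id) || !nzchar(id)) {
        stop("FASTA parse error at line ", ln, ": empty header")
      }
      if (!is.null(cur) && !nzchar(seqs[length(seqs)])) {
        stop("FASTA parse error at line ", ln, ": record '",
             ids[length(ids)], "' has no sequence")
      }
      ids <- c(ids, id)
      seqs <- c(seqs, "")
      cur <- id
    } else {
      if (is.null(cur)) {
        stop("FASTA parse error at line ", ln,
             ": sequence data before first '>' header")
      }
      seqs[length(seqs)] <- paste0(seqs[length(seqs)], gsub("\\s", "", line))
    }
  }
  if (!nzchar(seqs[length(seqs)])) {
    stop("FASTA parse error: record '", ids[length(ids)], "' has no sequence")
  }
  names(seqs) <- ids
  seq_set(seqs, alphabet)
}

#' Write a FASTA file (60-column wrap)
#'
#' @param seqs a [seq_set()] or named character vector.
#' @param path output file.
#' @param width line-wrap column, default 60.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  ids <- names(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", ids[i]), substring(s, starts, pmin(starts + width - 1L, nchar(s)))), con)
  }
  invisible(path)
}

#' Convert RNA to DNA by replacing U with T
#'
#' Idempotent; length-preserving. Accepts sequences over {A,C,G,U} (T also
#' tolerated so the map is idempotent).
#'
#' @param seqs a [seq_set()] or character vector of RNA sequences.
#' @return a `"dna"` [seq_set()] (or plain character if input was unnamed).
#' @export
rna_to_dna <- function(seqs) {
  out <- chartr("U", "T", toupper(unclass(seqs)))
  if (is.null(names(out))) return(out)
  seq_set(out, "dna")
}

#' Build an interaction dataset from components
#'
#' @param pairs data.frame with columns `aptamer_id`, `protein_id`,
#'   `label` (0/1).
#' @param aptamers DNA [seq_set()].
#' @param proteins protein [seq_set()].
#' @return an `interaction_dataset`: list of the three validated parts.
#' @export
interaction_dataset <- function(pairs, aptamers, proteins) {
  need <- c("aptamer_id", "protein_id", "label")
  if (!all(need %in% names(pairs))) {
    stop("pair table must have columns: ", paste(need, collapse = ", "))
  }
  pairs <- as.data.frame(pairs)[need]
  pairs$aptamer_id <- as.character(pairs$aptamer_id)
  pairs$protein_id <- as.character(pairs$protein_id)
  lab <- pairs$label
  if (!all(lab %in% c(0, 1))) {
    stop("labels must be 0 or 1; offending value(s): ",
         paste(unique(lab[!lab %in% c(0, 1)]), collapse = ", "))
  }
  pairs$label <- as.integer(lab)
  missing_a <- setdiff(pairs$aptamer_id, names(aptamers))
  if (length(missing_a)) stop("unknown aptamer id(s): ", paste(missing_a, collapse = ", "))
  missing_p <- setdiff(pairs$protein_id, names(proteins))
  if (length(missing_p)) stop("unknown protein id(s): ", paste(missing_p, collapse = ", "))
  key <- paste(pairs$aptamer_id, pairs$protein_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- pairs[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate pair: (", d$aptamer_id, ", ", d$protein_id, ")")
  }
  structure(list(pairs = pairs, aptamers = aptamers, proteins = proteins),
            class = "interaction_dataset")
}

#' @export
print.interaction_dataset <- function(x, ...) {
  cat("interaction_dataset:", nrow(x$pairs), "pairs (",
      sum(x$pairs$label == 1), "positive /", sum(x$pairs$label == 0),
      "negative ),", length(x$aptamers), "aptamers,",
      length(x$proteins), "proteins\n")
  invisible(x)
}

#' Read an aptamer-protein pair table
#'
#' Delimiter (tab or comma) is sniffed from the header line. Required
#' columns: `aptamer_id`, `protein_id`, `label`.
#'
#' @param path delimited text file with a header row.
#' @param aptamers DNA [seq_set()] the `aptamer_id` column must reference.
#' @param proteins protein [seq_set()] the `protein_id` column must reference.
#' @return an [interaction_dataset()]; row order preserved.
#' @export
read_pair_table <- function(path, aptamers, proteins) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  pairs <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  interaction_dataset(pairs, aptamers, proteins)
}

#' Write a pair table as CSV
#'
#' @param dataset an [interaction_dataset()] or a pairs data.frame.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(dataset, path) {
  pairs <- if (inherits(dataset, "interaction_dataset")) dataset$pairs else dataset
  write.csv(pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
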