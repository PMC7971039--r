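AA_ORDER <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Load an amino-acid property table
#'
#' The file format is a CSV with a `residue` column plus one column per
#' named property (20 rows, one per standard residue), followed by a
#' blank line and a group-definition section whose rows read
#' `group,<name>,<prop1>,<prop2>,<prop3>`. Lines starting with `#` are
#' comments. The packaged default
#' (`inst/extdata/aa_properties_synthetic.csv`) carries 24 literature
#' physicochemical/conformational/energetic scales grouped A-H in the
#' conventional triples (A = hydrophobicity, hydrophilicity, mass; ...;
#' H = helix N-terminal / C-terminal / middle powers). The packaged
#' values are a synthetic stand-in assembled from widely published
#' scales -- downstream use standardizes each property, so only relative
#' orderings matter -- and any table in this format may be substituted.
#'
#' @param path CSV file; default is the packaged table.
#' @return a `property_table`: list with `values` (20 x P numeric matrix,
#'   residues ACDEFGHIKLMNPQRSTVWY as rows), `groups` (named list of
#'   3-long property-name vectors) and `standardized` flag.
#' @export
load_property_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_properties_synthetic.csv",
                        package = "aptaml", mustWork = TRUE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#")]
  is_group <- startsWith(trimws(lines), "group,")
  body <- lines[!is_group & nzchar(trimws(lines))]
  tab <- read.csv(text = paste(body, collapse = "\n"), stringsAsFactors = FALSE)
  if (!"residue" %in% names(tab)) stop("property table needs a 'residue' column")
  vals <- as.matrix(tab[setdiff(names(tab), "residue")])
  rownames(vals) <- toupper(tab$residue)
  if (!setequal(rownames(vals), AA_ORDER) || nrow(vals) != 20L) {
    stop("property table must have exactly the 20 standard residues")
  }
  vals <- vals[AA_ORDER, , drop = FALSE]
  if (any(!is.finite(vals))) stop("non-finite property value in table")
  groups <- list()
  for (g in lines[is_group]) {
    f <- strsplit(trimws(g), ",")[[1]]
    if (length(f) != 5L) stop("bad group definition line: ", g)
    miss <- setdiff(f[3:5], colnames(vals))
    if (length(miss)) stop("group ", f[2], " references unknown propert",
                           if (length(miss) > 1) "ies: " else "y: ",
                           paste(miss, collapse = ", "))
    groups[[f[2]]] <- f[3:5]
  }
  structure(list(values = vals, groups = groups, standardized = FALSE),
            class = "property_table")
}

#' @export
print.property_table <- function(x, ...) {
  cat("property_table:", ncol(x$values), "properties x 20 residues,",
      length(x$groups), "groups",
      if (x$standardized) "(standardized)" else "(raw)", "\n")
  invisible(x)
}

#' Standardize a property table
#'
#' Each property is centered and scaled to mean 0 and unit *population*
#' variance across the 20 residues (denominator 20, the convention used
#' by pseudo amino acid composition). Idempotent up to rounding;
#' invariant to affine rescaling a*x + b (a > 0) of the raw values.
#'
#' @param table a [load_property_table()] result.
#' @return the same structure with standardized `values`.
#' @export
standardize_properties <- function(table) {
  vals <- table$values
  out <- vals
  for (p in colnames(vals)) {
    v <- vals[, p]
    mu <- mean(v)
    sdev <- sqrt(sum((v - mu)^2) / 20)
    if (sdev == 0) stop("property '", p, "' is constant across residues ",
                        "(zero denominator in standardization)")
    out[, p] <- (v - mu) / sdev
  }
  structure(list(values = out, groups = table$groups, standardized = TRUE),
            class = "property_table")
}
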