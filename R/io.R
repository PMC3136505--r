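# Readers and writers for trees, property tables, group files and TSV
# reports.  Trees are ape "phylo" objects throughout; branch lengths are
# optional and ignored by the parsimony stage.

#' Read a rooted phylogeny from a Newick file
#'
#' @param path Path to a file containing one Newick string, or a Newick
#'   string itself via `text`.
#' @param text Optional Newick string (used instead of `path`).
#' @return An [ape::read.tree()] `phylo` object with unique leaf labels.
#' @export
read_tree <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) abort_config(sprintf("no such file: %s", path))
    tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) NULL)
  } else {
    tr <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                   error = function(e) NULL)
  }
  if (is.null(tr) || !inherits(tr, "phylo")) {
    abort_parse("cannot parse Newick tree (unbalanced parentheses or empty input?)")
  }
  validate_tree(tr)
  tr
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort_parse("not a phylo object")
  if (length(tree$tip.label) < 2L) abort_shape("tree must have at least 2 leaves")
  if (anyDuplicated(tree$tip.label)) {
    abort_label(sprintf("duplicate leaf labels: %s",
                        paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                              collapse = ", ")))
  }
  invisible(tree)
}

#' Write a phylogeny to a Newick file
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Amino acid property table
#'
#' A set of named physicochemical properties, each assigning a numeric value
#' to all 20 standard amino acids.
#'
#' @param values Numeric matrix with one row per property (rownames =
#'   property names) and the 20 amino acid one-letter codes as columns.
#' @param description Optional named character vector of full property names.
#' @return Object of class `property_table`.
#' @export
property_table <- function(values, description = NULL) {
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    abort_label("property names must be present and unique")
  }
  missing <- setdiff(.AA20, colnames(values))
  if (length(missing) > 0L) {
    abort_completeness(sprintf("property table lacks amino acid column(s): %s",
                               paste(missing, collapse = ", ")))
  }
  values <- values[, .AA20, drop = FALSE]
  if (!is.numeric(values) || any(!is.finite(values))) {
    abort_value("property values must all be finite numbers")
  }
  if (nrow(values) < 1L) abort_completeness("property table has no properties")
  structure(list(values = values, description = description),
            class = "property_table")
}

#' @export
print.property_table <- function(x, ...) {
  cat(sprintf("Amino acid property table: %d properties x 20 amino acids\n",
              nrow(x$values)))
  cat("  ", paste(rownames(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' Property names of a table
#' @param table A `property_table`.
#' @return Character vector.
#' @export
property_names <- function(table) rownames(table$values)

#' Values of one property over the 20 amino acids
#' @param table A `property_table`.
#' @param property Property name.
#' @return Named numeric vector over the amino acids.
#' @export
property_values <- function(table, property) {
  stopifnot(inherits(table, "property_table"))
  if (!property %in% rownames(table$values)) {
    abort_lookup(sprintf("property '%s' not in table", property))
  }
  table$values[property, ]
}

#' Read a property table from TSV
#'
#' Expected layout: header `property<TAB>A<TAB>C...` with one row per
#' property; a `description` column is optional and carried as metadata.
#'
#' @param path Path to the TSV file.
#' @return A [property_table()].
#' @export
read_property_table <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  if (!"property" %in% names(df)) {
    abort_parse("property table must have a 'property' column")
  }
  missing <- setdiff(.AA20, names(df))
  if (length(missing) > 0L) {
    abort_completeness(sprintf("property table lacks amino acid column(s): %s",
                               paste(missing, collapse = ", ")))
  }
  vals <- df[, .AA20, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (nrow(vals) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, .AA20))
  if (any(is.na(num))) abort_value("property table contains non-numeric cells")
  rownames(num) <- df$property
  descr <- if ("description" %in% names(df)) {
    stats::setNames(df$description, df$property)
  } else NULL
  property_table(num, description = descr)
}

#' Write a property table to TSV
#' @param table A `property_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_property_table <- function(table, path) {
  stopifnot(inherits(table, "property_table"))
  df <- data.frame(property = rownames(table$values), check.names = FALSE)
  if (!is.null(table$description)) {
    df$description <- unname(table$description[df$property])
  }
  df <- cbind(df, as.data.frame(table$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The bundled default property table
#'
#' Twenty physicochemical properties covering the nine headline
#' abbreviations used in cross-clade comparison tables (pK', Ra, an, Hp, H,
#' Ko, F, Ht, P) plus eleven further standard scales.  The numeric values
#' are representative values compiled from the standard literature scales;
#' the table is configuration, not code, so analyses requiring a specific
#' published instrument can substitute their own TSV via
#' [read_property_table()].
#'
#' @return A [property_table()] with 20 properties.
#' @export
default_property_table <- function() {
  path <- system.file("extdata", "aa_properties.tsv", package = "propsel",
                      mustWork = TRUE)
  read_property_table(path)
}

#' Read a taxon-to-group assignment file
#'
#' TSV with header `taxon<TAB>group`.  Groups must be non-empty and a taxon
#' may belong to at most one group.
#'
#' @param path Path to the TSV file.
#' @return Named list: group name -> character vector of taxon labels.
#' @export
read_group_file <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  if (!all(c("taxon", "group") %in% names(df))) {
    abort_parse("group file must have 'taxon' and 'group' columns")
  }
  # preserve first-appearance group order (it sets report column order)
  as_group_definition(split(df$taxon, factor(df$group, levels = unique(df$group))))
}

#' Validate a group definition
#' @param groups Named list of character vectors (group -> taxa).
#' @return The validated list, classed `group_definition`.
#' @export
as_group_definition <- function(groups) {
  if (length(groups) == 0L || is.null(names(groups)) || any(names(groups) == "")) {
    abort_label("groups must be named")
  }
  if (any(lengths(groups) == 0L)) abort_shape("groups must be non-empty")
  all_taxa <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_taxa)) {
    abort_label(sprintf("taxa assigned to more than one group: %s",
                        paste(unique(all_taxa[duplicated(all_taxa)]), collapse = ", ")))
  }
  structure(groups, class = "group_definition")
}

# Shared helper for tabular reports.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
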