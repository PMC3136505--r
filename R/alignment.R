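#' Codon alignment container
#'
#' An in-frame nucleotide alignment viewed as taxa x codon columns.  The
#' alphabet is A, C, G, T plus `N` (ambiguous) and `-` (gap); any codon
#' containing `N` or `-` is *masked* for that taxon and site, and downstream
#' stages treat masked codons as missing data.  Codon sites are reported
#' 1-based.
#'
#' @param sequences Named character vector of aligned nucleotide sequences
#'   (equal lengths, length divisible by 3, unique names).
#' @return An object of class `codon_alignment`: list with `labels`,
#'   `sequences`, `n_sites`, `codons` (character matrix taxa x sites) and
#'   `masked` (logical matrix, same shape).
#' @examples
#' aln <- as_codon_alignment(c(a = "ATGAAA", b = "ATGAAG"))
#' aln$n_sites
#' @export
as_codon_alignment <- function(sequences) {
  if (length(sequences) == 0L) abort_shape("alignment contains no sequences")
  labels <- names(sequences)
  if (is.null(labels) || any(labels == "") || anyDuplicated(labels)) {
    abort_label("taxon labels must be present and unique")
  }
  sequences <- toupper(unname(sequences))
  names(sequences) <- labels
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    abort_shape(sprintf("ragged alignment: sequence lengths %s",
                        paste(sort(unique(lens)), collapse = ", ")))
  }
  if (lens[1L] %% 3L != 0L) {
    abort_frame(sprintf("alignment length %d is not divisible by 3", lens[1L]))
  }
  chars <- strsplit(sequences, "", fixed = TRUE)
  legal <- c(.BASES, "N", "-")
  for (i in seq_along(chars)) {
    bad <- setdiff(unique(chars[[i]]), legal)
    if (length(bad) > 0L) {
      abort_alphabet(sprintf("illegal characters in sequence '%s': %s",
                             labels[i], paste(bad, collapse = " ")))
    }
  }
  n_sites <- unname(lens[1L]) %/% 3L
  codon_mat <- t(vapply(chars, function(ch) {
    apply(matrix(ch, nrow = 3L), 2L, paste0, collapse = "")
  }, character(n_sites)))
  if (n_sites == 1L) codon_mat <- matrix(codon_mat, ncol = 1L)
  dimnames(codon_mat) <- list(labels, NULL)
  masked <- matrix(grepl("[N-]", codon_mat), nrow = length(labels),
                   dimnames = dimnames(codon_mat))
  structure(list(labels = labels, sequences = sequences, n_sites = n_sites,
                 codons = codon_mat, masked = masked),
            class = "codon_alignment")
}

#' Read an in-frame codon alignment from a FASTA file
#'
#' @param path Path to a FASTA file (sequential or wrapped).
#' @return A [as_codon_alignment()] object; record order is preserved.
#' @export
read_codon_alignment <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("no such file: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort_parse(
                    sprintf("cannot parse FASTA '%s': %s", path, conditionMessage(e))))
  seqs <- as.character(set)
  # FASTA headers: take the first whitespace-delimited token as the label
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  as_codon_alignment(seqs)
}

#' Write a codon alignment to FASTA
#'
#' @param alignment A `codon_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "codon_alignment"))
  set <- Biostrings::BStringSet(alignment$sequences)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Restrict an alignment to a subset of taxa
#'
#' @param alignment A `codon_alignment`.
#' @param taxa Character vector of taxon labels to keep.
#' @return A `codon_alignment` over `taxa`, sites unchanged (so site
#'   coordinates remain comparable across subsets of one master alignment).
#' @export
subset_alignment <- function(alignment, taxa) {
  stopifnot(inherits(alignment, "codon_alignment"))
  missing <- setdiff(taxa, alignment$labels)
  if (length(missing) > 0L) {
    abort_label(sprintf("taxa absent from alignment: %s",
                        paste(missing, collapse = ", ")))
  }
  as_codon_alignment(alignment$sequences[taxa])
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("Codon alignment: %d taxa x %d codon sites (%d nt)\n",
              length(x$labels), x$n_sites, 3L * x$n_sites))
  cat(sprintf("  masked codons: %d\n", sum(x$masked)))
  invisible(x)
}
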