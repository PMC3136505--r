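#' Genetic code tables
#'
#' Returns a genetic code mapping all 64 codons to amino acids (one-letter
#' codes, `"*"` for stop).  The default for the whole package is the
#' vertebrate mitochondrial code, since the motivating analyses concern the
#' 13 mtDNA-encoded oxidative phosphorylation proteins; the standard nuclear
#' code is selectable.
#'
#' @param code `"vertebrate mitochondrial"` (default), `"standard"`, or an
#'   existing `genetic_code` object (returned unchanged).
#' @return An object of class `genetic_code`: a list with elements `map`
#'   (named character, codon -> amino acid or `"*"`), `name`, `stops`
#'   (stop codons) and `sense` (non-stop codons), all in lexicographic codon
#'   order.
#' @examples
#' gc <- genetic_code("standard")
#' gc$map[["ATG"]]
#' @export
genetic_code <- function(code = c("vertebrate mitochondrial", "standard")) {
  if (inherits(code, "genetic_code")) return(code)
  code <- match.arg(code)
  id <- if (identical(code, "standard")) "1" else "2"
  map <- Biostrings::getGeneticCode(id)
  map <- stats::setNames(as.character(map), names(map))
  as_genetic_code(map, name = code)
}

#' Build a genetic code from a codon -> amino acid map
#'
#' Mainly useful for toy codes in tests and for non-standard translation
#' tables.  The map must cover all 64 codons, use one-letter amino acid
#' codes or `"*"` for stop, and contain at least one stop codon.
#'
#' @param map Named character vector of length 64 (names are codons over
#'   ACGT, values one-letter amino acids or `"*"`).
#' @param name Label stored on the object.
#' @return A `genetic_code` object; see [genetic_code()].
#' @export
as_genetic_code <- function(map, name = "custom") {
  if (is.null(names(map)) || length(map) != 64L ||
      !setequal(names(map), .CODONS)) {
    abort_completeness("genetic code must map exactly the 64 codons over ACGT")
  }
  map <- map[.CODONS]
  bad <- !(map %in% c(.AA20, "*"))
  if (any(bad)) {
    abort_value(sprintf("genetic code contains invalid amino acid symbols: %s",
                        paste(unique(map[bad]), collapse = ", ")))
  }
  stops <- names(map)[map == "*"]
  if (length(stops) == 0L) {
    abort_value("genetic code must contain at least one stop codon")
  }
  structure(list(map = map, name = name, stops = stops,
                 sense = names(map)[map != "*"]),
            class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code:", x$name, "\n")
  cat("  sense codons:", length(x$sense),
      " stop codons:", paste(x$stops, collapse = " "), "\n")
  invisible(x)
}

#' Translate codons to amino acids
#'
#' @param x Character vector of codons (ACGT only); codons containing gaps,
#'   `N`, or other symbols translate to `NA`.
#' @param code Genetic code (see [genetic_code()]).
#' @return Character vector of one-letter amino acids, `"*"` for stop, `NA`
#'   for untranslatable codons.
#' @export
translate_codons <- function(x, code = genetic_code()) {
  code <- genetic_code(code)
  out <- unname(code$map[x])
  out
}

# Single-nucleotide neighbours of a codon, lexicographic order.
codon_neighbors <- function(codon) {
  chars <- strsplit(codon, "", fixed = TRUE)[[1L]]
  out <- character(9L)
  k <- 0L
  for (pos in 1:3) {
    for (b in .BASES[.BASES != chars[pos]]) {
      k <- k + 1L
      tmp <- chars
      tmp[pos] <- b
      out[k] <- paste0(tmp, collapse = "")
    }
  }
  sort(out)
}
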