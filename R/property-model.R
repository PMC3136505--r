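# The neutral expectation: the genetic code's single-nucleotide
# neighbourhood, equal-width magnitude binning of property changes, and the
# expected category distribution under completely random amino acid
# replacement.

#' Enumerate the single-nucleotide codon neighbourhood of a genetic code
#'
#' All ordered pairs of sense codons differing at exactly one nucleotide
#' position.  This set, weighted uniformly, is the null model of "completely
#' random amino acid replacement": every single-step mutation that does not
#' create or destroy a stop codon is considered equally likely.
#'
#' @param code Genetic code (see [genetic_code()]).
#' @param nonsynonymous_only If `TRUE` (default), keep only pairs whose
#'   source and target amino acids differ.
#' @return A data frame with columns `from_codon`, `to_codon`, `from_aa`,
#'   `to_aa`, `synonymous`, in lexicographic (source, target) order.
#' @examples
#' nrow(build_neighborhood(genetic_code("standard"), nonsynonymous_only = FALSE))
#' @export
build_neighborhood <- function(code = genetic_code(), nonsynonymous_only = TRUE) {
  code <- genetic_code(code)
  sense <- code$sense                     # already lexicographic
  from <- character(0); to <- character(0)
  for (cdn in sense) {
    nb <- codon_neighbors(cdn)
    nb <- nb[nb %in% sense]
    from <- c(from, rep(cdn, length(nb)))
    to <- c(to, nb)
  }
  out <- data.frame(from_codon = from, to_codon = to,
                    from_aa = unname(code$map[from]),
                    to_aa = unname(code$map[to]),
                    stringsAsFactors = FALSE)
  out$synonymous <- out$from_aa == out$to_aa
  if (nonsynonymous_only) out <- out[!out$synonymous, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Equal-width magnitude binning for one property
#'
#' Partitions the attainable range of absolute property change, `[0, max
#' |delta| over the nonsynonymous neighbourhood]`, into 8 contiguous
#' equal-width categories: 1 the most conservative (includes magnitude 0), 8
#' the most radical (includes the maximum).  Bin edges are half-open
#' `[lo, hi)` with the final bin closed, so a magnitude equal to an interior
#' upper edge belongs to the higher bin.
#'
#' @param property Property name.
#' @param table A [property_table()].
#' @param neighborhood Neighbourhood pairs from [build_neighborhood()]
#'   (nonsynonymous pairs are used for the range).
#' @return Object of class `magnitude_binning`: list with `property`,
#'   `breaks` (length 9), `width`, and `max`.
#' @export
make_binning <- function(property, table, neighborhood = build_neighborhood()) {
  vals <- property_values(table, property)
  pairs <- neighborhood[!neighborhood$synonymous, , drop = FALSE]
  if (nrow(pairs) == 0L) abort_degenerate("empty nonsynonymous neighbourhood")
  d <- abs(vals[pairs$to_aa] - vals[pairs$from_aa])
  mx <- max(d)
  if (mx <= 0) {
    abort_degenerate(sprintf(
      "property '%s' is constant over the neighbourhood: no magnitude range", property))
  }
  structure(list(property = property, breaks = seq(0, mx, length.out = 9L),
                 width = mx / 8, max = mx),
            class = "magnitude_binning")
}

#' @export
print.magnitude_binning <- function(x, ...) {
  cat(sprintf("Magnitude binning for '%s': 8 bins of width %.4g over [0, %.4g]\n",
              x$property, x$width, x$max))
  invisible(x)
}

#' Magnitude category of an amino acid replacement
#'
#' @param from_aa,to_aa One-letter amino acid codes (vectors recycle).
#' @param binning A [make_binning()] result.
#' @param table The [property_table()] the binning was built from.
#' @return Integer category 1-8 for each replacement.  Identical amino
#'   acids have magnitude 0 and fall in category 1; magnitudes at or above
#'   the neighbourhood maximum fall in category 8 (pairs not reachable in a
#'   single nucleotide step may exceed the neighbourhood range and are
#'   clamped there).
#' @export
categorize_change <- function(from_aa, to_aa, binning, table) {
  stopifnot(inherits(binning, "magnitude_binning"))
  vals <- property_values(table, binning$property)
  bad <- !(c(from_aa, to_aa) %in% .AA20)
  if (any(bad)) {
    abort_lookup(sprintf("nonstandard amino acid(s): %s",
                         paste(unique(c(from_aa, to_aa)[bad]), collapse = " ")))
  }
  d <- abs(vals[to_aa] - vals[from_aa])
  # floor with a relative tolerance so magnitudes equal to a bin edge (up to
  # floating error) land in the higher bin, as documented
  cat <- pmin(as.integer(floor(d / binning$width + 1e-9)) + 1L, 8L)
  unname(cat)
}

#' Expected category distribution under random amino acid replacement
#'
#' The probability of each magnitude category is the fraction of
#' nonsynonymous single-nucleotide neighbourhood pairs whose property change
#' falls in it.
#'
#' @inheritParams make_binning
#' @param binning A [make_binning()] result for the same property.
#' @return Numeric vector of 8 probabilities (named "1".."8") summing to 1.
#' @export
expected_distribution <- function(property, table,
                                  neighborhood = build_neighborhood(),
                                  binning = make_binning(property, table, neighborhood)) {
  pairs <- neighborhood[!neighborhood$synonymous, , drop = FALSE]
  if (nrow(pairs) == 0L) abort_degenerate("empty nonsynonymous neighbourhood")
  cats <- categorize_change(pairs$from_aa, pairs$to_aa, binning, table)
  p <- tabulate(cats, nbins = 8L) / length(cats)
  stats::setNames(p, as.character(1:8))
}

# Convenience: binnings and expected distributions for every property in a
# table, against one shared neighbourhood.
property_model <- function(table, code = genetic_code()) {
  code <- genetic_code(code)
  nb <- build_neighborhood(code, nonsynonymous_only = FALSE)
  props <- property_names(table)
  binnings <- lapply(props, function(p) make_binning(p, table, nb))
  names(binnings) <- props
  expected <- t(vapply(props, function(p) {
    expected_distribution(p, table, nb, binnings[[p]])
  }, numeric(8L)))
  list(code = code, neighborhood = nb, binnings = binnings, expected = expected)
}

#' Export binnings and expected distributions for audit
#'
#' @param table A [property_table()].
#' @param code Genetic code.
#' @return Data frame with one row per (property, category): bin edges and
#'   expected probability.
#' @export
expected_table <- function(table, code = genetic_code()) {
  pm <- property_model(table, code)
  props <- property_names(table)
  do.call(rbind, lapply(props, function(p) {
    b <- pm$binnings[[p]]
    data.frame(property = p, category = 1:8,
               lower = b$breaks[1:8], upper = b$breaks[2:9],
               p = unname(pm$expected[p, ]), stringsAsFactors = FALSE)
  }))
}
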