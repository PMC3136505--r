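#' Fit the property-selection model to a gene on a phylogeny
#'
#' The package's main entry point.  Runs the full chain for one in-frame
#' codon alignment and one rooted tree: parsimony ancestral reconstruction
#' on codon states, enumeration of nonsynonymous replacement events,
#' per-site magnitude-category z-scores against the random-replacement
#' expectation for every property, site-level selection calls, and the
#' whole-protein sum-of-z test.
#'
#' @param alignment A [as_codon_alignment()] object, or a named character
#'   vector of aligned sequences.
#' @param tree A rooted `phylo`, or a Newick string.
#' @param properties A [property_table()]; default the bundled 20-property
#'   table.
#' @param code Genetic code; default vertebrate mitochondrial.
#' @param window Sliding-window size (codon sites) for the per-site tests;
#'   default 1 (pure per-site).
#' @param threshold z cutoff for positive selection; default 3.09.
#' @param focus Magnitude categories treated as the destabilizing focus
#'   band; default `6:8`.
#' @param call_mode `"band"` (default): site calls from the pooled
#'   focus-band test of [band_profiles()]; `"category"`: calls from the
#'   individual per-category tests of [site_profiles()], restricted to
#'   destabilizing regime.
#' @param sum_mode Whole-protein summation mode, `"focus"` or `"all"`; see
#'   [whole_protein_summary()].
#' @return Object of class `psel`: list with components `alignment`,
#'   `tree`, `code`, `properties`, `model` (neighbourhood, binnings,
#'   expected distributions), `states`, `events`, `profiles` (per-category
#'   tests), `band` (pooled focus-band tests), `calls`, `whole`
#'   (whole-protein summary) and `params`.
#' @examples
#' aln <- as_codon_alignment(c(a = "ATGAAACTT", b = "ATGAAGCTT",
#'                             c = "ACGAAACTA", d = "ACGAAACTA"))
#' fit <- psel(aln, "((a,b),(c,d));", window = 1)
#' print(fit)
#' @export
psel <- function(alignment, tree, properties = default_property_table(),
                 code = "vertebrate mitochondrial",
                 window = 1L, threshold = 3.09, focus = 6:8,
                 call_mode = c("band", "category"),
                 sum_mode = c("focus", "all")) {
  call_mode <- match.arg(call_mode)
  sum_mode <- match.arg(sum_mode)
  if (is.character(alignment)) alignment <- as_codon_alignment(alignment)
  if (is.character(tree)) tree <- read_tree(text = tree)
  validate_tree(tree)
  if (threshold <= 0) abort_config("threshold must be > 0")
  code <- genetic_code(code)
  model <- property_model(properties, code)
  states <- fitch_reconstruct(alignment, tree, code)
  events <- enumerate_replacements(states)
  n_sites <- alignment$n_sites
  profiles <- site_profiles(events, properties, model$binnings, model$expected,
                            window = window, n_sites = n_sites)
  band <- band_profiles(events, properties, model$binnings, model$expected,
                        categories = focus, window = window, n_sites = n_sites)
  calls <- if (call_mode == "band") {
    classify(band, threshold)
  } else {
    cc <- classify(profiles, threshold)
    cc[cc$regime == "destabilizing", , drop = FALSE]
  }
  whole <- whole_protein_summary(profiles, threshold, categories = focus,
                                 mode = sum_mode)
  structure(list(alignment = alignment, tree = tree, code = code,
                 properties = properties, model = model, states = states,
                 events = events, profiles = profiles, band = band,
                 calls = calls, whole = whole,
                 params = list(window = window, threshold = threshold,
                               focus = focus, call_mode = call_mode,
                               sum_mode = sum_mode)),
            class = "psel")
}

#' @export
print.psel <- function(x, ...) {
  ev <- x$events
  nonsyn <- sum(!is.na(ev$synonymous) & !ev$synonymous)
  syn <- sum(!is.na(ev$synonymous) & ev$synonymous)
  cat("Selection on amino acid properties (psel fit)\n")
  cat(sprintf("  %d taxa, %d codon sites, genetic code: %s\n",
              length(x$alignment$labels), x$alignment$n_sites, x$code$name))
  cat(sprintf("  replacement events: %d nonsynonymous, %d synonymous\n",
              nonsyn, syn))
  cat(sprintf("  sites with positive-destabilizing calls: %d (z > %.3g, window %d, %s mode)\n",
              length(unique(x$calls$site)), x$params$threshold,
              x$params$window, x$params$call_mode))
  cat(sprintf("  whole-protein positive properties: %d of %d\n",
              sum(x$whole$positive), nrow(x$whole)))
  invisible(x)
}

#' @export
summary.psel <- function(object, ...) {
  calls_by_prop <- if (nrow(object$calls) > 0L) {
    tab <- table(object$calls$property)
    data.frame(property = names(tab), flagged_sites = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    data.frame(property = character(0), flagged_sites = integer(0))
  }
  structure(list(whole = object$whole, calls_by_property = calls_by_prop,
                 n_events = nrow(object$events),
                 params = object$params),
            class = "summary.psel")
}

#' @export
print.summary.psel <- function(x, ...) {
  cat("Whole-protein sum-of-z per property (mode:", x$params$sum_mode, ")\n")
  print(x$whole, row.names = FALSE)
  cat("\nSites flagged positive-destabilizing per property:\n")
  if (nrow(x$calls_by_property) == 0L) cat("  none\n")
  else print(x$calls_by_property, row.names = FALSE)
  invisible(x)
}

#' @describeIn psel Whole-protein sum-of-z per property, as a named vector.
#' @param object,... Method arguments.
#' @export
coef.psel <- function(object, ...) {
  stats::setNames(object$whole$z_sum, object$whole$property)
}

#' Plot the site-level destabilizing-band z profile of one property
#'
#' @param x A `psel` fit.
#' @param property Property to plot (default: first in the table).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.psel <- function(x, property = property_names(x$properties)[1L], ...) {
  sub <- x$band[x$band$property == property, , drop = FALSE]
  graphics::plot(sub$site, sub$z, type = "h",
                 xlab = "codon site", ylab = "z (destabilizing band)",
                 main = sprintf("%s: pooled categories %s", property,
                                paste(range(x$params$focus), collapse = "-")),
                 ...)
  graphics::abline(h = x$params$threshold, lty = 2, col = "red3")
  invisible(x)
}
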