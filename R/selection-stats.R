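# Per-site, per-category z-scores against the neutral expectation,
# classification into stabilizing/destabilizing positive selection, and the
# whole-protein sum-of-z test.

#' z-score of an observed category count
#'
#' Normal approximation to the binomial: `z = (observed - n p) / sqrt(n p
#' (1 - p))`, and 0 when `n = 0`.  A z above the one-tailed 0.001 cutoff
#' 3.09 flags positive selection in the conventional analysis.
#'
#' @param observed Observed event count(s) in the category.
#' @param n Total nonsynonymous event count(s).
#' @param p Expected category probability, strictly inside (0, 1).
#' @return Numeric z-score(s).
#' @examples
#' category_z(5, 10, 0.1)  # 4 / sqrt(0.9)
#' @export
category_z <- function(observed, n, p) {
  if (any(p <= 0 | p >= 1)) {
    abort_degenerate("expected probability must lie strictly inside (0, 1)")
  }
  if (any(observed < 0 | observed > n)) {
    abort_value("observed count must lie in [0, n]")
  }
  ifelse(n == 0, 0, (observed - n * p) / sqrt(n * p * (1 - p)))
}

# z with edge-case policy used internally: p = 0 gives 0 when nothing was
# observed and NA when something was (the event is impossible under the
# null; it cannot be scored).  p = 1 gives 0.
.zscore <- function(observed, n, p) {
  z <- rep(0, length(observed))
  ok <- n > 0 & p > 0 & p < 1
  z[ok] <- (observed[ok] - n[ok] * p[ok]) / sqrt(n[ok] * p[ok] * (1 - p[ok]))
  z[n > 0 & p == 0 & observed > 0] <- NA_real_
  z
}

# exact upper-tail binomial p-value, for audit columns
.binom_upper <- function(observed, n, p) {
  out <- rep(NA_real_, length(observed))
  ok <- p >= 0 & p <= 1 & n >= 0
  out[ok] <- stats::pbinom(observed[ok] - 1, n[ok], p[ok], lower.tail = FALSE)
  out
}

# Shared engine: per-site windowed category counts for one property.
# Returns list(obs = n_sites x 8 matrix, n = length-n_sites vector).
.windowed_counts <- function(site, cat, n_sites, window) {
  C <- matrix(0L, n_sites, 8L)
  if (length(site) > 0L) {
    idx <- cbind(site, cat)
    for (i in seq_len(nrow(idx))) C[idx[i, 1L], idx[i, 2L]] <- C[idx[i, 1L], idx[i, 2L]] + 1L
  }
  half <- (window - 1L) %/% 2L
  s <- seq_len(n_sites)
  lo <- pmax(1L, s - half)
  hi <- pmin(n_sites, s + half)
  cum <- rbind(0L, apply(C, 2L, cumsum))
  obs <- cum[hi + 1L, , drop = FALSE] - cum[lo, , drop = FALSE]
  storage.mode(obs) <- "integer"
  list(obs = obs, n = as.integer(rowSums(obs)))
}

# Validate/clamp a window size against the gene length.
.check_window <- function(window, n_sites) {
  window <- as.integer(window)
  if (window < 1L) abort_config("window must be >= 1")
  if (window > n_sites) {
    warning(sprintf("window %d larger than gene (%d sites); clamped", window, n_sites))
    window <- n_sites
  }
  window
}

#' Per-site category tests for every property
#'
#' For each codon site (or sliding window of `window` sites centred on it,
#' clamped at the gene ends), each property, and each magnitude category:
#' the observed nonsynonymous event count, the window's total nonsynonymous
#' event count `n`, the expected category probability `p`, the z-score, and
#' an exact binomial upper-tail p-value for audit.
#'
#' @param events Replacement events from [enumerate_replacements()]
#'   (synonymous and stop-involving events are dropped internally).
#' @param table A [property_table()].
#' @param binnings Named list of [make_binning()] results (one per property).
#' @param expecteds Matrix of expected probabilities, properties x 8.
#' @param window Window size in codon sites (odd values centre cleanly);
#'   default 1 = pure per-site.
#' @param n_sites Number of codon sites in the gene.
#' @return Data frame with columns `site`, `property`, `category`,
#'   `observed`, `n`, `p`, `z`, `p_exact`.
#' @export
site_profiles <- function(events, table, binnings, expecteds, window = 1L,
                          n_sites) {
  window <- .check_window(window, n_sites)
  ev <- events[!is.na(events$synonymous) & !events$synonymous, , drop = FALSE]
  props <- property_names(table)
  out <- vector("list", length(props))
  for (i in seq_along(props)) {
    p_name <- props[i]
    cat <- if (nrow(ev) > 0L) {
      categorize_change(ev$from_aa, ev$to_aa, binnings[[p_name]], table)
    } else integer(0)
    wc <- .windowed_counts(ev$site, cat, n_sites, window)
    pvec <- expecteds[p_name, ]
    obs <- as.vector(wc$obs)                     # column-major: category blocks
    nn <- rep(wc$n, times = 8L)
    pp <- rep(unname(pvec), each = n_sites)
    out[[i]] <- data.frame(
      site = rep(seq_len(n_sites), times = 8L),
      property = p_name,
      category = rep(1:8, each = n_sites),
      observed = obs, n = nn, p = pp,
      z = .zscore(obs, nn, pp),
      p_exact = .binom_upper(obs, nn, pp),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$property, res$site, res$category), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Pooled destabilizing-band test per site and property
#'
#' Same windowed machinery as [site_profiles()], but the focus categories
#' (by default the radical band 6-8) are pooled into a single test per
#' (site, property): observed is the event count falling anywhere in the
#' band and `p` is the band's total null mass.  Pooling is the package's
#' default basis for site-level selection calls because single rare
#' categories at small event counts make the normal approximation
#' anticonservative (see the vignette).
#'
#' @inheritParams site_profiles
#' @param categories Categories pooled into the band (default `6:8`).
#' @return Data frame with columns `site`, `property`, `observed`, `n`,
#'   `p`, `z`, `p_exact`.
#' @export
band_profiles <- function(events, table, binnings, expecteds,
                          categories = 6:8, window = 1L, n_sites) {
  window <- .check_window(window, n_sites)
  ev <- events[!is.na(events$synonymous) & !events$synonymous, , drop = FALSE]
  props <- property_names(table)
  out <- vector("list", length(props))
  for (i in seq_along(props)) {
    p_name <- props[i]
    cat <- if (nrow(ev) > 0L) {
      categorize_change(ev$from_aa, ev$to_aa, binnings[[p_name]], table)
    } else integer(0)
    wc <- .windowed_counts(ev$site, cat, n_sites, window)
    obs <- rowSums(wc$obs[, categories, drop = FALSE])
    p_band <- sum(expecteds[p_name, categories])
    out[[i]] <- data.frame(
      site = seq_len(n_sites), property = p_name,
      observed = obs, n = wc$n, p = p_band,
      z = .zscore(obs, wc$n, rep(p_band, n_sites)),
      p_exact = .binom_upper(obs, wc$n, rep(p_band, n_sites)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify category tests into selection calls
#'
#' Emits one call per test exceeding the z threshold.  The regime follows
#' the magnitude band: categories 1-3 are stabilizing (excess conservative
#' change), 6-8 destabilizing (excess radical change, the signature of
#' molecular adaptation), 4-5 neither.
#'
#' @param tests Data frame from [site_profiles()] (needs `site`,
#'   `property`, `category`, `z`) or from [band_profiles()] (no `category`
#'   column; calls are destabilizing by construction).
#' @param threshold z cutoff; default 3.09 (one-tailed p of about 0.001).
#' @return Data frame of calls: `site`, `property`, `category` (`NA` for
#'   pooled band calls), `z`, `direction` (always "positive"), `regime`.
#' @export
classify <- function(tests, threshold = 3.09) {
  pos <- !is.na(tests$z) & tests$z > threshold
  hit <- tests[pos, , drop = FALSE]
  if (!"category" %in% names(hit)) {
    out <- data.frame(site = hit$site, property = hit$property,
                      category = rep(NA_integer_, nrow(hit)), z = hit$z,
                      direction = rep("positive", nrow(hit)),
                      regime = rep("destabilizing", nrow(hit)),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }
  regime <- ifelse(hit$category <= 3L, "stabilizing",
                   ifelse(hit$category >= 6L, "destabilizing", "none"))
  out <- data.frame(site = hit$site, property = hit$property,
                    category = hit$category, z = hit$z,
                    direction = rep("positive", nrow(hit)),
                    regime = regime, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Whole-protein sum-of-z test
#'
#' Sums the per-site z-scores of one property over the whole protein,
#' positive and negative values alike, and compares the sum with the same
#' threshold used per site.  An empty site list gives sum 0, not positive.
#'
#' @param z_by_site Numeric vector of per-site z-scores for one property.
#' @param threshold z cutoff (default 3.09).
#' @return Object of class `whole_protein_result`: list with `sum`,
#'   `threshold`, `positive`.
#' @examples
#' whole_protein(c(2, -2, -6, 4))  # sum -2: not positive
#' @export
whole_protein <- function(z_by_site, threshold = 3.09) {
  s <- if (length(z_by_site) == 0L) 0 else sum(z_by_site)
  structure(list(sum = s, threshold = threshold, positive = s > threshold),
            class = "whole_protein_result")
}

#' @export
print.whole_protein_result <- function(x, ...) {
  cat(sprintf("Whole-protein sum of z: %.4g (threshold %.3g) -> %s\n",
              x$sum, x$threshold,
              if (x$positive) "positive selection" else "not positive"))
  invisible(x)
}

#' Whole-protein summary for every property
#'
#' Applies [whole_protein()] per property to the per-site z-scores from a
#' [site_profiles()] table.  By default only the destabilizing categories
#' (6-8) contribute each site's z (summed within site first); `mode =
#' "all"` sums every category's z instead.  Both modes are labelled in the
#' output.
#'
#' @param profiles Data frame from [site_profiles()].
#' @param threshold z cutoff (default 3.09).
#' @param categories Focus categories for `mode = "focus"` (default `6:8`).
#' @param mode `"focus"` (default) or `"all"`.
#' @return Data frame: `property`, `mode`, `z_sum`, `threshold`, `positive`.
#' @export
whole_protein_summary <- function(profiles, threshold = 3.09,
                                  categories = 6:8,
                                  mode = c("focus", "all")) {
  mode <- match.arg(mode)
  keep <- if (mode == "focus") profiles$category %in% categories else
    rep(TRUE, nrow(profiles))
  sub <- profiles[keep & !is.na(profiles$z), , drop = FALSE]
  sums <- tapply(sub$z, sub$property, sum)
  props <- sort(unique(profiles$property))
  z_sum <- ifelse(props %in% names(sums), sums[props], 0)
  data.frame(property = props, mode = mode, z_sum = unname(z_sum),
             threshold = threshold, positive = unname(z_sum) > threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}
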