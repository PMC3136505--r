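# Cross-clade shared-site comparison: which codon sites carry
# positive-destabilizing calls in more than one clade group.  Site identity
# across groups is positional within the shared master alignment of each
# gene, so sites are keyed as (gene, codon site) pairs.

#' Collect a group's destabilizing call set for one gene
#'
#' @param calls Call data frame from [classify()] (or the `calls` component
#'   of a [psel()] fit) for one group's analysis of one gene.
#' @param gene Gene name (keys the site coordinate frame).
#' @param group Group name.
#' @return Object of class `group_call_set`: list with `group`, `genes`,
#'   and `sites` (named list property -> character vector of unique
#'   `"gene:site"` keys).  Only destabilizing-regime calls enter; a site
#'   flagged in several focus categories appears once.
#' @export
collect_calls <- function(calls, gene, group) {
  keep <- calls$regime == "destabilizing"
  hit <- calls[keep, , drop = FALSE]
  sites <- lapply(split(hit$site, hit$property),
                  function(s) unique(paste0(gene, ":", s)))
  structure(list(group = group, genes = gene, sites = sites),
            class = "group_call_set")
}

#' Merge call sets of one group across genes
#'
#' @param ... `group_call_set` objects for the same group.
#' @return A single merged `group_call_set`.
#' @export
merge_call_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) &&
      !inherits(sets[[1L]], "group_call_set")) {
    sets <- sets[[1L]]
  }
  stopifnot(all(vapply(sets, inherits, TRUE, "group_call_set")))
  groups <- unique(vapply(sets, `[[`, "", "group"))
  if (length(groups) != 1L) abort_config("cannot merge call sets from different groups")
  props <- unique(unlist(lapply(sets, function(s) names(s$sites))))
  merged <- lapply(props, function(p) {
    unique(unlist(lapply(sets, function(s) s$sites[[p]])))
  })
  names(merged) <- props
  structure(list(group = groups,
                 genes = unique(unlist(lapply(sets, `[[`, "genes"))),
                 sites = merged),
            class = "group_call_set")
}

#' @export
print.group_call_set <- function(x, ...) {
  cat(sprintf("Call set for group '%s': %d gene(s), %d properties, %d distinct sites\n",
              x$group, length(x$genes), length(x$sites),
              length(unique(unlist(x$sites)))))
  invisible(x)
}

#' Shared-site comparison between clade groups
#'
#' For each property and each requested group tuple, counts the codon sites
#' flagged positive-destabilizing in *every* group of the tuple.  Also
#' reports, per tuple, a deduplicated total: the number of distinct sites
#' shared under at least one property, each site counted once however many
#' properties flag it.  Per-property cells must therefore not be summed --
#' the deduplicated total is the honest aggregate, and the object checks
#' that invariant.
#'
#' @param sets Named list of `group_call_set` objects (names = group names).
#' @param groupings List of character vectors of group names, e.g.
#'   `list(c("A","L"), c("A","C"), c("L","C"), c("A","L","C"))`.
#' @return Object of class `group_comparison`: list with `counts` (matrix
#'   properties x groupings), `totals` (deduplicated distinct-site count
#'   per grouping) and `groupings`.
#' @export
intersect_groups <- function(sets, groupings) {
  if (length(sets) < 2L) abort_config("need at least 2 groups to compare")
  if (is.null(names(sets))) names(sets) <- vapply(sets, `[[`, "", "group")
  for (g in groupings) {
    unknown <- setdiff(g, names(sets))
    if (length(unknown) > 0L) {
      abort_config(sprintf("unknown group(s) in grouping: %s",
                           paste(unknown, collapse = ", ")))
    }
  }
  labels <- vapply(groupings, paste, "", collapse = "-")
  props <- sort(unique(unlist(lapply(sets, function(s) names(s$sites)))))
  counts <- matrix(0L, length(props), length(groupings),
                   dimnames = list(props, labels))
  totals <- stats::setNames(integer(length(groupings)), labels)
  for (j in seq_along(groupings)) {
    gg <- groupings[[j]]
    union_shared <- character(0)
    for (p in props) {
      shared <- Reduce(intersect,
                       lapply(gg, function(g) sets[[g]]$sites[[p]] %||% character(0)))
      counts[p, j] <- length(shared)
      union_shared <- union(union_shared, shared)
    }
    totals[j] <- length(union_shared)
  }
  # the no-totaling caveat as a checked invariant
  stopifnot(all(totals <= colSums(counts)))
  structure(list(counts = counts, totals = totals, groupings = groupings),
            class = "group_comparison")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.group_comparison <- function(x, ...) {
  cat("Shared positive-destabilizing sites between groups\n")
  print(x$counts)
  cat("\nDistinct shared sites per grouping (each site counted once):\n")
  print(x$totals)
  cat("Note: per-property cells overlap and must not be totaled;\n")
  cat("use the deduplicated counts above for aggregates.\n")
  invisible(x)
}

#' Write a group comparison to TSV
#'
#' One row per property (plus a `distinct_total` row), one column per
#' grouping.
#'
#' @param comparison A [intersect_groups()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  df <- data.frame(property = rownames(comparison$counts),
                   comparison$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  tot <- data.frame(property = "distinct_total",
                    t(comparison$totals), check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(rbind(df, tot), path)
}
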