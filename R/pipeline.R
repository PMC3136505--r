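# End-to-end orchestration: per-group analysis of many genes, then the
# cross-clade shared-site comparison.  Genes are analyzed independently in
# sorted order; every run writes its intermediates and a manifest so
# results can be audited and reruns are byte-identical.

#' Build and validate a run configuration
#'
#' @param genes Named list, one entry per gene: `list(alignment = <fasta
#'   path>, trees = list(<group> = <newick path>, ...))`.  All groups are
#'   analyzed against the same master alignment per gene, which is what
#'   makes site coordinates comparable across groups.
#' @param groups Path to a `taxon<TAB>group` TSV, or a named list of taxa
#'   per group (see [as_group_definition()]).
#' @param property_table Path to a property TSV, or a [property_table()];
#'   `NULL` for the bundled default.
#' @param code Genetic code name.
#' @param threshold z cutoff (> 0), default 3.09.
#' @param window Sliding-window size, default 1.
#' @param focus Destabilizing focus categories, default `6:8`.
#' @param call_mode `"band"` or `"category"`; see [psel()].
#' @param groupings List of group tuples for the comparison; default all
#'   pairs plus the full tuple, in the order given by `groups`.
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in manifests (the analysis itself is
#'   deterministic).
#' @return Object of class `run_config`.
#' @export
run_config <- function(genes, groups, property_table = NULL,
                       code = "vertebrate mitochondrial", threshold = 3.09,
                       window = 1L, focus = 6:8,
                       call_mode = c("band", "category"),
                       groupings = NULL, out_dir = tempfile("propsel_run_"),
                       seed = 1L) {
  call_mode <- match.arg(call_mode)
  if (length(genes) == 0L || is.null(names(genes))) {
    abort_config("genes must be a non-empty named list")
  }
  for (g in names(genes)) {
    entry <- genes[[g]]
    if (!all(c("alignment", "trees") %in% names(entry))) {
      abort_config(sprintf("gene '%s' needs 'alignment' and 'trees'", g))
    }
    if (!file.exists(entry$alignment)) {
      abort_config(sprintf("gene '%s': missing alignment file %s", g, entry$alignment))
    }
    for (grp in names(entry$trees)) {
      if (!file.exists(entry$trees[[grp]])) {
        abort_config(sprintf("gene '%s', group '%s': missing tree file %s",
                             g, grp, entry$trees[[grp]]))
      }
    }
  }
  groups <- if (is.character(groups)) read_group_file(groups) else
    as_group_definition(groups)
  table <- if (is.null(property_table)) default_property_table()
  else if (is.character(property_table)) read_property_table(property_table)
  else property_table
  if (threshold <= 0) abort_config("threshold must be > 0")
  if (window < 1L) abort_config("window must be >= 1")
  if (is.null(groupings)) {
    gn <- names(groups)
    groupings <- c(utils::combn(gn, 2L, simplify = FALSE),
                   if (length(gn) > 2L) list(gn))
  }
  structure(list(genes = genes[sort(names(genes))], groups = groups,
                 table = table, code = code, threshold = threshold,
                 window = as.integer(window), focus = focus,
                 call_mode = call_mode, groupings = groupings,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Analyze all genes for one clade group
#'
#' Runs the full chain (read alignment and tree, subset to the group's
#' taxa, [psel()]) for each configured gene in sorted order, writing the
#' event table, z table, calls and whole-protein summary per gene plus a
#' manifest.  A failing gene is logged and skipped; the run continues.
#'
#' @param config A [run_config()].
#' @param group Group name (must exist in the config's group definition).
#' @return Object of class `group_analysis`: list with `group`, `fits`
#'   (named list of [psel()] objects), `call_sets` (per-gene
#'   [collect_calls()] sets), `failed` (named character vector of error
#'   messages), `manifest` (path).
#' @export
run_group_analysis <- function(config, group) {
  stopifnot(inherits(config, "run_config"))
  if (!group %in% names(config$groups)) {
    abort_config(sprintf("unknown group '%s'", group))
  }
  taxa <- config$groups[[group]]
  out_dir <- file.path(config$out_dir, group)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fits <- list(); call_sets <- list(); failed <- character(0)
  manifest <- c(sprintf("package\tpropsel %s",
                        as.character(utils::packageVersion("propsel"))),
                sprintf("group\t%s", group),
                sprintf("taxa\t%s", paste(taxa, collapse = ",")),
                sprintf("code\t%s", config$code),
                sprintf("threshold\t%g", config$threshold),
                sprintf("window\t%d", config$window),
                sprintf("focus\t%s", paste(config$focus, collapse = ",")),
                sprintf("call_mode\t%s", config$call_mode),
                sprintf("seed\t%d", config$seed))
  for (gene in names(config$genes)) {
    entry <- config$genes[[gene]]
    tree_path <- entry$trees[[group]]
    if (is.null(tree_path)) {
      failed[gene] <- "no tree configured for this group"
      manifest <- c(manifest, sprintf("gene\t%s\tFAILED\t%s", gene, failed[gene]))
      next
    }
    res <- tryCatch({
      aln <- read_codon_alignment(entry$alignment)
      tr <- read_tree(tree_path)
      sub <- subset_alignment(aln, intersect(aln$labels, tr$tip.label))
      fit <- psel(sub, tr, properties = config$table, code = config$code,
                  window = config$window, threshold = config$threshold,
                  focus = config$focus, call_mode = config$call_mode)
      write_events(fit$events, file.path(out_dir, paste0(gene, ".events.tsv")))
      write_tsv(fit$profiles, file.path(out_dir, paste0(gene, ".ztable.tsv")))
      write_tsv(fit$calls, file.path(out_dir, paste0(gene, ".calls.tsv")))
      write_tsv(fit$whole, file.path(out_dir, paste0(gene, ".whole.tsv")))
      fit
    }, propsel_error = function(e) e)
    if (inherits(res, "propsel_error")) {
      failed[gene] <- conditionMessage(res)
      manifest <- c(manifest, sprintf("gene\t%s\tFAILED\t%s", gene, failed[gene]))
    } else {
      fits[[gene]] <- res
      call_sets[[gene]] <- collect_calls(res$calls, gene, group)
      manifest <- c(manifest,
                    sprintf("gene\t%s\tOK\tsites=%d\tevents=%d\tcalls=%d",
                            gene, res$alignment$n_sites, nrow(res$events),
                            nrow(res$calls)))
    }
  }
  manifest_path <- file.path(out_dir, "MANIFEST.txt")
  writeLines(manifest, manifest_path)
  structure(list(group = group, fits = fits, call_sets = call_sets,
                 failed = failed, manifest = manifest_path),
            class = "group_analysis")
}

#' @export
print.group_analysis <- function(x, ...) {
  cat(sprintf("Group analysis '%s': %d genes analyzed, %d failed\n",
              x$group, length(x$fits), length(x$failed)))
  invisible(x)
}

#' Cross-clade comparison over completed group analyses
#'
#' Merges each group's per-gene call sets and intersects them per property
#' and grouping.  All analyses must share the master-alignment site frame:
#' a gene analyzed with differing site counts across groups raises a
#' site-frame error naming the gene.
#'
#' @param config A [run_config()].
#' @param analyses List of [run_group_analysis()] results (two or more).
#' @return A [intersect_groups()] `group_comparison`; also written to
#'   `comparison.tsv` in the run's output directory.
#' @export
run_comparison <- function(config, analyses) {
  stopifnot(inherits(config, "run_config"))
  if (length(analyses) < 2L) abort_config("need at least 2 group analyses")
  # site-frame check: every group must have seen each gene at the same length
  genes <- unique(unlist(lapply(analyses, function(a) names(a$fits))))
  for (g in genes) {
    lens <- unlist(lapply(analyses, function(a) {
      if (g %in% names(a$fits)) a$fits[[g]]$alignment$n_sites else NULL
    }))
    if (length(unique(lens)) > 1L) {
      abort_site_frame(sprintf("gene '%s' analyzed on differing site frames (%s)",
                               g, paste(lens, collapse = " vs ")))
    }
  }
  sets <- lapply(analyses, function(a) {
    if (length(a$call_sets) == 0L) {
      structure(list(group = a$group, genes = character(0),
                     sites = stats::setNames(list(), character(0))),
                class = "group_call_set")
    } else merge_call_sets(a$call_sets)
  })
  names(sets) <- vapply(analyses, `[[`, "", "group")
  cmp <- intersect_groups(sets, config$groupings)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_comparison(cmp, file.path(config$out_dir, "comparison.tsv"))
  message("note: per-property cells overlap; do not total them -- ",
          "use the deduplicated distinct-site counts")
  cmp
}
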