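# Parsimony ancestral reconstruction on codon states and enumeration of
# replacement events.  Reconstruction is on codons, not amino acids, so
# synonymous changes remain identifiable for exclusion downstream.
#
# The algorithm is Fitch parsimony generalized to arbitrary node degree
# (Hartigan's formulation): bottom-up, each node keeps the set of states
# with the maximum vote count among its children (and the cost grows by
# children-minus-max); top-down, a node takes its parent's state when that
# state is in its set, otherwise the lexicographically smallest member --
# the documented deterministic tie-break.  Masked (gap/N) leaf codons enter
# as wildcards (the full set of states observed at the site) and therefore
# never force a change.

# children[[node]] for an ape phylo; nodes are ape-indexed (tips 1..n).
tree_children <- function(tree) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    ch[[p]] <- c(ch[[p]], tree$edge[i, 2L])
  }
  ch
}

# internal nodes in postorder (children before parents)
postorder_nodes <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  unique(po$edge[, 1L])
}

#' Parsimony ancestral codon states
#'
#' Assigns a codon to every internal node at every codon site so that the
#' number of state changes on the tree is the parsimony minimum, with the
#' deterministic tie-breaks described in the package vignette.  Sites where
#' fewer than two taxa carry an unmasked codon are skipped.
#'
#' @param alignment A [as_codon_alignment()] object.
#' @param tree A rooted `phylo` whose tip labels all occur in the alignment.
#' @param code Genetic code (used downstream; stored on the result).
#' @return Object of class `ancestral_states`: list with `states` (character
#'   matrix, nodes x sites, `NA` where skipped), `changes` (integer
#'   parsimony minimum per site, `NA` where skipped), `skipped` (site
#'   indices), `tree`, `alignment`, `code`.
#' @examples
#' aln <- as_codon_alignment(c(a = "ATG", b = "ATG", c = "ACG", d = "ACG"))
#' tr <- read_tree(text = "((a,b),(c,d));")
#' fitch_reconstruct(aln, tr)$changes
#' @export
fitch_reconstruct <- function(alignment, tree, code = genetic_code()) {
  stopifnot(inherits(alignment, "codon_alignment"))
  validate_tree(tree)
  code <- genetic_code(code)
  missing <- setdiff(tree$tip.label, alignment$labels)
  if (length(missing) > 0L) {
    abort_label(sprintf("tree tips absent from alignment: %s",
                        paste(missing, collapse = ", ")))
  }
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  root <- n_tip + 1L
  children <- tree_children(tree)
  post <- postorder_nodes(tree)         # internal nodes, children-first
  pre <- rev(post)                      # parents before children
  tip_codons <- alignment$codons[tree$tip.label, , drop = FALSE]
  tip_masked <- alignment$masked[tree$tip.label, , drop = FALSE]

  states <- matrix(NA_character_, n_nodes, alignment$n_sites)
  changes <- rep(NA_integer_, alignment$n_sites)
  skipped <- integer(0)

  for (s in seq_len(alignment$n_sites)) {
    obs <- tip_codons[, s]
    msk <- tip_masked[, s]
    if (sum(!msk) < 2L) {
      skipped <- c(skipped, s)
      next
    }
    universe <- sort(unique(obs[!msk]))   # lex order; index order = lex order
    k <- length(universe)
    # leaf state sets as logical membership vectors over the universe
    sets <- matrix(FALSE, n_nodes, k)
    for (tip in seq_len(n_tip)) {
      if (msk[tip]) sets[tip, ] <- TRUE          # wildcard
      else sets[tip, match(obs[tip], universe)] <- TRUE
    }
    cost <- 0L
    for (v in post) {
      kids <- children[[v]]
      votes <- colSums(sets[kids, , drop = FALSE])
      m <- max(votes)
      sets[v, ] <- votes == m
      cost <- cost + length(kids) - as.integer(m)
    }
    # top-down assignment
    assign <- integer(n_nodes)
    root_set <- which(sets[root, ])
    assign[root] <- root_set[1L]
    for (v in pre) {
      for (ch in children[[v]]) {
        if (sets[ch, assign[v]]) assign[ch] <- assign[v]
        else assign[ch] <- which(sets[ch, ])[1L]
      }
    }
    realized <- sum(assign[tree$edge[, 1L]] != assign[tree$edge[, 2L]])
    stopifnot(realized == cost)   # Hartigan top-down must achieve the minimum
    states[, s] <- universe[assign]
    changes[s] <- cost
  }
  structure(list(states = states, changes = changes, skipped = skipped,
                 tree = tree, alignment = alignment, code = code),
            class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, ...) {
  scored <- sum(!is.na(x$changes))
  cat(sprintf("Ancestral codon states: %d sites scored (%d skipped), %d changes total\n",
              scored, length(x$skipped), sum(x$changes, na.rm = TRUE)))
  invisible(x)
}

# edges ordered parents-before-children (preorder), each row (parent, child)
preorder_edges <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
}

#' Enumerate replacement events from an ancestral reconstruction
#'
#' One event per (branch, site) where the parent and child codon
#' assignments differ.  A multi-nucleotide codon difference on one branch
#' counts as a single source-to-target replacement.  Branches leading to a
#' leaf whose codon is masked at a site never yield events at that site
#' (the wildcard assignment follows the parent).
#'
#' @param states An [fitch_reconstruct()] result.
#' @return Data frame of events ordered by site then preorder branch:
#'   `site` (1-based codon site), `parent`, `child` (ape node numbers),
#'   `child_label`, `from_codon`, `to_codon`, `from_aa`, `to_aa`,
#'   `synonymous`.  Stop-translating assignments (possible under unusual
#'   codes) are marked synonymous = NA and excluded from property
#'   statistics downstream.
#' @export
enumerate_replacements <- function(states) {
  stopifnot(inherits(states, "ancestral_states"))
  tree <- states$tree
  code <- states$code
  edges <- preorder_edges(tree)
  n_tip <- length(tree$tip.label)
  rows <- vector("list", 0L)
  sites <- which(!is.na(states$changes))
  for (s in sites) {
    st <- states$states[, s]
    p <- st[edges[, 1L]]
    c2 <- st[edges[, 2L]]
    hit <- which(p != c2)
    if (length(hit) == 0L) next
    child <- edges[hit, 2L]
    lab <- ifelse(child <= n_tip, tree$tip.label[child],
                  paste0("node", child))
    from_aa <- translate_codons(p[hit], code)
    to_aa <- translate_codons(c2[hit], code)
    syn <- ifelse(from_aa == "*" | to_aa == "*", NA, from_aa == to_aa)
    rows[[length(rows) + 1L]] <- data.frame(
      site = s, parent = edges[hit, 1L], child = child, child_label = lab,
      from_codon = p[hit], to_codon = c2[hit],
      from_aa = from_aa, to_aa = to_aa, synonymous = syn,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(site = integer(0), parent = integer(0), child = integer(0),
                      child_label = character(0), from_codon = character(0),
                      to_codon = character(0), from_aa = character(0),
                      to_aa = character(0), synonymous = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a replacement event table to TSV
#' @param events Data frame from [enumerate_replacements()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) write_tsv(events, path)
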