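# Shared fixtures and independent oracles, built in code.

# balanced clade Newick for deterministic topologies
clade_newick <- function(labels) {
  if (length(labels) == 1L) return(labels)
  k <- ceiling(length(labels) / 2)
  sprintf("(%s,%s)", clade_newick(labels[1:k]), clade_newick(labels[-(1:k)]))
}

make_tree <- function(groups, bl = 0.1) {
  nwk <- paste0("(",
                paste(vapply(groups, clade_newick, ""), collapse = ","), ");")
  t <- ape::read.tree(text = nwk)
  t$edge.length <- rep(bl, nrow(t$edge))
  t
}

# write a FASTA fixture
write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

# A toy genetic code whose amino acid is set by the first codon position
# (A->K, C->R, G->D, T->E), with the usual TAA/TAG/TGA stops.  Changes at
# positions 2-3 are synonymous; changes at position 1 are nonsynonymous.
toy_first_base_code <- function() {
  map <- vapply(codons(), function(cdn) {
    switch(substr(cdn, 1, 1), A = "K", C = "R", G = "D", T = "E")
  }, "")
  map[c("TAA", "TAG", "TGA")] <- "*"
  as_genetic_code(map, name = "toy first-base")
}

# Exhaustive minimum-change oracle: tries every assignment of observed
# states to internal nodes.  Only feasible for small trees.
exhaustive_min_changes <- function(tree, tip_states) {
  states <- sort(unique(tip_states))
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  edge <- tree$edge
  tip_idx <- match(tip_states[tree$tip.label], states)
  grid <- as.matrix(expand.grid(rep(list(seq_along(states)), n_int)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    assign <- c(tip_idx, grid[r, ])
    ch <- sum(assign[edge[, 1L]] != assign[edge[, 2L]])
    if (ch < best) best <- ch
  }
  best
}

# independent brute-force single-nucleotide neighbourhood census
oracle_neighborhood_count <- function(map, nonsynonymous_only = FALSE) {
  bases <- c("A", "C", "G", "T")
  sense <- names(map)[map != "*"]
  count <- 0L
  for (cdn in sense) {
    for (pos in 1:3) {
      for (b in bases) {
        if (b == substr(cdn, pos, pos)) next
        tgt <- cdn
        substr(tgt, pos, pos) <- b
        if (!tgt %in% sense) next
        if (nonsynonymous_only && map[[cdn]] == map[[tgt]]) next
        count <- count + 1L
      }
    }
  }
  count
}

default_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- propsel:::property_model(default_property_table())
    }
    cache
  }
})
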