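# Codon evolution simulator with known ground truth.  The neutral law is
# constructed to match the analysis null exactly: every ordered pair of
# sense codons one nucleotide apart carries the same substitution rate, so
# the stationary state distribution is uniform over sense codons and the
# realized (source, target) pairs are uniform over the neighbourhood --
# the keystone consistency property tying the simulator to
# expected_distribution().  Destabilizing bias multiplies the rate of
# moves whose property change falls in the radical band (categories 6-8)
# by beta at chosen (clade, site) pairs.

#' Specify a codon evolution simulation
#'
#' @param tree Rooted `phylo` with branch lengths in expected substitutions
#'   per codon site (at the neutral baseline rate).
#' @param n_sites Number of codon sites to simulate.
#' @param rate Per-site rate multiplier: scalar or vector of length
#'   `n_sites`; default 1.
#' @param bias `NULL` for neutral evolution, or a bias specification: a
#'   list with elements `clade` (character vector of tip labels; bias acts
#'   on every branch whose descendant tips all lie in the clade), `sites`
#'   (integer vector of target codon sites), `property` (property name) and
#'   `beta` (>= 1; 1 means neutral).  A list of several such specifications
#'   is accepted.
#' @param code Genetic code; default vertebrate mitochondrial.
#' @param root_seq Optional character vector of `n_sites` sense codons for
#'   the root; drawn uniformly over sense codons when `NULL`.
#' @param seed Master integer seed.  Per-branch substreams are derived from
#'   it and from the branch's descendant-leaf set, so enlarging the tree
#'   leaves unrelated branches unperturbed.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(tree, n_sites, rate = 1, bias = NULL,
                            code = "vertebrate mitochondrial",
                            root_seq = NULL, seed = 1L) {
  validate_tree(tree)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    abort_config("tree must carry non-negative branch lengths")
  }
  n_sites <- as.integer(n_sites)
  if (n_sites < 1L) abort_config("n_sites must be >= 1")
  if (!length(rate) %in% c(1L, n_sites) || any(rate <= 0)) {
    abort_config("rate must be a positive scalar or one value per site")
  }
  if (!is.null(bias)) {
    if (!is.null(names(bias)) && "clade" %in% names(bias)) bias <- list(bias)
    for (b in bias) {
      if (!all(c("clade", "sites", "property", "beta") %in% names(b))) {
        abort_config("each bias needs clade, sites, property and beta")
      }
      if (length(setdiff(b$clade, tree$tip.label)) > 0L) {
        abort_config("bias clade contains taxa not in the tree")
      }
      if (any(b$sites < 1L | b$sites > n_sites)) {
        abort_config("bias sites outside the sequence")
      }
      if (b$beta < 1) abort_config("bias strength beta must be >= 1")
    }
  }
  structure(list(tree = tree, n_sites = n_sites, rate = rate, bias = bias,
                 code = genetic_code(code), root_seq = root_seq,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# deterministic small-integer hash of (seed, string key), below 2^31
seed_mix <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.numeric(seed) * 7919 + 1) %% 2147483647)
}

# descendant tip labels per node
descendant_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  out <- vector("list", n_nodes)
  for (i in seq_len(n_tip)) out[[i]] <- tree$tip.label[i]
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  lapply(out, sort)
}

#' Simulate codon evolution along a tree
#'
#' Gillespie simulation: each sense-to-sense single-nucleotide move carries
#' a constant baseline rate (stop-creating changes never occur), scaled so
#' one unit of branch length yields one expected substitution per codon
#' site at stationarity; biased moves are accelerated by `beta`.  The same
#' seed always reproduces the identical alignment and event log.
#'
#' @param spec A [simulation_spec()].
#' @param properties Property table used to resolve bias categories.
#' @return A list of class `codon_simulation` with `alignment`
#'   ([as_codon_alignment()]), `tree`, and `truth` (class
#'   `simulation_truth`: `selected` data frame of planted (clade, site,
#'   property, beta) rows, `events` data frame of every realized
#'   substitution, `root` codons, and the `spec`).
#' @export
simulate_codon_evolution <- function(spec, properties = default_property_table()) {
  stopifnot(inherits(spec, "simulation_spec"))
  tree <- spec$tree
  code <- spec$code
  sense <- code$sense
  S <- length(sense)
  nb <- lapply(sense, function(cdn) {
    match(intersect(codon_neighbors(cdn), sense), sense)
  })
  deg <- lengths(nb)
  r0 <- 1 / mean(deg)
  wbase <- lapply(deg, function(d) rep(r0, d))
  rate <- if (length(spec$rate) == 1L) rep(spec$rate, spec$n_sites) else spec$rate

  # per-bias precomputation: radical-move masks and biased edge sets
  n_tip <- length(tree$tip.label)
  edges <- preorder_edges(tree)
  edge_len <- tree$edge.length[match(paste(edges[, 1L], edges[, 2L]),
                                     paste(tree$edge[, 1L], tree$edge[, 2L]))]
  desc <- descendant_tips(tree)
  biases <- spec$bias
  if (!is.null(biases)) {
    nbhood <- build_neighborhood(code, nonsynonymous_only = FALSE)
    for (i in seq_along(biases)) {
      b <- biases[[i]]
      binning <- make_binning(b$property, properties, nbhood)
      aa <- unname(code$map[sense])
      rad <- vector("list", S)
      for (ci in seq_len(S)) {
        tgt <- nb[[ci]]
        nonsyn <- aa[tgt] != aa[ci]
        cats <- rep(1L, length(tgt))
        if (any(nonsyn)) {
          cats[nonsyn] <- categorize_change(rep(aa[ci], sum(nonsyn)),
                                            aa[tgt][nonsyn], binning, properties)
        }
        rad[[ci]] <- nonsyn & cats >= 6L & cats <= 8L
      }
      biases[[i]]$rad <- rad
      biases[[i]]$edge_biased <- vapply(seq_len(nrow(edges)), function(e) {
        all(desc[[edges[e, 2L]]] %in% b$clade)
      }, TRUE)
      biases[[i]]$site_mask <- seq_len(spec$n_sites) %in% b$sites
    }
  }

  # root sequence
  if (is.null(spec$root_seq)) {
    set.seed(seed_mix(spec$seed, "root"))
    root_state <- sample.int(S, spec$n_sites, replace = TRUE)
  } else {
    root_state <- match(toupper(spec$root_seq), sense)
    if (length(root_state) != spec$n_sites || any(is.na(root_state))) {
      abort_config("root_seq must be n_sites sense codons")
    }
  }

  n_nodes <- n_tip + tree$Nnode
  node_state <- matrix(NA_integer_, n_nodes, spec$n_sites)
  node_state[n_tip + 1L, ] <- root_state
  ev_child <- integer(0); ev_parent <- integer(0); ev_site <- integer(0)
  ev_time <- numeric(0); ev_from <- integer(0); ev_to <- integer(0)

  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1L]; child <- edges[e, 2L]
    len <- edge_len[e]
    key <- if (child <= n_tip) tree$tip.label[child] else
      paste(desc[[child]], collapse = ",")
    set.seed(seed_mix(spec$seed, key))
    seq_st <- node_state[parent, ]
    if (len > 0) {
      active <- if (is.null(biases)) NULL else
        Filter(function(b) b$edge_biased[e], biases)
      for (s in seq_len(spec$n_sites)) {
        st <- seq_st[s]
        t <- 0
        repeat {
          w <- wbase[[st]]
          if (!is.null(active) && length(active) > 0L) {
            for (b in active) {
              if (b$site_mask[s]) w[b$rad[[st]]] <- w[b$rad[[st]]] * b$beta
            }
          }
          R <- sum(w) * rate[s]
          t <- t + stats::rexp(1L, R)
          if (t > len) break
          j <- if (length(w) == 1L) 1L else
            sample.int(length(w), 1L, prob = w)
          new_st <- nb[[st]][j]
          ev_parent <- c(ev_parent, parent); ev_child <- c(ev_child, child)
          ev_site <- c(ev_site, s); ev_time <- c(ev_time, t)
          ev_from <- c(ev_from, st); ev_to <- c(ev_to, new_st)
          st <- new_st
        }
        seq_st[s] <- st
      }
    }
    node_state[child, ] <- seq_st
  }

  seqs <- vapply(seq_len(n_tip), function(tip) {
    paste0(sense[node_state[tip, ]], collapse = "")
  }, "")
  names(seqs) <- tree$tip.label
  alignment <- as_codon_alignment(seqs)

  from_aa <- unname(code$map[sense[ev_from]])
  to_aa <- unname(code$map[sense[ev_to]])
  events <- data.frame(parent = ev_parent, child = ev_child,
                       child_label = ifelse(ev_child <= n_tip,
                                            tree$tip.label[ev_child],
                                            paste0("node", ev_child)),
                       site = ev_site, time = ev_time,
                       from_codon = sense[ev_from], to_codon = sense[ev_to],
                       from_aa = from_aa, to_aa = to_aa,
                       synonymous = from_aa == to_aa,
                       stringsAsFactors = FALSE)
  selected <- if (is.null(biases)) {
    data.frame(clade = character(0), site = integer(0),
               property = character(0), beta = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(biases, function(b) {
      data.frame(clade = paste(sort(b$clade), collapse = ","),
                 site = sort(unique(as.integer(b$sites))),
                 property = b$property, beta = b$beta,
                 stringsAsFactors = FALSE)
    }))
  }
  truth <- structure(list(selected = selected, events = events,
                          root = sense[root_state], spec = spec),
                     class = "simulation_truth")
  structure(list(alignment = alignment, tree = tree, truth = truth),
            class = "codon_simulation")
}

#' @export
print.codon_simulation <- function(x, ...) {
  cat(sprintf("Codon simulation: %d taxa x %d sites, %d realized substitutions\n",
              length(x$alignment$labels), x$alignment$n_sites,
              nrow(x$truth$events)))
  if (nrow(x$truth$selected) > 0L) {
    cat(sprintf("  planted bias: %d (clade, site) pairs\n", nrow(x$truth$selected)))
  } else cat("  neutral (no planted bias)\n")
  invisible(x)
}

#' Confusion summary of selection calls against simulation truth
#'
#' Compares site-level calls from a pipeline run on simulated data with the
#' planted (clade, property) truth.
#'
#' @param truth `simulation_truth` from [simulate_codon_evolution()].
#' @param calls Call data frame with a `site` column (and optionally
#'   `property`, used to restrict calls to each planted property).
#' @param n_sites Number of codon sites in the analyzed frame; defaults to
#'   the simulated length.
#' @return Data frame, one row per planted (clade, property): `tp`, `fp`,
#'   `fn`, `tn`, `sensitivity`, `specificity`.
#' @export
truth_report <- function(truth, calls, n_sites = truth$spec$n_sites) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (nrow(calls) > 0L && any(calls$site < 1L | calls$site > n_sites)) {
    abort_site_frame("calls refer to sites outside the simulated frame")
  }
  sel <- truth$selected
  if (nrow(sel) == 0L) {
    called <- unique(calls$site)
    return(data.frame(clade = NA_character_, property = NA_character_,
                      tp = 0L, fp = length(called), fn = 0L,
                      tn = n_sites - length(called),
                      sensitivity = NA_real_,
                      specificity = (n_sites - length(called)) / n_sites,
                      stringsAsFactors = FALSE))
  }
  combos <- unique(sel[, c("clade", "property")])
  out <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    planted <- sel$site[sel$clade == combos$clade[i] &
                          sel$property == combos$property[i]]
    called <- if ("property" %in% names(calls)) {
      unique(calls$site[calls$property == combos$property[i]])
    } else unique(calls$site)
    tp <- length(intersect(called, planted))
    fp <- length(setdiff(called, planted))
    fn <- length(setdiff(planted, called))
    tn <- n_sites - tp - fp - fn
    out[[i]] <- data.frame(clade = combos$clade[i],
                           property = combos$property[i],
                           tp = tp, fp = fp, fn = fn, tn = tn,
                           sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                           specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a simulation to an output directory
#'
#' Writes FASTA alignment, Newick tree, the planted-truth and event-log
#' TSVs, and a plain-text echo of the specification, so a run is fully
#' reproducible from its output directory.
#'
#' @param sim A `codon_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "codon_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_codon_alignment(sim$alignment, file.path(dir, "alignment.fasta"))
  write_tree(sim$tree, file.path(dir, "tree.nwk"))
  write_tsv(sim$truth$selected, file.path(dir, "truth_selected.tsv"))
  write_tsv(sim$truth$events, file.path(dir, "truth_events.tsv"))
  spec <- sim$truth$spec
  lines <- c(paste0("n_sites\t", spec$n_sites),
             paste0("seed\t", spec$seed),
             paste0("code\t", spec$code$name),
             paste0("rate\t", paste(unique(spec$rate), collapse = ",")),
             paste0("n_bias\t", length(spec$bias)))
  writeLines(lines, file.path(dir, "spec.txt"))
  invisible(dir)
}
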