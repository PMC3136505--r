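test_that("zero-length branches copy the root everywhere with an empty log", {
  tr <- make_tree(list(c("a", "b", "c", "d")), bl = 0)
  sim <- simulate_codon_evolution(simulation_spec(tr, 20, seed = 5))
  expect_identical(nrow(sim$truth$events), 0L)
  root_seq <- paste0(sim$truth$root, collapse = "")
  for (lab in tr$tip.label) {
    expect_identical(unname(sim$alignment$sequences[lab]), root_seq)
  }
})

test_that("identical seeds give byte-identical FASTA; different seeds differ", {
  tr <- make_tree(list(paste0("t", 1:4)), bl = 0.2)
  spec <- simulation_spec(tr, 40, seed = 9)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_codon_alignment(simulate_codon_evolution(spec)$alignment, f1)
  write_codon_alignment(simulate_codon_evolution(spec)$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))
  spec2 <- simulation_spec(tr, 40, seed = 10)
  expect_false(identical(
    simulate_codon_evolution(spec2)$alignment$sequences,
    simulate_codon_evolution(spec)$alignment$sequences))
})

test_that("per-branch substreams keep shared clades stable when taxa are added", {
  t3 <- read_tree(text = "((a:0.2,b:0.2):0.2,c:0.2);")
  t4 <- read_tree(text = "((a:0.2,b:0.2):0.2,(c:0.2,d:0.2):0.2);")
  s3 <- simulate_codon_evolution(simulation_spec(t3, 50, seed = 21))
  s4 <- simulate_codon_evolution(simulation_spec(t4, 50, seed = 21))
  expect_identical(s3$alignment$sequences[c("a", "b")],
                   s4$alignment$sequences[c("a", "b")])
})

test_that("the event log replays exactly to the leaf sequences", {
  tr <- make_tree(list(paste0("t", 1:6)), bl = 0.25)
  sim <- simulate_codon_evolution(simulation_spec(tr, 30, seed = 13))
  ev <- sim$truth$events
  n_tip <- length(tr$tip.label)
  node_seq <- vector("list", n_tip + tr$Nnode)
  node_seq[[n_tip + 1L]] <- sim$truth$root
  edges <- propsel:::preorder_edges(tr)
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1L]; ch <- edges[e, 2L]
    s <- node_seq[[p]]
    sub <- ev[ev$parent == p & ev$child == ch, ]
    sub <- sub[order(sub$site, sub$time), ]
    for (i in seq_len(nrow(sub))) {
      expect_identical(s[sub$site[i]], sub$from_codon[i])
      s[sub$site[i]] <- sub$to_codon[i]
    }
    node_seq[[ch]] <- s
  }
  for (tip in seq_len(n_tip)) {
    expect_identical(paste0(node_seq[[tip]], collapse = ""),
                     unname(sim$alignment$sequences[tr$tip.label[tip]]))
  }
})

test_that("realized substitution counts follow the Poisson moment prediction", {
  tr <- make_tree(list(paste0("t", 1:4)), bl = 0.25)   # tree length 1.5
  n_sites <- 60
  lambda <- sum(tr$edge.length) * n_sites
  counts <- vapply(1:40, function(seed) {
    nrow(simulate_codon_evolution(simulation_spec(tr, n_sites, seed = 500 + seed))$truth$events)
  }, 0)
  se <- sqrt(lambda / length(counts))
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("planted bias enriches the radical band beyond the neutral expectation", {
  tab <- default_property_table()
  pm <- propsel:::property_model(tab)
  prop <- "Hp"
  p_band <- sum(pm$expected[prop, 6:8])
  tr <- make_tree(list(paste0("t", 1:6)), bl = 0.2)
  sites <- 1:20
  spec <- simulation_spec(tr, 60, bias = list(clade = tr$tip.label, sites = sites,
                                              property = prop, beta = 10),
                          seed = 31)
  sim <- simulate_codon_evolution(spec)
  ev <- sim$truth$events
  evn <- ev[!ev$synonymous, ]
  cats <- categorize_change(evn$from_aa, evn$to_aa, pm$binnings[[prop]], tab)
  frac_target <- mean(cats[evn$site %in% sites] >= 6)
  frac_rest <- mean(cats[!evn$site %in% sites] >= 6)
  expect_gt(frac_target, p_band)
  expect_gt(frac_target, frac_rest)
})

test_that("simulation specs validate their fields", {
  tr <- make_tree(list(c("a", "b")), bl = 0.1)
  expect_error(simulation_spec(tr, 0), class = "propsel_config_error")
  expect_error(simulation_spec(tr, 10, rate = -1), class = "propsel_config_error")
  expect_error(simulation_spec(tr, 10, bias = list(clade = "zz", sites = 1,
                                                   property = "H", beta = 10)),
               class = "propsel_config_error")
  expect_error(simulation_spec(tr, 10, bias = list(clade = "a", sites = 99,
                                                   property = "H", beta = 10)),
               class = "propsel_config_error")
  expect_error(simulation_spec(tr, 10, bias = list(clade = "a", sites = 1,
                                                   property = "H", beta = 0.5)),
               class = "propsel_config_error")
  bare <- ape::read.tree(text = "(a,b);")
  expect_error(simulation_spec(bare, 10), class = "propsel_config_error")
})

test_that("truth reports tabulate confusion counts exactly", {
  tr <- make_tree(list(c("a", "b", "c")), bl = 0.1)
  spec <- simulation_spec(tr, 50, bias = list(clade = c("a", "b", "c"),
                                              sites = c(3, 7, 9),
                                              property = "H", beta = 10),
                          seed = 2)
  truth <- simulate_codon_evolution(spec)$truth
  exact <- data.frame(site = c(3, 7, 9), property = "H")
  rep1 <- truth_report(truth, exact)
  expect_equal(rep1$sensitivity, 1)
  expect_equal(rep1$specificity, 1)
  rep2 <- truth_report(truth, exact[0, ])
  expect_equal(rep2$sensitivity, 0)
  expect_equal(rep2$specificity, 1)
  mixed <- data.frame(site = c(3, 20, 21), property = "H")
  rep3 <- truth_report(truth, mixed)
  expect_identical(c(rep3$tp, rep3$fp, rep3$fn, rep3$tn), c(1L, 2L, 2L, 45L))
  expect_error(truth_report(truth, data.frame(site = 99, property = "H")),
               class = "propsel_site_frame_error")
})

test_that("simulation outputs reproduce from their run directory", {
  tr <- make_tree(list(paste0("t", 1:4)), bl = 0.1)
  sim <- simulate_codon_evolution(simulation_spec(tr, 20, seed = 3))
  dir <- tempfile("simout_")
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("alignment.fasta", "tree.nwk",
                                               "truth_selected.tsv",
                                               "truth_events.tsv", "spec.txt")))))
  back <- read_codon_alignment(file.path(dir, "alignment.fasta"))
  expect_identical(back$sequences, sim$alignment$sequences)
})
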