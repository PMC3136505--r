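test_that("category_z matches the closed form and the exact binomial tail", {
  expect_equal(category_z(1, 10, 0.1), 0)
  expect_equal(category_z(5, 10, 0.1), 4 / sqrt(0.9))
  expect_equal(category_z(0, 0, 0.5), 0)
  expect_error(category_z(1, 2, 0), class = "propsel_degenerate_error")
  expect_error(category_z(1, 2, 1), class = "propsel_degenerate_error")
  expect_error(category_z(3, 2, 0.5), class = "propsel_value_error")
  # the 3.09 cutoff sits at one-tailed p about 0.001, and the exact
  # binomial tail agrees in order of magnitude for moderate n*p
  expect_equal(stats::pnorm(3.09, lower.tail = FALSE), 0.001, tolerance = 0.01)
  expect_lt(stats::pbinom(4, 10, 0.1, lower.tail = FALSE), 0.01)
})

test_that("site profiles score a lone radical event as the closed form predicts", {
  # one property whose value spikes at K: any A->K change has the maximum
  # magnitude and lands in category 8
  tab <- property_table(matrix(c(8, rep(0, 19)), nrow = 1,
                               dimnames = list("spike", c("K", setdiff(amino_acids(), "K")))))
  nb <- build_neighborhood(genetic_code("standard"), nonsynonymous_only = FALSE)
  binnings <- list(spike = make_binning("spike", tab, nb))
  expecteds <- matrix(c(0.3, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1), nrow = 1,
                      dimnames = list("spike", 1:8))
  ev <- data.frame(site = 3L, from_aa = "A", to_aa = "K", synonymous = FALSE)
  pr <- site_profiles(ev, tab, binnings, expecteds, window = 1, n_sites = 5)
  hit <- pr[pr$site == 3 & pr$category == 8, ]
  expect_identical(hit$observed, 1L)
  expect_identical(hit$n, 1L)
  expect_equal(hit$z, 0.9 / sqrt(0.09))   # = 3.0, just below the 3.09 cutoff
  expect_equal(hit$p_exact, 0.1)
  # all other sites carry z = 0
  expect_true(all(pr$z[pr$site != 3] == 0))
  obs8 <- pr$observed[pr$category == 8]
  expect_identical(sum(obs8), 1L)
})

test_that("per-site observed counts recount the gene-wide category tally", {
  set.seed(11)
  tr <- make_tree(list(paste0("t", 1:8)), bl = 0.15)
  sim <- simulate_codon_evolution(simulation_spec(tr, 60, seed = 11))
  fit <- psel(sim$alignment, sim$tree, window = 1)
  ev <- fit$events
  evn <- ev[!is.na(ev$synonymous) & !ev$synonymous, ]
  tab <- fit$properties
  for (prop in c("H", "Hp")) {
    cats <- categorize_change(evn$from_aa, evn$to_aa, fit$model$binnings[[prop]], tab)
    gene_tally <- tabulate(cats, 8)
    pr <- fit$profiles[fit$profiles$property == prop, ]
    per_site <- vapply(1:8, function(k) sum(pr$observed[pr$category == k]), 0)
    expect_equal(per_site, gene_tally)
  }
})

test_that("windows pool neighbouring sites and clamp with a warning", {
  ev <- data.frame(site = c(2L, 3L, 9L), from_aa = c("A", "A", "A"),
                   to_aa = c("K", "K", "K"), synonymous = FALSE)
  tab <- property_table(matrix(c(8, rep(0, 19)), nrow = 1,
                               dimnames = list("spike", c("K", setdiff(amino_acids(), "K")))))
  nb <- build_neighborhood(genetic_code("standard"), nonsynonymous_only = FALSE)
  binnings <- list(spike = make_binning("spike", tab, nb))
  expecteds <- matrix(rep(0.125, 8), nrow = 1, dimnames = list("spike", 1:8))
  pr3 <- site_profiles(ev, tab, binnings, expecteds, window = 3, n_sites = 10)
  n_by_site <- pr3$n[pr3$category == 1]
  expect_identical(n_by_site[1:4], c(1L, 2L, 2L, 1L))   # edge clamping
  expect_identical(n_by_site[8:10], c(1L, 1L, 1L))
  expect_warning(site_profiles(ev, tab, binnings, expecteds, window = 99,
                               n_sites = 10),
                 "clamped")
})

test_that("classification respects the category band invariants", {
  tests <- data.frame(site = 1:4, property = "H", category = c(7L, 2L, 4L, 8L),
                      z = c(3.2, 3.2, 5, 1))
  calls <- classify(tests, threshold = 3.09)
  expect_identical(nrow(calls), 3L)
  expect_identical(calls$regime[calls$category == 7], "destabilizing")
  expect_identical(calls$regime[calls$category == 2], "stabilizing")
  expect_identical(calls$regime[calls$category == 4], "none")
  expect_true(all(calls$z > 3.09))
  expect_true(all(calls$category[calls$regime == "destabilizing"] %in% 6:8))
  expect_true(all(calls$category[calls$regime == "stabilizing"] %in% 1:3))
  # all-zero z: no calls
  tests$z <- 0
  expect_identical(nrow(classify(tests)), 0L)
  # pooled band tests classify as destabilizing
  band <- data.frame(site = 1:2, property = "H", z = c(4, 1))
  bc <- classify(band)
  expect_identical(nrow(bc), 1L)
  expect_identical(bc$regime, "destabilizing")
})

test_that("whole-protein sum reproduces the worked example and is additive", {
  res <- whole_protein(c(2, -2, -6, 4), threshold = 3.09)
  expect_equal(res$sum, -2)
  expect_false(res$positive)
  expect_equal(whole_protein(numeric(0))$sum, 0)
  expect_false(whole_protein(numeric(0))$positive)
  expect_true(whole_protein(4)$positive)
  for (seed in 1:5) {
    set.seed(seed)
    a <- rnorm(7); b <- rnorm(5)
    expect_equal(whole_protein(c(a, b))$sum,
                 whole_protein(a)$sum + whole_protein(b)$sum)
  }
})

test_that("increasing an observed count never decreases its z", {
  for (n in c(1, 5, 20)) {
    for (p in c(0.05, 0.3, 0.8)) {
      z <- category_z(0:n, n, p)
      expect_true(all(diff(z) > 0))
    }
  }
})

test_that("whole-protein summary modes label and sum as documented", {
  pr <- expand.grid(site = 1:3, property = c("x", "y"), category = 1:8,
                    stringsAsFactors = FALSE)
  pr$z <- seq(0.01, by = 0.01, length.out = nrow(pr))
  s_focus <- whole_protein_summary(pr, threshold = 3.09, categories = 6:8)
  s_all <- whole_protein_summary(pr, mode = "all")
  for (p in c("x", "y")) {
    expect_equal(s_focus$z_sum[s_focus$property == p],
                 sum(pr$z[pr$property == p & pr$category %in% 6:8]))
    expect_equal(s_all$z_sum[s_all$property == p],
                 sum(pr$z[pr$property == p]))
  }
  expect_identical(unique(s_focus$mode), "focus")
})
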