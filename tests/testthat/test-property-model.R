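test_that("neighbourhood enumeration matches a brute-force census for both codes", {
  for (name in c("standard", "vertebrate mitochondrial")) {
    code <- genetic_code(name)
    all_pairs <- build_neighborhood(code, nonsynonymous_only = FALSE)
    nonsyn <- build_neighborhood(code, nonsynonymous_only = TRUE)
    expect_identical(nrow(all_pairs), oracle_neighborhood_count(code$map))
    expect_identical(nrow(nonsyn),
                     oracle_neighborhood_count(code$map, nonsynonymous_only = TRUE))
    # no self pairs, all single-nucleotide, no stops
    expect_true(all(all_pairs$from_codon != all_pairs$to_codon))
    nt_diff <- mapply(function(a, b) {
      sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    }, all_pairs$from_codon, all_pairs$to_codon)
    expect_true(all(nt_diff == 1L))
    expect_false(any(all_pairs$from_aa == "*" | all_pairs$to_aa == "*"))
    expect_true(all(nonsyn$from_aa != nonsyn$to_aa))
  }
})

test_that("binning spans [0, max] with equal widths and forced width examples", {
  tab <- property_table(matrix(c(8, rep(0, 19)), nrow = 1,
                               dimnames = list("spike", c("K", setdiff(amino_acids(), "K")))))
  nb <- build_neighborhood(genetic_code("standard"), nonsynonymous_only = FALSE)
  b <- make_binning("spike", tab, nb)
  expect_equal(b$max, 8)
  expect_equal(b$width, 1)
  expect_equal(b$breaks, 0:8)

  const <- property_table(matrix(rep(1, 20), nrow = 1,
                                 dimnames = list("flat", amino_acids())))
  expect_error(make_binning("flat", const, nb), class = "propsel_degenerate_error")
  expect_error(make_binning("nope", const, nb), class = "propsel_lookup_error")
})

test_that("categorize_change covers 1..8, is magnitude-symmetric and monotone", {
  tab <- default_property_table()
  nb <- build_neighborhood(genetic_code(), nonsynonymous_only = TRUE)
  for (prop in c("H", "Ra", "an")) {
    b <- make_binning(prop, tab, nb)
    expect_identical(categorize_change("A", "A", b, tab), 1L)
    cats <- categorize_change(nb$from_aa, nb$to_aa, b, tab)
    expect_true(all(cats %in% 1:8))
    # the argmax pair by brute force lands in category 8
    vals <- property_values(tab, prop)
    d <- abs(vals[nb$to_aa] - vals[nb$from_aa])
    expect_identical(cats[which.max(d)], 8L)
    # symmetry and monotonicity over all ordered amino acid pairs
    grid <- expand.grid(from = amino_acids(), to = amino_acids(),
                        stringsAsFactors = FALSE)
    cg <- categorize_change(grid$from, grid$to, b, tab)
    cg_rev <- categorize_change(grid$to, grid$from, b, tab)
    expect_identical(cg, cg_rev)
    dd <- abs(vals[grid$to] - vals[grid$from])
    ord <- order(dd)
    expect_true(all(diff(cg[ord]) >= 0L))
  }
  expect_error(categorize_change("A", "B", make_binning("H", tab, nb), tab),
               class = "propsel_lookup_error")
})

test_that("expected distribution normalizes and matches an exhaustive tally", {
  tab <- default_property_table()
  nb <- build_neighborhood(genetic_code(), nonsynonymous_only = FALSE)
  for (prop in c("H", "pK'", "P")) {
    b <- make_binning(prop, tab, nb)
    p <- expected_distribution(prop, tab, nb, b)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    # independent tally: loop over nonsynonymous pairs, bin by hand
    vals <- property_values(tab, prop)
    ns <- nb[!nb$synonymous, ]
    tally <- integer(8)
    for (i in seq_len(nrow(ns))) {
      d <- abs(vals[[ns$to_aa[i]]] - vals[[ns$from_aa[i]]])
      k <- min(floor(d / (b$max / 8) + 1e-9) + 1, 8)
      tally[k] <- tally[k] + 1L
    }
    expect_equal(unname(p), tally / sum(tally))
  }
})

test_that("expected distribution is invariant under affine property transforms", {
  tab <- default_property_table()
  nb <- build_neighborhood(genetic_code(), nonsynonymous_only = FALSE)
  vals <- tab$values["H", , drop = FALSE]
  for (tf in list(c(1, 5), c(-3, 0), c(0.25, -2))) {
    shifted <- property_table(vals * tf[1] + tf[2])
    b0 <- make_binning("H", tab, nb)
    b1 <- make_binning("H", shifted, nb)
    expect_equal(expected_distribution("H", shifted, nb, b1),
                 expected_distribution("H", tab, nb, b0))
  }
})

test_that("a two-valued property under the first-base toy code splits mass between categories 1 and 8", {
  code <- toy_first_base_code()
  # K,R carry value 0; D,E carry value 1; all other amino acids unused
  vals <- stats::setNames(rep(0, 20), amino_acids())
  vals[c("D", "E")] <- 1
  tab <- property_table(matrix(vals, nrow = 1,
                               dimnames = list("twoval", names(vals))))
  nb <- build_neighborhood(code, nonsynonymous_only = FALSE)
  b <- make_binning("twoval", tab, nb)
  p <- expected_distribution("twoval", tab, nb, b)
  expect_true(all(p[2:7] == 0))
  expect_equal(sum(p[c(1, 8)]), 1)
  # hand enumeration: nonsynonymous pairs are first-base changes between
  # sense codons; within {K,R} or {D,E} the magnitude is 0 (category 1),
  # across the value classes it is the maximum (category 8)
  ns <- nb[!nb$synonymous, ]
  zero_mag <- (ns$from_aa %in% c("K", "R") & ns$to_aa %in% c("K", "R")) |
    (ns$from_aa %in% c("D", "E") & ns$to_aa %in% c("D", "E"))
  expect_equal(unname(p[1]), mean(zero_mag))
  expect_equal(unname(p[8]), mean(!zero_mag))
})

test_that("custom genetic codes are validated", {
  expect_error(as_genetic_code(c(AAA = "K")), class = "propsel_completeness_error")
  map <- stats::setNames(rep("K", 64), codons())
  expect_error(as_genetic_code(map), class = "propsel_value_error")  # no stops
  map["TAA"] <- "Z"
  expect_error(as_genetic_code(map), class = "propsel_value_error")
})
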