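test_that("pure-birth trees are reproducible and well formed", {
  tr <- simulate_tree(8, seed = 1)
  expect_equal(ape::Ntip(tr), 8)
  expect_equal(tr$Nnode, 7)
  expect_identical(ape::write.tree(simulate_tree(8, seed = 1)),
                   ape::write.tree(tr))
  tr3 <- simulate_tree(3, seed = 2)
  expect_equal(tr3$Nnode, 2)  # root plus exactly one other internal node
  expect_error(simulate_tree(2), ">= 3")
})

test_that("clade assignment partitions the tips into monophyletic groups", {
  tr <- simulate_tree(20, seed = 4)
  for (k in 2:5) {
    cl <- clade_assignment(tr, k)
    expect_equal(length(cl), k)
    expect_setequal(unlist(cl), tr$tip.label)
    expect_equal(anyDuplicated(unlist(cl)), 0L)
  }
})

test_that("evolution is seed-deterministic and respects the codon model", {
  cfg <- synth_config(n_taxa = 15, n_codons = 60, n_injected_sites = 0,
                      n_indels = 0, seed = 31)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1$alignment$mat, ds2$alignment$mat)
  expect_identical(ds1$phenotypes, ds2$phenotypes)
  # no stop codons anywhere
  rng <- covered_codons(ds1$alignment)
  for (ci in rng[1]:rng[2]) {
    cols <- ds1$alignment$mat[, (3 * (ci - 1) + 1):(3 * ci)]
    cods <- apply(cols, 1, paste, collapse = "")
    expect_false(any(translate_codon(cods) == "*"))
  }
})

test_that("omega = 0 yields exclusively silent variable columns", {
  cfg <- synth_config(n_taxa = 12, n_codons = 80, omega = 0,
                      branch_scale = 0.1, n_injected_sites = 0,
                      n_indels = 0, seed = 5)
  ds <- simulate_dataset(cfg)
  cl <- classify_sites(ds$alignment)$table
  kinds <- cl$site_kind[cl$is_variable]
  expect_true(length(kinds) > 10)  # enough variation to be meaningful
  expect_true(all(kinds == "silent"))
})

test_that("doubling branch_scale increases mean pairwise distance", {
  wins <- 0L
  for (s in 1:10) {
    d1 <- simulate_dataset(synth_config(n_taxa = 10, n_codons = 50,
                                        branch_scale = 0.03,
                                        n_injected_sites = 0, n_indels = 0,
                                        seed = s))
    d2 <- simulate_dataset(synth_config(n_taxa = 10, n_codons = 50,
                                        branch_scale = 0.06,
                                        n_injected_sites = 0, n_indels = 0,
                                        seed = s))
    p1 <- mean(pairwise_distances(d1$alignment)[upper.tri(diag(10))])
    p2 <- mean(pairwise_distances(d2$alignment)[upper.tri(diag(10))])
    if (p2 > p1) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("clade injection creates exactly the ledgered fixed differences", {
  cfg <- synth_config(n_taxa = 20, n_codons = 100, n_clades = 3,
                      n_injected_sites = 6, n_indels = 0, seed = 17)
  ds <- simulate_dataset(cfg)
  a <- ds$clades[[ds$injection$clades[1]]]
  b <- ds$clades[[ds$injection$clades[2]]]
  expect_gte(min(length(a), length(b)), 2L)  # two largest clades by default
  before <- simulate_dataset(synth_config(n_taxa = 20, n_codons = 100,
                                          n_clades = 3, n_injected_sites = 0,
                                          n_indels = 0, seed = 17))
  fd_after <- fixed_differences(ds$alignment, a, b, f_high = 1, f_low = 0)
  fd_before <- fixed_differences(before$alignment, a, b, f_high = 1, f_low = 0)
  truth <- ds$injection$truth_columns
  expect_true(all(truth %in% fd_after$column))          # sensitivity 1
  expect_true(all(setdiff(fd_after$column, fd_before$column) %in% truth))
  # empty injection is the identity
  same <- inject_clade_mutations(before$alignment, before$clades,
                                 data.frame(clade = character(),
                                            codon_index = integer(),
                                            codon = character()))
  expect_identical(same$mat, before$alignment$mat)
  # injecting into a clade containing both groups leaves no trace between them
  all_ids <- list(root = record_ids(before$alignment))
  inj <- data.frame(clade = "root", codon_index = 10L, codon = "TGC")
  rooted <- inject_clade_mutations(before$alignment, all_ids, inj)
  fd_root <- fixed_differences(rooted, a, b, f_high = 1, f_low = 0)
  expect_false(any(28:30 %in% setdiff(fd_root$column, fd_before$column)))
  expect_error(inject_clade_mutations(before$alignment, before$clades,
                                      data.frame(clade = "clade_1",
                                                 codon_index = 10L,
                                                 codon = "TGA")),
               "sense codons")
  expect_error(inject_clade_mutations(before$alignment, before$clades,
                                      data.frame(clade = "clade_1",
                                                 codon_index = 999L,
                                                 codon = "TGC")),
               "out of covered range")
})

test_that("phenotypes are clade-correlated, truncated and reproducible", {
  cl <- list(clade_1 = paste0("a", 1:6), clade_2 = paste0("b", 1:6))
  ph <- assign_phenotypes(cl, means = c(2, 45), sd = 1, seed = 8)
  expect_identical(assign_phenotypes(cl, means = c(2, 45), sd = 1, seed = 8),
                   ph)
  cats <- categorize(ph$erucic_pct)
  expect_true(all(cats[ph$clade == "clade_1"] == "L"))
  expect_true(all(cats[ph$clade == "clade_2"] == "H"))
  ph0 <- assign_phenotypes(cl, means = c(2, 45), sd = 0, seed = 8)
  expect_equal(ph0$erucic_pct, rep(c(2, 45), each = 6))
  expect_true(all(ph$erucic_pct >= 0 & ph$erucic_pct <= 100))
})

test_that("estimated Ka/Ks decreases with omega", {
  omegas <- c(0.05, 0.1, 0.5, 1.0)
  means <- vapply(omegas, function(w) {
    vals <- vapply(1:3, function(s) {
      ds <- simulate_dataset(synth_config(n_taxa = 12, n_codons = 80,
                                          omega = w, n_injected_sites = 0,
                                          n_indels = 0, seed = 100 + s))
      ka_ks(ds$alignment)$ratio
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_lt(means[1], 1)
})

test_that("datasets round-trip through disk", {
  ds <- simulate_dataset(synth_config(n_taxa = 10, n_codons = 30, seed = 77,
                                      n_injected_sites = 4, n_indels = 1))
  dir <- tempfile("synth")
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  aln <- read_alignment(paths["alignment"], paths["metadata"],
                        ds$config$coding_offset)
  expect_identical(aln$mat, ds$alignment$mat)
  expect_identical(aln$meta$clade, ds$alignment$meta$clade)
  tr <- read_clade_tree(paths["tree"])
  expect_setequal(tr$tip.label, record_ids(aln))
  ledger <- jsonlite::read_json(paths["ledger"], simplifyVector = TRUE)
  expect_equal(sort(ledger$injection$truth_columns),
               sort(ds$injection$truth_columns))
})
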