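test_that("p-distance excludes gapped and missing sites pairwise", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("AC-T", "ACGT"), 0)   # 3 compared sites
  expect_equal(p_distance("ACNT", "ACGA"), 1 / 3)
  expect_error(p_distance("---", "AAA"), "zero comparable sites")
  aln <- make_aln(c(x = "ACGT", y = "ACGA"))
  expect_equal(p_distance("x", "y", aln), 0.25)
})

test_that("nucleotide diversity equals the mean over all pairs", {
  aln <- make_aln(c(a = "AAAAAAAAAA", b = "AAAAAAAAAT"))
  expect_equal(nucleotide_diversity(aln)$pi, 0.1)
  aln2 <- make_aln(c(a = "AAAA", b = "AAAT", c = "AATT"))
  r <- nucleotide_diversity(aln2)
  expect_equal(r$pi, 1 / 3)
  expect_equal(r$n_pairs, 3)
  expect_error(nucleotide_diversity(aln2, "a"), "at least 2")
})

test_that("pi matches the brute-force all-pairs oracle on random matrices", {
  set.seed(202)
  for (rep in 1:15) {
    aln <- random_alignment(sample(4:20, 1), sample(30:120, 1))
    expect_equal(nucleotide_diversity(aln)$pi, o_pi(aln$mat),
                 tolerance = 1e-12)
  }
})

test_that("divergence is symmetric and Jukes-Cantor corrected", {
  aln <- make_aln(c(a = "AAAA", b = "AAAT", c = "TTTT", d = "TTTT"))
  d1 <- suppressWarnings(divergence(aln, c("a", "b"), c("c", "d")))
  d2 <- suppressWarnings(divergence(aln, c("c", "d"), c("a", "b")))
  expect_equal(d1$pi_between, d2$pi_between)
  expect_equal(d1$dxy, d2$dxy)
  expect_equal(d1$pi_between, mean(c(1, 1, 0.75, 0.75)))
  expect_true(is.na(d1$dxy))  # 0.875 >= 3/4
  d3 <- suppressWarnings(divergence(aln, "a", c("c", "d")))
  expect_equal(d3$pi_between, 1)
  expect_true(is.na(d3$dxy))
  # identical groups diverge by zero
  aln2 <- make_aln(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  d0 <- divergence(aln2, c("a", "b"), "c")
  expect_equal(d0$pi_between, 0)
  expect_equal(d0$dxy, 0)
  expect_error(divergence(aln, c("a", "b"), c("b", "c")), "disjoint")
  # low divergence stays in the correction domain
  aln3 <- make_aln(c(a = "AAAAAAAAAA", b = "TAAAAAAAAA"))
  dv <- divergence(aln3, "a", "b")
  expect_equal(dv$dxy, -0.75 * log(1 - 4 / 3 * 0.1))
})

test_that("JC correction is monotone increasing on its domain", {
  p <- seq(0, 0.74, by = 0.01)
  v <- jc_correction(p)
  expect_true(all(diff(v) > 0))
  expect_true(all(v >= p - 1e-12))
})

test_that("Nei-Gojobori counts match the worked example and conserve sites", {
  aln <- make_aln(c(a = "GGAGGGGGA", b = "GGAGGGGGG"))
  r <- ka_ks(aln)
  expect_equal(r$S_sites, 3)
  expect_equal(r$N_sites, 6)
  expect_equal(r$sd, 1)
  expect_equal(r$nd, 0)
  expect_equal(r$ks, -0.75 * log(1 - 4 / 9), tolerance = 1e-12)
  expect_equal(round(r$ks, 4), 0.4408)
  expect_equal(r$ka, 0)
  expect_true(is.na(ka_ks(make_aln(c(a = "GGAGGA", b = "GGAGGA")))$ratio))

  set.seed(303)
  for (rep in 1:5) {
    aln <- random_codon_alignment(sample(3:8, 1), sample(10:40, 1))
    r <- suppressWarnings(ka_ks(aln))  # random codons can saturate pN/pS
    expect_equal(r$S_sites + r$N_sites, 3 * r$n_codons_used,
                 tolerance = 1e-9)
  }
})

test_that("Ka/Ks agrees with the recursive pathway-enumeration oracle", {
  set.seed(404)
  sense <- names(o_code())[o_code() != "*"]
  for (rep in 1:12) {
    L <- sample(5:15, 1)
    a <- sample(sense, L, replace = TRUE)
    b <- ifelse(runif(L) < 0.4, sample(sense, L, replace = TRUE), a)
    aln <- make_aln(c(x = paste(a, collapse = ""),
                      y = paste(b, collapse = "")))
    r <- suppressWarnings(ka_ks(aln))
    o <- o_kaks_pair(a, b)
    expect_equal(r$S_sites, o$S, tolerance = 1e-9)
    expect_equal(r$sd, o$sd, tolerance = 1e-9)
    expect_equal(r$nd, o$nd, tolerance = 1e-9)
    expect_equal(r$ks, o$ks, tolerance = 1e-9)
    expect_equal(r$ka, o$ka, tolerance = 1e-9)
  }
})

test_that("sliding windows advance in silent-site ordinals", {
  # 85 GGA codons (silent at phase 3) + TGG codons (replacement everywhere)
  n_sil <- 85
  base <- paste0(strrep("GGA", n_sil), strrep("TGG", 20))
  v <- strsplit(base, "")[[1]]
  w <- v; w[seq(3, by = 3, length.out = 40)] <- "G"  # silent variants
  aln <- coding_alignment(rbind(s1 = v, s2 = w, s3 = v), NULL, 1)
  expect_equal(sum(site_kinds(aln) == "silent"), n_sil)
  prof <- sliding_window_silent(aln, window_size = 25, step = 10)
  expect_equal(nrow(prof), 7)
  expect_equal(prof$first_silent, seq(1, 61, by = 10))
  # identical sequences give a flat zero profile
  aln0 <- coding_alignment(rbind(s1 = v, s2 = v), NULL, 1)
  prof0 <- sliding_window_silent(aln0, 25, 10)
  expect_true(all(prof0$pi_silent == 0))
  expect_error(sliding_window_silent(aln, window_size = 100),
               "fewer silent columns")
})

test_that("window diversity is consistent with whole-matrix silent pi", {
  set.seed(9)
  ds <- simulate_dataset(synth_config(n_taxa = 20, n_codons = 200,
                                      n_injected_sites = 0, n_indels = 0,
                                      seed = 9))
  aln <- ds$alignment
  silent <- which(site_kinds(aln) == "silent")
  prof <- sliding_window_silent(aln, 25, 10)
  total <- .subset2(nucleotide_diversity(
    coding_alignment(aln$mat[, silent, drop = FALSE], aln$meta, 1)), "pi")
  expect_equal(mean(prof$pi_silent), total, tolerance = 0.25)
})
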