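test_that("alignment construction validates lengths, alphabet and metadata", {
  meta <- data.frame(record_id = c("a", "b", "c"), tribe = "T",
                     genus = "G", species = "sp")
  aln <- coding_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC",
                            c = "ACGTACGTAT"), meta)
  expect_equal(n_columns(aln), 10L)
  expect_equal(aln$meta$tribe, rep("T", 3))

  expect_error(coding_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTA")),
               "alignment error")
  expect_error(coding_alignment(c(a = "ACGX")), "alphabet error")
  expect_error(coding_alignment(c(a = "ACGT", d = "ACGT"), meta),
               "metadata error.*d")
})

test_that("FASTA write/read round trip is byte identical", {
  fa <- tempfile(fileext = ".fa")
  tsv <- tempfile(fileext = ".tsv")
  set.seed(42)
  aln <- random_alignment(6, 157)
  write_alignment(aln, fa, tsv)
  aln2 <- read_alignment(fa, tsv, coding_offset = 1)
  expect_identical(aln2$mat, aln$mat)
  fa2 <- tempfile(fileext = ".fa")
  write_alignment(aln2, fa2)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fa2, "raw", file.size(fa2)))
})

test_that("column_to_coding maps the amplicon coordinates correctly", {
  expect_equal(unlist(column_to_coding(431, 1)),
               c(column = 1, coding_position = 431, codon_index = 144,
                 codon_phase = 2))
  expect_equal(column_to_coding(431, 3)$codon_index, 145)
  expect_equal(column_to_coding(431, 3)$codon_phase, 1)
  expect_equal(column_to_coding(431, 892)$coding_position, 1322)
  expect_error(column_to_coding(431, 0), "out of range")
  expect_error(column_to_coding(431, 11, n_columns = 10), "out of range")
})

test_that("column_to_coding is a bijection onto the coding interval", {
  for (off in c(1L, 2L, 431L)) {
    nc <- 50L
    got <- column_to_coding(off, seq_len(nc))$coding_position
    expect_identical(got, seq.int(off, off + nc - 1L))
    expect_identical(anyDuplicated(got), 0L)
  }
})

test_that("indel events are maximal runs with frameshift and terminal flags", {
  s <- strrep("A", 30)
  gapped <- function(x, at) {
    v <- strsplit(x, "")[[1]]; v[at] <- "-"; paste(v, collapse = "")
  }
  aln <- make_aln(c(a = gapped(s, 10:11), b = gapped(s, 20:22),
                    c = s, d = gapped(s, 1:4)))
  ev <- detect_indel_events(aln)
  expect_equal(nrow(ev), 3L)
  e_a <- ev[ev$record_id == "a", ]
  expect_equal(e_a$length, 2L)
  expect_true(e_a$frameshift)
  e_b <- ev[ev$record_id == "b", ]
  expect_equal(e_b$start_column, 20L)
  expect_false(e_b$frameshift)
  e_d <- ev[ev$record_id == "d", ]
  expect_true(e_d$terminal)
  expect_true(is.na(e_d$frameshift))
  expect_false("c" %in% ev$record_id)
})

test_that("indel event lengths account for every internal gap", {
  set.seed(7)
  for (rep in 1:10) {
    aln <- random_alignment(8, 60, p_gap = 0.08)
    ev <- detect_indel_events(aln)
    for (id in record_ids(aln)) {
      g <- aln$mat[id, ] == "-"
      internal <- g
      # strip leading/trailing runs
      if (any(!g)) {
        internal[seq_len(which(!g)[1])] <- FALSE
        internal[max(which(!g)):length(g)] <- FALSE
        internal <- internal & g
      } else internal[] <- FALSE
      expect_equal(sum(ev$length[ev$record_id == id & !ev$terminal]),
                   sum(internal))
    }
  }
})

test_that("conserved-residue checks report match, mismatch and coverage", {
  # codons: M A C K  -> protein positions 1-4 under offset 1
  aln <- make_aln(c(a = "ATGGCTTGCAAA", b = "ATGGCTAGCAAA"))
  spec <- data.frame(aa = c("C", "K"), position = c(3L, 4L))
  res <- check_conserved_residues(aln, spec)
  expect_equal(res$status[res$record_id == "a" & res$position == 3], "match")
  r_b <- res[res$record_id == "b" & res$position == 3, ]
  expect_equal(r_b$status, "mismatch")
  expect_equal(r_b$observed_aa, "S")
  expect_equal(unique(res$status[res$position == 4]), "match")

  # a 892-column matrix starting at coding 431 covers codons 145-440 only
  wide <- make_aln(c(a = strrep("A", 892), b = strrep("A", 892)),
                   coding_offset = 431)
  expect_equal(covered_codons(wide), c(first = 145L, last = 440L))
  out <- check_conserved_residues(wide, data.frame(aa = "C", position = 84L))
  expect_true(all(out$status == "not_assessable"))
  # gap in the codon -> not assessable
  gap <- make_aln(c(a = "ATG-CTTGCAAA"))
  res_gap <- check_conserved_residues(gap, data.frame(aa = "A", position = 2L))
  expect_equal(res_gap$status, "not_assessable")
  expect_error(check_conserved_residues(aln, data.frame(x = 1)),
               "malformed residue_spec")
})

test_that("newick clade trees round-trip and resolve labelled clades", {
  path <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1)n2:1,C:2)n1;", path)
  tr <- read_clade_tree(path)
  expect_setequal(clade_members(tr, "n2"), c("A", "B"))
  expect_setequal(clade_members(tr, "n1"), c("A", "B", "C"))
  expect_error(clade_members(tr, "nope"), "unknown")
  out <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, out)
  tr2 <- read_clade_tree(out)
  expect_identical(ape::write.tree(tr2), ape::write.tree(tr))
  expect_setequal(clade_members(tr2, "n2"), c("A", "B"))

  bad <- tempfile(fileext = ".nwk")
  writeLines("((A,B;", bad)
  expect_error(suppressWarnings(read_clade_tree(bad)), "parse error")
})
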