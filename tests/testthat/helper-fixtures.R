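# Small in-code fixtures.

make_aln <- function(seqs, coding_offset = 1, meta = NULL) {
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  coding_alignment(seqs, meta, coding_offset)
}

# alignment from a list of column state vectors (records are rows)
aln_from_cols <- function(cols, coding_offset = 1) {
  mat <- do.call(cbind, cols)
  rownames(mat) <- paste0("s", seq_len(nrow(mat)))
  coding_alignment(mat, NULL, coding_offset)
}

# random gapped/missing alignment matrix for oracle-equivalence runs
random_alignment <- function(n, m, p_gap = 0.03, p_n = 0.02,
                             coding_offset = 1) {
  states <- sample(c("A", "C", "G", "T"), n * m, replace = TRUE)
  mask <- runif(n * m)
  states[mask < p_gap] <- "-"
  states[mask >= p_gap & mask < p_gap + p_n] <- "N"
  mat <- matrix(states, n, m)
  # keep some shared structure so informative sites exist
  anc <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
  conserve <- runif(m) < 0.5
  for (j in which(conserve)) {
    keep <- runif(n) < 0.8
    mat[keep, j] <- anc[j]
  }
  rownames(mat) <- paste0("s", seq_len(n))
  coding_alignment(mat, NULL, coding_offset)
}

# gap-free alignment of in-frame codons drawn from a pool
random_codon_alignment <- function(n, n_codons,
                                   pool = setdiff(names(o_code())[o_code() != "*"], NULL)) {
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(pool, n_codons, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("s", seq_len(n))
  coding_alignment(seqs, NULL, coding_offset = 1)
}
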