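## The coding_alignment class: an equal-length DNA alignment with taxon
## metadata and a coding-coordinate offset.  Every statistic in the package
## operates on this object.

ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Construct a coding alignment
#'
#' An in-frame protein-coding alignment over `A,C,G,T,N,-` with per-record
#' taxon metadata and a coding-coordinate offset: alignment column 1
#' corresponds to position `coding_offset` of the coding region (1-based from
#' the start codon of the reference sequence).  The default offset of 431
#' matches a FAE1 amplicon beginning at coding position 431.
#'
#' @param sequences named character vector of aligned sequences (equal
#'   length), or a character matrix with one row per record and one aligned
#'   column per matrix column (rownames are record ids).
#' @param metadata data frame with columns `record_id`, `tribe`, `genus`,
#'   `species` and optionally `clade`; one row per record.  When `NULL`,
#'   placeholder metadata is created.
#' @param coding_offset integer >= 1; coding-region position of column 1.
#' @return object of class `coding_alignment` with elements `mat` (character
#'   matrix), `meta` (data frame) and `coding_offset`.
#' @examples
#' aln <- coding_alignment(c(s1 = "ATGGCT", s2 = "ATGGAT"), coding_offset = 1)
#' aln
#' @export
coding_alignment <- function(sequences, metadata = NULL, coding_offset = 431) {
  if (is.matrix(sequences)) {
    mat <- sequences
  } else {
    if (is.null(names(sequences)) || anyNA(names(sequences)) ||
        any(names(sequences) == ""))
      stop("sequences must be named by record id")
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L)
      stop("alignment error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    mat <- do.call(rbind, strsplit(toupper(sequences), ""))
    rownames(mat) <- names(sequences)
  }
  mat[] <- toupper(mat)
  if (ncol(mat) < 1L) stop("alignment error: zero columns")
  if (anyDuplicated(rownames(mat)))
    stop("record ids must be unique")
  bad <- setdiff(unique(as.vector(mat)), ALPHABET)
  if (length(bad))
    stop("alphabet error: unknown characters in alignment: ",
         paste(bad, collapse = ", "))
  coding_offset <- as.integer(coding_offset)
  if (is.na(coding_offset) || coding_offset < 1L)
    stop("coding_offset must be an integer >= 1")
  if (is.null(metadata)) {
    metadata <- data.frame(record_id = rownames(mat), tribe = NA_character_,
                           genus = NA_character_, species = NA_character_,
                           stringsAsFactors = FALSE)
  }
  req <- c("record_id", "tribe", "genus", "species")
  if (!all(req %in% names(metadata)))
    stop("metadata error: metadata must have columns ",
         paste(req, collapse = ", "))
  missing_ids <- setdiff(rownames(mat), metadata$record_id)
  if (length(missing_ids))
    stop("metadata error: no metadata for record(s): ",
         paste(missing_ids, collapse = ", "))
  meta <- metadata[match(rownames(mat), metadata$record_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(mat = mat, meta = meta, coding_offset = coding_offset),
            class = "coding_alignment")
}

#' Read a coding alignment from FASTA plus a metadata table
#'
#' @param fasta_path path to an aligned FASTA file (`-` gaps allowed).
#' @param metadata_path path to a tab-separated table with columns
#'   `record_id`, `tribe`, `genus`, `species` and optionally `clade`; every
#'   FASTA id must be present.  `NULL` for placeholder metadata.
#' @param coding_offset coding-region position of alignment column 1.
#' @return a [coding_alignment()] object.
#' @export
read_alignment <- function(fasta_path, metadata_path = NULL,
                           coding_offset = 431) {
  dna <- ape::read.FASTA(fasta_path)
  if (length(dna) == 0L) stop("alignment error: no sequences in ", fasta_path)
  seqs <- vapply(as.character(dna),
                 function(x) paste(toupper(x), collapse = ""), character(1))
  meta <- NULL
  if (!is.null(metadata_path))
    meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                              colClasses = "character")
  coding_alignment(seqs, meta, coding_offset)
}

#' Write a coding alignment to FASTA (and optionally its metadata to TSV)
#'
#' Sequences are written uppercase at a fixed line width, so that writing and
#' re-reading an alignment is byte-stable.
#'
#' @param aln a [coding_alignment()].
#' @param fasta_path output FASTA path.
#' @param metadata_path optional output TSV path for the metadata table.
#' @param width line width for wrapped sequence lines.
#' @return `fasta_path`, invisibly.
#' @export
write_alignment <- function(aln, fasta_path, metadata_path = NULL,
                            width = 70) {
  stopifnot(inherits(aln, "coding_alignment"))
  con <- file(fasta_path, "wb")
  on.exit(close(con))
  for (id in rownames(aln$mat)) {
    s <- paste(aln$mat[id, ], collapse = "")
    starts <- seq(1L, nchar(s), by = width)
    lines <- substring(s, starts, pmin(starts + width - 1L, nchar(s)))
    writeLines(c(paste0(">", id), lines), con, sep = "\n")
  }
  if (!is.null(metadata_path))
    utils::write.table(aln$meta, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(fasta_path)
}

#' Number of alignment columns
#' @param aln a [coding_alignment()].
#' @return integer column count.
#' @export
n_columns <- function(aln) ncol(aln$mat)

#' Record ids of an alignment
#' @param aln a [coding_alignment()].
#' @return character vector of record ids, in alignment order.
#' @export
record_ids <- function(aln) rownames(aln$mat)

#' Subset an alignment to a set of records
#' @param aln a [coding_alignment()].
#' @param ids record ids to keep (alignment order preserved).
#' @return a [coding_alignment()] over the selected records.
#' @export
subset_records <- function(aln, ids) {
  miss <- setdiff(ids, record_ids(aln))
  if (length(miss)) stop("unknown record id(s): ", paste(miss, collapse = ", "))
  keep <- record_ids(aln)[record_ids(aln) %in% ids]
  coding_alignment(aln$mat[keep, , drop = FALSE],
                   aln$meta[aln$meta$record_id %in% keep, , drop = FALSE],
                   aln$coding_offset)
}

#' @export
print.coding_alignment <- function(x, ...) {
  cat("Coding alignment:", nrow(x$mat), "records x", ncol(x$mat),
      "columns\n")
  cat("Coding coordinates:", x$coding_offset, "-",
      x$coding_offset + ncol(x$mat) - 1L,
      sprintf("(codons %d-%d fully covered)\n",
              covered_codons(x)[1], covered_codons(x)[2]))
  gaps <- sum(x$mat == "-")
  cat("Gap characters:", gaps, " Missing (N):", sum(x$mat == "N"), "\n")
  invisible(x)
}

#' @export
summary.coding_alignment <- function(object, ...) {
  print(object)
  cl <- classify_sites(object)
  print(cl)
  invisible(object)
}

#' Map alignment columns to coding coordinates
#'
#' Converts 1-based alignment columns into coding-region positions, codon
#' indices and codon phases under the alignment's coding offset.  The map is
#' a bijection from `[1, n_columns]` onto
#' `[coding_offset, coding_offset + n_columns - 1]`.
#'
#' @param aln a [coding_alignment()], or an integer coding offset.
#' @param column integer vector of 1-based alignment columns.
#' @param n_columns optional column count for range checking when `aln` is a
#'   bare offset.
#' @return data frame with columns `column`, `coding_position`,
#'   `codon_index`, `codon_phase`.
#' @examples
#' column_to_coding(431, 1:3)
#' @export
column_to_coding <- function(aln, column, n_columns = NULL) {
  if (inherits(aln, "coding_alignment")) {
    offset <- aln$coding_offset
    n_columns <- ncol(aln$mat)
  } else {
    offset <- as.integer(aln)
  }
  column <- as.integer(column)
  if (anyNA(column) || any(column < 1L) ||
      (!is.null(n_columns) && any(column > n_columns)))
    stop("column out of range")
  coding <- column + offset - 1L
  codon <- (coding + 2L) %/% 3L
  phase <- coding - 3L * (codon - 1L)
  data.frame(column = column, coding_position = coding,
             codon_index = codon, codon_phase = phase)
}

## Alignment columns spanned by a codon index; NA when not fully covered.
codon_columns <- function(aln, codon_index) {
  offset <- aln$coding_offset
  first <- 3L * (as.integer(codon_index) - 1L) + 1L
  cols <- cbind(first, first + 1L, first + 2L) - offset + 1L
  cols[cols < 1L | cols > ncol(aln$mat)] <- NA_integer_
  cols
}

#' Range of codon indices fully covered by an alignment
#' @param aln a [coding_alignment()].
#' @return integer vector `c(first, last)` of fully covered codon indices.
#' @export
covered_codons <- function(aln) {
  offset <- aln$coding_offset
  last_pos <- offset + ncol(aln$mat) - 1L
  first <- (offset + 2L) %/% 3L
  if (3L * (first - 1L) + 1L < offset) first <- first + 1L
  last <- last_pos %/% 3L
  c(first = first, last = last)
}

#' Detect insertion/deletion events in an alignment
#'
#' One event per maximal gap run per record.  Runs touching the first or last
#' alignment column are flagged `terminal` and treated as missing data
#' (partial sequences), not deletions: their `frameshift` flag is `NA`.
#' Internal runs are frameshifting when their length is not a multiple of 3.
#' Both alignment-column and coding coordinates are reported.
#'
#' @param aln a [coding_alignment()].
#' @return data frame with columns `record_id`, `start_column`, `end_column`,
#'   `length`, `terminal`, `frameshift`, `coding_start`, `coding_end`; zero
#'   rows if the alignment is gap-free.
#' @export
detect_indel_events <- function(aln) {
  stopifnot(inherits(aln, "coding_alignment"))
  out <- list()
  nc <- ncol(aln$mat)
  for (id in rownames(aln$mat)) {
    g <- aln$mat[id, ] == "-"
    if (!any(g)) next
    r <- rle(g)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      terminal <- starts[k] == 1L || ends[k] == nc
      out[[length(out) + 1L]] <- data.frame(
        record_id = id, start_column = starts[k], end_column = ends[k],
        length = r$lengths[k], terminal = terminal,
        frameshift = if (terminal) NA else (r$lengths[k] %% 3L != 0L),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(record_id = character(), start_column = integer(),
                      end_column = integer(), length = integer(),
                      terminal = logical(), frameshift = logical(),
                      coding_start = integer(), coding_end = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$coding_start <- res$start_column + aln$coding_offset - 1L
  res$coding_end <- res$end_column + aln$coding_offset - 1L
  rownames(res) <- NULL
  res
}

#' Conserved residues of the FAE1 condensing enzyme
#'
#' The default residue specification checked by
#' [check_conserved_residues()]: the four conserved histidines (302, 387,
#' 391, 420), six conserved cysteines (84, 223, 270, 312, 389, 460 —
#' including the catalytic Cys223) and the asparagine at 424 required for
#' ketoacyl-CoA synthase activity, in reference protein coordinates.
#'
#' @return data frame with columns `aa` (one-letter code) and `position`.
#' @export
kcs_conserved_residues <- function() {
  data.frame(
    aa = c(rep("H", 4), rep("C", 6), "N"),
    position = c(302L, 387L, 391L, 420L, 84L, 223L, 270L, 312L, 389L, 460L,
                 424L),
    stringsAsFactors = FALSE)
}

#' Check conservation of reference residues across an alignment
#'
#' For each record and each residue of `residue_spec`, translates the codon
#' at the residue's reference protein position (codon index equals protein
#' position under the alignment's coding offset) and reports `match`,
#' `mismatch` (with the observed amino acid), or `not_assessable` when the
#' codon is not fully covered by the alignment or contains gaps or `N`.
#'
#' @param aln a [coding_alignment()].
#' @param residue_spec data frame with columns `aa` (expected one-letter
#'   amino acid) and `position` (protein position); defaults to
#'   [kcs_conserved_residues()].
#' @return data frame with columns `record_id`, `residue`, `expected_aa`,
#'   `position`, `status`, `observed_aa`.
#' @export
check_conserved_residues <- function(aln, residue_spec = kcs_conserved_residues()) {
  stopifnot(inherits(aln, "coding_alignment"))
  if (!is.data.frame(residue_spec) ||
      !all(c("aa", "position") %in% names(residue_spec)) ||
      !all(residue_spec$aa %in% LETTERS) ||
      any(residue_spec$position < 1))
    stop("malformed residue_spec: need columns aa (one-letter) and position (>= 1)")
  ids <- rownames(aln$mat)
  rows <- vector("list", nrow(residue_spec) * length(ids))
  n <- 0L
  for (r in seq_len(nrow(residue_spec))) {
    pos <- residue_spec$position[r]
    exp_aa <- residue_spec$aa[r]
    cols <- codon_columns(aln, pos)
    covered <- !anyNA(cols)
    for (id in ids) {
      n <- n + 1L
      status <- "not_assessable"; obs <- NA_character_
      if (covered) {
        cd <- paste(aln$mat[id, cols], collapse = "")
        obs <- translate_codon(cd)
        if (!is.na(obs))
          status <- if (obs == exp_aa) "match" else "mismatch"
        else obs <- NA_character_
      }
      rows[[n]] <- data.frame(record_id = id,
                              residue = paste0(exp_aa, pos),
                              expected_aa = exp_aa, position = pos,
                              status = status, observed_aa = obs,
                              stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Read a rooted clade tree from newick
#'
#' @param newick_path path to a newick file; internal node labels are
#'   permitted and used as clade names, branch lengths optional.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_clade_tree <- function(newick_path) {
  tr <- tryCatch(ape::read.tree(newick_path),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error: could not parse ", newick_path)
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf names in tree")
  tr
}

#' Leaf set of a labelled clade
#'
#' @param tree a `phylo` object with internal node labels.
#' @param node_label label of an internal node (the root label yields all
#'   leaves).
#' @return character vector of the record ids descending from that node.
#' @export
clade_members <- function(tree, node_label) {
  if (is.null(tree$node.label)) stop("tree has no internal node labels")
  idx <- which(tree$node.label == node_label)
  if (length(idx) != 1L)
    stop("unknown or ambiguous clade label: ", node_label)
  node <- ape::Ntip(tree) + idx
  if (node == ape::Ntip(tree) + 1L) return(tree$tip.label)
  ape::extract.clade(tree, node)$tip.label
}
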