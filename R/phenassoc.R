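## Erucic-acid phenotype categorization and genotype-phenotype association
## via a diversity-based Fst with a label-permutation null.

#' Category boundaries for erucic-acid content
#'
#' Cut points partitioning erucic-acid content (% of seed fatty acids) into
#' ordered categories.  The defaults are the observed gaps in the published
#' distribution of seed contents: low (L) below 10.5, intermediate M1, M2,
#' M3, and high (H) from 41.1 upward.  Intervals are half-open with each cut
#' point belonging to the upper category: L = [0, 10.5), M1 = [10.5, 20.5),
#' M2 = [20.5, 31.11), M3 = [31.11, 41.1), H = [41.1, 100].
#'
#' @param cuts strictly increasing cut points within (0, 100).
#' @param labels category labels; one more than `cuts`.
#' @return object of class `category_boundaries`.
#' @export
category_boundaries <- function(cuts = c(10.5, 20.5, 31.11, 41.1),
                                labels = c("L", "M1", "M2", "M3", "H")) {
  if (any(diff(cuts) <= 0)) stop("cuts must be strictly increasing")
  if (length(labels) != length(cuts) + 1L)
    stop("need one more label than cut points")
  structure(list(cuts = cuts, labels = labels),
            class = "category_boundaries")
}

#' Categorize erucic-acid contents
#'
#' @param erucic_pct numeric vector of contents in `[0, 100]`.
#' @param boundaries a [category_boundaries()].
#' @return factor of category labels (levels in boundary order).
#' @examples
#' categorize(c(0, 10.5, 39.8, 41.1))
#' @export
categorize <- function(erucic_pct, boundaries = category_boundaries()) {
  stopifnot(inherits(boundaries, "category_boundaries"))
  if (any(is.na(erucic_pct)) || any(erucic_pct < 0 | erucic_pct > 100))
    stop("erucic_pct values must lie in [0, 100]")
  idx <- findInterval(erucic_pct, boundaries$cuts) + 1L
  factor(boundaries$labels[idx], levels = boundaries$labels)
}

#' Read a phenotype table
#'
#' @param path TSV with columns `accession` and `erucic_pct`.
#' @return data frame with those columns.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("accession", "erucic_pct") %in% names(df)))
    stop("phenotype table must have columns accession, erucic_pct")
  df$erucic_pct <- as.numeric(df$erucic_pct)
  df
}

.partition_factor <- function(aln, partition) {
  if (is.list(partition)) {
    .check_grouping(aln, partition)
    ids <- unlist(partition, use.names = FALSE)
    partition <- stats::setNames(
      factor(rep(names(partition), lengths(partition))), ids)
  }
  if (is.null(names(partition)))
    stop("partition must be a named factor or a named list of record ids")
  partition <- droplevels(as.factor(partition))
  unknown <- setdiff(names(partition), record_ids(aln))
  if (length(unknown))
    stop("unknown record id(s): ", paste(unknown, collapse = ", "))
  partition
}

.fst_from_dist <- function(d, labels) {
  same <- outer(labels, labels, "==")
  ut <- upper.tri(d)
  hw <- mean(d[ut & same])
  hb <- mean(d[ut & !same])
  list(fst = 1 - hw / hb, hw = hw, hb = hb,
       n_within_pairs = sum(ut & same), n_between_pairs = sum(ut & !same))
}

#' Hudson-style Fst from nucleotide diversities
#'
#' `Fst = 1 - Hw/Hb`, where `Hw` is the mean pairwise-deletion p-distance
#' over all within-category sequence pairs pooled across categories, and `Hb`
#' the mean over all between-category pairs.  Applies both overall (all
#' categories) and pairwise (two categories).
#'
#' @param aln a [coding_alignment()].
#' @param partition named factor of category labels (names are record ids),
#'   or a named list of record-id vectors.  Each category needs >= 2
#'   members, and >= 2 categories are required.
#' @return object of class `fst_result`: list with `fst`, `hw`, `hb`,
#'   `n_within_pairs`, `n_between_pairs`, `categories`.
#' @examples
#' aln <- coding_alignment(
#'   c(a = "AAAA", b = "AAAT", c = "TTTT", d = "TTTA"), coding_offset = 1)
#' hudson_fst(aln, list(g1 = c("a", "b"), g2 = c("c", "d")))
#' @export
hudson_fst <- function(aln, partition) {
  stopifnot(inherits(aln, "coding_alignment"))
  partition <- .partition_factor(aln, partition)
  sizes <- table(partition)
  if (length(sizes) < 2L) stop("need at least 2 categories")
  if (any(sizes < 2L))
    stop("every category needs at least 2 members; undersized: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  d <- pairwise_distances(aln, names(partition))
  r <- .fst_from_dist(d, as.character(partition))
  if (r$hb == 0) stop("undefined Fst: mean between-category distance is 0")
  structure(c(r, list(categories = levels(partition))), class = "fst_result")
}

#' Permutation test for Fst
#'
#' Shuffles category labels among records (preserving category sizes),
#' recomputes Fst for each permutation, and reports the add-one permutation
#' p-value `(#{Fst_perm >= Fst_obs} + 1) / (n_permutations + 1)`.
#' Reproducible under `seed`.
#'
#' @param aln a [coding_alignment()].
#' @param partition as in [hudson_fst()].
#' @param n_permutations number of label permutations (>= 1).
#' @param seed integer seed for the permutation stream (required).
#' @return object of class `fst_result` with additional elements `p_value`,
#'   `n_permutations`, `seed`, `perm_mean_fst`.
#' @export
fst_permutation_test <- function(aln, partition, n_permutations = 10000,
                                 seed) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  partition <- .partition_factor(aln, partition)
  obs <- hudson_fst(aln, partition)
  d <- pairwise_distances(aln, names(partition))
  labels <- as.character(partition)
  set.seed(as.integer(seed))
  perm_fst <- vapply(seq_len(n_permutations), function(i) {
    .fst_from_dist(d, sample(labels))$fst
  }, numeric(1))
  p <- (sum(perm_fst >= obs$fst) + 1) / (n_permutations + 1)
  out <- unclass(obs)
  out$p_value <- p
  out$n_permutations <- as.integer(n_permutations)
  out$seed <- as.integer(seed)
  out$perm_mean_fst <- mean(perm_fst)
  structure(out, class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Fst = %.4f  (Hw = %.4f, Hb = %.4f; %d within / %d between pairs)\n",
              x$fst, x$hw, x$hb, x$n_within_pairs, x$n_between_pairs))
  cat("Categories:", paste(x$categories, collapse = ", "), "\n")
  if (!is.null(x$p_value))
    cat(sprintf("Permutation p = %.4g  (%d permutations, seed %d)\n",
                x$p_value, x$n_permutations, x$seed))
  invisible(x)
}

#' Genotype-phenotype association report
#'
#' Categorizes phenotypes by the boundary configuration, maps accessions onto
#' sequence records, and reports the overall Fst with its permutation
#' p-value together with the pairwise category Fst matrix.  Accessions
#' without a sequence record are listed as dropped, not fatal; categories
#' with fewer than 2 sequenced members are excluded from Fst computation.
#'
#' @param aln a [coding_alignment()].
#' @param phenotypes data frame with columns `accession` and `erucic_pct`
#'   (e.g. from [read_phenotypes()]).
#' @param boundaries a [category_boundaries()].
#' @param n_permutations permutations for the overall test (0 skips it).
#' @param seed integer seed (required when `n_permutations > 0`).
#' @return object of class `association_report`: list with `assignments`
#'   (accession, erucic_pct, category, has_sequence), `dropped`, `overall`
#'   (an `fst_result` or `NA` when fewer than 2 usable categories),
#'   `pairwise_fst` (matrix), `boundaries`.
#' @export
association_report <- function(aln, phenotypes,
                               boundaries = category_boundaries(),
                               n_permutations = 10000, seed = NULL) {
  stopifnot(inherits(aln, "coding_alignment"))
  if (!all(c("accession", "erucic_pct") %in% names(phenotypes)))
    stop("phenotypes must have columns accession, erucic_pct")
  phen <- phenotypes
  phen$category <- categorize(phen$erucic_pct, boundaries)
  phen$has_sequence <- phen$accession %in% record_ids(aln)
  dropped <- phen$accession[!phen$has_sequence]
  usable <- phen[phen$has_sequence, , drop = FALSE]
  part <- stats::setNames(usable$category, usable$accession)
  sizes <- table(droplevels(part))
  ok_cats <- names(sizes)[sizes >= 2L]
  labels <- levels(droplevels(part))
  overall <- NA
  if (length(ok_cats) >= 2L) {
    keep <- names(part)[as.character(part) %in% ok_cats]
    sub_part <- droplevels(part[keep])
    overall <- if (n_permutations > 0) {
      if (is.null(seed)) stop("seed is required when permutations are requested")
      fst_permutation_test(aln, sub_part, n_permutations, seed)
    } else hudson_fst(aln, sub_part)
  }
  k <- length(labels)
  pw <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (labels[i] %in% ok_cats && labels[j] %in% ok_cats) {
          keep <- names(part)[as.character(part) %in% labels[c(i, j)]]
          f <- tryCatch(hudson_fst(aln, droplevels(part[keep])),
                        error = function(e) NULL)
          if (!is.null(f)) pw[i, j] <- pw[j, i] <- f$fst
        }
      }
    }
  }
  structure(list(assignments = phen, dropped = dropped, overall = overall,
                 pairwise_fst = pw, boundaries = boundaries,
                 n_permutations = n_permutations, seed = seed),
            class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  cat("Phenotype-genotype association\n")
  cat("  accessions:", nrow(x$assignments), " with sequence:",
      sum(x$assignments$has_sequence), " dropped:", length(x$dropped), "\n")
  cat("  category sizes:",
      paste(names(table(x$assignments$category)),
            table(x$assignments$category), sep = "=", collapse = "  "), "\n")
  if (inherits(x$overall, "fst_result")) {
    cat("Overall: ")
    print(x$overall)
  } else {
    cat("Overall Fst not applicable (fewer than 2 usable categories)\n")
  }
  cat("Pairwise Fst:\n")
  print(round(x$pairwise_fst, 4))
  invisible(x)
}
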