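## Pairwise distances, nucleotide diversity, between-group divergence,
## Nei-Gojobori Ka/Ks and sliding-window silent-site diversity.

## columns usable for a set of records: no gap, no N in any of them
.shared_sites <- function(mat) {
  ok <- colSums(mat == "-" | mat == "N") == 0L
  which(ok)
}

.pdist_chars <- function(x, y) {
  comp <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  n <- sum(comp)
  if (n == 0L) stop("zero comparable sites between the two sequences")
  sum(x[comp] != y[comp]) / n
}

#' Uncorrected pairwise distance between two aligned sequences
#'
#' Proportion of differing sites among sites where neither sequence carries a
#' gap or `N` (pairwise deletion).
#'
#' @param a,b either two record ids (when `aln` is given), or two aligned
#'   sequences as strings / character vectors.
#' @param aln optional [coding_alignment()] holding the records.
#' @return proportion of differing compared sites, in `[0, 1]`.
#' @examples
#' p_distance("ACGT", "ACGA")
#' @export
p_distance <- function(a, b, aln = NULL) {
  if (!is.null(aln)) {
    stopifnot(inherits(aln, "coding_alignment"))
    x <- aln$mat[a, ]; y <- aln$mat[b, ]
  } else {
    x <- if (length(a) == 1L) strsplit(toupper(a), "")[[1]] else toupper(a)
    y <- if (length(b) == 1L) strsplit(toupper(b), "")[[1]] else toupper(b)
    if (length(x) != length(y)) stop("sequences have unequal lengths")
  }
  .pdist_chars(x, y)
}

#' Matrix of pairwise distances
#'
#' @param aln a [coding_alignment()].
#' @param subset optional record ids (default: all records).
#' @param columns optional column indices to restrict the comparison to.
#' @return symmetric numeric matrix of pairwise-deletion p-distances.
#' @export
pairwise_distances <- function(aln, subset = NULL, columns = NULL) {
  stopifnot(inherits(aln, "coding_alignment"))
  ids <- if (is.null(subset)) record_ids(aln) else subset
  mat <- aln$mat[ids, , drop = FALSE]
  if (!is.null(columns)) mat <- mat[, columns, drop = FALSE]
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- .pdist_chars(mat[i, ], mat[j, ])
    }
  }
  d
}

## mean pairwise difference per shared site, complete deletion across mat
.pi_complete <- function(mat) {
  sites <- .shared_sites(mat)
  n <- nrow(mat)
  if (length(sites) == 0L) stop("no shared gap- and N-free sites")
  sub <- mat[, sites, drop = FALSE]
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) total <- total + sum(sub[i, ] != sub[j, ])
  }
  n_pairs <- n * (n - 1) / 2
  list(pi = total / n_pairs / length(sites), n_pairs = n_pairs,
       n_sites = length(sites))
}

#' Nucleotide diversity (pi)
#'
#' Mean per-site pairwise difference among the sequences of `subset`, using
#' the equal-weight mean-pairwise estimator over the shared site set
#' (complete deletion: columns with a gap or `N` in any subset record are
#' dropped, so site counts are reproducible).
#'
#' @param aln a [coding_alignment()].
#' @param subset record ids (>= 2); default all records.
#' @return object of class `diversity_result`: list with `pi`,
#'   `n_sequences`, `n_pairs`, `n_sites_used`.
#' @examples
#' aln <- coding_alignment(c(a = "AAAA", b = "AAAT", c = "AATT"),
#'                         coding_offset = 1)
#' nucleotide_diversity(aln)$pi
#' @export
nucleotide_diversity <- function(aln, subset = NULL) {
  stopifnot(inherits(aln, "coding_alignment"))
  ids <- if (is.null(subset)) record_ids(aln) else subset
  if (length(ids) < 2L) stop("subset must contain at least 2 sequences")
  r <- .pi_complete(aln$mat[ids, , drop = FALSE])
  structure(list(pi = r$pi, n_sequences = length(ids), n_pairs = r$n_pairs,
                 n_sites_used = r$n_sites),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("pi = %.4f  (%d sequences, %d pairs, %d sites)\n",
              x$pi, x$n_sequences, x$n_pairs, x$n_sites_used))
  invisible(x)
}

#' Between-group divergence (pi_between and Dxy)
#'
#' `pi_between` is the mean per-site pairwise difference over all
#' cross-group sequence pairs, computed on the shared site set of the pooled
#' groups (complete deletion); `dxy` applies the Jukes-Cantor correction.
#' When `pi_between >= 3/4` the correction is undefined and `dxy` is `NA`
#' with a warning.
#'
#' @param aln a [coding_alignment()].
#' @param group_a,group_b disjoint, non-empty character vectors of record
#'   ids.
#' @return object of class `divergence_result`: list with `pi_between`,
#'   `dxy`, `n_pairs`, `n_sites_used`.
#' @export
divergence <- function(aln, group_a, group_b) {
  stopifnot(inherits(aln, "coding_alignment"))
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  ids <- c(group_a, group_b)
  mat <- aln$mat[ids, , drop = FALSE]
  sites <- .shared_sites(mat)
  if (length(sites) == 0L) stop("no shared gap- and N-free sites")
  sub <- mat[, sites, drop = FALSE]
  total <- 0
  for (i in group_a) {
    for (j in group_b) total <- total + sum(sub[i, ] != sub[j, ])
  }
  n_pairs <- length(group_a) * length(group_b)
  pi_b <- total / n_pairs / length(sites)
  structure(list(pi_between = pi_b, dxy = jc_correction(pi_b),
                 n_pairs = n_pairs, n_sites_used = length(sites)),
            class = "divergence_result")
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf("pi_between = %.4f  Dxy = %s  (%d pairs, %d sites)\n",
              x$pi_between,
              if (is.na(x$dxy)) "NA" else sprintf("%.4f", x$dxy),
              x$n_pairs, x$n_sites_used))
  invisible(x)
}

#' Nei-Gojobori Ka/Ks
#'
#' Proportions of nonsynonymous and synonymous differences per
#' nonsynonymous/synonymous site (Nei & Gojobori 1986), Jukes-Cantor
#' corrected.  Fractional site counts per codon exclude substitutions to stop
#' codons from the synonymous fraction (so `N_sites + S_sites = 3 x` codons
#' used); differences per codon pair are averaged over all minimal
#' substitution pathways that avoid stop codons, with equal weight.  Pairwise
#' counts are pooled over all sequence pairs before correction.  Only codons
#' fully covered by the alignment and gap- and `N`-free in every subset
#' sequence are used.
#'
#' @param aln a [coding_alignment()].
#' @param subset record ids (>= 2); default all records.
#' @return object of class `kaks_result`: list with `n_codons_used`,
#'   `S_sites`, `N_sites` (mean fractional site counts), `sd`, `nd` (total
#'   differences over pairs), `ps`, `pn`, `ks`, `ka`, `ratio` (`NA` when `Ks
#'   = 0`), `n_pairs`.
#' @examples
#' aln <- coding_alignment(c(a = "GGAGGGGGA", b = "GGAGGGGGG"),
#'                         coding_offset = 1)
#' ka_ks(aln)
#' @export
ka_ks <- function(aln, subset = NULL) {
  stopifnot(inherits(aln, "coding_alignment"))
  ids <- if (is.null(subset)) record_ids(aln) else subset
  if (length(ids) < 2L) stop("subset must contain at least 2 sequences")
  mat <- aln$mat[ids, , drop = FALSE]
  rng <- covered_codons(aln)
  if (rng[1] > rng[2]) stop("no codon fully covered by the alignment")
  code <- genetic_code()
  syn_sites <- codon_syn_sites()
  ## codon strings per record for each fully covered codon
  codon_idx <- rng[1]:rng[2]
  cols <- codon_columns(aln, codon_idx)
  codmat <- matrix("", nrow = nrow(mat), ncol = length(codon_idx),
                   dimnames = list(ids, NULL))
  for (k in seq_along(codon_idx)) {
    cc <- cols[k, ]
    codmat[, k] <- paste0(mat[, cc[1]], mat[, cc[2]], mat[, cc[3]])
  }
  ## complete deletion at codon granularity: every sequence must carry a
  ## sense codon (stop codons in the observed data also drop the codon)
  usable <- apply(codmat, 2, function(x) all(x %in% sense_codons()))
  if (!any(usable)) stop("no complete shared codon across the subset")
  codmat <- codmat[, usable, drop = FALSE]
  L <- ncol(codmat)
  S_seq <- rowSums(matrix(syn_sites[codmat], nrow = nrow(codmat)))
  tabs <- codon_diff_tables()
  n <- length(ids)
  sum_sd <- 0; sum_nd <- 0; sum_S <- 0; sum_N <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      idx <- cbind(codmat[i, ], codmat[j, ])
      sum_sd <- sum_sd + sum(tabs$sd[idx])
      sum_nd <- sum_nd + sum(tabs$nd[idx])
      S_ij <- (S_seq[i] + S_seq[j]) / 2
      sum_S <- sum_S + S_ij
      sum_N <- sum_N + (3 * L - S_ij)
    }
  }
  n_pairs <- n * (n - 1) / 2
  ps <- sum_sd / sum_S
  pn <- sum_nd / sum_N
  if (ps >= 0.75 || pn >= 0.75)
    warning("pN or pS >= 3/4: Jukes-Cantor correction undefined")
  ks <- jc_correction(ps, warn = FALSE)
  ka <- jc_correction(pn, warn = FALSE)
  ratio <- if (!is.na(ks) && ks > 0 && !is.na(ka)) ka / ks else NA_real_
  structure(list(n_codons_used = L, S_sites = sum_S / n_pairs,
                 N_sites = sum_N / n_pairs, sd = sum_sd, nd = sum_nd,
                 ps = ps, pn = pn, ks = ks, ka = ka, ratio = ratio,
                 n_pairs = n_pairs),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("Nei-Gojobori Ka/Ks over %d pairs, %d codons\n",
              x$n_pairs, x$n_codons_used))
  cat(sprintf("  S sites = %.2f  N sites = %.2f  sd = %.2f  nd = %.2f\n",
              x$S_sites, x$N_sites, x$sd, x$nd))
  cat(sprintf("  Ks = %s  Ka = %s  Ka/Ks = %s\n",
              if (is.na(x$ks)) "NA" else sprintf("%.4f", x$ks),
              if (is.na(x$ka)) "NA" else sprintf("%.4f", x$ka),
              if (is.na(x$ratio)) "undefined" else sprintf("%.4f", x$ratio)))
  invisible(x)
}

#' Sliding-window silent-site diversity
#'
#' Profiles nucleotide diversity along the alignment over silent columns
#' only.  Windows contain `window_size` silent columns and successive windows
#' are displaced by `step` silent columns; a trailing partial window is
#' dropped.  Within each window, pi is computed over the window's silent
#' columns with complete deletion across the subset.
#'
#' @param aln a [coding_alignment()].
#' @param window_size number of silent columns per window.
#' @param step displacement between successive windows, in silent columns.
#' @param subset record ids (default all).
#' @return object of class `window_profile`: data frame with columns
#'   `window`, `first_silent`, `last_silent`, `start_column`, `end_column`,
#'   `mid_coding_position`, `pi_silent`.
#' @export
sliding_window_silent <- function(aln, window_size = 25, step = 10,
                                  subset = NULL) {
  stopifnot(inherits(aln, "coding_alignment"), window_size >= 2, step >= 1)
  ids <- if (is.null(subset)) record_ids(aln) else subset
  if (length(ids) < 2L) stop("need at least 2 sequences")
  silent_cols <- which(site_kinds(aln) == "silent")
  if (length(silent_cols) < window_size)
    stop("fewer silent columns (", length(silent_cols),
         ") than window_size (", window_size, ")")
  starts <- seq(1L, length(silent_cols) - window_size + 1L, by = step)
  mat <- aln$mat[ids, , drop = FALSE]
  rows <- lapply(seq_along(starts), function(w) {
    ord <- starts[w]:(starts[w] + window_size - 1L)
    cols <- silent_cols[ord]
    sub <- mat[, cols, drop = FALSE]
    keep <- .shared_sites(sub)
    pi_w <- if (length(keep) == 0L) NA_real_ else .pi_complete(sub)$pi
    data.frame(window = w, first_silent = starts[w],
               last_silent = starts[w] + window_size - 1L,
               start_column = cols[1], end_column = cols[window_size],
               mid_coding_position = aln$coding_offset - 1L +
                 as.integer(round((cols[1] + cols[window_size]) / 2)),
               pi_silent = pi_w)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("window_profile", "data.frame")
  attr(out, "window_size") <- window_size
  attr(out, "step") <- step
  attr(out, "n_silent_columns") <- length(silent_cols)
  out
}

#' Plot a silent-site diversity profile
#'
#' @param x a `window_profile` from [sliding_window_silent()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.window_profile <- function(x, ...) {
  graphics::plot(x$mid_coding_position, x$pi_silent, type = "o", pch = 16,
                 xlab = "coding position (window midpoint)",
                 ylab = expression(pi ~ "(silent sites)"), ...)
  invisible(x)
}
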