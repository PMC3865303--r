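## Group-diagnostic character states, frequency-threshold fixed differences,
## and the within/between group diversity report.

#' Build a grouping scheme from alignment metadata
#'
#' @param aln a [coding_alignment()].
#' @param by metadata column to group by (e.g. `"tribe"` or `"clade"`).
#' @param drop_na drop records with missing group labels (they stay
#'   ungrouped).
#' @return named list mapping group label to character vector of record ids.
#' @export
groups_from_metadata <- function(aln, by = "clade", drop_na = TRUE) {
  stopifnot(inherits(aln, "coding_alignment"))
  if (!by %in% names(aln$meta)) stop("no metadata column named ", by)
  lab <- aln$meta[[by]]
  ids <- aln$meta$record_id
  if (drop_na) { ids <- ids[!is.na(lab)]; lab <- lab[!is.na(lab)] }
  split(ids, lab)
}

.check_grouping <- function(aln, groups) {
  if (!length(groups) || is.null(names(groups)))
    stop("groups must be a named list of record-id vectors")
  all_ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_ids)) stop("groups must be pairwise disjoint")
  unknown <- setdiff(all_ids, record_ids(aln))
  if (length(unknown))
    stop("unknown record id(s) in grouping: ", paste(unknown, collapse = ", "))
  invisible(groups)
}

## per-column state frequencies among assessable (A/C/G/T) members
.state_freqs <- function(mat_rows, j) {
  col <- mat_rows[, j]
  col <- col[col %in% c("A", "C", "G", "T")]
  n <- length(col)
  if (n == 0L) return(NULL)
  tab <- table(factor(col, levels = c("A", "C", "G", "T")))
  list(freq = as.numeric(tab) / n, n = n,
       states = c("A", "C", "G", "T"))
}

#' Group-diagnostic character states
#'
#' A column is diagnostic for the focal group when all its gap- and `N`-free
#' members share one state and no gap- and `N`-free non-member (member of any
#' other group in the scheme) carries that state.  Columns where either side
#' has zero assessable members contribute nothing.  Gap characters are never
#' diagnostic states.
#'
#' @param aln a [coding_alignment()].
#' @param groups named list of record-id vectors (disjoint).
#' @param focal_group name of the group to scan.
#' @return data frame with columns `group`, `column`, `coding_position`,
#'   `state`; zero rows when nothing is diagnostic.
#' @export
diagnostic_sites <- function(aln, groups, focal_group) {
  .check_grouping(aln, groups)
  if (!focal_group %in% names(groups))
    stop("unknown group label: ", focal_group)
  members <- groups[[focal_group]]
  others <- setdiff(unlist(groups, use.names = FALSE), members)
  if (!length(members)) stop("focal group is empty")
  if (!length(others)) stop("no non-members to compare against")
  m_in <- aln$mat[members, , drop = FALSE]
  m_out <- aln$mat[others, , drop = FALSE]
  hits <- list()
  for (j in seq_len(ncol(aln$mat))) {
    s_in <- m_in[, j];  s_in <- s_in[s_in %in% c("A", "C", "G", "T")]
    s_out <- m_out[, j]; s_out <- s_out[s_out %in% c("A", "C", "G", "T")]
    if (!length(s_in) || !length(s_out)) next
    u <- unique(s_in)
    if (length(u) == 1L && !(u %in% s_out))
      hits[[length(hits) + 1L]] <- data.frame(
        group = focal_group, column = j,
        coding_position = j + aln$coding_offset - 1L, state = u,
        stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(group = character(), column = integer(),
                      coding_position = integer(), state = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Fixed differences between two groups under frequency thresholds
#'
#' For every column with at least `min_assessable` gap- and `N`-free members
#' in each group, a state is reported when its frequency strictly exceeds
#' `f_high` in one group and is strictly below `f_low` in the other (the
#' relaxed fixed-difference rule: a >70% allele frequency in one group but
#' <30% in the other, by default).  Passing `f_high = 1` and `f_low = 0`
#' selects strictly fixed differences (frequency exactly 1 vs exactly 0).
#' The column set is symmetric in group order; only the frequency labels
#' swap.
#'
#' @param aln a [coding_alignment()].
#' @param group_a,group_b character vectors of record ids.
#' @param f_high,f_low frequency thresholds, `f_low < f_high`.
#' @param min_assessable minimum assessable members per group per column.
#' @return data frame with columns `column`, `coding_position`, `state`,
#'   `freq_a`, `freq_b`, `n_a`, `n_b`.
#' @export
fixed_differences <- function(aln, group_a, group_b, f_high = 0.70,
                              f_low = 0.30, min_assessable = 2L) {
  stopifnot(inherits(aln, "coding_alignment"))
  if (f_low >= f_high) stop("parameter error: f_low must be < f_high")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  unknown <- setdiff(c(group_a, group_b), record_ids(aln))
  if (length(unknown))
    stop("unknown record id(s): ", paste(unknown, collapse = ", "))
  m_a <- aln$mat[group_a, , drop = FALSE]
  m_b <- aln$mat[group_b, , drop = FALSE]
  high <- function(f) if (f_high >= 1) f >= 1 else f > f_high
  low <- function(f) if (f_low <= 0) f <= 0 else f < f_low
  hits <- list()
  for (j in seq_len(ncol(aln$mat))) {
    fa <- .state_freqs(m_a, j); fb <- .state_freqs(m_b, j)
    if (is.null(fa) || is.null(fb) ||
        fa$n < min_assessable || fb$n < min_assessable) next
    for (k in 1:4) {
      if ((high(fa$freq[k]) && low(fb$freq[k])) ||
          (high(fb$freq[k]) && low(fa$freq[k])))
        hits[[length(hits) + 1L]] <- data.frame(
          column = j, coding_position = j + aln$coding_offset - 1L,
          state = fa$states[k], freq_a = fa$freq[k], freq_b = fb$freq[k],
          n_a = fa$n, n_b = fb$n, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(column = integer(), coding_position = integer(),
                      state = character(), freq_a = numeric(),
                      freq_b = numeric(), n_a = integer(), n_b = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Within/between group diversity and polymorphism report
#'
#' Assembles, for a grouping scheme, the per-group polymorphic-site counts
#' and matrix percentages, within-group nucleotide diversity, and the
#' between-group `pi_between` / `dxy` matrices.
#'
#' @param aln a [coding_alignment()].
#' @param groups named list of record-id vectors (>= 2 groups).
#' @param gap_policy passed to [classify_sites()] for the per-group counts.
#' @return object of class `group_report`: list with `per_group` (data
#'   frame: `group`, `n`, `polymorphic_sites`, `pct_polymorphic`, `pi`),
#'   `pi_between` and `dxy` (symmetric matrices with within-group pi on the
#'   diagonal).
#' @export
group_report <- function(aln, groups, gap_policy = "complete_deletion") {
  .check_grouping(aln, groups)
  if (length(groups) < 2L) stop("need at least 2 groups")
  gl <- names(groups)
  per <- lapply(gl, function(g) {
    ids <- groups[[g]]
    sub <- subset_records(aln, ids)
    cl <- classify_sites(sub, gap_policy = gap_policy)
    pi_g <- if (length(ids) >= 2L) nucleotide_diversity(aln, ids)$pi
            else NA_real_
    data.frame(group = g, n = length(ids),
               polymorphic_sites = cl$counts$total_polymorphic,
               pct_polymorphic = percent_of_matrix(
                 cl$counts$total_polymorphic, ncol(aln$mat)),
               pi = pi_g, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  k <- length(gl)
  pi_b <- matrix(NA_real_, k, k, dimnames = list(gl, gl))
  dxy <- pi_b
  for (i in seq_len(k)) {
    if (per$n[i] >= 2L) pi_b[i, i] <- dxy[i, i] <- per$pi[i]
    if (i == k) break
    for (j in (i + 1):k) {
      d <- divergence(aln, groups[[gl[i]]], groups[[gl[j]]])
      pi_b[i, j] <- pi_b[j, i] <- d$pi_between
      dxy[i, j] <- dxy[j, i] <- d$dxy
    }
  }
  structure(list(per_group = per, pi_between = pi_b, dxy = dxy,
                 n_columns = ncol(aln$mat), gap_policy = gap_policy),
            class = "group_report")
}

#' @export
print.group_report <- function(x, digits = 4, ...) {
  cat("Group report (", nrow(x$per_group), " groups, ", x$n_columns,
      " columns, ", x$gap_policy, ")\n", sep = "")
  df <- x$per_group
  df$pct_polymorphic <- sprintf("%.2f%%", df$pct_polymorphic)
  print(df, row.names = FALSE)
  cat("\npi (within on diagonal, pi_between off-diagonal):\n")
  print(round(x$pi_between, digits))
  cat("\nDxy (Jukes-Cantor corrected, off-diagonal):\n")
  print(round(x$dxy, digits))
  invisible(x)
}
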