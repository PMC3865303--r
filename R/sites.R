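## Per-column site classification: variability, parsimony information,
## gap/missing content, and the silent/replacement kind of each column.

#' Classify alignment columns
#'
#' Flags each column as variable (at least two distinct non-gap, non-`N`
#' states), parsimony-informative (at least two states each carried by at
#' least two records), or singleton, records gap and missing content, and
#' assigns each column a silent/replacement kind (see [site_kind()]).
#'
#' Matrix-level counts honour the gap policy.  Under `complete_deletion`
#' (the default, matching the convention of excluding indels from most
#' calculations) columns containing any gap are excluded from the counts.
#' Under `indel_as_one_site`, columns are counted regardless of gaps (gap
#' characters themselves are never states) and each internal indel event adds
#' one polymorphic site to the total.
#'
#' @param aln a [coding_alignment()].
#' @param gap_policy `"complete_deletion"` or `"indel_as_one_site"`.
#' @return object of class `site_classification`: list with `table` (one row
#'   per column: `column`, `coding_position`, `codon_index`, `codon_phase`,
#'   `has_gap`, `has_missing`, `n_states`, `is_variable`,
#'   `is_parsimony_informative`, `is_singleton`, `site_kind`, `counted`) and
#'   `counts` (named list: `n_columns`, `n_counted`, `variable`,
#'   `informative`, `singleton`, `indel_events`, `total_polymorphic`,
#'   `pct_variable`, `pct_informative`).
#' @examples
#' aln <- coding_alignment(c(a = "ATGGCT", b = "ATGGAT", c = "ATGGAT"),
#'                         coding_offset = 1)
#' classify_sites(aln)
#' @export
classify_sites <- function(aln,
                           gap_policy = c("complete_deletion",
                                          "indel_as_one_site")) {
  stopifnot(inherits(aln, "coding_alignment"))
  gap_policy <- match.arg(gap_policy)
  if (nrow(aln$mat) == 0L) stop("empty alignment")
  nc <- ncol(aln$mat)
  has_gap <- logical(nc); has_missing <- logical(nc)
  n_states <- integer(nc); variable <- logical(nc)
  informative <- logical(nc); singleton <- logical(nc)
  for (j in seq_len(nc)) {
    col <- aln$mat[, j]
    has_gap[j] <- any(col == "-")
    has_missing[j] <- any(col == "N")
    states <- col[col %in% c("A", "C", "G", "T")]
    tab <- table(states)
    n_states[j] <- length(tab)
    variable[j] <- length(tab) >= 2L
    informative[j] <- sum(tab >= 2L) >= 2L
    singleton[j] <- variable[j] && !informative[j]
  }
  coords <- column_to_coding(aln, seq_len(nc))
  kinds <- site_kinds(aln)
  counted <- if (gap_policy == "complete_deletion") !has_gap else rep(TRUE, nc)
  tab <- data.frame(coords, has_gap = has_gap, has_missing = has_missing,
                    n_states = n_states, is_variable = variable,
                    is_parsimony_informative = informative,
                    is_singleton = singleton, site_kind = kinds,
                    counted = counted, stringsAsFactors = FALSE)
  n_var <- sum(variable & counted)
  n_inf <- sum(informative & counted)
  n_indel <- if (gap_policy == "indel_as_one_site") {
    ev <- detect_indel_events(aln)
    sum(!ev$terminal)
  } else 0L
  counts <- list(
    n_columns = nc, n_counted = sum(counted),
    variable = n_var, informative = n_inf,
    singleton = sum(singleton & counted),
    indel_events = n_indel,
    total_polymorphic = n_var + n_indel,
    pct_variable = percent_of_matrix(n_var, nc),
    pct_informative = percent_of_matrix(n_inf, nc))
  structure(list(table = tab, counts = counts, gap_policy = gap_policy),
            class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  ct <- x$counts
  cat("Site classification (", x$gap_policy, "):\n", sep = "")
  cat(sprintf("  %d columns, %d counted under gap policy\n",
              ct$n_columns, ct$n_counted))
  cat(sprintf("  variable: %d (%.2f%%)  informative: %d (%.2f%%)  singleton: %d\n",
              ct$variable, ct$pct_variable, ct$informative,
              ct$pct_informative, ct$singleton))
  if (ct$indel_events > 0)
    cat(sprintf("  indel events counted as sites: %d (total polymorphic %d)\n",
                ct$indel_events, ct$total_polymorphic))
  kinds <- table(x$table$site_kind)
  cat("  site kinds:", paste(names(kinds), kinds, sep = "=", collapse = "  "),
      "\n")
  invisible(x)
}

#' Silent/replacement kind of alignment columns
#'
#' For a polymorphic column, the kind is `silent` when every observed variant
#' codon encodes the same amino acid as the column's majority codon,
#' `replacement` when every variant changes it, and `mixed` otherwise.  For a
#' monomorphic column, the kind reflects the mutational opportunity of the
#' majority codon at that position: `silent` when all three possible
#' substitutions are synonymous (and non-stop), `replacement` when none is,
#' `mixed` otherwise.  Columns whose codon is not fully covered by the
#' alignment, or with no record carrying a gap- and `N`-free codon, are
#' `not_assessable`.  Ties for the majority codon are broken by lexicographic
#' codon order.
#'
#' @param aln a [coding_alignment()].
#' @param column 1-based column index (scalar) for [site_kind()].
#' @return [site_kind()]: a single string; [site_kinds()]: a character vector
#'   over all columns, in order.
#' @export
site_kind <- function(aln, column) {
  column <- as.integer(column)
  if (length(column) != 1L || is.na(column) || column < 1L ||
      column > ncol(aln$mat))
    stop("column out of range")
  site_kinds(aln)[column]
}

#' @rdname site_kind
#' @export
site_kinds <- function(aln) {
  stopifnot(inherits(aln, "coding_alignment"))
  code <- genetic_code()
  nc <- ncol(aln$mat)
  out <- rep("not_assessable", nc)
  rng <- covered_codons(aln)
  if (rng[1] > rng[2]) return(out)
  b <- c("A", "C", "G", "T")
  for (ci in rng[1]:rng[2]) {
    cols <- codon_columns(aln, ci)
    codons <- paste0(aln$mat[, cols[1]], aln$mat[, cols[2]], aln$mat[, cols[3]])
    ok <- codons %in% names(code)
    if (!any(ok)) next
    codons <- codons[ok]
    tab <- table(codons)
    maj <- names(tab)[tab == max(tab)]
    maj <- sort(maj)[1]   # lexicographic tie-break
    maj_nts <- strsplit(maj, "")[[1]]
    aa_maj <- code[maj]
    for (phase in 1:3) {
      j <- cols[phase]
      obs_states <- unique(substr(codons, phase, phase))
      if (length(obs_states) >= 2L) {
        variants <- unique(codons[substr(codons, phase, phase) != maj_nts[phase]])
        same <- code[variants] == aa_maj & code[variants] != "*"
        out[j] <- if (all(same)) "silent"
                  else if (!any(same)) "replacement" else "mixed"
      } else {
        alt <- vapply(setdiff(b, maj_nts[phase]), function(nt) {
          v <- maj_nts; v[phase] <- nt; paste(v, collapse = "")
        }, character(1))
        syn <- code[alt] == aa_maj & code[alt] != "*"
        out[j] <- if (all(syn)) "silent"
                  else if (!any(syn)) "replacement" else "mixed"
      }
    }
  }
  out
}

#' Percentage of the alignment matrix, rounded half-up to 2 decimals
#'
#' @param count number of columns in the numerator (`0 <= count <=
#'   n_columns`).
#' @param n_columns total number of alignment columns.
#' @return `100 * count / n_columns`, rounded half-up to two decimals.
#' @examples
#' percent_of_matrix(489, 892)
#' @export
percent_of_matrix <- function(count, n_columns) {
  stopifnot(is.numeric(count), is.numeric(n_columns), n_columns > 0)
  if (any(count < 0) || any(count > n_columns))
    stop("count must be between 0 and n_columns")
  p <- 100 * count / n_columns
  floor(p * 100 + 0.5 + 1e-9) / 100
}
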