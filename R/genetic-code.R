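## Codon-level utilities shared by the site classifier, the Ka/Ks estimator
## and the sequence simulator.  The standard nuclear genetic code is built
## once from seqinr's translation tables and cached.

.erucaseq_cache <- new.env(parent = emptyenv())

#' Standard nuclear genetic code
#'
#' Returns the 64-entry codon to amino-acid map used throughout the package
#' (one-letter amino-acid codes, `"*"` for the three stop codons).
#'
#' @return Named character vector of length 64; names are codons over
#'   `A`, `C`, `G`, `T`, values are one-letter amino acids or `"*"`.
#' @examples
#' genetic_code()[c("ATG", "TGG", "TAA")]
#' @export
genetic_code <- function() {
  code <- .erucaseq_cache$genetic_code
  if (is.null(code)) {
    b <- c("A", "C", "G", "T")
    codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
    aa <- vapply(codons,
                 function(cd) seqinr::translate(strsplit(cd, "")[[1]]),
                 character(1))
    code <- stats::setNames(aa, codons)
    stopifnot(sum(code == "*") == 3L, sum(code != "*") == 61L)
    .erucaseq_cache$genetic_code <- code
  }
  code
}

#' @return character vector of the 61 sense codons
#' @noRd
sense_codons <- function() {
  code <- genetic_code()
  names(code)[code != "*"]
}

#' Translate codon strings
#'
#' @param codon character vector of 3-letter codons (uppercase `ACGT`).
#' @return one-letter amino acids (`"*"` for stops); `NA` for codons
#'   containing gaps, `N` or other non-`ACGT` characters.
#' @examples
#' translate_codon(c("TGC", "TGA", "TG-"))
#' @export
translate_codon <- function(codon) {
  code <- genetic_code()
  out <- unname(code[codon])
  out[is.na(match(codon, names(code)))] <- NA_character_
  out
}

## transition partner of each base (A<->G, C<->T)
.transition <- c(A = "G", G = "A", C = "T", T = "C")

is_transition <- function(from, to) .transition[from] == to

## Nei-Gojobori fractional synonymous site count per sense codon: at each of
## the three positions, the fraction of the three possible changes that are
## synonymous and do not create a stop.  Changes to stop codons count as
## nonsynonymous, so syn + nonsyn sites always total 3 per codon.
codon_syn_sites <- function() {
  ss <- .erucaseq_cache$codon_syn_sites
  if (is.null(ss)) {
    code <- genetic_code()
    sense <- sense_codons()
    b <- c("A", "C", "G", "T")
    ss <- vapply(sense, function(cd) {
      nts <- strsplit(cd, "")[[1]]
      aa0 <- code[cd]
      s <- 0
      for (pos in 1:3) {
        for (nt in setdiff(b, nts[pos])) {
          alt <- nts
          alt[pos] <- nt
          alt_cd <- paste(alt, collapse = "")
          if (code[alt_cd] != "*" && code[alt_cd] == aa0) s <- s + 1 / 3
        }
      }
      s
    }, numeric(1))
    .erucaseq_cache$codon_syn_sites <- ss
  }
  ss
}

## All orderings of the differing positions between two codons (at most 3! = 6)
.perms3 <- list(
  list(1L), list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

## Synonymous/nonsynonymous difference counts between two sense codons,
## averaged with equal weight over all minimal substitution pathways that do
## not pass through a stop codon (Nei & Gojobori 1986).  If every pathway is
## blocked by a stop, all pathways are used, with steps into or out of stop
## codons counted as nonsynonymous.
codon_pair_diffs <- function(codon_a, codon_b) {
  code <- genetic_code()
  a <- strsplit(codon_a, "")[[1]]
  bb <- strsplit(codon_b, "")[[1]]
  diff_pos <- which(a != bb)
  k <- length(diff_pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  paths <- .perms3[[k]]
  tally <- function(skip_stops) {
    sd_tot <- 0; nd_tot <- 0; n_ok <- 0L
    for (ord in paths) {
      cur <- a
      sd <- 0; nd <- 0; ok <- TRUE
      for (step in seq_len(k)) {
        pos <- diff_pos[ord[step]]
        nxt <- cur
        nxt[pos] <- bb[pos]
        aa_cur <- code[paste(cur, collapse = "")]
        aa_nxt <- code[paste(nxt, collapse = "")]
        if (skip_stops && (aa_cur == "*" || aa_nxt == "*")) { ok <- FALSE; break }
        if (aa_cur == aa_nxt && aa_cur != "*") sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) { sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd; n_ok <- n_ok + 1L }
    }
    if (n_ok == 0L) return(NULL)
    c(sd = sd_tot / n_ok, nd = nd_tot / n_ok)
  }
  res <- tally(skip_stops = TRUE)
  if (is.null(res)) res <- tally(skip_stops = FALSE)
  res
}

## Cached 61x61 lookup tables of pairwise sd/nd between sense codons.
codon_diff_tables <- function() {
  tabs <- .erucaseq_cache$codon_diff_tables
  if (is.null(tabs)) {
    sense <- sense_codons()
    n <- length(sense)
    sd <- matrix(0, n, n, dimnames = list(sense, sense))
    nd <- sd
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- codon_pair_diffs(sense[i], sense[j])
        sd[i, j] <- sd[j, i] <- d["sd"]
        nd[i, j] <- nd[j, i] <- d["nd"]
      }
    }
    tabs <- list(sd = sd, nd = nd)
    .erucaseq_cache$codon_diff_tables <- tabs
  }
  tabs
}

#' Jukes-Cantor distance correction
#'
#' Corrects a proportion of observed differences for multiple hits,
#' `-(3/4) log(1 - (4/3) p)`.  Monotone increasing on `[0, 3/4)`.
#'
#' @param p proportion(s) of differing sites, in `[0, 1]`.
#' @param warn warn (rather than error) and return `NA` when `p >= 3/4`,
#'   where the correction is undefined.
#' @return corrected distance(s); `NA` outside the domain when `warn = TRUE`.
#' @examples
#' jc_correction(1 / 3)
#' @export
jc_correction <- function(p, warn = TRUE) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- ifelse(p < 0.75, -0.75 * log(1 - (4 / 3) * p), NA_real_)
  out[!is.na(out) & out == 0] <- 0   # avoid -0
  if (anyNA(out[!is.na(p)]) && warn)
    warning("Jukes-Cantor correction undefined for p >= 3/4; returning NA")
  out
}
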