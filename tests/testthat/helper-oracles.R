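# Brute-force reference implementations, independent of the package's code
# paths: plain loops over columns/pairs, and recursive pathway enumeration
# for codon differences.  Used to freeze expected values and for
# oracle-equivalence checks on random matrices.

o_code <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      b <- c("A", "C", "G", "T")
      cods <- apply(expand.grid(b, b, b, stringsAsFactors = FALSE), 1,
                    paste, collapse = "")
      tab <<- stats::setNames(
        vapply(cods, function(cd) seqinr::translate(strsplit(cd, "")[[1]]),
               character(1)), cods)
    }
    tab
  }
})

o_pdist <- function(x, y) {
  nt <- c("A", "C", "G", "T")
  n <- 0L; d <- 0L
  for (k in seq_along(x)) {
    if (x[k] %in% nt && y[k] %in% nt) {
      n <- n + 1L
      if (x[k] != y[k]) d <- d + 1L
    }
  }
  d / n
}

# complete-deletion mean pairwise difference per site
o_pi <- function(mat) {
  keep <- apply(mat, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  sub <- mat[, keep, drop = FALSE]
  n <- nrow(sub); tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(sub[i, ] != sub[j, ])
  tot / (n * (n - 1) / 2) / ncol(sub)
}

o_pi_between <- function(mat, ia, ib) {
  keep <- apply(mat[c(ia, ib), , drop = FALSE], 2,
                function(col) all(col %in% c("A", "C", "G", "T")))
  sub <- mat[, keep, drop = FALSE]
  tot <- 0
  for (i in ia) for (j in ib) tot <- tot + sum(sub[i, ] != sub[j, ])
  tot / (length(ia) * length(ib)) / sum(keep)
}

o_classify_column <- function(col) {
  states <- col[col %in% c("A", "C", "G", "T")]
  tab <- table(states)
  list(variable = length(tab) >= 2,
       informative = sum(tab >= 2) >= 2)
}

o_diagnostic <- function(mat, groups, focal) {
  nt <- c("A", "C", "G", "T")
  members <- groups[[focal]]
  others <- setdiff(unlist(groups), members)
  hits <- list()
  for (j in seq_len(ncol(mat))) {
    sin <- mat[members, j]; sin <- sin[sin %in% nt]
    sout <- mat[others, j]; sout <- sout[sout %in% nt]
    if (length(sin) == 0 || length(sout) == 0) next
    if (length(unique(sin)) == 1 && !(sin[1] %in% sout))
      hits[[length(hits) + 1]] <- data.frame(column = j, state = sin[1])
  }
  if (!length(hits)) return(data.frame(column = integer(), state = character()))
  do.call(rbind, hits)
}

o_fixed <- function(mat, ga, gb, fh, fl, min_n = 2) {
  nt <- c("A", "C", "G", "T")
  hi <- function(f) if (fh >= 1) f >= 1 else f > fh
  lo <- function(f) if (fl <= 0) f <= 0 else f < fl
  hits <- list()
  for (j in seq_len(ncol(mat))) {
    a <- mat[ga, j]; a <- a[a %in% nt]
    b <- mat[gb, j]; b <- b[b %in% nt]
    if (length(a) < min_n || length(b) < min_n) next
    for (s in nt) {
      fa <- mean(a == s); fb <- mean(b == s)
      if ((hi(fa) && lo(fb)) || (hi(fb) && lo(fa)))
        hits[[length(hits) + 1]] <- data.frame(column = j, state = s,
                                               freq_a = fa, freq_b = fb)
    }
  }
  if (!length(hits))
    return(data.frame(column = integer(), state = character(),
                      freq_a = numeric(), freq_b = numeric()))
  do.call(rbind, hits)
}

# Recursive pathway enumeration of synonymous/nonsynonymous differences
# between two sense codons (character vectors of length 3).  Returns every
# minimal path as c(sd, nd, blocked); blocked paths pass through a stop.
o_paths <- function(a, b) {
  dp <- which(a != b)
  if (!length(dp)) return(list(c(sd = 0, nd = 0, blocked = 0)))
  code <- o_code()
  out <- list()
  for (p in dp) {
    nxt <- a; nxt[p] <- b[p]
    aa1 <- code[paste(a, collapse = "")]
    aa2 <- code[paste(nxt, collapse = "")]
    syn <- (aa1 == aa2) && aa1 != "*"
    blocked <- (aa1 == "*" || aa2 == "*")
    for (tail in o_paths(nxt, b)) {
      out[[length(out) + 1]] <- c(
        sd = unname(tail["sd"]) + as.numeric(syn),
        nd = unname(tail["nd"]) + as.numeric(!syn),
        blocked = max(unname(tail["blocked"]), as.numeric(blocked)))
    }
  }
  out
}

o_codon_diffs <- function(ca, cb) {
  paths <- o_paths(strsplit(ca, "")[[1]], strsplit(cb, "")[[1]])
  m <- do.call(rbind, paths)
  ok <- m[, "blocked"] == 0
  if (any(ok)) m <- m[ok, , drop = FALSE]
  c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
}

o_syn_sites <- function(codon) {
  code <- o_code()
  nts <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), nts[pos])) {
    alt <- nts; alt[pos] <- nt
    aa <- code[paste(alt, collapse = "")]
    if (aa != "*" && aa == code[codon]) s <- s + 1 / 3
  }
  s
}

# full NG86 for a pair of codon-string vectors
o_kaks_pair <- function(cods_a, cods_b) {
  S <- (sum(vapply(cods_a, o_syn_sites, 0)) +
        sum(vapply(cods_b, o_syn_sites, 0))) / 2
  N <- 3 * length(cods_a) - S
  sd <- 0; nd <- 0
  for (k in seq_along(cods_a)) {
    d <- o_codon_diffs(cods_a[k], cods_b[k])
    sd <- sd + d["sd"]; nd <- nd + d["nd"]
  }
  ps <- sd / S; pn <- nd / N
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  list(S = S, N = N, sd = unname(sd), nd = unname(nd), ps = unname(ps),
       pn = unname(pn), ks = jc(unname(ps)), ka = jc(unname(pn)))
}

# exact permutation p-value by exhaustive label assignment (small n only)
o_exact_perm_p <- function(d, labels) {
  fst <- function(lab) {
    same <- outer(lab, lab, "==")
    ut <- upper.tri(d)
    1 - mean(d[ut & same]) / mean(d[ut & !same])
  }
  obs <- fst(labels)
  perms <- combn(length(labels), sum(labels == labels[1]))
  hits <- 0; total <- 0
  for (k in seq_len(ncol(perms))) {
    lab <- rep(labels[which(labels != labels[1])[1]], length(labels))
    lab[perms[, k]] <- labels[1]
    total <- total + 1
    if (fst(lab) >= obs - 1e-12) hits <- hits + 1
  }
  hits / total
}
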