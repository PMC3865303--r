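## Synthetic data generator: pure-birth trees, codon-level sequence
## evolution under purifying selection, clade-targeted mutation injection,
## indels, and clade-correlated phenotypes.  Provides ground truth for every
## analysis in the package.

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate the structure of a Brassicaceae FAE1-style study: a
#' ~900-column in-frame coding alignment over 60 taxa falling into 5 clades,
#' evolved under strong purifying selection (`omega = 0.1`) with a
#' transition bias (`kappa = 2`), 16 fixed differences injected between the
#' first two clades, two occasional internal deletions (one frameshifting
#' 1-bp, one in-frame 3-bp), and clade-correlated seed erucic-acid contents
#' whose clade means sit inside the five default category intervals, well
#' separated from the category gaps.  `branch_scale` (expected substitution
#' attempts per nucleotide site per unit branch length) is calibrated so
#' total nucleotide diversity is near 0.10.
#'
#' @param n_taxa number of tips (>= 3).
#' @param n_codons number of codons (alignment has `3 * n_codons` columns).
#' @param n_clades number of clades to cut the tree into (2-5 typical).
#' @param branch_scale substitution attempts per site per unit branch length.
#' @param kappa transition/transversion rate ratio (>= 0).
#' @param omega acceptance probability of nonsynonymous changes relative to
#'   synonymous ones (0 = no replacement substitutions).
#' @param coding_offset coding position of column 1 of the output alignment.
#' @param n_injected_sites fixed differences to inject between
#'   `inject_clades[1]` and `inject_clades[2]` (0 disables injection).
#' @param inject_clades length-2 character vector of clade names, or `NULL`
#'   (default) for the two largest clades, which are guaranteed to have
#'   enough members for frequency-based detection.
#' @param n_indels number of random internal deletion events (lengths cycle
#'   through 1 and 3; 0 disables).
#' @param phenotype_means per-clade mean erucic-acid content (%), recycled
#'   across clades.
#' @param phenotype_sd standard deviation of contents around the clade mean.
#' @param seed integer seed making the whole dataset reproducible.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_taxa = 60, n_codons = 300, n_clades = 5,
                         branch_scale = 0.065, kappa = 2, omega = 0.1,
                         coding_offset = 1, n_injected_sites = 16,
                         inject_clades = NULL,
                         n_indels = 2,
                         phenotype_means = c(2, 15, 24, 35, 48),
                         phenotype_sd = 1, seed = 1) {
  stopifnot(n_taxa >= 3, n_codons >= 1, n_clades >= 1, omega >= 0,
            kappa >= 0, branch_scale >= 0, phenotype_sd >= 0)
  structure(list(n_taxa = as.integer(n_taxa), n_codons = as.integer(n_codons),
                 n_clades = as.integer(n_clades),
                 branch_scale = branch_scale, kappa = kappa, omega = omega,
                 coding_offset = as.integer(coding_offset),
                 n_injected_sites = as.integer(n_injected_sites),
                 inject_clades = inject_clades,
                 n_indels = as.integer(n_indels),
                 phenotype_means = phenotype_means,
                 phenotype_sd = phenotype_sd, seed = as.integer(seed)),
            class = "synth_config")
}

#' Simulate a rooted pure-birth tree
#'
#' @param n_taxa number of tips (>= 3).
#' @param seed optional integer seed (when `NULL`, the current RNG stream is
#'   used).
#' @return a rooted binary `phylo` object with tip labels `t01, t02, ...`
#'   and internal node labels `n1` (root), `n2, ...`.
#' @export
simulate_tree <- function(n_taxa, seed = NULL) {
  if (n_taxa < 3) stop("n_taxa must be >= 3")
  if (!is.null(seed)) set.seed(as.integer(seed))
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tr$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  tr$node.label <- paste0("n", seq_len(tr$Nnode))
  tr
}

#' Cut a tree into clades
#'
#' Deterministically partitions the tips into `n_clades` monophyletic groups
#' by repeatedly splitting the largest remaining clade at its root.
#'
#' @param tree a rooted binary `phylo`.
#' @param n_clades number of clades (between 1 and the number of tips).
#' @return named list `clade_1 ... clade_k` of tip-label vectors.
#' @export
clade_assignment <- function(tree, n_clades) {
  n_tip <- ape::Ntip(tree)
  stopifnot(n_clades >= 1, n_clades <= n_tip)
  children <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  tips_of <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    unlist(lapply(children(node), tips_of))
  }
  groups <- list(n_tip + 1L)  # root node
  while (length(groups) < n_clades) {
    sizes <- vapply(groups, function(nd) length(tips_of(nd)), integer(1))
    internal <- vapply(groups, function(nd) nd > n_tip, logical(1))
    if (!any(internal)) break
    sizes[!internal] <- -1L
    pick <- which.max(sizes)
    groups <- c(groups[-pick], as.list(children(groups[[pick]])))
  }
  out <- lapply(groups, tips_of)
  ## stable order: by smallest tip index
  ord <- order(vapply(out, function(x) min(match(x, tree$tip.label)),
                      integer(1)))
  out <- out[ord]
  names(out) <- paste0("clade_", seq_along(out))
  out
}

#' Evolve a coding alignment along a tree
#'
#' Codon-level simulation: the root sequence is drawn uniformly from sense
#' codons; along each branch, candidate single-nucleotide substitutions arise
#' at rate `branch_scale` per site per unit branch length, with the
#' transition partner weighted `kappa` relative to each transversion.  A
#' candidate is rejected if it creates a stop codon, accepted with
#' probability 1 if synonymous, and with probability `omega` if
#' nonsynonymous.  Uses the current RNG stream (seed it, or go through
#' [simulate_dataset()]).
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param config a [synth_config()].
#' @param clades optional clade assignment used to fill metadata (defaults
#'   to [clade_assignment()] with `config$n_clades`).
#' @return a [coding_alignment()] with clade labels in its metadata.
#' @export
evolve_alignment <- function(tree, config, clades = NULL) {
  stopifnot(inherits(config, "synth_config"))
  code <- genetic_code()
  sense <- sense_codons()
  n_cod <- config$n_codons
  n_sites <- 3L * n_cod
  b <- c("A", "C", "G", "T")
  root <- sample(sense, n_cod, replace = TRUE)
  if (!all(root %in% sense)) stop("invalid codon in root sequence")
  n_tip <- ape::Ntip(tree)
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[n_tip + 1L]] <- root
  edges <- ape::reorder.phylo(tree, "cladewise")
  elen <- edges$edge.length
  kappa <- config$kappa
  omega <- config$omega
  for (e in seq_len(nrow(edges$edge))) {
    parent <- edges$edge[e, 1]; child <- edges$edge[e, 2]
    s <- seqs[[parent]]
    n_events <- stats::rpois(1, config$branch_scale * elen[e] * n_sites)
    if (n_events > 0) {
      for (ev in seq_len(n_events)) {
        site <- sample.int(n_sites, 1L)
        ci <- (site + 2L) %/% 3L
        pos <- site - 3L * (ci - 1L)
        nts <- strsplit(s[ci], "")[[1]]
        cand <- setdiff(b, nts[pos])
        w <- ifelse(is_transition(nts[pos], cand), kappa, 1)
        nt <- sample(cand, 1L, prob = w)
        alt <- nts; alt[pos] <- nt
        alt_cd <- paste(alt, collapse = "")
        if (code[alt_cd] == "*") next
        syn <- code[alt_cd] == code[s[ci]]
        if (syn || stats::runif(1) < omega) s[ci] <- alt_cd
      }
    }
    seqs[[child]] <- s
  }
  tipseq <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""),
                   character(1))
  names(tipseq) <- tree$tip.label
  if (is.null(clades)) clades <- clade_assignment(tree, config$n_clades)
  clade_of <- stats::setNames(rep(names(clades), lengths(clades)),
                              unlist(clades, use.names = FALSE))
  meta <- data.frame(record_id = tree$tip.label,
                     tribe = unname(clade_of[tree$tip.label]),
                     genus = paste0("genus_", unname(clade_of[tree$tip.label])),
                     species = tree$tip.label,
                     clade = unname(clade_of[tree$tip.label]),
                     stringsAsFactors = FALSE)
  coding_alignment(tipseq, meta, config$coding_offset)
}

#' Build an injection specification creating known fixed differences
#'
#' Picks `n_sites` distinct covered codons and, for each, a single-nucleotide
#' edit of clade B's majority codon that yields a different sense codon.
#' Injecting the edited codon into every member of clade A and the majority
#' codon into every member of clade B makes the edited column a strict fixed
#' difference between the clades, while the codon's other two columns become
#' identical across both clades.
#'
#' @param aln a [coding_alignment()].
#' @param clades named list of record-id vectors.
#' @param clade_a,clade_b clade names; A receives the derived state.
#' @param n_sites number of fixed differences to create.
#' @return list with `spec` (data frame `clade`, `codon_index`, `codon`) and
#'   `truth_columns` (the alignment columns that differ after injection).
#' @export
make_fixed_difference_spec <- function(aln, clades, clade_a, clade_b,
                                       n_sites) {
  stopifnot(inherits(aln, "coding_alignment"))
  code <- genetic_code()
  b <- c("A", "C", "G", "T")
  rng <- covered_codons(aln)
  pool <- rng[1]:rng[2]
  if (length(pool) < n_sites) stop("not enough covered codons")
  picks <- sort(sample(pool, n_sites))
  members_b <- clades[[clade_b]]
  spec <- list(); truth <- integer(n_sites)
  for (k in seq_along(picks)) {
    ci <- picks[k]
    cols <- codon_columns(aln, ci)
    cods <- apply(aln$mat[members_b, cols, drop = FALSE], 1, paste, collapse = "")
    cods <- cods[cods %in% sense_codons()]
    base_cd <- if (length(cods)) names(sort(table(cods), decreasing = TRUE))[1]
               else sample(sense_codons(), 1)
    nts <- strsplit(base_cd, "")[[1]]
    repeat {
      pos <- sample.int(3L, 1L)
      nt <- sample(setdiff(b, nts[pos]), 1L)
      alt <- nts; alt[pos] <- nt
      alt_cd <- paste(alt, collapse = "")
      if (code[alt_cd] != "*") break
    }
    spec[[length(spec) + 1L]] <- data.frame(
      clade = c(clade_a, clade_b), codon_index = ci,
      codon = c(alt_cd, base_cd), stringsAsFactors = FALSE)
    truth[k] <- cols[pos]
  }
  list(spec = do.call(rbind, spec), truth_columns = truth)
}

#' Inject clade-wide codon states into an alignment
#'
#' Overwrites, for every member of the named clade, the codon at each stated
#' codon index with the target sense codon.
#'
#' @param aln a [coding_alignment()].
#' @param clades named list of record-id vectors.
#' @param injected_sites data frame with columns `clade`, `codon_index`,
#'   `codon` (sense codons); `NULL` or zero rows leaves the alignment
#'   unchanged.
#' @return the edited [coding_alignment()], with the applied specification
#'   attached as attribute `"edit_ledger"`.
#' @export
inject_clade_mutations <- function(aln, clades, injected_sites) {
  stopifnot(inherits(aln, "coding_alignment"))
  if (is.null(injected_sites) || nrow(injected_sites) == 0L) {
    attr(aln, "edit_ledger") <- injected_sites
    return(aln)
  }
  stopifnot(all(c("clade", "codon_index", "codon") %in% names(injected_sites)))
  if (!all(injected_sites$codon %in% sense_codons()))
    stop("injected codons must be sense codons")
  rng <- covered_codons(aln)
  if (any(injected_sites$codon_index < rng[1] |
          injected_sites$codon_index > rng[2]))
    stop("codon index out of covered range [", rng[1], ", ", rng[2], "]")
  unknown <- setdiff(unique(injected_sites$clade), names(clades))
  if (length(unknown)) stop("unknown clade(s): ", paste(unknown, collapse = ", "))
  for (r in seq_len(nrow(injected_sites))) {
    ids <- clades[[injected_sites$clade[r]]]
    cols <- codon_columns(aln, injected_sites$codon_index[r])
    nts <- strsplit(injected_sites$codon[r], "")[[1]]
    for (p in 1:3) aln$mat[ids, cols[p]] <- nts[p]
  }
  attr(aln, "edit_ledger") <- injected_sites
  aln
}

#' Assign clade-correlated phenotypes
#'
#' Draws erucic-acid contents from a normal distribution around each clade's
#' mean, truncated to `[0, 100]` by resampling.  Uses the current RNG stream
#' unless `seed` is given.
#'
#' @param clades named list of record-id vectors covering all accessions.
#' @param means per-clade means, recycled across clades in order.
#' @param sd common standard deviation (`0` gives the means exactly).
#' @param seed optional integer seed.
#' @return data frame with columns `accession`, `erucic_pct`, `clade`.
#' @export
assign_phenotypes <- function(clades, means = c(2, 15, 24, 35, 48), sd = 1,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  means <- rep_len(means, length(clades))
  rows <- lapply(seq_along(clades), function(k) {
    ids <- clades[[k]]
    vals <- stats::rnorm(length(ids), means[k], sd)
    while (any(vals < 0 | vals > 100)) {
      bad <- vals < 0 | vals > 100
      vals[bad] <- stats::rnorm(sum(bad), means[k], sd)
    }
    data.frame(accession = ids, erucic_pct = vals,
               clade = names(clades)[k], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a complete synthetic dataset
#'
#' Draws a tree, cuts it into clades, evolves a coding alignment under the
#' configured codon model, injects the configured fixed differences between
#' the two target clades, applies random internal deletions, and assigns
#' clade-correlated phenotypes.  Fully reproducible from `config$seed`.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_dataset` with elements `alignment`, `tree`,
#'   `clades`, `phenotypes`, `injection` (spec + ground-truth columns or
#'   `NULL`), `indels` (data frame or `NULL`), `config`.
#' @examples
#' ds <- simulate_dataset(synth_config(n_taxa = 12, n_codons = 40, seed = 7))
#' ds$alignment
#' @export
simulate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  tree <- simulate_tree(config$n_taxa, seed = NULL)
  clades <- clade_assignment(tree, config$n_clades)
  aln <- evolve_alignment(tree, config, clades)
  injection <- NULL
  if (config$n_injected_sites > 0) {
    target <- config$inject_clades
    if (is.null(target))
      target <- names(sort(lengths(clades), decreasing = TRUE))[1:2]
    if (!all(target %in% names(clades)))
      stop("inject_clades not present in the clade assignment")
    injection <- make_fixed_difference_spec(
      aln, clades, target[1], target[2], config$n_injected_sites)
    injection$clades <- target
    aln <- inject_clade_mutations(aln, clades, injection$spec)
  }
  indels <- NULL
  if (config$n_indels > 0) {
    nc <- ncol(aln$mat)
    lens <- rep_len(c(1L, 3L), config$n_indels)
    taxa <- sample(record_ids(aln), config$n_indels)
    avoid <- if (is.null(injection)) integer(0) else injection$truth_columns
    starts <- integer(config$n_indels)
    for (k in seq_len(config$n_indels)) {
      repeat {
        st <- sample(2:(nc - lens[k] - 1L), 1L)  # internal, never terminal
        if (!any((st:(st + lens[k] - 1L)) %in% avoid)) break
      }
      starts[k] <- st
      aln$mat[taxa[k], st:(st + lens[k] - 1L)] <- "-"
    }
    indels <- data.frame(record_id = taxa, start_column = starts,
                         length = lens, stringsAsFactors = FALSE)
  }
  phen <- assign_phenotypes(clades, config$phenotype_means,
                            config$phenotype_sd, seed = NULL)
  structure(list(alignment = aln, tree = tree, clades = clades,
                 phenotypes = phen, injection = injection, indels = indels,
                 config = config),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("Synthetic dataset (seed ", x$config$seed, ")\n", sep = "")
  print(x$alignment)
  cat("Clades:", paste(names(x$clades), lengths(x$clades), sep = "=",
                       collapse = "  "), "\n")
  if (!is.null(x$injection))
    cat("Injected fixed differences:", length(x$injection$truth_columns),
        "columns\n")
  if (!is.null(x$indels))
    cat("Indel events:", nrow(x$indels), "\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes the alignment (FASTA), metadata (TSV), phenotypes (TSV), tree
#' (newick) and a JSON ledger holding the configuration and the injection /
#' indel ground truth.
#'
#' @param dataset a `synth_dataset` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(alignment = file.path(dir, "alignment.fasta"),
             metadata = file.path(dir, "metadata.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             tree = file.path(dir, "tree.nwk"),
             ledger = file.path(dir, "ledger.json"))
  write_alignment(dataset$alignment, paths["alignment"], paths["metadata"])
  utils::write.table(dataset$phenotypes, paths["phenotypes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(dataset$tree, paths["tree"])
  ledger <- list(config = unclass(dataset$config),
                 clades = dataset$clades,
                 injection = if (is.null(dataset$injection)) NULL else
                   list(spec = dataset$injection$spec,
                        truth_columns = dataset$injection$truth_columns,
                        clades = dataset$injection$clades),
                 indels = dataset$indels)
  jsonlite::write_json(ledger, paths["ledger"], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}
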