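## One-config orchestration of the full analysis: site classification ->
## diversity/divergence -> diagnostic & fixed differences -> phenotype
## association -> sliding windows, with TSV/CSV reports and a JSON manifest.

#' Assemble (or load) a pipeline run configuration
#'
#' @param alignment path to the aligned FASTA input.
#' @param metadata path to the metadata TSV (`record_id`, `tribe`, `genus`,
#'   `species`, optional `clade`).
#' @param phenotypes optional path to the phenotype TSV (`accession`,
#'   `erucic_pct`); `NULL` skips the association stage.
#' @param tree optional newick path; when given together with
#'   `grouping = "tree:<label1>,<label2>"` clades are taken from labelled
#'   nodes, otherwise `grouping` names a metadata column.
#' @param out_dir output directory for reports.
#' @param grouping metadata column defining groups (default `"clade"`).
#' @param coding_offset coding position of alignment column 1.
#' @param gap_policy gap policy for site counts (see [classify_sites()]).
#' @param f_high,f_low fixed-difference frequency thresholds.
#' @param fixed_groups length-2 character vector naming the two groups to
#'   scan for fixed differences (default: the two largest groups).
#' @param boundaries numeric cut points for phenotype categories.
#' @param window_size,window_step sliding-window geometry in silent sites.
#' @param n_permutations permutations for the Fst test.
#' @param seed integer seed (required when `n_permutations > 0`).
#' @return list of class `run_config`.
#' @export
run_config <- function(alignment, metadata, phenotypes = NULL, tree = NULL,
                       out_dir = ".", grouping = "clade", coding_offset = 431,
                       gap_policy = "complete_deletion", f_high = 0.70,
                       f_low = 0.30, fixed_groups = NULL,
                       boundaries = c(10.5, 20.5, 31.11, 41.1),
                       window_size = 25, window_step = 10,
                       n_permutations = 10000, seed = NULL) {
  cfg <- list(alignment = alignment, metadata = metadata,
              phenotypes = phenotypes, tree = tree, out_dir = out_dir,
              grouping = grouping, coding_offset = coding_offset,
              gap_policy = gap_policy, f_high = f_high, f_low = f_low,
              fixed_groups = fixed_groups, boundaries = boundaries,
              window_size = window_size, window_step = window_step,
              n_permutations = n_permutations, seed = seed)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a JSON file
#' @param path JSON file with the fields of [run_config()].
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

.validate_config <- function(cfg) {
  for (f in c("alignment", "metadata", "phenotypes", "tree")) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p))
      stop("config error: ", f, " file not found: ", p)
  }
  if (!is.null(cfg$phenotypes) && cfg$n_permutations > 0 && is.null(cfg$seed))
    stop("config error: seed required when permutations are requested")
  invisible(cfg)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured inputs and writes
#' `site_report.tsv`, `site_summary.json`, `group_report.tsv`,
#' `divergence_matrix.tsv`, `kaks.tsv`, `windows.tsv`,
#' `diagnostic_sites.tsv`, `fixed_differences.tsv`, `indel_events.tsv`,
#' `association.csv`, `association_pairs.tsv` and `manifest.json` under
#' `cfg$out_dir`.  Outputs are a deterministic function of (inputs, config,
#' seed): the manifest carries no timestamps, so repeated runs are
#' byte-identical.
#'
#' @param cfg a [run_config()] (or path to a JSON config file).
#' @return invisibly, a list with the in-memory results and `paths` of all
#'   written files.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  .validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  aln <- .stage("read_alignment",
                read_alignment(cfg$alignment, cfg$metadata, cfg$coding_offset))
  say("read_alignment: %d records x %d columns", nrow(aln$mat), ncol(aln$mat))

  groups <- .stage("grouping", groups_from_metadata(aln, cfg$grouping))
  say("grouping: %d groups by %s (%s)", length(groups), cfg$grouping,
      paste(names(groups), lengths(groups), sep = "=", collapse = ", "))

  cl <- .stage("classify_sites", classify_sites(aln, cfg$gap_policy))
  paths["site_report"] <- .write_tsv(cl$table,
                                     file.path(cfg$out_dir, "site_report.tsv"))
  jsonlite::write_json(cl$counts, file.path(cfg$out_dir, "site_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths["site_summary"] <- file.path(cfg$out_dir, "site_summary.json")
  say("classify_sites: %d variable, %d informative, %d columns dropped by gap policy",
      cl$counts$variable, cl$counts$informative,
      cl$counts$n_columns - cl$counts$n_counted)

  indels <- .stage("detect_indel_events", detect_indel_events(aln))
  paths["indel_events"] <- .write_tsv(indels,
                                      file.path(cfg$out_dir, "indel_events.tsv"))

  grp <- .stage("group_report", group_report(aln, groups, cfg$gap_policy))
  paths["group_report"] <- .write_tsv(grp$per_group,
                                      file.path(cfg$out_dir, "group_report.tsv"))
  dmat <- data.frame(group = rownames(grp$pi_between),
                     round(grp$pi_between, 6), check.names = FALSE)
  dxymat <- data.frame(group = rownames(grp$dxy), round(grp$dxy, 6),
                       check.names = FALSE)
  paths["divergence_matrix"] <- .write_tsv(
    rbind(cbind(stat = "pi_between", dmat), cbind(stat = "dxy", dxymat)),
    file.path(cfg$out_dir, "divergence_matrix.tsv"))

  kk <- .stage("ka_ks", ka_ks(aln))
  paths["kaks"] <- .write_tsv(
    data.frame(n_codons = kk$n_codons_used, S_sites = kk$S_sites,
               N_sites = kk$N_sites, sd = kk$sd, nd = kk$nd, ps = kk$ps,
               pn = kk$pn, ks = kk$ks, ka = kk$ka, ratio = kk$ratio),
    file.path(cfg$out_dir, "kaks.tsv"))
  say("ka_ks: ratio %.4f over %d codons", kk$ratio, kk$n_codons_used)

  win <- .stage("sliding_window",
                tryCatch(sliding_window_silent(aln, cfg$window_size,
                                               cfg$window_step),
                         error = function(e) NULL))
  if (!is.null(win)) {
    paths["windows"] <- .write_tsv(as.data.frame(win),
                                   file.path(cfg$out_dir, "windows.tsv"))
    say("sliding_window: %d windows of %d silent sites (step %d)",
        nrow(win), cfg$window_size, cfg$window_step)
  } else say("sliding_window: skipped (fewer silent columns than window size)")

  diag <- .stage("diagnostic_sites", {
    out <- lapply(names(groups), function(g)
      diagnostic_sites(aln, groups, g))
    do.call(rbind, out)
  })
  paths["diagnostic_sites"] <- .write_tsv(
    diag, file.path(cfg$out_dir, "diagnostic_sites.tsv"))
  say("diagnostic_sites: %d sites across %d groups", nrow(diag),
      length(groups))

  fg <- cfg$fixed_groups
  if (is.null(fg)) fg <- names(sort(lengths(groups), decreasing = TRUE))[1:2]
  fd <- .stage("fixed_differences",
               fixed_differences(aln, groups[[fg[1]]], groups[[fg[2]]],
                                 cfg$f_high, cfg$f_low))
  paths["fixed_differences"] <- .write_tsv(
    fd, file.path(cfg$out_dir, "fixed_differences.tsv"))
  say("fixed_differences: %d states between %s and %s", nrow(fd), fg[1], fg[2])

  assoc <- NULL
  if (!is.null(cfg$phenotypes)) {
    assoc <- .stage("association", {
      phen <- read_phenotypes(cfg$phenotypes)
      association_report(aln, phen,
                         category_boundaries(cfg$boundaries),
                         cfg$n_permutations, cfg$seed)
    })
    paths["association"] <- file.path(cfg$out_dir, "association.csv")
    utils::write.csv(assoc$assignments, paths["association"],
                     row.names = FALSE, quote = FALSE)
    pwdf <- data.frame(category = rownames(assoc$pairwise_fst),
                       round(assoc$pairwise_fst, 6), check.names = FALSE)
    paths["association_pairs"] <- .write_tsv(
      pwdf, file.path(cfg$out_dir, "association_pairs.tsv"))
    if (inherits(assoc$overall, "fst_result"))
      say("association: overall Fst %.4f, p = %.4g", assoc$overall$fst,
          assoc$overall$p_value)
  }

  manifest <- list(
    package = "erucaseq",
    version = as.character(utils::packageVersion("erucaseq")),
    config = unclass(cfg),
    log = log,
    outputs = as.list(paths))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  paths["manifest"] <- file.path(cfg$out_dir, "manifest.json")

  invisible(list(alignment = aln, sites = cl, groups = grp, kaks = kk,
                 windows = win, diagnostic = diag, fixed = fd,
                 association = assoc, indels = indels, paths = paths,
                 log = log))
}
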