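## End-to-end orchestration: simulate -> align -> tree -> synapo ->
## profile -> amyloid -> annotate, each stage resumable from its files.
## Every inter-stage file is one of the package's standard plain-text
## formats, and a checksum manifest makes full-run determinism checkable.

#' Pipeline configuration
#'
#' @param seed master RNG seed; every random stage derives from it.
#' @param stages ordered subset of
#'   `c("simulate","align","tree","synapo","profile","amyloid","annotate")`.
#' @param simulate list: `n_tips`, `sequence_length`, `subs_per_site`.
#' @param tree list: `n_starts`, `outgroup` (`NULL` = the simulated
#'   outgroup recorded in the truth file).
#' @param profile list: `bin_width`.
#' @param amyloid list: `k`, `t_high`, `t_low`, `min_run`,
#'   `min_strand_len`.
#' @param external_aligner optional command for [align_adapter()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            stages = c("simulate", "align", "tree", "synapo",
                                       "profile", "amyloid", "annotate"),
                            simulate = list(),
                            tree = list(),
                            profile = list(),
                            amyloid = list(),
                            external_aligner = NULL) {
  defaults <- list(
    simulate = list(n_tips = 18, sequence_length = 240, subs_per_site = 0.2),
    tree = list(n_starts = 2, outgroup = NULL),
    profile = list(bin_width = 5),
    amyloid = list(k = 2, t_high = -4, t_low = -3, min_run = 3,
                   min_strand_len = 4))
  merge <- function(d, u) { d[names(u)] <- u; d }
  structure(list(seed = seed, stages = stages,
                 simulate = merge(defaults$simulate, simulate),
                 tree = merge(defaults$tree, tree),
                 profile = merge(defaults$profile, profile),
                 amyloid = merge(defaults$amyloid, amyloid),
                 external_aligner = external_aligner),
            class = "pipeline_config")
}

stage_files <- function(out_dir) {
  list(
    simulate = file.path(out_dir, c("sequences.fasta", "alignment.fasta",
                                    "true_tree.nwk", "domain_map.tsv",
                                    "truth.json")),
    align = file.path(out_dir, "aligned.fasta"),
    tree = file.path(out_dir, c("mp_tree.nwk", "mp_trees.nwk")),
    synapo = file.path(out_dir, "synapomorphies.tsv"),
    profile = file.path(out_dir, c("histogram.tsv", "domain_freq_whole.tsv",
                                   "domain_freq_branch.tsv")),
    amyloid = file.path(out_dir, c("ba4_regions.tsv", "amyloid_classes.tsv",
                                   "amyloid_profiles.tsv")),
    annotate = file.path(out_dir, "annotated_tree.nwk"))
}

is_monophyletic <- function(tree, tips) {
  if (length(tips) < 2) return(FALSE)
  if (!all(tips %in% tree$tip.label)) return(FALSE)
  setequal(descendant_tips(tree, ape::getMRCA(tree, tips)), tips)
}

#' Run the analysis pipeline
#'
#' Stages execute in order; each writes standard-format outputs under
#' `out_dir`.  With `resume = TRUE` a stage whose outputs already exist is
#' skipped.  A `manifest.json` (file -> md5) and a `run_log.txt` (stage
#' timings, parameter echo, record counts) are written at the end; rerun
#' with an identical config reproduces identical manifests.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created).
#' @param resume skip stages whose outputs exist.
#' @return invisible list: `out_dir`, `manifest` (named md5 vector),
#'   `log` (character).
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- stage_files(out_dir)
  log <- c(paste0("seed: ", config$seed),
           paste0("stages: ", paste(config$stages, collapse = " ")))
  note <- function(...) log <<- c(log, paste0(...))
  done <- function(stage) all(file.exists(files[[stage]]))
  for (stage in config$stages) {
    if (resume && done(stage)) { note(stage, ": resumed (outputs exist)"); next }
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({
      run_stage(stage, config, out_dir, files, note)
      TRUE
    }, error = function(e) {
      stop("pipeline halted in stage '", stage, "': ", conditionMessage(e),
           call. = FALSE)
    })
    note(stage, ": ", sprintf("%.2fs", proc.time()[["elapsed"]] - t0))
  }
  produced <- unlist(files[config$stages], use.names = FALSE)
  produced <- produced[file.exists(produced)]
  manifest <- tools::md5sum(produced)
  names(manifest) <- basename(names(manifest))
  jsonlite::write_json(as.list(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(list(out_dir = out_dir, manifest = manifest, log = log))
}

run_stage <- function(stage, config, out_dir, files, note) {
  switch(stage,
    simulate = {
      fam <- example_family_config(
        seed = config$seed,
        n_tips = config$simulate$n_tips,
        sequence_length = config$simulate$sequence_length,
        subs_per_site = config$simulate$subs_per_site)
      bundle <- evolve_family(fam$tree, fam$config)
      bundle$cleavage <- fam$cleavage
      write_truth_bundle2(bundle, out_dir)
      note("  simulated ", nrow(bundle$records), " sequences, ",
           length(fam$config$clades), " planted clades")
    },
    align = {
      records <- read_fasta(files$simulate[1])
      m <- align_adapter(records, config$external_aligner)
      write_fasta(m, files$align)
      note("  aligned ", nrow(m), " sequences to width ", ncol(m))
    },
    tree = {
      m <- read_alignment_fasta(files$align)
      res <- heuristic_search(m, n_starts = config$tree$n_starts,
                              seed = config$seed)
      truth <- jsonlite::read_json(files$simulate[5], simplifyVector = TRUE)
      og <- config$tree$outgroup %||% truth$outgroup
      cons <- if (length(res$trees) > 1) {
        consensus_tree(res$trees, rule = "majority")
      } else res$trees[[1]]
      rooted <- root_at_outgroup(cons, og)
      write_newick(rooted, files$tree[1])
      writeLines(vapply(res$trees, function(t) write_newick(t), ""),
                 files$tree[2])
      note("  best parsimony score ", res$score, " (",
           length(res$trees), " topologies); rooted on ", og)
    },
    synapo = {
      m <- read_alignment_fasta(files$align)
      tree <- read_newick(files$tree[1])
      tab <- detect_synapomorphies(tree, m)
      write_synapo_table(tab, files$synapo)
      note("  ", nrow(tab), " unambiguous synapomorphies at internal nodes")
    },
    profile = {
      m <- read_alignment_fasta(files$align)
      tree <- read_newick(files$tree[1])
      tab <- read_synapo_tsv(files$synapo, tree, ncol(m))
      prof <- column_frequencies(tab, ncol(m))
      write_profile_tsv(bin_histogram(prof, config$profile$bin_width),
                        files$profile[1])
      map <- read_domain_map(files$simulate[4])
      truth <- jsonlite::read_json(files$simulate[5], simplifyVector = TRUE)
      branches <- lapply(truth$clades, unlist)
      mono <- vapply(branches, is_monophyletic, TRUE, tree = tree)
      if (any(!mono)) {
        note("  dropped non-monophyletic branch(es): ",
             paste(names(branches)[!mono], collapse = ", "))
      }
      branches <- branches[mono]
      write_profile_tsv(
        domain_frequencies(tab, map, m, tree, branches, scope = "whole"),
        files$profile[2])
      write_profile_tsv(
        domain_frequencies(tab, map, m, tree, branches, scope = "branch"),
        files$profile[3])
      note("  profiled ", attr(prof, "total") %||% prof$total,
           " synapomorphies over ", length(branches), " branches")
    },
    amyloid = {
      m <- read_alignment_fasta(files$align)
      tree <- read_newick(files$tree[1])
      map <- read_domain_map(files$simulate[4])
      truth <- jsonlite::read_json(files$simulate[5], simplifyVector = TRUE)
      cl <- as.data.frame(truth$cleavage)
      regions <- extract_ba4_regions(m, map, cleavage = cl, tree = tree)
      write_region_table(regions, files$amyloid[1])
      a <- config$amyloid
      classes <- classify_taxa_amyloid(
        regions, k = a$k, t_high = a$t_high, t_low = a$t_low,
        min_run = a$min_run, min_strand_len = a$min_strand_len)
      utils::write.table(classes, files$amyloid[2], sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_amyloid_profiles(regions, files$amyloid[3], a)
      note("  classes: ",
           paste(names(table(classes$class)), table(classes$class),
                 sep = "=", collapse = ", "))
    },
    annotate = {
      tree <- read_newick(files$tree[1])
      cls <- utils::read.delim(files$amyloid[2], stringsAsFactors = FALSE)
      ann <- suppressMessages(annotate_tree_with_classes(
        tree, stats::setNames(cls$class, cls$id)))
      write_newick(ann, files$annotate)
      note("  annotated tree written")
    },
    stop("unknown stage: ", stage))
}

write_truth_bundle2 <- function(bundle, dir) {
  f <- write_truth_bundle(bundle, dir)
  if (!is.null(bundle$cleavage)) {
    # fold the cleavage annotation into truth.json (keeps the 5-file layout)
    truth <- jsonlite::read_json(f[["truth"]], simplifyVector = TRUE)
    truth$cleavage <- bundle$cleavage
    jsonlite::write_json(truth, f[["truth"]], auto_unbox = TRUE, digits = NA)
  }
  f
}

read_synapo_tsv <- function(path, tree, n_columns) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- data.frame(node = tab$node_id, column = tab$column_1based,
                    ancestral = tab$ancestral, derived = tab$derived,
                    stringsAsFactors = FALSE)
  attr(out, "n_columns") <- n_columns
  attr(out, "tree") <- tree
  class(out) <- c("synapo_table", "data.frame")
  out
}

write_region_table <- function(regions, path) {
  out <- data.frame(taxon = regions$id,
                    n_start = regions$n_start + 1L, n_end = regions$n_end,
                    c_start = regions$c_start + 1L, c_end = regions$c_end,
                    provenance = regions$provenance)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_amyloid_profiles <- function(regions, path, a) {
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    if (!nzchar(r$full_seq)) return(NULL)
    prof <- pasta_energy_profile(r$full_seq, min_strand_len = a$min_strand_len)
    cons <- consensus_predict(r$full_seq, k = a$k)
    segs <- classify_segments(prof, cons, a$t_high, a$t_low, a$min_run)
    cls <- rep("none", nchar(r$full_seq))
    for (s in seq_len(nrow(segs))) {
      cls[(segs$start[s] + 1L):segs$end[s]] <- segs$class[s]
    }
    data.frame(taxon = r$id, position_1based = seq_len(nchar(r$full_seq)),
               energy = round(prof$energy, 3), consensus = cons, class = cls)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
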