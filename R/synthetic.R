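## Synthetic gene-family generator.
##
## Emulates, at toy scale, a multi-clade gene family evolved along a known
## tree: domain-structured rate variation (fast ectodomain analogue, slow
## C-terminal analogue), planted clade-diagnostic substitutions on clade
## stem branches (known synapomorphies), and planted aggregation-prone
## hydrophobic segments at known coordinates.  Everything downstream is
## testable against the emitted truth bundle without any downloads.
##
## Model: site-independent uniform-exchange substitution on 20 states
## (Jukes-Cantor-like): along a branch of length t, a site with rate
## multiplier r substitutes with probability 1 - exp(-r * t), and the new
## state is uniform over the other 19.  Planted columns are frozen
## globally (rate 0) so the planted truth stays assertable; the derived
## state is applied once, on the designated clade's stem branch.

#' Simulate a reproducible Yule tree
#'
#' @param n_tips number of tips (>= 3).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param mode only `"yule"` (pure-birth) is implemented.
#' @return rooted binary `phylo` with branch lengths, tips `t1..tn`.
#' @export
simulate_tree <- function(n_tips, seed, mode = "yule") {
  mode <- match.arg(mode, "yule")
  if (n_tips < 3) stop("n_tips must be >= 3")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$tip.label <- sprintf("t%02d", seq_len(n_tips))
  tree
}

#' Simulation configuration
#'
#' @param sequence_length alignment length in residues.
#' @param domains optional [domain_map()] on the root sequence (reference =
#'   the root, so sequence coordinates = alignment columns; the generator
#'   introduces no indels).
#' @param domain_rates named numeric, per-domain rate multiplier (> 0);
#'   unlisted domains and inter-domain sites have rate 1.
#' @param clades named list of tip-label vectors: the "major branches";
#'   each must be monophyletic in the tree handed to [evolve_family()].
#' @param planted_synapomorphies data.frame `clade`, `column`, `derived`:
#'   diagnostic substitutions applied on each clade's stem branch.
#' @param amyloid_plants list of `list(ids =, position =, length =)`
#'   entries (0-based position): hydrophobic window replacements.
#' @param subs_per_site expected substitutions per (rate-1) site from root
#'   to tip; 0.2 by default, comfortably in the low-homoplasy regime.
#' @param root_weights residue sampling weights for the root sequence
#'   (named by residue; default uniform over the 20 amino acids).
#' @param hydrophobic_weights sampling weights for planted motifs (default
#'   heavy in I, V, F, L, A).
#' @param gene_labels optional named character: clade name -> gene label
#'   for the emitted records (defaults to the clade name when it is a known
#'   label, else `other`).
#' @param seed mandatory RNG seed.
#' @return config list of class `sim_config`.
#' @export
sim_config <- function(sequence_length = 300, domains = NULL,
                       domain_rates = NULL, clades = list(),
                       planted_synapomorphies = NULL,
                       amyloid_plants = list(),
                       subs_per_site = 0.2, root_weights = NULL,
                       hydrophobic_weights = c(I = 0.3, V = 0.3, F = 0.2,
                                               L = 0.15, A = 0.05),
                       gene_labels = NULL, seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  if (!is.null(domain_rates) && any(domain_rates <= 0)) {
    stop("domain rates must be > 0")
  }
  ps <- planted_synapomorphies
  if (!is.null(ps)) {
    stopifnot(all(c("clade", "column", "derived") %in% names(ps)))
    if (any(ps$column < 1L | ps$column > sequence_length)) {
      stop("planted column outside sequence length")
    }
    if (anyDuplicated(ps$column)) {
      stop("planted synapomorphy columns collide")
    }
    if (!all(ps$clade %in% names(clades))) {
      stop("planted synapomorphies refer to unknown clades")
    }
  }
  for (ap in amyloid_plants) {
    stopifnot(all(c("ids", "position", "length") %in% names(ap)))
    if (ap$position < 0 || ap$position + ap$length > sequence_length) {
      stop("amyloid plant window out of range")
    }
    if (!is.null(ps) &&
        any(ps$column - 1L >= ap$position &
            ps$column - 1L < ap$position + ap$length)) {
      stop("amyloid plant window collides with a planted synapomorphy column")
    }
  }
  structure(list(sequence_length = sequence_length, domains = domains,
                 domain_rates = domain_rates, clades = clades,
                 planted_synapomorphies = ps, amyloid_plants = amyloid_plants,
                 subs_per_site = subs_per_site, root_weights = root_weights,
                 hydrophobic_weights = hydrophobic_weights,
                 gene_labels = gene_labels, seed = seed),
            class = "sim_config")
}

#' Replace a window by a sampled aggregation-prone motif
#'
#' @param residues amino-acid string.
#' @param position 0-based window start.
#' @param length window length (0 leaves the sequence unchanged).
#' @param weights motif sampling weights (hydrophobic/beta-prone alphabet).
#' @param motif explicit motif string (overrides sampling); recycled plants
#'   across taxa of a clade pass the same motif.
#' @param seed optional seed for standalone use.
#' @return list: `residues` (modified), `motif`, `start`, `end` (0-based
#'   half-open).
#' @export
plant_amyloid_motif <- function(residues, position, length,
                                weights = c(I = 0.3, V = 0.3, F = 0.2,
                                            L = 0.15, A = 0.05),
                                motif = NULL, seed = NULL) {
  n <- nchar(residues)
  if (position < 0 || position + length > n) {
    stop("plant window [", position, ",", position + length,
         ") outside sequence of length ", n)
  }
  if (length == 0L) {
    return(list(residues = residues, motif = "", start = position,
                end = position))
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(motif)) {
    motif <- paste0(sample(names(weights), length, replace = TRUE,
                           prob = weights), collapse = "")
  }
  stopifnot(nchar(motif) == length)
  out <- paste0(substr(residues, 1, position), motif,
                substr(residues, position + length + 1L, n))
  list(residues = out, motif = motif, start = position,
       end = position + length)
}

#' Evolve a gene family along a tree with planted truth
#'
#' @param tree rooted binary `phylo` with branch lengths (see
#'   [simulate_tree()]); rescaled so the mean root-to-tip path equals
#'   `config$subs_per_site`.
#' @param config a [sim_config()].
#' @return truth bundle (class `truth_bundle`): `tree` (rescaled),
#'   `records` ([seq_set()]), `alignment` (no indels, so rows equal the
#'   sequences), `root_seq`, `domain_map`, `truth_synapo` (clade, node,
#'   column, ancestral, derived), `truth_amyloid` (id, start, end, motif),
#'   `mutation_log` (one row per substitution: child node, column, from,
#'   to, in traversal order), `outgroup` (a tip outside every planted
#'   clade, `NA` if none) and `config`.
#' @export
evolve_family <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"), ape::is.rooted(tree))
  set.seed(config$seed)
  L <- config$sequence_length
  ntip <- length(tree$tip.label)
  # validate clades and find stem nodes
  clade_mrca <- list()
  for (cn in names(config$clades)) {
    tips <- config$clades[[cn]]
    missing <- setdiff(tips, tree$tip.label)
    if (length(missing)) stop("clade ", cn, " tips not in tree: ",
                              paste(missing, collapse = ", "))
    if (length(tips) < 2) stop("clade ", cn, " needs >= 2 tips")
    mrca <- ape::getMRCA(tree, tips)
    desc <- descendant_tips(tree, mrca)
    if (!setequal(desc, tips)) {
      stop("clade ", cn, " is not monophyletic (MRCA also spans: ",
           paste(setdiff(desc, tips), collapse = ", "), ")")
    }
    clade_mrca[[cn]] <- mrca
  }
  # rescale branch lengths to the target expected substitutions per site
  depths <- ape::node.depth.edgelength(tree)
  mean_depth <- mean(depths[seq_len(ntip)])
  tree$edge.length <- tree$edge.length * config$subs_per_site / mean_depth
  # per-site rate multipliers
  rate <- rep(1, L)
  if (!is.null(config$domains) && !is.null(config$domain_rates)) {
    for (dn in intersect(names(config$domain_rates), config$domains$name)) {
      iv <- config$domains[config$domains$name == dn, ]
      rate[(iv$start + 1L):iv$end] <- config$domain_rates[[dn]]
    }
  }
  ps <- config$planted_synapomorphies
  if (!is.null(ps)) rate[ps$column] <- 0      # frozen planted columns
  # root sequence; planted columns must start in a state != derived
  w <- config$root_weights
  if (is.null(w)) w <- stats::setNames(rep(1, 20), AA_ALPHABET20)
  root_seq <- sample(names(w), L, replace = TRUE, prob = w)
  truth_synapo <- NULL
  if (!is.null(ps)) {
    for (i in seq_len(nrow(ps))) {
      j <- ps$column[i]
      if (root_seq[j] == ps$derived[i]) {
        root_seq[j] <- sample(setdiff(AA_ALPHABET20, ps$derived[i]), 1)
      }
    }
    truth_synapo <- data.frame(
      clade = ps$clade,
      node = vapply(ps$clade, function(cn) clade_mrca[[cn]], 0L),
      column = ps$column,
      ancestral = root_seq[ps$column],
      derived = ps$derived, stringsAsFactors = FALSE)
  }
  # walk the tree
  ti <- tree_index(tree)
  elen <- numeric(max(tree$edge)); elen[tree$edge[, 2]] <- tree$edge.length
  seqs <- vector("list", ti$nnode)
  seqs[[ti$root]] <- root_seq
  log_rows <- list()
  stem_plants <- if (is.null(ps)) NULL else
    split(seq_len(nrow(ps)), vapply(ps$clade, function(cn) clade_mrca[[cn]], 0L))
  for (v in ti$preorder) {
    if (v == ti$root) next
    s <- seqs[[ti$parent[v]]]
    p_sub <- 1 - exp(-rate * elen[v])
    hit <- which(stats::runif(L) < p_sub)
    for (j in hit) {
      new <- sample(setdiff(AA_ALPHABET20, s[j]), 1)
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        node = v, column = j, from = s[j], to = new)
      s[j] <- new
    }
    key <- as.character(v)
    if (!is.null(stem_plants) && key %in% names(stem_plants)) {
      for (i in stem_plants[[key]]) {
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          node = v, column = ps$column[i], from = s[ps$column[i]],
          to = ps$derived[i])
        s[ps$column[i]] <- ps$derived[i]
      }
    }
    seqs[[v]] <- s
  }
  tip_seqs <- vapply(seq_len(ntip), function(i) paste0(seqs[[i]], collapse = ""), "")
  names(tip_seqs) <- tree$tip.label
  # amyloid plants on tip sequences
  truth_amyloid <- list()
  for (ap in config$amyloid_plants) {
    motif <- paste0(sample(names(config$hydrophobic_weights), ap$length,
                           replace = TRUE, prob = config$hydrophobic_weights),
                    collapse = "")
    for (id in ap$ids) {
      if (!id %in% names(tip_seqs)) stop("amyloid plant id not a tip: ", id)
      res <- plant_amyloid_motif(tip_seqs[[id]], ap$position, ap$length,
                                 motif = motif)
      tip_seqs[[id]] <- res$residues
      truth_amyloid[[length(truth_amyloid) + 1L]] <- data.frame(
        id = id, start = res$start, end = res$end, motif = res$motif,
        stringsAsFactors = FALSE)
    }
  }
  truth_amyloid <- if (length(truth_amyloid)) {
    do.call(rbind, truth_amyloid)
  } else {
    data.frame(id = character(0), start = integer(0), end = integer(0),
               motif = character(0))
  }
  # records: gene label = clade name when known
  tip_clade <- rep(NA_character_, ntip); names(tip_clade) <- tree$tip.label
  for (cn in names(config$clades)) tip_clade[config$clades[[cn]]] <- cn
  glab <- function(cn) {
    if (is.na(cn)) return("other")
    if (!is.null(config$gene_labels) && cn %in% names(config$gene_labels)) {
      return(config$gene_labels[[cn]])
    }
    if (cn %in% KNOWN_GENE_LABELS) cn else "other"
  }
  records <- suppressWarnings(seq_set(
    id = tree$tip.label,
    taxon = paste0("Taxon ", sub("^t", "", tree$tip.label)),
    gene_label = vapply(tip_clade, glab, ""),
    residues = unname(tip_seqs)))
  aln <- aligned_matrix(tip_seqs, meta = records[, c("id", "taxon", "gene_label")])
  outgroup <- setdiff(tree$tip.label, unlist(config$clades))
  structure(list(
    tree = tree, records = records, alignment = aln,
    root_seq = paste0(root_seq, collapse = ""),
    domain_map = config$domains,
    truth_synapo = truth_synapo %||%
      data.frame(clade = character(0), node = integer(0), column = integer(0),
                 ancestral = character(0), derived = character(0)),
    truth_amyloid = truth_amyloid,
    mutation_log = if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(node = integer(0), column = integer(0),
                 from = character(0), to = character(0)),
    outgroup = if (length(outgroup)) outgroup[1] else NA_character_,
    config = config), class = "truth_bundle")
}

#' Write a truth bundle to a directory (5 plain-text files)
#'
#' `sequences.fasta`, `alignment.fasta`, `true_tree.nwk`,
#' `domain_map.tsv`, `truth.json`.
#' @param bundle [evolve_family()] output.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
write_truth_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- c(sequences = file.path(dir, "sequences.fasta"),
         alignment = file.path(dir, "alignment.fasta"),
         tree = file.path(dir, "true_tree.nwk"),
         domains = file.path(dir, "domain_map.tsv"),
         truth = file.path(dir, "truth.json"))
  write_fasta(bundle$records, f[["sequences"]])
  write_fasta(bundle$alignment, f[["alignment"]])
  write_newick(bundle$tree, f[["tree"]])
  if (!is.null(bundle$domain_map)) {
    write_domain_map(bundle$domain_map, f[["domains"]])
  } else {
    writeLines("# reference=NA", f[["domains"]])
  }
  jsonlite::write_json(
    list(truth_synapo = bundle$truth_synapo,
         truth_amyloid = bundle$truth_amyloid,
         outgroup = bundle$outgroup,
         clades = bundle$config$clades,
         seed = bundle$config$seed),
    f[["truth"]], auto_unbox = TRUE, digits = NA)
  f
}

#' Greedily choose disjoint planted clades from a tree
#'
#' Picks non-nested monophyletic clades whose sizes fall in the requested
#' range, largest-first, leaving at least one tip outside every clade to
#' serve as outgroup.
#'
#' @param tree `phylo`.
#' @param n number of clades wanted.
#' @param min_size,max_size allowed clade sizes.
#' @return named list (`cladeA`, `cladeB`, ...) of tip-label vectors.
#' @export
choose_planted_clades <- function(tree, n, min_size = 2, max_size = 5) {
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 2L):(ntip + tree$Nnode)    # exclude the root
  sets <- lapply(nodes, function(v) descendant_tips(tree, v))
  sizes <- lengths(sets)
  ok <- which(sizes >= min_size & sizes <= max_size)
  ok <- ok[order(-sizes[ok])]
  chosen <- list()
  used <- character(0)
  for (i in ok) {
    if (length(chosen) == n) break
    if (length(intersect(sets[[i]], used))) next
    if (length(used) + sizes[i] >= ntip) next  # keep an outgroup tip
    chosen[[sprintf("clade%s", LETTERS[length(chosen) + 1L])]] <- sets[[i]]
    used <- c(used, sets[[i]])
  }
  if (length(chosen) < n) {
    stop("could only find ", length(chosen), " disjoint clades of size ",
         min_size, "-", max_size)
  }
  chosen
}
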