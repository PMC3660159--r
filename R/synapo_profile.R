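## Synapomorphy frequency profiling: per-column percentages, 5-residue
## binned histograms, and per-domain percentage tables for the whole tree
## and for named major branches.
##
## Two denominator conventions exist and both are provided:
##   scope = "whole":  percentages of ALL synapomorphies on the tree
##                     (the whole-tree table convention);
##   scope = "branch": percentages of the synapomorphies within each branch
##                     (the per-branch table convention).

#' Per-column synapomorphy frequencies
#'
#' @param table a `synapo_table` from [detect_synapomorphies()].
#' @param n_columns number of alignment columns (defaults to the table's
#'   `n_columns` attribute).
#' @return list of class `freq_profile`: `counts` (length `n_columns`),
#'   `percent`, `total`, and `empty` flag (all-zero profile).
#' @export
column_frequencies <- function(table, n_columns = attr(table, "n_columns")) {
  if (is.null(n_columns)) stop("n_columns not supplied")
  if (nrow(table) && max(table$column) > n_columns) {
    stop("synapomorphy column ", max(table$column),
         " exceeds n_columns = ", n_columns)
  }
  counts <- tabulate(table$column, nbins = n_columns)
  total <- sum(counts)
  percent <- if (total > 0) 100 * counts / total else rep(0, n_columns)
  structure(list(counts = counts, percent = percent, total = total,
                 n_columns = n_columns, empty = total == 0L),
            class = "freq_profile")
}

#' Bin a column-frequency profile
#'
#' Bins are half-open windows of `bin_width` alignment columns anchored at
#' column 0 (0-based), i.e. `[0,5), [5,10), ...` for the default width; the
#' final bin may be partial.  Bin values are exact sums of member-column
#' percentages, so total mass is conserved.
#'
#' @param profile a [column_frequencies()] result.
#' @param bin_width integer >= 1 (5 matches the published histograms).
#' @return data.frame with `bin_start`, `bin_end` (0-based half-open) and
#'   `percent`.
#' @export
bin_histogram <- function(profile, bin_width = 5) {
  stopifnot(inherits(profile, "freq_profile"), bin_width >= 1)
  n <- profile$n_columns
  bin_of <- ((seq_len(n) - 1L) %/% bin_width)    # 0-based column index
  percent <- as.numeric(tapply(profile$percent, bin_of, sum))
  starts <- sort(unique(bin_of)) * bin_width
  data.frame(bin_start = starts,
             bin_end = pmin(starts + bin_width, n),
             percent = percent)
}

## clades ----------------------------------------------------------------------

#' Internal nodes belonging to a named clade
#'
#' @param tree rooted `phylo`.
#' @param tips tip labels; must be monophyletic in `tree`.
#' @param include_stem count the clade's MRCA node (whose entering branch is
#'   the clade's stem) as inside the clade.
#' @return integer vector of ape node numbers.
#' @export
clade_nodes <- function(tree, tips, include_stem = TRUE) {
  stopifnot(length(tips) >= 1)
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing)) stop("tips not in tree: ", paste(missing, collapse = ", "))
  ntip <- length(tree$tip.label)
  if (length(tips) == 1L) return(integer(0))      # a single tip has no internal nodes
  mrca <- ape::getMRCA(tree, tips)
  desc <- descendant_tips(tree, mrca)
  extra <- setdiff(desc, tips)
  if (length(extra)) {
    stop("tip set is not monophyletic; clade of its MRCA also contains: ",
         paste(extra, collapse = ", "))
  }
  nodes <- internal_descendants(tree, mrca)
  if (include_stem) nodes else setdiff(nodes, mrca)
}

descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  ti <- tree_index(tree)
  out <- character(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (v <= ntip) out <- c(out, tree$tip.label[v]) else stack <- c(stack, ti$kids[[v]])
  }
  out
}

internal_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  ti <- tree_index(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (v > ntip) { out <- c(out, v); stack <- c(stack, ti$kids[[v]]) }
  }
  sort(out)
}

#' Restrict a synapomorphy table to a clade
#'
#' @inheritParams clade_nodes
#' @param table a `synapo_table`.
#' @return `synapo_table` containing only entries whose node lies inside the
#'   clade (stem-inclusive by default).
#' @export
branch_stratify <- function(table, tree, tips, include_stem = TRUE) {
  nodes <- clade_nodes(tree, tips, include_stem = include_stem)
  out <- table[table$node %in% nodes, , drop = FALSE]
  attr(out, "n_columns") <- attr(table, "n_columns")
  attr(out, "tree") <- tree
  class(out) <- class(table)
  out
}

#' Per-domain synapomorphy percentage table
#'
#' Synapomorphies are assigned to domains by alignment column (via the
#' reference-sequence projection of the domain map); a column inside several
#' overlapping domains counts once per domain, and columns outside every
#' domain fall into an implicit `inter-domain` row so totals reconcile.
#' Branches are named, disjoint, monophyletic tip sets; entries on nodes
#' outside every branch land in an `unassigned` column.
#'
#' @param table a `synapo_table`.
#' @param map a [domain_map()] whose reference row is in `m`.
#' @param m the aligned matrix the table was computed from.
#' @param tree rooted `phylo` (defaults to the table's tree attribute).
#' @param branches named list of tip-label vectors.
#' @param scope `"whole"`: every value is a percentage of all synapomorphies
#'   on the tree; `"branch"`: percentages of the synapomorphies within that
#'   branch (the whole-tree summary column is only present for `"whole"`).
#' @param include_stem passed to [clade_nodes()].
#' @return data.frame (rows = domains + `inter-domain`) of class
#'   `domain_freq_table` with attribute `scope`.
#' @export
domain_frequencies <- function(table, map, m, tree = attr(table, "tree"),
                               branches = list(),
                               scope = c("whole", "branch"),
                               include_stem = TRUE) {
  scope <- match.arg(scope)
  dcols <- domain_columns(m, map)
  dnames <- c(names(dcols), "inter-domain")
  covered <- sort(unique(unlist(dcols)))
  # domain membership per entry (an entry may belong to several domains)
  entry_domains <- lapply(table$column, function(j) {
    hit <- names(dcols)[vapply(dcols, function(cc) j %in% cc, TRUE)]
    if (length(hit)) hit else "inter-domain"
  })
  branch_nodes <- lapply(branches, clade_nodes, tree = tree,
                         include_stem = include_stem)
  entry_branch <- rep("unassigned", nrow(table))
  for (b in names(branches)) {
    entry_branch[table$node %in% branch_nodes[[b]]] <- b
  }
  bnames <- c(names(branches),
              if (any(entry_branch == "unassigned")) "unassigned")
  total <- nrow(table)
  count <- function(domain, branch = NULL) {
    in_dom <- vapply(entry_domains, function(d) domain %in% d, TRUE)
    if (is.null(branch)) sum(in_dom) else sum(in_dom & entry_branch == branch)
  }
  pct <- function(num, den) if (den > 0) 100 * num / den else 0
  rows <- lapply(dnames, function(dn) {
    vals <- if (scope == "whole") {
      c(whole_tree = pct(count(dn), total),
        vapply(bnames, function(b) pct(count(dn, b), total), 0))
    } else {
      vapply(bnames, function(b) pct(count(dn, b), sum(entry_branch == b)), 0)
    }
    as.data.frame(as.list(vals), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- dnames
  attr(out, "scope") <- scope
  attr(out, "total") <- total
  class(out) <- c("domain_freq_table", "data.frame")
  out
}

#' Write a domain-frequency table or histogram as TSV
#' @param x `domain_freq_table` or the [bin_histogram()] data.frame.
#' @param path output file.
#' @export
write_profile_tsv <- function(x, path) {
  df <- as.data.frame(x)
  if (inherits(x, "domain_freq_table")) df <- cbind(domain = rownames(x), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
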