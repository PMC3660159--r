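## Heuristic maximum-parsimony tree search.
##
## TNT-grade machinery (xmult, tree-drifting, TBR, symmetric resampling)
## is not reimplemented here; the standard substitute is multi-start
## random stepwise addition followed by SPR hill-climbing, with ordinary
## nonparametric bootstrap for supports.  Support values from these two
## families of methods are comparable in kind, not in number.
##
## Search trees are kept in a flat array representation (parent vector +
## children list over 2n-1 slots) so SPR moves are cheap; results are
## converted to ape "phylo" at the end.

st_new3 <- function(labels3, all_labels) {
  ntip <- length(all_labels)
  n <- 2L * ntip - 1L
  parent <- integer(n); kids <- vector("list", n)
  i <- match(labels3, all_labels)
  root <- ntip + 1L; inner <- ntip + 2L
  kids[[root]] <- c(inner, i[3]); parent[c(inner, i[3])] <- root
  kids[[inner]] <- c(i[1], i[2]); parent[c(i[1], i[2])] <- inner
  list(parent = parent, kids = kids, root = root, labels = all_labels,
       ntip = ntip, used = c(i, root, inner), next_internal = ntip + 3L)
}

st_nodes <- function(tr) tr$used

## insert tip (by tip index) above node y, consuming internal slot `slot`
st_add_tip <- function(tr, tip, y, slot) {
  p <- tr$parent[y]
  if (p == 0L) stop("cannot insert above the root")
  tr$kids[[p]][tr$kids[[p]] == y] <- slot
  tr$parent[slot] <- p
  tr$kids[[slot]] <- c(y, tip)
  tr$parent[y] <- slot
  tr$parent[tip] <- slot
  tr$used <- c(tr$used, tip, slot)
  tr
}

## is a an ancestor of (or equal to) b?
st_is_ancestor <- function(tr, a, b) {
  v <- b
  while (v != 0L) {
    if (v == a) return(TRUE)
    v <- tr$parent[v]
  }
  FALSE
}

## SPR: prune subtree at v, regraft above y; returns NULL when invalid or
## identical to the input tree
st_spr <- function(tr, v, y) {
  p <- tr$parent[v]
  if (p == 0L) return(NULL)                      # v is root
  sib <- setdiff(tr$kids[[p]], v)
  if (y == v || y == p) return(NULL)
  if (st_is_ancestor(tr, v, y)) return(NULL)     # y inside pruned subtree
  if (y == sib) return(NULL)                     # regraft to same place
  q <- tr$parent[p]
  # detach p, splice sib upward
  if (q == 0L) {
    tr$root <- sib
    tr$parent[sib] <- 0L
  } else {
    tr$kids[[q]][tr$kids[[q]] == p] <- sib
    tr$parent[sib] <- q
  }
  if (y == tr$root && q != 0L) {
    # regraft above the (possibly new) root is allowed: p becomes new root
    tr$kids[[p]] <- c(y, v)
    tr$parent[y] <- p
    tr$parent[p] <- 0L
    tr$root <- p
    return(tr)
  }
  z <- tr$parent[y]
  if (z == 0L) return(NULL)
  tr$kids[[z]][tr$kids[[z]] == y] <- p
  tr$parent[p] <- z
  tr$kids[[p]] <- c(y, v)
  tr$parent[y] <- p
  tr
}

## Fitch score of a search tree against encoded tip data (rows = tip labels)
st_score <- function(tr, enc) {
  ncols <- ncol(enc)
  sets <- matrix(0L, nrow = length(tr$parent), ncol = ncols)
  tips_used <- tr$used[tr$used <= tr$ntip]
  sets[tips_used, ] <- enc[tr$labels[tips_used], , drop = FALSE]
  cost <- 0L
  po <- st_postorder(tr)
  for (v in po) {
    if (v <= tr$ntip) next
    ch <- tr$kids[[v]]
    a <- sets[ch[1], ]; b <- sets[ch[2], ]
    inter <- bitwAnd(a, b)
    hit <- inter != 0L
    cost <- cost + sum(!hit)
    sets[v, ] <- ifelse(hit, inter, bitwOr(a, b))
  }
  cost
}

st_postorder <- function(tr) {
  stack <- tr$root; out <- integer(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    out <- c(out, v)
    if (v > tr$ntip) stack <- c(stack, tr$kids[[v]])
  }
  rev(out)
}

st_newick <- function(tr) {
  build <- function(v) {
    if (v <= tr$ntip) return(tr$labels[v])
    paste0("(", paste(vapply(tr$kids[[v]], build, ""), collapse = ","), ")")
  }
  paste0(build(tr$root), ";")
}

## canonical string of the *unrooted* topology: reroot on the first
## alphabetical tip, then sort children recursively
st_canonical <- function(tr) {
  phy <- ape::read.tree(text = st_newick(tr))
  unrooted_canonical(phy)
}

unrooted_canonical <- function(phy) {
  og <- sort(phy$tip.label)[1]
  phy <- ape::root(phy, outgroup = og, resolve.root = TRUE)
  canonical_newick(phy)
}

random_addition_tree <- function(enc, order) {
  labels <- rownames(enc)
  tr <- st_new3(order[1:3], labels)
  for (tip_lab in order[-(1:3)]) {
    tip <- match(tip_lab, labels)
    slot <- tr$next_internal
    best <- NULL; best_score <- Inf
    for (y in st_nodes(tr)) {
      if (tr$parent[y] == 0L) next
      cand <- st_add_tip(tr, tip, y, slot)
      s <- st_score(cand, enc)
      if (s < best_score) { best_score <- s; best <- cand }
    }
    best$next_internal <- slot + 1L
    tr <- best
  }
  tr
}

#' Heuristic maximum-parsimony search
#'
#' Random stepwise-addition starting trees followed by subtree
#' pruning-regrafting (SPR) hill climbing; all distinct topologies attaining
#' the best score seen across starts are retained.  Deterministic for a
#' fixed seed.
#'
#' @param m aligned character matrix (rows = taxa), at least 4 rows.
#' @param n_starts number of random-addition starts.
#' @param seed RNG seed (required for reproducibility).
#' @param swap branch-swapping scheme; only `"SPR"` is implemented.
#' @param max_rounds cap on full SPR improvement sweeps per start.
#' @return list with `score` (best parsimony length) and `trees` (list of
#'   ape `phylo`, distinct unrooted topologies at that score).
#' @export
heuristic_search <- function(m, n_starts = 10, seed = 1, swap = "SPR",
                             max_rounds = 50) {
  swap <- match.arg(swap, "SPR")
  if (nrow(m) < 4L) stop("need at least 4 taxa")
  enc <- if (is.character(m)) encode_alignment(m) else m
  set.seed(seed)
  best_score <- Inf
  best <- list()   # canonical newick -> phylo
  for (st in seq_len(n_starts)) {
    order <- sample(rownames(enc))
    tr <- random_addition_tree(enc, order)
    sc <- st_score(tr, enc)
    improved <- TRUE; rounds <- 0L
    while (improved && rounds < max_rounds) {
      improved <- FALSE
      rounds <- rounds + 1L
      nodes <- st_nodes(tr)
      for (v in nodes) {
        for (y in nodes) {
          cand <- st_spr(tr, v, y)
          if (is.null(cand)) next
          s <- st_score(cand, enc)
          if (s < sc) {
            tr <- cand; sc <- s; improved <- TRUE
          }
        }
      }
    }
    if (sc < best_score) {
      best_score <- sc
      best <- list()
    }
    if (sc == best_score) {
      key <- st_canonical(tr)
      if (is.null(best[[key]])) {
        best[[key]] <- ape::read.tree(text = st_newick(tr))
      }
    }
  }
  list(score = as.integer(best_score), trees = unname(best))
}

#' Consensus tree (strict or majority rule)
#'
#' @param trees list of `phylo` with identical tip sets.
#' @param rule `"strict"` or `"majority"`.
#' @param cutoff for majority rule, clades present in more than this
#'   fraction of trees are kept (default 0.5 = 50% majority rule).
#' @return `phylo`, possibly with polytomies.
#' @export
consensus_tree <- function(trees, rule = c("majority", "strict"),
                           cutoff = 0.5) {
  rule <- match.arg(rule)
  if (!length(trees)) stop("no trees supplied")
  tipsets <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(tipsets)) != 1L) stop("trees have different tip sets")
  if (length(trees) == 1L) return(trees[[1]])
  p <- if (rule == "strict") 1 else min(cutoff + 1e-9, 1)
  ape::consensus(trees, p = p, check.labels = TRUE)
}

#' Bootstrap clade supports from replicate parsimony searches
#'
#' Columns are resampled with replacement; each replicate is analysed with
#' [heuristic_search()]; clade frequencies over the replicate best trees are
#' attached (0-100) to the majority consensus of those trees.
#'
#' @param m aligned character matrix.
#' @param n_reps bootstrap replicates.
#' @param seed RNG seed.
#' @param n_starts starts per replicate search.
#' @return a `phylo` (majority consensus of replicate trees) whose
#'   `node.support` holds percentages.
#' @export
bootstrap_support <- function(m, n_reps = 100, seed = 1, n_starts = 2) {
  stopifnot(n_reps >= 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  col_idx <- replicate(n_reps, sample.int(ncol(m), replace = TRUE),
                       simplify = FALSE)
  rep_trees <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    mm <- m[, col_idx[[r]], drop = FALSE]
    rep_trees[[r]] <- heuristic_search(mm, n_starts = n_starts,
                                       seed = rep_seeds[r])$trees[[1]]
  }
  cons <- consensus_tree(rep_trees, rule = "majority", cutoff = 0.5)
  counts <- ape::prop.clades(cons, rep_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  cons$node.support <- 100 * counts / n_reps
  cons
}
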