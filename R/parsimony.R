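## Maximum-parsimony machinery.
##
## Characters are unordered (Fitch) amino-acid states.  Gaps, X and missing
## cells are wildcards: they can take any state and contribute no forced
## change.  Scoring on binary nodes is classic Fitch set
## intersection/union; polytomies use Hartigan's generalization (state
## counts over children, cost k - max), which is exact for unordered
## characters on multifurcating trees.

FULL_MASK <- bitwShiftL(1L, 20L) - 1L

#' Encode an aligned amino-acid matrix as Fitch bitmasks
#'
#' Each cell becomes an integer bitmask over [AA_ALPHABET20]; gap (`-`),
#' `X`, `?` and `NA` become the full wildcard mask.
#'
#' @param m aligned character matrix (see [aligned_matrix()]).
#' @return integer matrix with the same dimnames.
#' @export
encode_alignment <- function(m) {
  idx <- match(m, AA_ALPHABET20)
  enc <- ifelse(is.na(idx), FULL_MASK, bitwShiftL(1L, idx - 1L))
  enc <- matrix(as.integer(enc), nrow = nrow(m), dimnames = dimnames(m))
  enc
}

## internal indexed view of a phylo ------------------------------------------

tree_index <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  kids <- vector("list", nnode)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; c <- tree$edge[i, 2]
    kids[[p]] <- c(kids[[p]], c)
  }
  parent <- integer(nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  # postorder internal-node sequence
  po <- integer(0)
  stack <- root; visited <- logical(nnode)
  order_stack <- integer(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    order_stack <- c(order_stack, v)
    if (v > ntip) stack <- c(stack, kids[[v]])
  }
  po <- rev(order_stack)
  list(ntip = ntip, nnode = nnode, root = root, kids = kids,
       parent = parent, postorder = po,
       preorder = order_stack, labels = tree$tip.label)
}

check_tips_vs_matrix <- function(tree, m) {
  missing <- setdiff(tree$tip.label, rownames(m))
  if (length(missing)) {
    stop("tree tips without a matrix row: ", paste(missing, collapse = ", "))
  }
}

## Fitch / Hartigan scoring ----------------------------------------------------

#' Per-column parsimony change counts (Fitch/Hartigan)
#'
#' @param tree rooted or unrooted `phylo` (scores are rooting-invariant);
#'   polytomies allowed.
#' @param m aligned character matrix or an [encode_alignment()] result.
#' @return integer vector of per-column minimum change counts.
#' @export
fitch_column_scores <- function(tree, m) {
  enc <- if (is.character(m)) encode_alignment(m) else m
  check_tips_vs_matrix(tree, enc)
  ti <- tree_index(tree)
  ncol <- ncol(enc)
  sets <- matrix(0L, nrow = ti$nnode, ncol = ncol)
  sets[seq_len(ti$ntip), ] <- enc[ti$labels, , drop = FALSE]
  cost <- integer(ncol)
  for (v in ti$postorder) {
    if (v <= ti$ntip) next
    ch <- ti$kids[[v]]
    if (length(ch) == 2L) {
      a <- sets[ch[1], ]; b <- sets[ch[2], ]
      inter <- bitwAnd(a, b)
      hit <- inter != 0L
      cost <- cost + as.integer(!hit)
      sets[v, ] <- ifelse(hit, inter, bitwOr(a, b))
    } else if (length(ch) == 1L) {
      sets[v, ] <- sets[ch, ]
    } else {
      # Hartigan: count, per state, how many children admit it
      cnt <- matrix(0L, nrow = 20L, ncol = ncol)
      for (c in ch) {
        cs <- sets[c, ]
        for (s in seq_len(20L)) {
          cnt[s, ] <- cnt[s, ] + bitwAnd(bitwShiftR(cs, s - 1L), 1L)
        }
      }
      mx <- apply(cnt, 2L, max)
      cost <- cost + length(ch) - mx
      hs <- integer(ncol)
      for (s in seq_len(20L)) {
        hs <- bitwOr(hs, bitwShiftL(as.integer(cnt[s, ] == mx), s - 1L))
      }
      sets[v, ] <- hs
    }
  }
  cost
}

#' Total parsimony length of a tree for a character matrix
#' @inheritParams fitch_column_scores
#' @return integer scalar.
#' @export
fitch_score <- function(tree, m) {
  sum(fitch_column_scores(tree, m))
}

## Sankoff DP over one column --------------------------------------------------

## A column is handed around as a character vector named by tip label.
## Wildcards (-, X, ?, NA) may take any observed state.

column_from_matrix <- function(m, j) {
  stats::setNames(m[, j], rownames(m))
}

column_dp <- function(ti, column) {
  obs <- column[ti$labels]
  wild <- is.na(obs) | obs %in% c("-", "X", "?")
  states <- sort(unique(obs[!wild]))
  k <- length(states)
  if (k < 2L) return(NULL)
  n <- ti$nnode
  INF <- 1e9
  down <- matrix(INF, n, k)
  for (i in seq_len(ti$ntip)) {
    down[i, ] <- if (wild[i]) 0 else ifelse(states == obs[i], 0, INF)
  }
  g <- matrix(0, n, k)       # g[v,t] = min cost of subtree(v) given parent=t
  for (i in seq_len(ti$ntip)) {
    mind <- min(down[i, ])
    g[i, ] <- pmin(down[i, ], mind + 1)
  }
  for (v in ti$postorder) {
    if (v <= ti$ntip) next
    d <- rep(0, k)
    for (c in ti$kids[[v]]) d <- d + g[c, ]
    down[v, ] <- d
    g[v, ] <- pmin(d, min(d) + 1)
  }
  L <- min(down[ti$root, ])
  up <- matrix(0, n, k)
  h <- matrix(0, n, k)       # h[v,t] = cost outside subtree(v) if parent(v)=t
  for (u in ti$preorder) {
    if (u <= ti$ntip) next
    ch <- ti$kids[[u]]
    tot <- up[u, ]
    for (c in ch) tot <- tot + g[c, ]
    for (c in ch) {
      hv <- tot - g[c, ]
      h[c, ] <- hv
      up[c, ] <- pmin(hv, min(hv) + 1)
    }
  }
  list(states = states, L = L, down = down, up = up, h = h, g = g,
       wild = wild)
}

#' Enumerate all most-parsimonious reconstructions of one column
#'
#' All internal-node state assignments achieving the Fitch minimum, found by
#' unit-cost Sankoff dynamic programming with exhaustive optimal backtracking.
#' Guarded to small trees.
#'
#' @param tree rooted `phylo`, at most 20 tips.
#' @param column character vector of tip states named by tip label
#'   (wildcards: `-`, `X`, `?`, `NA`).
#' @param max_mprs abort if more than this many reconstructions exist.
#' @return list with `score` and `labelings`, a list of character vectors
#'   named by internal node number (ape numbering).  A constant column has a
#'   single labeling (every internal node in that state).
#' @export
enumerate_mprs <- function(tree, column, max_mprs = 100000L) {
  ntip <- length(tree$tip.label)
  if (ntip > 20L) {
    stop("enumerate_mprs is guarded to <= 20 tips (got ", ntip,
         "); sample columns or use detect_synapomorphies()")
  }
  ti <- tree_index(tree)
  dp <- column_dp(ti, column)
  if (is.null(dp)) {
    obs <- column[ti$labels]
    wild <- is.na(obs) | obs %in% c("-", "X", "?")
    st <- unique(obs[!wild])
    if (length(st) == 0L) st <- NA_character_
    internal <- setdiff(seq_len(ti$nnode), seq_len(ti$ntip))
    lab <- stats::setNames(rep(st[1], length(internal)), internal)
    return(list(score = 0L, labelings = list(lab)))
  }
  states <- dp$states
  out <- list()
  assign_node <- function(v, s_idx, partial) {
    if (v > ti$ntip) partial[[as.character(v)]] <- states[s_idx]
    # recurse into internal children only: tip states are data, and wildcard
    # tips must not multiply the reconstruction count
    kids <- if (v > ti$ntip) Filter(function(c) c > ti$ntip, ti$kids[[v]]) else integer(0)
    if (!length(kids)) return(list(partial))
    # allowed child states given this parent state
    child_choices <- lapply(kids, function(c) {
      cost <- dp$down[c, ] + as.numeric(seq_along(states) != s_idx)
      which(abs(cost - dp$g[c, s_idx]) < 1e-9)
    })
    res <- list(partial)
    for (ci in seq_along(kids)) {
      new_res <- list()
      for (p in res) {
        for (t in child_choices[[ci]]) {
          sub <- assign_node(kids[ci], t, p)
          new_res <- c(new_res, sub)
          if (length(out) + length(new_res) > max_mprs) {
            stop("more than ", max_mprs, " MPRs; raise max_mprs")
          }
        }
      }
      res <- new_res
    }
    res
  }
  root_states <- which(abs(dp$down[ti$root, ] - dp$L) < 1e-9)
  for (s in root_states) {
    out <- c(out, assign_node(ti$root, s, stats::setNames(character(0), NULL)))
  }
  # drop tip entries, keep internal labels only (assign_node only records
  # internal nodes, but tips recurse through assign_node too)
  list(score = as.integer(dp$L), labelings = out)
}

## Unambiguous synapomorphies --------------------------------------------------

#' Call unambiguous synapomorphies on a rooted tree
#'
#' A (node, column) pair is an unambiguous synapomorphy iff every
#' most-parsimonious reconstruction of that column places a state change on
#' the branch entering the node and the derived state is the same in all of
#' them.  Implemented exactly (without enumeration) from the inside/outside
#' unit-cost Sankoff costs.  Internal, non-root nodes only; constant columns
#' yield nothing.  The ancestral state is the parent's MPR state when it is
#' itself unambiguous, otherwise the alphabetically smallest optimal parent
#' state (documented tie-break).
#'
#' @param tree rooted `phylo`.
#' @param m aligned character matrix.
#' @return data.frame of class `synapo_table` with columns `node`, `column`,
#'   `ancestral`, `derived`; attributes `n_columns`, `tree`.
#' @export
detect_synapomorphies <- function(tree, m) {
  if (!ape::is.rooted(tree)) {
    stop("tree must be rooted (root_at_outgroup() first)")
  }
  check_tips_vs_matrix(tree, m)
  ti <- tree_index(tree)
  rows <- list()
  internal <- setdiff(seq_len(ti$nnode), c(seq_len(ti$ntip), ti$root))
  # tip branches excluded: autapomorphies are not node synapomorphies
  for (j in seq_len(ncol(m))) {
    dp <- column_dp(ti, column_from_matrix(m, j))
    if (is.null(dp)) next
    for (v in internal) {
      joint <- dp$down[v, ] + dp$h[v, ]     # u and v share state s
      if (any(abs(joint - dp$L) < 1e-9)) next   # a no-change MPR exists
      mv <- which(abs(dp$down[v, ] + dp$up[v, ] - dp$L) < 1e-9)
      if (length(mv) != 1L) next            # derived state ambiguous
      pv <- which(abs(dp$h[v, ] + dp$g[v, ] - dp$L) < 1e-9)
      anc <- dp$states[min(pv)]
      rows[[length(rows) + 1L]] <- data.frame(
        node = v, column = j, ancestral = anc, derived = dp$states[mv],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(node = integer(0), column = integer(0),
               ancestral = character(0), derived = character(0))
  }
  attr(out, "n_columns") <- ncol(m)
  attr(out, "tree") <- tree
  class(out) <- c("synapo_table", "data.frame")
  out
}

#' Write a synapomorphy table as TSV (columns 1-based)
#' @param table a `synapo_table`.
#' @param path output file.
#' @export
write_synapo_table <- function(table, path) {
  utils::write.table(
    data.frame(node_id = table$node, column_1based = table$column,
               ancestral = table$ancestral, derived = table$derived),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
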