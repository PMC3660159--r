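# Independent brute-force oracles.  These deliberately share no code with
# the package implementations they check.

# minimum change count of one column by exhaustive internal labeling over
# the observed states; also returns every optimal labeling
oracle_column_parsimony <- function(tree, column) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  internal <- (ntip + 1L):nnode
  obs <- column[tree$tip.label]
  wild <- is.na(obs) | obs %in% c("-", "X", "?")
  states <- sort(unique(obs[!wild]))
  if (length(states) < 2L) {
    st <- if (length(states)) states else NA_character_
    lab <- stats::setNames(rep(st, length(internal)), internal)
    return(list(score = 0L, labelings = list(lab)))
  }
  grids <- rep(list(states), length(internal))
  combos <- as.matrix(do.call(expand.grid, c(grids, stringsAsFactors = FALSE)))
  colnames(combos) <- as.character(internal)
  changes <- integer(nrow(combos))
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    av <- combos[, as.character(a)]
    if (b > ntip) {
      changes <- changes + (av != combos[, as.character(b)])
    } else if (!wild[b]) {
      changes <- changes + (av != obs[[b]])
    }
  }
  best <- min(changes)
  labelings <- lapply(which(changes == best), function(i) {
    stats::setNames(as.character(combos[i, ]), internal)
  })
  list(score = as.integer(best), labelings = labelings)
}

oracle_fitch_score <- function(tree, m) {
  sum(vapply(seq_len(ncol(m)), function(j) {
    oracle_column_parsimony(tree, stats::setNames(m[, j], rownames(m)))$score
  }, 0L))
}

# synapomorphy table derived from the oracle's full MPR enumeration
oracle_synapomorphies <- function(tree, m) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  rows <- list()
  for (j in seq_len(ncol(m))) {
    colv <- stats::setNames(m[, j], rownames(m))
    obs <- colv[tree$tip.label]
    wild <- is.na(obs) | obs %in% c("-", "X", "?")
    if (length(unique(obs[!wild])) < 2L) next
    oc <- oracle_column_parsimony(tree, colv)
    for (v in setdiff((ntip + 1L):(ntip + tree$Nnode), root)) {
      vs <- vapply(oc$labelings, function(l) l[[as.character(v)]], "")
      ps <- vapply(oc$labelings, function(l) l[[as.character(parent[v])]], "")
      if (all(vs != ps) && length(unique(vs)) == 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          node = v, column = j, derived = vs[1], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(node = integer(0), column = integer(0), derived = character(0))
}

# linear-gap Smith-Waterman oracle (quadratic space, gap d per residue)
oracle_sw_score <- function(a, b, mat, d) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      H[i + 1L, j + 1L] <- max(
        0,
        H[i, j] + mat[av[i], bv[j]],
        H[i, j + 1L] - d,
        H[i + 1L, j] - d)
    }
  }
  max(H)
}

# exhaustive window-pair energy oracle (disjoint equal-length windows,
# both orientations)
oracle_energy_profile <- function(seq, table, min_len) {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  lookup <- function(mat, x, y) {
    if (!x %in% rownames(mat) || !y %in% colnames(mat)) 0 else mat[x, y]
  }
  energy <- rep(NA_real_, L)
  if (L < 2L * min_len) return(energy)
  for (len in min_len:floor(L / 2)) {
    for (i in 1:(L - len + 1L)) {
      for (j in 1:(L - len + 1L)) {
        if (abs(i - j) < len) next
        wi <- chars[i:(i + len - 1L)]
        wj <- chars[j:(j + len - 1L)]
        epar <- sum(mapply(function(x, y) lookup(table$parallel, x, y), wi, wj))
        eant <- sum(mapply(function(x, y) lookup(table$antiparallel, x, y),
                           wi, rev(wj)))
        cov <- unique(c(i:(i + len - 1L), j:(j + len - 1L)))
        for (e in c(epar, eant)) {
          upd <- cov[is.na(energy[cov]) | e < energy[cov]]
          energy[upd] <- e
        }
      }
    }
  }
  energy
}

# graph reachability oracle for the similarity closure
oracle_reachable <- function(edges_df, seeds, all_ids) {
  g <- igraph::graph_from_data_frame(edges_df, directed = TRUE,
                                     vertices = all_ids)
  unique(unlist(lapply(seeds, function(s) {
    names(igraph::subcomponent(g, s, mode = "out"))
  })))
}
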