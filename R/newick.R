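## Newick IO with a small comment-annotation dialect.
##
## Trees are ape "phylo" objects.  Two optional annotation channels ride on
## the object: `node.support` (numeric, length Nnode, NA where absent) and
## `tip.class` (character named by tip label).  On disk they appear as
## `[&support=..]` after an internal node's closing parenthesis and
## `[&class=..]` after a tip label -- ape drops square-bracket comments, so
## the reader rewrites them into temporary node labels before parsing.

#' Read a Newick tree, keeping `[&support=..,class=..]` annotations
#'
#' @param path file containing one Newick tree.
#' @return an ape `phylo`, possibly carrying `node.support` and `tip.class`.
#' @export
read_newick <- function(path) {
  txt <- paste(trimws(readLines(path)), collapse = "")
  read_newick_text(txt)
}

#' @rdname read_newick
#' @param text Newick string.
#' @export
read_newick_text <- function(text) {
  check_balanced(text)
  ann <- list()
  idx <- 0L
  # rewrite every [&...] comment into a unique label token
  repl <- function(m) {
    idx <<- idx + 1L
    tag <- sprintf("AMYPHYTAG%04d", idx)
    ann[[tag]] <<- sub("^\\[&", "", sub("\\]$", "", m))
    tag
  }
  rx <- "\\[&[^]]*\\]"
  while (grepl(rx, text)) {
    m <- regmatches(text, regexpr(rx, text))
    tag <- repl(m)
    # a comment after a tip label glues onto the label; after ')' it becomes
    # the internal node label -- both are plain labels for ape
    text <- sub(rx, tag, text)
  }
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick: ", substr(text, 1, 60))
  support <- rep(NA_real_, tree$Nnode)
  tipclass <- character(0)
  # internal labels
  if (!is.null(tree$node.label)) {
    for (i in seq_along(tree$node.label)) {
      tag <- regmatches(tree$node.label[i],
                        regexpr("AMYPHYTAG\\d{4}", tree$node.label[i]))
      if (length(tag) == 1L) {
        fields <- parse_ann_fields(ann[[tag]])
        if (!is.null(fields$support)) support[i] <- as.numeric(fields$support)
        tree$node.label[i] <- sub("AMYPHYTAG\\d{4}", "", tree$node.label[i])
      }
    }
    if (all(!nzchar(tree$node.label))) tree$node.label <- NULL
  }
  for (i in seq_along(tree$tip.label)) {
    tag <- regmatches(tree$tip.label[i],
                      regexpr("AMYPHYTAG\\d{4}", tree$tip.label[i]))
    if (length(tag) == 1L) {
      fields <- parse_ann_fields(ann[[tag]])
      tree$tip.label[i] <- sub("AMYPHYTAG\\d{4}", "", tree$tip.label[i])
      if (!is.null(fields$class)) {
        tipclass[tree$tip.label[i]] <- fields$class
      }
      if (!is.null(fields$support)) {
        warning("support annotation on tip ", tree$tip.label[i], " ignored")
      }
    }
  }
  if (any(!is.na(support))) tree$node.support <- support
  if (length(tipclass)) tree$tip.class <- tipclass
  tree
}

parse_ann_fields <- function(s) {
  kv <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
  out <- lapply(kv, function(p) if (length(p) == 2L) p[[2]] else NA_character_)
  names(out) <- vapply(kv, `[[`, "", 1L)
  out
}

check_balanced <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' at character ", i)
    }
  }
  if (depth != 0L) stop("unbalanced parentheses: ", depth, " '(' unclosed")
  invisible(TRUE)
}

#' Write a Newick tree with optional support / class annotations
#'
#' @param tree an ape `phylo`; `tree$node.support` (numeric per internal
#'   node, ape order) and `tree$tip.class` (named by tip) are serialized as
#'   `[&support=..]` / `[&class=..]` comments.
#' @param path output file; `NULL` returns the string.
#' @param digits branch-length precision.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  elen <- tree$edge.length
  eidx <- integer(max(tree$edge))     # edge index by child node
  eidx[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  support <- tree$node.support
  tipclass <- tree$tip.class
  fmt_len <- function(node) {
    if (is.null(elen) || node == root) return("")
    paste0(":", format(elen[eidx[node]], digits = digits, scientific = FALSE))
  }
  build <- function(node) {
    if (node <= ntip) {
      lab <- tree$tip.label[node]
      cls <- if (!is.null(tipclass) && lab %in% names(tipclass)) {
        paste0("[&class=", tipclass[[lab]], "]")
      } else ""
      return(paste0(lab, cls, fmt_len(node)))
    }
    inner <- paste(vapply(kids[[as.character(node)]], build, ""),
                   collapse = ",")
    sup <- ""
    if (!is.null(support)) {
      s <- support[node - ntip]
      if (!is.na(s)) sup <- paste0("[&support=", format(s), "]")
    }
    paste0("(", inner, ")", sup, fmt_len(node))
  }
  out <- paste0(build(root), ";")
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(path)
}

#' Root a tree on a designated outgroup
#'
#' Thin wrapper over [ape::root.phylo()] that resolves the root so downstream
#' parsimony passes see a rooted binary basal split where possible.
#'
#' @param tree `phylo`.
#' @param outgroup tip label(s) forming the outgroup.
#' @return rooted `phylo`.
#' @export
root_at_outgroup <- function(tree, outgroup) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing)) stop("outgroup tips not in tree: ",
                            paste(missing, collapse = ", "))
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Canonical Newick form of a topology (labels sorted, no lengths)
#'
#' Used to deduplicate topologies found by the heuristic search; identical
#' unrooted topologies rooted the same way give identical strings.
#' @param tree `phylo`.
#' @return character scalar.
#' @export
canonical_newick <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  build <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    parts <- sort(vapply(kids[[as.character(node)]], build, ""))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(build(root), ";")
}
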