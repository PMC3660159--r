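mk_table <- function(nodes, columns, n_columns, tree = NULL) {
  out <- data.frame(node = nodes, column = columns,
                    ancestral = rep("A", length(nodes)),
                    derived = rep("T", length(nodes)),
                    stringsAsFactors = FALSE)
  attr(out, "n_columns") <- n_columns
  attr(out, "tree") <- tree
  class(out) <- c("synapo_table", "data.frame")
  out
}

test_that("column frequencies normalize to 100 and flag empties", {
  tab <- mk_table(rep(7L, 3), rep(7L, 3), 10)
  prof <- column_frequencies(tab)
  expect_equal(prof$percent[7], 100)
  expect_equal(sum(prof$percent), 100)

  tab2 <- mk_table(7L, c(2L, 2L, 2L, 2L, 3L, 3L, 3L, 7L, 7L, 8L),
                   10)
  prof2 <- column_frequencies(tab2)
  expect_equal(prof2$percent[c(2, 3, 7, 8)], c(40, 30, 20, 10))

  empty <- column_frequencies(mk_table(integer(0), integer(0), 5), 5)
  expect_true(empty$empty)
  expect_equal(sum(empty$percent), 0)

  expect_error(column_frequencies(mk_table(1L, 12L, 12), n_columns = 10),
               "exceeds")
})

test_that("binning conserves mass with bins anchored at column zero", {
  tab <- mk_table(7L, c(2L, 2L, 2L, 2L, 3L, 3L, 3L, 7L, 7L, 8L), 10)
  prof <- column_frequencies(tab)
  h <- bin_histogram(prof, bin_width = 5)
  # columns 2,3 (0-based 1,2) land in [0,5); 7,8 (0-based 6,7) in [5,10)
  expect_equal(h$percent, c(70, 30))
  expect_equal(h$bin_start, c(0, 5))
  expect_equal(sum(h$percent), sum(prof$percent))
  # width 1 is the identity
  h1 <- bin_histogram(prof, bin_width = 1)
  expect_equal(h1$percent, prof$percent)
  # ragged final bin still conserves mass
  h3 <- bin_histogram(prof, bin_width = 3)
  expect_equal(sum(h3$percent), 100)
  expect_equal(h3$bin_end[length(h3$bin_end)], 10)
})

test_that("branch stratification restricts to clade nodes", {
  tr <- tree_of("(((t1,t2),(t3,t4)),t5);")
  n12 <- ape::getMRCA(tr, c("t1", "t2"))
  n34 <- ape::getMRCA(tr, c("t3", "t4"))
  n14 <- ape::getMRCA(tr, c("t1", "t4"))
  tab <- mk_table(c(n12, n34, n14), c(1L, 2L, 3L), 10, tr)
  # single cherry keeps only its own node's entries
  s12 <- branch_stratify(tab, tr, c("t1", "t2"))
  expect_equal(s12$node, n12)
  # whole ingroup (stem-inclusive) keeps everything below the root
  sall <- branch_stratify(tab, tr, c("t1", "t2", "t3", "t4"))
  expect_equal(sort(sall$node), sort(c(n12, n34, n14)))
  # stem exclusion drops the MRCA itself
  snostem <- branch_stratify(tab, tr, c("t1", "t2", "t3", "t4"),
                             include_stem = FALSE)
  expect_equal(sort(snostem$node), sort(c(n12, n34)))
  # disjoint clades partition the non-root internal nodes
  expect_equal(sort(c(branch_stratify(tab, tr, c("t1", "t2"))$node,
                      branch_stratify(tab, tr, c("t3", "t4"))$node)),
               sort(c(n12, n34)))
  expect_error(branch_stratify(tab, tr, c("t1", "t3")), "monophyletic")
})

test_that("domain frequency tables implement both denominator modes", {
  tr <- tree_of("(((t1,t2),(t3,t4)),t5);")
  strs <- stats::setNames(rep(paste0(rep("A", 10), collapse = ""), 5),
                          paste0("t", 1:5))
  m <- aligned_matrix(strs)
  map <- domain_map(c("domA", "domB"), c(0, 6), c(4, 10), "t1")
  n12 <- ape::getMRCA(tr, c("t1", "t2"))
  n34 <- ape::getMRCA(tr, c("t3", "t4"))
  # 3 entries in domA and 1 in domB, all inside clade {t1,t2}
  tab <- mk_table(rep(n12, 4), c(1L, 2L, 3L, 7L), 10, tr)
  branches <- list(br12 = c("t1", "t2"), br34 = c("t3", "t4"))
  w <- domain_frequencies(tab, map, m, tr, branches, scope = "whole")
  expect_equal(w["domA", "br12"], 75)
  expect_equal(w["domB", "br12"], 25)
  expect_equal(w["domA", "whole_tree"], 75)
  expect_equal(w["domA", "br34"], 0)
  b <- domain_frequencies(tab, map, m, tr, branches, scope = "branch")
  expect_equal(b["domA", "br12"], 75)   # within-branch denominator
  expect_equal(b["domB", "br12"], 25)
  # single branch holding all entries, one domain covering all columns
  map_all <- domain_map("all", 0, 10, "t1")
  w2 <- domain_frequencies(tab, map_all, m, tr,
                           list(br12 = c("t1", "t2")), scope = "whole")
  b2 <- domain_frequencies(tab, map_all, m, tr,
                           list(br12 = c("t1", "t2")), scope = "branch")
  expect_equal(w2["all", "br12"], 100)
  expect_equal(b2["all", "br12"], 100)
})

test_that("whole-tree mode over a full partition sums to 100", {
  fam <- example_family_config(seed = 31, n_tips = 14)
  b <- evolve_family(fam$tree, fam$config)
  rooted <- b$tree
  tab <- detect_synapomorphies(rooted, b$alignment)
  expect_gt(nrow(tab), 0)
  # disjoint domains spanning all columns
  L <- ncol(b$alignment)
  map <- domain_map(c("left", "mid", "right"), c(0, 80, 160), c(80, 160, L),
                    rownames(b$alignment)[1])
  w <- domain_frequencies(tab, map, b$alignment, rooted,
                          branches = fam$config$clades, scope = "whole")
  expect_equal(sum(w[, setdiff(colnames(w), "whole_tree")]), 100,
               tolerance = 1e-9)
  expect_equal(sum(w[, "whole_tree"]), 100, tolerance = 1e-9)
  # stratify-then-profile == profile-then-filter
  cl <- fam$config$clades$cladeA
  strat <- branch_stratify(tab, rooted, cl)
  nodes <- clade_nodes(rooted, cl)
  keep <- tab$node %in% nodes
  expect_equal(sort(paste(strat$node, strat$column)),
               sort(paste(tab$node[keep], tab$column[keep])))
})
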