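test_that("fitch score handles the textbook cases", {
  tr <- tree_of("((t1,t2),(t3,t4));")
  m0 <- matrix("A", 4, 3, dimnames = list(paste0("t", 1:4), NULL))
  expect_equal(fitch_score(tr, m0), 0L)
  m1 <- matrix(c("A", "A", "T", "T"), 4, 1,
               dimnames = list(paste0("t", 1:4), NULL))
  expect_equal(fitch_score(tr, m1), 1L)
  # grouping against the data costs two
  tr2 <- tree_of("((t1,t3),(t2,t4));")
  expect_equal(fitch_score(tr2, m1), 2L)
  expect_error(fitch_score(tr, m1[1:3, , drop = FALSE]), "without a matrix row")
})

test_that("missing data and gaps contribute no forced changes", {
  tr <- tree_of("((t1,t2),(t3,t4));")
  m <- matrix(c("A", "-", "X", "A"), 4, 1,
              dimnames = list(paste0("t", 1:4), NULL))
  expect_equal(fitch_score(tr, m), 0L)
})

test_that("fitch equals exhaustive labeling on random binary trees", {
  for (seed in 1:12) {
    tr <- random_tree(sample(4:7, 1), seed)
    m <- random_matrix(length(tr$tip.label), 6, seed + 100,
                       p_missing = ifelse(seed %% 3 == 0, 0.15, 0))
    expect_equal(fitch_score(tr, m), oracle_fitch_score(tr, m),
                 info = paste("seed", seed))
  }
})

test_that("hartigan scoring is exact on polytomies", {
  star <- tree_of("(t1,t2,t3,t4);")
  m <- matrix(c("A", "A", "T", "T"), 4, 1,
              dimnames = list(paste0("t", 1:4), NULL))
  expect_equal(fitch_score(star, m), oracle_fitch_score(star, m))
  for (seed in 1:8) {
    poly <- tree_of("((t1,t2,t3),(t4,t5),t6);")
    mm <- random_matrix(6, 5, seed + 500, alphabet = c("A", "C", "G"))
    expect_equal(fitch_score(poly, mm), oracle_fitch_score(poly, mm),
                 info = paste("seed", seed))
  }
})

test_that("MPR enumeration matches brute force", {
  tr <- tree_of("((t1,t2),(t3,t4));")
  col <- c(t1 = "A", t2 = "A", t3 = "T", t4 = "T")
  mine <- enumerate_mprs(tr, col)
  orac <- oracle_column_parsimony(tr, col)
  expect_equal(mine$score, orac$score)
  canon <- function(ls) sort(vapply(ls, function(l) {
    paste(names(sort(l)), sort(l), l[order(names(l))], collapse = ";")
  }, ""))
  norm <- function(ls) sort(vapply(ls, function(l) {
    l <- l[order(as.integer(names(l)))]
    paste(names(l), l, sep = "=", collapse = ";")
  }, ""))
  expect_equal(norm(mine$labelings), norm(orac$labelings))

  # cherry (A,T): both internal labelings are MPRs of score 1
  ch <- tree_of("(t1,t2);")
  mm <- enumerate_mprs(ch, c(t1 = "A", t2 = "T"))
  expect_equal(mm$score, 1L)
  expect_equal(length(mm$labelings), 2L)

  # constant column: a single all-same labeling
  cc <- enumerate_mprs(tr, c(t1 = "G", t2 = "G", t3 = "G", t4 = "G"))
  expect_equal(cc$score, 0L)
  expect_equal(length(cc$labelings), 1L)
  expect_true(all(unlist(cc$labelings) == "G"))

  expect_error(enumerate_mprs(random_tree(21, 1), NULL), "20 tips")
})

test_that("MPR enumeration matches brute force on random instances", {
  for (seed in 1:10) {
    tr <- random_tree(sample(4:6, 1), seed + 30)
    m <- random_matrix(length(tr$tip.label), 4, seed + 60,
                       alphabet = c("A", "C", "G"),
                       p_missing = ifelse(seed %% 2 == 0, 0.2, 0))
    for (j in seq_len(ncol(m))) {
      col <- stats::setNames(m[, j], rownames(m))
      mine <- enumerate_mprs(tr, col)
      orac <- oracle_column_parsimony(tr, col)
      expect_equal(mine$score, orac$score)
      norm <- function(ls) sort(vapply(ls, function(l) {
        l <- l[order(as.integer(names(l)))]
        paste(names(l), l, sep = "=", collapse = ";")
      }, ""))
      if (mine$score > 0L) {
        expect_equal(norm(mine$labelings), norm(orac$labelings),
                     info = paste("seed", seed, "col", j))
      }
    }
  }
})

test_that("synapomorphy detection follows the all-MPR definition", {
  # planted clade-diagnostic change: exactly one entry at the clade node
  tr <- tree_of("(((t1,t2),(t3,t4)),t5);")
  m <- matrix("A", 5, 2, dimnames = list(paste0("t", 1:5), NULL))
  m[c("t1", "t2"), 2] <- "W"
  tab <- detect_synapomorphies(tr, m)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$column, 2L)
  expect_equal(tab$derived, "W")
  expect_equal(tab$ancestral, "A")
  expect_equal(tab$node, ape::getMRCA(tr, c("t1", "t2")))

  # a tip-only change yields no internal-node entry (autapomorphy)
  m2 <- matrix("A", 5, 1, dimnames = list(paste0("t", 1:5), NULL))
  m2["t3", 1] <- "T"
  expect_equal(nrow(detect_synapomorphies(tr, m2)), 0L)

  # unrooted tree is rejected with a hint
  expect_error(detect_synapomorphies(ape::unroot(tree_of("((t1,t2),(t3,t4),t5);")),
                                     m),
               "rooted")
})

test_that("synapomorphy tables equal the oracle on random instances", {
  for (seed in 1:8) {
    tr <- random_tree(sample(5:8, 1), seed + 200)
    m <- random_matrix(length(tr$tip.label), 8, seed + 300,
                       alphabet = c("A", "C", "G"))
    mine <- detect_synapomorphies(tr, m)
    orac <- oracle_synapomorphies(tr, m)
    key <- function(d) sort(paste(d$node, d$column, d$derived))
    expect_equal(key(mine), key(orac), info = paste("seed", seed))
  }
})

test_that("synapomorphy output is invariant to tip-order permutation", {
  tr <- random_tree(6, 77)
  m <- random_matrix(6, 10, 78)
  t1 <- detect_synapomorphies(tr, m)
  perm <- m[sample(rownames(m)), , drop = FALSE]
  t2 <- detect_synapomorphies(tr, perm)
  key <- function(d) sort(paste(d$node, d$column, d$ancestral, d$derived))
  expect_equal(key(t1), key(t2))
})

test_that("synapomorphy count never exceeds the parsimony length", {
  for (seed in 1:6) {
    tr <- random_tree(6, seed + 400)
    m <- random_matrix(6, 12, seed + 450)
    expect_lte(nrow(detect_synapomorphies(tr, m)), fitch_score(tr, m))
  }
})
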