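test_that("local alignment reproduces the classic textbook optimum", {
  # HEAGAWGHEE vs PAWHEAE under BLOSUM50 with linear gap 8: optimum 28,
  # aligning AWGHE against AW-HE
  al <- local_align_score("HEAGAWGHEE", "PAWHEAE", "BLOSUM50",
                          gap_open = 0, gap_extend = 8)
  expect_equal(al$score, 28)
  expect_equal(al$a_aln, "AWGHE")
  expect_equal(al$b_aln, "AW-HE")
  expect_equal(al$a_span, c(4L, 9L))   # 0-based half-open
  expect_equal(al$b_span, c(1L, 5L))
})

test_that("self-alignment scores the diagonal and hopeless pairs floor at 0", {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B62 <- e$BLOSUM62
  s <- "MKWVLFYACD"
  al <- local_align_score(s, s, "BLOSUM62")
  diag_sum <- sum(vapply(strsplit(s, "")[[1]], function(a) B62[a, a], 0))
  expect_equal(al$score, diag_sum)
  z <- local_align_score("GGGG", "PPPP", "BLOSUM62")
  expect_equal(z$score, 0)
  expect_equal(z$a_span, c(0L, 0L))
})

test_that("local alignment agrees with an independent DP oracle", {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B62 <- e$BLOSUM62
  set.seed(8)
  for (i in 1:10) {
    a <- paste0(sample(AA_ALPHABET20, sample(6:12, 1), TRUE), collapse = "")
    b <- paste0(sample(AA_ALPHABET20, sample(6:12, 1), TRUE), collapse = "")
    al <- local_align_score(a, b, "BLOSUM62", gap_open = 0, gap_extend = 8)
    expect_equal(al$score, oracle_sw_score(a, b, B62, 8),
                 info = paste(a, b))
  }
})

test_that("E-values follow the Karlin-Altschul closed form", {
  K <- 0.041; lambda <- 0.267
  # lambda*S = ln(K*m*n)  =>  E = 1
  m <- 250; n <- 400
  S <- log(K * m * n) / lambda
  expect_equal(evalue_from_score(S, m, n, K, lambda), 1, tolerance = 1e-12)
  # linear in n
  e1 <- evalue_from_score(50, 100, 100, K, lambda)
  expect_equal(evalue_from_score(50, 100, 200, K, lambda), 2 * e1)
  # closed-form spot value
  expect_equal(evalue_from_score(100, 100, 100, K, lambda),
               0.041 * 1e4 * exp(-26.7), tolerance = 1e-12)
  expect_error(evalue_from_score(10, 0, 5), "m >= 1")
})

test_that("iterative closure reaches the least fixed point", {
  recs <- seq_set(id = c("A", "B", "C", "D"),
                  taxon = paste0("sp", 1:4), gene_label = "APP",
                  residues = rep("MKVL", 4))
  hits <- data.frame(
    query_id  = c("A", "B", "B", "C"),
    subject_id = c("B", "A", "C", "B"),
    evalue = c(1e-200, 1e-200, 1e-200, 1e-200))
  db <- seq_database(recs, hit_table_backend(hits))
  out <- iterative_closure("A", db, 1e-180)
  expect_setequal(out$id, c("A", "B", "C"))
  expect_equal(attr(out, "n_iterations"), 2L)   # B then C
  # seeds with no passing hits return exactly the seeds
  out2 <- iterative_closure("D", db)
  expect_equal(out2$id, "D")
  # cycles terminate
  cyc <- seq_database(recs, hit_table_backend(
    data.frame(query_id = c("A", "B"), subject_id = c("B", "A"),
               evalue = 0)))
  expect_setequal(iterative_closure("A", cyc)$id, c("A", "B"))
  expect_error(iterative_closure(character(0), db), "empty seed")
  expect_error(iterative_closure("Z", db), "not in database")
})

test_that("closure is idempotent and monotone in seeds and threshold", {
  set.seed(5)
  ids <- paste0("s", 1:12)
  recs <- seq_set(ids, taxon = ids, gene_label = "APP",
                  residues = rep("MKVL", 12))
  edges <- expand.grid(query_id = ids, subject_id = ids,
                       stringsAsFactors = FALSE)
  edges <- edges[edges$query_id != edges$subject_id, ]
  edges <- edges[runif(nrow(edges)) < 0.15, ]
  edges$evalue <- 10^-sample(150:220, nrow(edges), TRUE)
  db <- seq_database(recs, hit_table_backend(edges))
  thr <- 1e-180
  c1 <- iterative_closure(c("s1", "s2"), db, thr)
  # idempotence
  c2 <- iterative_closure(c1$id, db, thr)
  expect_setequal(c2$id, c1$id)
  # seed monotonicity
  c3 <- iterative_closure(c("s1", "s2", "s5"), db, thr)
  expect_true(all(c1$id %in% c3$id))
  # threshold monotonicity (relaxing keeps everything)
  c4 <- iterative_closure(c("s1", "s2"), db, 1e-150)
  expect_true(all(c1$id %in% c4$id))
})

test_that("closure with the SW backend joins only near-identical pairs", {
  base <- paste0(rep("MKWVLFYACDEHIGNPQRST", 8), collapse = "")
  mut <- function(s, k, seed) {
    set.seed(seed)
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), k)
    ch[pos] <- vapply(ch[pos], function(x) sample(setdiff(AA_ALPHABET20, x), 1), "")
    paste0(ch, collapse = "")
  }
  recs <- seq_set(id = c("q", "near", "far"),
                  taxon = c("a", "b", "c"), gene_label = "APP",
                  residues = c(base, mut(base, 3, 1),
                               paste0(sample(AA_ALPHABET20, 160, TRUE), collapse = "")))
  db <- seq_database(recs)     # default exact SW backend
  out <- iterative_closure("q", db, evalue_threshold = 1e-60)
  expect_true("near" %in% out$id)
  expect_false("far" %in% out$id)
})

test_that("deduplication keeps the longest isoform per taxon and gene", {
  recs <- seq_set(
    id = c("APP695", "APP751", "APP770", "MUSAPP"),
    taxon = c("Homo sapiens", "Homo sapiens", "Homo sapiens", "Mus musculus"),
    gene_label = "APP",
    residues = c(strrep("M", 695), strrep("M", 751), strrep("M", 770),
                 strrep("M", 100)))
  out <- dedupe_longest_per_taxon_gene(recs)
  expect_setequal(out$id, c("APP770", "MUSAPP"))
  # ties break to the lexicographically smallest id
  t2 <- seq_set(id = c("B2", "A1"), taxon = c("x", "x"),
                gene_label = c("APP", "APP"), residues = c("MKVL", "MKVL"))
  expect_equal(dedupe_longest_per_taxon_gene(t2)$id, "A1")
  # single record survives; 'other' groups by taxon with a warning
  one <- seq_set("solo", "y", "APLP2", "MMM")
  expect_equal(dedupe_longest_per_taxon_gene(one)$id, "solo")
  oth <- seq_set(c("u1", "u2"), c("z", "z"), c("other", "other"),
                 c("MKV", "MKVL"))
  expect_warning(kept <- dedupe_longest_per_taxon_gene(oth), "taxon alone")
  expect_equal(kept$id, "u2")
  # at most one record per (taxon, gene) and each is a length maximum
  mix <- seq_set(paste0("r", 1:6),
                 taxon = c("a", "a", "a", "b", "b", "b"),
                 gene_label = c("APP", "APP", "APLP1", "APP", "APP", "APP"),
                 residues = c("MK", "MKV", "MKVL", "MKVLW", "MK", "MKV"))
  got <- dedupe_longest_per_taxon_gene(mix)
  expect_equal(nrow(got), 3L)
  expect_true(all(got$id %in% c("r2", "r3", "r4")))
})
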