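test_that("energy table calibration matches its documented anchors", {
  tab <- pairing_energy_table()
  # human Abeta42 C-terminal window is a strong fibril former ...
  cterm <- pasta_energy_profile("GAIIGLMVGGVVIA", tab)
  expect_lt(cterm$min_energy, -4)
  # ... and a poly-serine control never approaches the -2 line
  ser <- pasta_energy_profile(strrep("S", 20), tab)
  expect_gt(ser$min_energy, -2)
  # hydrophobic beats polar
  ivl <- pasta_energy_profile(strrep("IV", 10), tab)
  expect_lt(ivl$min_energy, ser$min_energy)
})

test_that("profiles carry sentinels where no pairing exists", {
  tab <- pairing_energy_table()
  short <- pasta_energy_profile("MKVLAGH", tab, min_strand_len = 4)
  expect_true(all(is.na(short$energy)))   # 7 < 2*4
  ok <- pasta_energy_profile("MKVLAGHW", tab, min_strand_len = 4)
  expect_false(any(is.na(ok$energy)))     # exactly one pairing covers all
})

test_that("energy profile equals the exhaustive window-pair oracle", {
  tab <- pairing_energy_table()
  set.seed(21)
  for (i in 1:12) {
    L <- sample(8:13, 1)
    s <- paste0(sample(AA_ALPHABET20, L, TRUE), collapse = "")
    mine <- pasta_energy_profile(s, tab)
    orac <- oracle_energy_profile(s, tab, 4)
    expect_equal(mine$energy, orac, tolerance = 1e-12, info = s)
  }
  # non-alphabet residues are neutral, not an error
  expect_message(p <- pasta_energy_profile("IVIVXIVIV", tab), "neutral")
  expect_false(any(is.na(p$energy)))
})

test_that("consensus predictor implements the k-of-n rule", {
  always <- function(seq) rep(TRUE, nchar(seq))
  never <- function(seq) rep(FALSE, nchar(seq))
  s <- "MKVLWGH"
  expect_true(all(consensus_predict(s, list(always), k = 1)))
  # flagged by exactly 1 of 3 at k = 2 -> not flagged
  expect_false(any(consensus_predict(s, list(always, never, never), k = 2)))
  expect_true(all(consensus_predict(s, list(always, always, never), k = 2)))
  expect_error(consensus_predict(s, list(always), k = 2), "exceeds")
})

test_that("consensus is antitone in k and in scorer thresholds", {
  set.seed(33)
  for (i in 1:20) {
    s <- paste0(sample(AA_ALPHABET20, 40, TRUE), collapse = "")
    f2 <- consensus_predict(s, k = 2)
    f3 <- consensus_predict(s, k = 3)
    expect_true(all(f3 <= f2), info = s)
    loose <- list(h = make_window_scorer(KD_HYDROPATHY, 5, 1.0))
    tight <- list(h = make_window_scorer(KD_HYDROPATHY, 5, 2.0))
    expect_true(all(consensus_predict(s, tight, k = 1) <=
                    consensus_predict(s, loose, k = 1)), info = s)
  }
})

test_that("segment classification applies the threshold bands", {
  # no consensus -> no segments regardless of energy
  e <- rep(-6, 10)
  expect_equal(nrow(classify_segments(e, rep(FALSE, 10))), 0L)
  # six -5 residues with consensus -> one high segment over all six
  seg <- classify_segments(rep(-5, 6), rep(TRUE, 6))
  expect_equal(seg, data.frame(start = 0L, end = 6L, class = "high"))
  # -3.5 band flanked by -2 -> one low segment of length 8
  e2 <- c(-2, rep(-3.5, 8), -2)
  seg2 <- classify_segments(e2, rep(TRUE, 10))
  expect_equal(seg2, data.frame(start = 1L, end = 9L, class = "low"))
  # runs shorter than min_run are dropped; NA energies never qualify
  e3 <- c(-5, -5, NA, -5, -5)
  expect_equal(nrow(classify_segments(e3, rep(TRUE, 5), min_run = 3)), 0L)
  expect_error(classify_segments(rep(-5, 4), rep(TRUE, 5)), "length")
})

test_that("high and low segments never overlap and respect the bands", {
  set.seed(9)
  for (i in 1:15) {
    n <- 30
    e <- runif(n, -6, 0)
    cons <- runif(n) < 0.6
    segs <- classify_segments(e, cons, min_run = 2)
    cover <- integer(0)
    for (j in seq_len(nrow(segs))) {
      idx <- (segs$start[j] + 1):segs$end[j]
      expect_true(all(!idx %in% cover))   # disjoint
      cover <- c(cover, idx)
      if (segs$class[j] == "high") expect_true(all(e[idx] < -4))
      if (segs$class[j] == "low") expect_true(all(e[idx] >= -4 & e[idx] <= -3))
      expect_true(all(cons[idx]))
    }
  }
})

test_that("truncation scan stops at the first crossing of -2", {
  tab <- pairing_energy_table()
  # already weak at full length: single entry
  one <- truncation_scan(strrep("S", 16), tab)
  expect_equal(nrow(one), 1L)
  expect_gt(one$min_energy[1], -2)
  # strong core eroded from the C-terminus: monotone bookkeeping
  s <- paste0(strrep("S", 2), strrep("V", 10), strrep("S", 10))
  scan <- truncation_scan(s, tab)
  expect_equal(scan$length, seq(nchar(s), by = -1, length.out = nrow(scan)))
  last <- scan$min_energy[nrow(scan)]
  expect_true(is.na(last) || last > -2)
  expect_true(all(scan$min_energy[-nrow(scan)] <= -2, na.rm = TRUE))
  # every entry equals a from-scratch evaluation of that prefix
  for (i in seq_len(nrow(scan))) {
    expect_equal(scan$min_energy[i],
                 pasta_energy_profile(substr(s, 1, scan$length[i]),
                                      tab)$min_energy)
  }
})

test_that("per-taxon class follows the two-region rule truth table", {
  seg <- function(cls) {
    if (is.na(cls)) {
      data.frame(start = integer(0), end = integer(0), class = character(0))
    } else {
      data.frame(start = 0L, end = 5L, class = cls)
    }
  }
  # enumerate all 3x3 window-class combinations
  want <- matrix(c(
    # C: high    low     none      (N down the rows)
    "high", "high", "none",   # N high
    "low",  "low",  "none",   # N low
    "none", "none", "none"),  # N none
    nrow = 3, byrow = TRUE)
  lv <- c("high", "low", NA)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(classify_taxon(seg(lv[i]), seg(lv[j])), want[i, j],
                 info = paste("N=", lv[i], "C=", lv[j]))
  }
  # a lone C-terminal high segment is not enough
  expect_equal(classify_taxon(seg(NA), seg("high")), "none")
})

test_that("energy table TSV round-trips through read_energy_table", {
  tab <- pairing_energy_table()
  f <- tempfile(fileext = ".tsv")
  con <- file(f, "w")
  for (ori in c("parallel", "antiparallel")) {
    writeLines(paste0("# orientation=", ori), con)
    utils::write.table(tab[[ori]], con, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  close(con)
  back <- read_energy_table(f)
  expect_equal(unname(back$parallel), unname(tab$parallel), tolerance = 1e-9)
  expect_equal(unname(back$antiparallel), unname(tab$antiparallel),
               tolerance = 1e-9)
})
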