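## Beta-pairing pseudo-energy model (PASTA-style).
##
## A pairing is a pair of equal-length ungapped windows of one sequence laid
## against each other in parallel or antiparallel orientation; its energy is
## the sum of tabulated residue-pair energies over the paired positions.
## Each residue's profile value is the minimum (most stabilizing) energy
## among all pairings whose windows cover it.  Interpretation thresholds
## follow the published convention: < -4 ordered beta-fibril former,
## -4..-3 marginal, > -2 non-amyloidogenic.
##
## The original published pairing tables are not redistributable here, so
## the packaged default is a clearly tagged synthetic surrogate: the
## negative outer product of a normalized Chou-Fasman beta-sheet propensity
## scale, affinely calibrated so that the human Abeta42 C-terminal window
## scores well below -4 while a poly-serine control stays above -2.

#' Kyte-Doolittle hydropathy scale
#' @export
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Chou-Fasman beta-sheet propensity scale (P-beta)
#' @export
CF_BETA_PROPENSITY <- c(
  A = 0.83, R = 0.93, N = 0.89, D = 0.54, C = 1.19, Q = 1.10, E = 0.37,
  G = 0.75, H = 0.87, I = 1.60, L = 1.30, K = 0.74, M = 1.05, F = 1.38,
  P = 0.55, S = 0.75, T = 1.19, W = 1.37, Y = 1.47, V = 1.70)

#' Build the packaged synthetic surrogate pairing-energy table
#'
#' `E(a, b) = gamma - alpha * p(a) * p(b)` with `p` the Chou-Fasman
#' beta-sheet propensity normalized by its maximum (valine).  The same
#' matrix is used for both orientations except for a mild multiplicative
#' penalty on the stabilizing part of parallel pairings, reflecting the
#' generally weaker parallel in-register stacking.
#'
#' @param alpha stabilization strength per strongly beta-prone residue pair.
#' @param gamma per-position offset; keeps weakly beta-prone pairings
#'   destabilizing so polar sequences never cross the -2 threshold.
#' @param parallel_scale multiplier on the stabilizing term for parallel
#'   pairings.
#' @return list of class `pairing_energy_table`: `parallel`, `antiparallel`
#'   (20 x 20 named matrices) and `provenance`.
#' @export
pairing_energy_table <- function(alpha = 2.2, gamma = 0.44,
                                 parallel_scale = 0.9) {
  p <- CF_BETA_PROPENSITY[AA_ALPHABET20] / max(CF_BETA_PROPENSITY)
  anti <- gamma - alpha * outer(p, p)
  par <- gamma - parallel_scale * alpha * outer(p, p)
  dimnames(anti) <- dimnames(par) <- list(AA_ALPHABET20, AA_ALPHABET20)
  structure(list(parallel = par, antiparallel = anti,
                 provenance = "synthetic-surrogate (Chou-Fasman outer product)"),
            class = "pairing_energy_table")
}

#' Read a pairing-energy table from TSV
#'
#' Format: a `# orientation=parallel|antiparallel` comment introduces each
#' 20 x 20 block (tab-separated, row and column names = one-letter codes).
#' A file with a single block is used for both orientations.
#' @param path TSV file.
#' @export
read_energy_table <- function(path) {
  lines <- readLines(path)
  marks <- grep("^#\\s*orientation=", lines)
  if (!length(marks)) stop("no '# orientation=' blocks in ", path)
  blocks <- list()
  bounds <- c(marks, length(lines) + 1L)
  for (i in seq_along(marks)) {
    ori <- sub("^#\\s*orientation=", "", lines[marks[i]])
    body <- lines[(marks[i] + 1L):(bounds[i + 1L] - 1L)]
    m <- as.matrix(utils::read.delim(text = body, row.names = 1L,
                                     check.names = FALSE))
    if (!identical(sort(rownames(m)), sort(AA_ALPHABET20))) {
      stop("energy table block must cover the 20 amino acids")
    }
    blocks[[ori]] <- m[AA_ALPHABET20, AA_ALPHABET20]
  }
  if (is.null(blocks$antiparallel)) blocks$antiparallel <- blocks[[1]]
  if (is.null(blocks$parallel)) blocks$parallel <- blocks$antiparallel
  structure(list(parallel = blocks$parallel,
                 antiparallel = blocks$antiparallel,
                 provenance = paste0("file:", path)),
            class = "pairing_energy_table")
}

encode_for_energy <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  idx <- match(chars, AA_ALPHABET20)
  if (anyNA(idx)) {
    message(sum(is.na(idx)),
            " residue(s) outside the 20-letter alphabet scored as neutral")
    idx[is.na(idx)] <- 21L
  }
  idx
}

pad_energy_matrix <- function(mat) {
  out <- rbind(cbind(mat, 0), 0)   # 21st row/col: neutral unknown residue
  out
}

## enumerate all admissible pairings, calling f(i, j, len, orient, energy)
## for each.  A pairing is two equal-length, ungapped, NON-overlapping
## windows (two strands of one chain cannot share residues), evaluated in
## both orientations; hence no pairing exists below 2*min_len residues.
for_each_pairing <- function(idx, epar, eanti, min_len, f) {
  L <- length(idx)
  if (L < 2L * min_len) return(invisible(NULL))
  for (len in min_len:(L %/% 2L)) {
    starts <- seq_len(L - len + 1L)
    for (i in starts) {
      wi <- idx[i:(i + len - 1L)]
      for (j in starts) {
        if (abs(j - i) < len) next              # overlapping windows
        wj <- idx[j:(j + len - 1L)]
        f(i, j, len, "parallel", sum(epar[cbind(wi, wj)]))
        f(i, j, len, "antiparallel", sum(eanti[cbind(wi, rev(wj))]))
      }
    }
  }
  invisible(NULL)
}

#' Per-residue best beta-pairing energy profile
#'
#' @param seq amino-acid string; residues outside the 20-letter alphabet
#'   contribute zero energy.
#' @param table a [pairing_energy_table()].
#' @param min_strand_len minimum paired-window length (default 4).
#' @return list of class `energy_profile`: `energy` (per-residue minima,
#'   `NA` where no admissible pairing covers the residue), `best` (per
#'   residue: window start/partner start/length/orientation of the best
#'   covering pairing, 0-based half-open starts), `min_energy` and `seq`.
#' @export
pasta_energy_profile <- function(seq, table = pairing_energy_table(),
                                 min_strand_len = 4) {
  idx <- encode_for_energy(seq)
  L <- length(idx)
  energy <- rep(NA_real_, L)
  best <- data.frame(start = rep(NA_integer_, L), partner = NA_integer_,
                     len = NA_integer_, orientation = NA_character_)
  epar <- pad_energy_matrix(table$parallel)
  eanti <- pad_energy_matrix(table$antiparallel)
  if (L >= 2L * min_strand_len) {
    env <- environment()
    for_each_pairing(idx, epar, eanti, min_strand_len,
      function(i, j, len, orient, e) {
        cover <- unique(c(i:(i + len - 1L), j:(j + len - 1L)))
        upd <- cover[is.na(env$energy[cover]) | e < env$energy[cover]]
        if (length(upd)) {
          env$energy[upd] <- e
          env$best$start[upd] <- i - 1L
          env$best$partner[upd] <- j - 1L
          env$best$len[upd] <- len
          env$best$orientation[upd] <- orient
        }
      })
  }
  structure(list(energy = energy, best = best,
                 min_energy = if (all(is.na(energy))) NA_real_ else min(energy, na.rm = TRUE),
                 seq = toupper(seq)),
            class = "energy_profile")
}

## global minimum pairing energy only (cheaper than the full profile)
global_min_energy <- function(seq, table, min_strand_len) {
  idx <- encode_for_energy(seq)
  if (length(idx) < 2L * min_strand_len) return(NA_real_)
  epar <- pad_energy_matrix(table$parallel)
  eanti <- pad_energy_matrix(table$antiparallel)
  env <- new.env()
  env$m <- Inf
  for_each_pairing(idx, epar, eanti, min_strand_len,
                   function(i, j, len, orient, e) if (e < env$m) env$m <- e)
  if (is.infinite(env$m)) NA_real_ else env$m
}

#' C-terminal truncation scan of pairing energy
#'
#' Records the global minimum pairing energy of the full sequence, then of
#' each successive C-terminal truncation, stopping the first time the
#' energy rises above `stop_above` (that entry is included).  A length too
#' short for any pairing yields `NA` energy and also stops the scan.
#'
#' @inheritParams pasta_energy_profile
#' @param stop_above stop threshold (-2 by the published convention).
#' @return data.frame with `length` and `min_energy`.
#' @export
truncation_scan <- function(seq, table = pairing_energy_table(),
                            min_strand_len = 4, stop_above = -2) {
  seq <- toupper(seq)
  stopifnot(nchar(seq) >= 1)
  out <- list()
  for (len in nchar(seq):1) {
    e <- global_min_energy(substr(seq, 1L, len), table, min_strand_len)
    out[[length(out) + 1L]] <- data.frame(length = len, min_energy = e)
    if (is.na(e) || e > stop_above) break
  }
  do.call(rbind, out)
}
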