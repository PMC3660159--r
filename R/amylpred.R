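## k-of-n consensus aggregation predictor.
##
## The published consensus tool combines five proprietary component methods
## with an agreement-of-2 rule; those components are replaced here by three
## documented built-in window scorers (hydropathy, beta-sheet propensity,
## amyloid-prone hexapeptide stretch), keeping the k-of-n consensus rule
## itself.  Each scorer flags every residue of any sliding window whose
## statistic passes its threshold, so predictions are antitone in both k
## and the thresholds.

#' Build a sliding-window scale scorer
#'
#' Flags all residues of every window whose mean scale value is at least
#' `threshold`.  Residues outside the scale (e.g. `X`) take the scale
#' minimum, so they never create flags on their own.
#'
#' @param scale named numeric vector over amino acids.
#' @param window window length.
#' @param threshold mean-scale cutoff.
#' @return function: character scalar -> logical vector.
#' @export
make_window_scorer <- function(scale, window = 5, threshold) {
  force(scale); force(window); force(threshold)
  function(seq) {
    chars <- strsplit(toupper(seq), "")[[1]]
    v <- scale[chars]
    v[is.na(v)] <- min(scale)
    n <- length(v)
    flags <- logical(n)
    if (n >= window) {
      cs <- c(0, cumsum(v))
      means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
      for (s in which(means >= threshold)) {
        flags[s:(s + window - 1L)] <- TRUE
      }
    }
    flags
  }
}

#' Hexapeptide stretch scorer
#'
#' Flags windows of `window` residues drawn entirely from an
#' amyloid-prone residue set (beta-branched/aromatic/hydrophobic).
#'
#' @param window window length (6: the classic hexapeptide motif length).
#' @param amyloid_set residues considered amyloid-prone.
#' @return scorer function.
#' @export
hexapeptide_scorer <- function(window = 6,
                               amyloid_set = c("I", "V", "F", "L", "Y",
                                               "W", "M", "A", "T", "C")) {
  force(window); force(amyloid_set)
  function(seq) {
    chars <- strsplit(toupper(seq), "")[[1]]
    ok <- chars %in% amyloid_set
    n <- length(ok)
    flags <- logical(n)
    if (n >= window) {
      run <- stats::filter(as.numeric(ok), rep(1, window), sides = 1)
      for (e in which(!is.na(run) & run == window)) {
        flags[(e - window + 1L):e] <- TRUE
      }
    }
    flags
  }
}

#' Default component scorers for the consensus predictor
#'
#' Hydropathy (Kyte-Doolittle, window 5, mean >= 1.6 -- the classic
#' membrane-interaction cutoff), beta-sheet propensity (Chou-Fasman, window
#' 5, mean >= 1.05, i.e. net beta-former), and a hexapeptide stretch scorer.
#' @return named list of scorer functions.
#' @export
default_scorers <- function() {
  list(
    hydropathy = make_window_scorer(KD_HYDROPATHY, window = 5, threshold = 1.6),
    beta_propensity = make_window_scorer(CF_BETA_PROPENSITY, window = 5,
                                         threshold = 1.05),
    hexapeptide = hexapeptide_scorer())
}

#' Per-residue k-of-n consensus prediction
#'
#' @param seq amino-acid string.
#' @param scorers list of scorer functions (see [default_scorers()]).
#' @param k minimum number of agreeing scorers (2 by the published rule).
#' @return logical vector, one flag per residue.
#' @export
consensus_predict <- function(seq, scorers = default_scorers(), k = 2) {
  if (k > length(scorers)) {
    stop("k = ", k, " exceeds the number of scorers (", length(scorers), ")")
  }
  votes <- vapply(scorers, function(f) f(seq), logical(nchar(seq)))
  if (nchar(seq) == 1L) votes <- matrix(votes, nrow = 1L)
  rowSums(votes) >= k
}

#' Classify amyloidogenic segments from energy + consensus
#'
#' Maximal runs of residues with pairing energy < `t_high` AND consensus
#' become `high` segments; runs with energy in `[t_high, t_low]` AND
#' consensus become `low`; runs shorter than `min_run` are dropped.
#' Residues with sentinel (`NA`) energy never qualify.
#'
#' @param profile an [pasta_energy_profile()] result or numeric energy
#'   vector.
#' @param consensus logical vector from [consensus_predict()].
#' @param t_high,t_low class thresholds (-4 and -3 by the published
#'   convention).
#' @param min_run minimum reportable segment length.
#' @return data.frame `start`, `end` (0-based half-open), `class`.
#' @export
classify_segments <- function(profile, consensus, t_high = -4, t_low = -3,
                              min_run = 3) {
  energy <- if (inherits(profile, "energy_profile")) profile$energy else profile
  if (length(energy) != length(consensus)) {
    stop("profile length ", length(energy), " != consensus length ",
         length(consensus))
  }
  state <- rep("none", length(energy))
  ok <- !is.na(energy) & consensus
  state[ok & energy < t_high] <- "high"
  state[ok & energy >= t_high & energy <= t_low] <- "low"
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "none" & r$lengths >= min_run
  data.frame(start = starts[keep] - 1L, end = ends[keep],
             class = r$values[keep], stringsAsFactors = FALSE)
}

#' Two-region per-taxon amyloid class
#'
#' A stable amyloid beta-fold needs two aggregation-prone regions in the
#' peptide: the class is `high` when both the N- and C-terminal windows
#' contain a qualifying segment and the best N-terminal segment is `high`;
#' `low` when both contain one and the best N-terminal segment is `low`;
#' `none` when either window lacks a qualifying segment.
#'
#' @param n_segments,c_segments [classify_segments()] results for the
#'   N-terminal and C-terminal windows.
#' @return `"high"`, `"low"` or `"none"`.
#' @export
classify_taxon <- function(n_segments, c_segments) {
  if (nrow(n_segments) == 0L || nrow(c_segments) == 0L) return("none")
  if (any(n_segments$class == "high")) "high" else "low"
}

#' Annotate tree tips with per-taxon amyloid classes
#'
#' @param tree `phylo`.
#' @param classes character vector named by tip label with values
#'   `high`/`low`/`none`; tips without a class get `none` with a warning.
#' @return the tree with `tip.class` set (serialized by [write_newick()]).
#' @export
annotate_tree_with_classes <- function(tree, classes) {
  missing <- setdiff(tree$tip.label, names(classes))
  if (length(missing)) {
    warning("no class for ", length(missing), " tip(s); set to 'none': ",
            paste(missing, collapse = ", "))
    classes[missing] <- "none"
  }
  bad <- setdiff(unique(classes), c("high", "low", "none"))
  if (length(bad)) stop("unknown class values: ", paste(bad, collapse = ", "))
  tree$tip.class <- classes[tree$tip.label]
  counts <- table(factor(tree$tip.class, levels = c("high", "low", "none")))
  message("amyloid classes on tree: ",
          paste(names(counts), counts, sep = "=", collapse = ", "))
  tree
}
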