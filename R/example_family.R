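## The packaged example world: a toy gene family shaped like the AbetaPP
## family.  Five planted clades stand in for the five major branches
## (APP, APLP1, APLP2, APL-1, APPL-1); a domain layout analogous to
## NTS / E1 / E2 / E3 / beta-A4 carries domain-structured rates (E2
## analogue fastest, E3 analogue slowest -- the pattern the real family
## shows); the APP-analogue clade gets aggregation-prone windows planted
## on both sides of the beta-A4 alpha-split so the two-region rule fires.

clade_sizes <- function(n, k) {
  if (n < 2L * k) stop("need at least ", 2L * k, " non-outgroup tips")
  base <- rep(2L, k)
  extra <- n - 2L * k
  base + tabulate((seq_len(extra) - 1L) %% k + 1L, nbins = k)
}

#' Build the default simulated family configuration
#'
#' @param seed RNG seed for both tree and evolution.
#' @param n_tips number of tips (>= 14 so five clades plus an outgroup fit).
#' @param sequence_length alignment length (default 240).
#' @param subs_per_site expected root-to-tip substitutions per unit-rate
#'   site (low-homoplasy default 0.2).
#' @param polar_background sample the root from polar residues only
#'   (sharpens the contrast of planted hydrophobic windows).
#' @return list: `tree`, `config` ([sim_config()]), `cleavage`
#'   (per-reference cleavage annotation), `gene_of_clade`.
#' @export
example_family_config <- function(seed, n_tips = 18, sequence_length = 240,
                                  subs_per_site = 0.2,
                                  polar_background = TRUE) {
  stopifnot(n_tips >= 11, sequence_length >= 240)
  # five clade subtrees grafted on a ladder backbone plus one outgroup tip:
  # guarantees five disjoint monophyletic "major branches" at any n_tips
  sizes <- clade_sizes(n_tips - 1L, 5L)
  set.seed(seed)
  sub <- lapply(sizes, function(k) {
    t <- if (k == 1L) NULL else ape::rphylo(k, birth = 1, death = 0)
    t
  })
  lab_start <- cumsum(c(0, sizes))
  sub_nwk <- vapply(seq_along(sub), function(i) {
    labs <- sprintf("t%02d", lab_start[i] + seq_len(sizes[i]))
    t <- sub[[i]]; t$tip.label <- labs
    paste0(sub(";$", "", ape::write.tree(t)), ":0.5")
  }, "")
  og <- sprintf("t%02d", n_tips)
  nwk <- sprintf("(((((%s,%s):0.3,%s):0.3,%s):0.3,%s):0.3,%s:1.5);",
                 sub_nwk[1], sub_nwk[2], sub_nwk[3], sub_nwk[4], sub_nwk[5],
                 og)
  tree <- ape::read.tree(text = nwk)
  clades <- lapply(seq_along(sizes), function(i) {
    sprintf("t%02d", lab_start[i] + seq_len(sizes[i]))
  })
  names(clades) <- paste0("clade", LETTERS[1:5])
  gene_of_clade <- c(cladeA = "APP", cladeB = "APLP2", cladeC = "APLP1",
                     cladeD = "APL-1", cladeE = "APPL-1")
  L <- sequence_length
  ref <- clades$cladeA[1]
  dmap <- domain_map(
    name  = c("NTS", "E1", "E2", "E3", "bA4"),
    start = c(0L, 24L, 102L, 180L, 186L),
    end   = c(18L, 78L, 168L, L, 228L),
    reference_id = ref, allow_overlap = TRUE)
  rates <- c(NTS = 1.5, E1 = 1.0, E2 = 5.0, E3 = 0.2, bA4 = 0.3)
  # two diagnostic substitutions per clade, spread over distinct domains,
  # away from the beta-A4 plant windows
  cols <- c(5L, 30L, 40L, 110L, 120L, 130L, 140L, 150L, 60L, 70L)
  ps <- data.frame(
    clade = rep(names(clades), each = 2),
    column = cols,
    derived = rep(c("W", "H", "C", "M", "Y"), each = 2),
    stringsAsFactors = FALSE)
  # beta-A4 analogue [186, 228), alpha split at 204:
  #   N window [186, 204), C window [204, 228)
  plants <- list(
    list(ids = clades$cladeA, position = 190L, length = 10L),  # N window
    list(ids = clades$cladeA, position = 208L, length = 12L),  # C window
    list(ids = clades$cladeB, position = 208L, length = 12L))  # C only
  cleavage <- data.frame(id = ref, start = 186L, end = 228L, alpha = 204L)
  bg <- NULL
  if (polar_background) {
    bg <- stats::setNames(rep(1, 8), c("S", "G", "N", "D", "E", "K", "P", "R"))
  }
  config <- sim_config(
    sequence_length = L, domains = dmap, domain_rates = rates,
    clades = clades, planted_synapomorphies = ps, amyloid_plants = plants,
    subs_per_site = subs_per_site, root_weights = bg,
    gene_labels = gene_of_clade, seed = seed)
  list(tree = tree, config = config, cleavage = cleavage,
       gene_of_clade = gene_of_clade)
}
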