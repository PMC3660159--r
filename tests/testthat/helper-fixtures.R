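# Small fixture builders shared across test files.

tree_of <- function(newick) ape::read.tree(text = newick)

# random rooted binary tree with tips t1..tn
random_tree <- function(n, seed) {
  set.seed(seed)
  t <- ape::rtree(n)
  t$tip.label <- paste0("t", seq_len(n))
  t$edge.length <- NULL
  t
}

# random character matrix over a small alphabet
random_matrix <- function(n_taxa, n_cols, seed, alphabet = c("A", "C", "D", "E"),
                          p_missing = 0) {
  set.seed(seed)
  cells <- sample(alphabet, n_taxa * n_cols, replace = TRUE)
  if (p_missing > 0) {
    miss <- runif(length(cells)) < p_missing
    cells[miss] <- "-"
  }
  matrix(cells, nrow = n_taxa,
         dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
}

fasta_file <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

small_seq_set <- function() {
  seq_set(id = c("X1", "X2", "X3"),
          taxon = c("Homo sapiens", "Homo sapiens", "Mus musculus"),
          gene_label = c("APP", "APP", "APLP1"),
          residues = c("MLPGLALLLL", "MLPGL", "MKVVTW"))
}
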