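## Iterative homolog collection.
##
## This is the classic harvest strategy for a gene family: stringent
## (effectively zero E-value) protein similarity searches repeated for
## every newly found sequence until a fixed point.  Live remote searches
## are out of scope; the closure algorithm runs over a local database
## behind a pluggable search backend.  The built-in backend is exact Smith-Waterman local
## alignment (via Biostrings) with Karlin-Altschul E-values; a literal
## floating-point zero E-value is representation-dependent, so stringency
## is expressed as E <= epsilon (default 1e-180).

get_subst_matrix <- function(name) {
  if (is.matrix(name)) return(name)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Smith-Waterman local alignment score and spans
#'
#' Exact optimal local alignment with affine gaps.  Residues outside the
#' 20-letter alphabet plus `X` are scored as `X` (not an error).  A pair
#' with no positive-scoring alignment returns score 0 and empty spans.
#'
#' @param a,b amino-acid strings.
#' @param substitution_matrix matrix or a Biostrings matrix name
#'   (`"BLOSUM62"`, `"BLOSUM50"`, ...).
#' @param gap_open,gap_extend penalties (positive numbers).
#' @return list: `score`, `a_span`, `b_span` (0-based half-open; empty =
#'   `c(0, 0)`), `a_aln`, `b_aln` (aligned strings with gaps).
#' @export
local_align_score <- function(a, b, substitution_matrix = "BLOSUM62",
                              gap_open = 10, gap_extend = 1) {
  stopifnot(nzchar(a), nzchar(b))
  mat <- get_subst_matrix(substitution_matrix)
  clean <- function(s) {
    s <- toupper(s)
    chars <- strsplit(s, "")[[1]]
    chars[!chars %in% rownames(mat)] <- "X"
    paste0(chars, collapse = "")
  }
  pa <- Biostrings::pairwiseAlignment(
    clean(a), clean(b), type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  s <- Biostrings::score(pa)
  if (s <= 0) {
    return(list(score = 0, a_span = c(0L, 0L), b_span = c(0L, 0L),
                a_aln = "", b_aln = ""))
  }
  p <- Biostrings::pattern(pa); q <- Biostrings::subject(pa)
  list(score = s,
       a_span = c(Biostrings::start(p) - 1L, Biostrings::end(p)),
       b_span = c(Biostrings::start(q) - 1L, Biostrings::end(q)),
       a_aln = as.character(p), b_aln = as.character(q))
}

#' Karlin-Altschul E-value from a raw local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: expected number of chance local
#' alignments scoring at least `S` between sequences of lengths `m`, `n`.
#'
#' @param score raw score `S`.
#' @param m,n sequence (or search-space) lengths, >= 1.
#' @param K,lambda Karlin-Altschul parameters (> 0); defaults are the
#'   classic gapped BLOSUM62 values.
#' @export
evalue_from_score <- function(score, m, n, K = 0.041, lambda = 0.267) {
  stopifnot(K > 0, lambda > 0, m >= 1, n >= 1)
  K * m * n * exp(-lambda * score)
}

#' Sequence database with a pluggable search backend
#'
#' @param records a [seq_set()].
#' @param backend function `(db, query_id) -> hit data.frame` with columns
#'   `query_id`, `subject_id`, `score`, `bitscore`, `evalue`,
#'   `q_start`, `q_end`, `s_start`, `s_end` (0-based half-open spans);
#'   default [sw_backend()].
#' @return list of class `seq_database`.
#' @export
seq_database <- function(records, backend = sw_backend()) {
  stopifnot(inherits(records, "seq_set"))
  structure(list(records = records, backend = backend),
            class = "seq_database")
}

#' Built-in exact Smith-Waterman search backend
#'
#' @inheritParams local_align_score
#' @param K,lambda Karlin-Altschul parameters for [evalue_from_score()].
#' @return backend function for [seq_database()].
#' @export
sw_backend <- function(substitution_matrix = "BLOSUM62", gap_open = 10,
                       gap_extend = 1, K = 0.041, lambda = 0.267) {
  mat <- get_subst_matrix(substitution_matrix)
  function(db, query_id) {
    rec <- db$records
    qi <- match(query_id, rec$id)
    if (is.na(qi)) stop("query not in database: ", query_id)
    q <- rec$residues[qi]
    rows <- lapply(seq_len(nrow(rec)), function(i) {
      al <- local_align_score(q, rec$residues[i], mat, gap_open, gap_extend)
      data.frame(query_id = query_id, subject_id = rec$id[i],
                 score = al$score,
                 bitscore = (lambda * al$score - log(K)) / log(2),
                 evalue = evalue_from_score(al$score, nchar(q),
                                            rec$length[i], K, lambda),
                 q_start = al$a_span[1], q_end = al$a_span[2],
                 s_start = al$b_span[1], s_end = al$b_span[2],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
}

#' Search backend serving a fixed hit table
#'
#' Useful for tests and for importing externally computed (e.g. tabular
#' BLAST) hits.  Missing span/score columns are filled with zeros.
#'
#' @param hits data.frame with at least `query_id`, `subject_id`, `evalue`.
#' @return backend function for [seq_database()].
#' @export
hit_table_backend <- function(hits) {
  stopifnot(all(c("query_id", "subject_id", "evalue") %in% names(hits)))
  for (col in c("score", "bitscore", "q_start", "q_end", "s_start", "s_end")) {
    if (is.null(hits[[col]])) hits[[col]] <- 0
  }
  function(db, query_id) hits[hits$query_id == query_id, , drop = FALSE]
}

#' Iterative similarity closure over a sequence database
#'
#' Least fixed point of "add every subject whose hit from any current
#' member passes the threshold": seeds in, then each newly added sequence
#' is itself queried, until an iteration adds nothing.  Self-hits are
#' ignored.  The result does not depend on seed processing order.
#'
#' @param seed_ids non-empty character vector of database ids.
#' @param db a [seq_database()].
#' @param evalue_threshold inclusion stringency (`E <= threshold`);
#'   1e-180 approximates the "E-value = 0.0" setting deterministically.
#' @return [seq_set()] of the closure members (database order), with
#'   attributes `n_iterations` and `rounds` (per-round added ids).
#' @export
iterative_closure <- function(seed_ids, db, evalue_threshold = 1e-180) {
  if (!length(seed_ids)) stop("empty seed set")
  missing <- setdiff(seed_ids, db$records$id)
  if (length(missing)) stop("seeds not in database: ",
                            paste(missing, collapse = ", "))
  member <- unique(seed_ids)
  frontier <- member
  rounds <- list()
  while (length(frontier)) {
    added <- character(0)
    for (q in frontier) {
      hits <- db$backend(db, q)
      pass <- hits$subject_id[hits$evalue <= evalue_threshold &
                                hits$subject_id != q]
      added <- union(added, setdiff(pass, member))
    }
    if (!length(added)) break
    rounds[[length(rounds) + 1L]] <- sort(added)
    member <- c(member, added)
    frontier <- added
  }
  out <- db$records[db$records$id %in% member, , drop = FALSE]
  attr(out, "alphabet") <- attr(db$records, "alphabet")
  class(out) <- class(db$records)
  attr(out, "n_iterations") <- length(rounds)
  attr(out, "rounds") <- rounds
  out
}

#' Keep the single longest record per (taxon, gene label)
#'
#' Reproduces the longest-isoform rule (e.g. keeping the 770-residue human
#' AbetaPP over the 695/751 isoforms).  Ties break to the
#' lexicographically smallest id.  Records labelled `other` group by taxon
#' alone, with a warning.
#'
#' @param records a [seq_set()].
#' @return deduplicated [seq_set()] in input order.
#' @export
dedupe_longest_per_taxon_gene <- function(records) {
  stopifnot(inherits(records, "seq_set"))
  if (any(records$gene_label == "other")) {
    warning("records labelled 'other' are grouped by taxon alone")
  }
  key <- ifelse(records$gene_label == "other",
                paste0(records$taxon, "\r"),
                paste0(records$taxon, "\r", records$gene_label))
  keep <- logical(nrow(records))
  for (k in unique(key)) {
    idx <- which(key == k)
    best <- idx[order(-records$length[idx], records$id[idx])][1]
    keep[best] <- TRUE
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "alphabet") <- attr(records, "alphabet")
  class(out) <- class(records)
  out
}

#' Write a hit table as TSV (spans printed 1-based inclusive)
#' @param hits backend hit data.frame.
#' @param path output file.
#' @export
write_hit_table <- function(hits, path) {
  out <- data.frame(query = hits$query_id, subject = hits$subject_id,
                    score = hits$score, bitscore = round(hits$bitscore, 2),
                    evalue = format(hits$evalue, digits = 3),
                    q_start = hits$q_start + 1L, q_end = hits$q_end,
                    s_start = hits$s_start + 1L, s_end = hits$s_end)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
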