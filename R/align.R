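## Alignment adapter.
##
## Multiple sequence alignment is not this package's business: production
## runs should hand in an alignment or configure an external aligner
## command.  The built-in fallback is a plain center-star progressive
## alignment (global pairwise alignments against the highest-total-score
## center sequence, gaps merged through the center) -- adequate for toy and
## simulated data, explicitly NOT for production phylogenetics.

center_star_align <- function(seqs, substitution_matrix = "BLOSUM62",
                              gap_open = 10, gap_extend = 1) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  n <- length(seqs)
  if (n == 1L) return(aligned_matrix(seqs))
  mat <- get_subst_matrix(substitution_matrix)
  clean <- vapply(seqs, function(s) {
    chars <- strsplit(toupper(s), "")[[1]]
    chars[!chars %in% rownames(mat)] <- "X"
    paste0(chars, collapse = "")
  }, "")
  pair_score <- function(a, b) {
    Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend))
  }
  total <- numeric(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- pair_score(clean[i], clean[j])
      total[i] <- total[i] + s
      total[j] <- total[j] + s
    }
  }
  ci <- which.max(total)
  center <- clean[ci]
  # msa rows as char vectors; map[k] = msa column of center residue k
  rows <- list()
  rows[[names(seqs)[ci]]] <- strsplit(seqs[[ci]], "")[[1]]
  map <- seq_len(nchar(center))
  for (oi in setdiff(seq_len(n), ci)) {
    pa <- Biostrings::pairwiseAlignment(
      clean[oi], center, type = "global", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend)
    po <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
    co <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
    orig <- strsplit(seqs[[oi]], "")[[1]]   # un-X-ified residues
    oresid <- 0L
    newrow <- rep("-", max(map))
    k <- 0L
    ins <- 0L                # consecutive insertions after center residue k
    for (t in seq_along(co)) {
      if (co[t] != "-") {
        k <- k + 1L
        ins <- 0L
        if (po[t] != "-") {
          oresid <- oresid + 1L
          newrow[map[k]] <- orig[oresid]
        }
      } else {
        # insertion relative to the center: new msa column after residue k
        # (and after any insertion just made in this run)
        at <- (if (k == 0L) 0L else map[k]) + ins + 1L
        ins <- ins + 1L
        for (rn in names(rows)) {
          rows[[rn]] <- append(rows[[rn]], "-", after = at - 1L)
        }
        newrow <- append(newrow, "-", after = at - 1L)
        oresid <- oresid + 1L
        newrow[at] <- orig[oresid]
        map[map >= at] <- map[map >= at] + 1L
      }
    }
    rows[[names(seqs)[oi]]] <- newrow
  }
  width <- max(lengths(rows))
  strs <- vapply(rows, function(r) {
    paste0(c(r, rep("-", width - length(r))), collapse = "")
  }, "")
  aligned_matrix(strs[names(seqs)])
}

#' Align sequences via an external command or the built-in fallback
#'
#' With `external_cmd`, the command is run as
#' `<external_cmd> <input.fasta>` and must print aligned FASTA on stdout
#' (e.g. `"mafft --auto"`); a failure raises an error carrying the captured
#' output.  Without it, the toy center-star fallback is used.  In either
#' case every output row, degapped, is checked to equal its input.
#'
#' @param records a [seq_set()].
#' @param external_cmd optional aligner command prefix.
#' @return aligned matrix with the records' metadata attached.
#' @export
align_adapter <- function(records, external_cmd = NULL) {
  stopifnot(inherits(records, "seq_set"))
  seqs <- stats::setNames(records$residues, records$id)
  if (!is.null(external_cmd)) {
    tmp <- tempfile(fileext = ".fasta")
    on.exit(unlink(tmp))
    write_fasta(records, tmp)
    out <- suppressWarnings(
      system(paste(external_cmd, shQuote(tmp)), intern = TRUE))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0) {
      stop("external aligner failed (status ", status, "):\n",
           paste(utils::tail(out, 20), collapse = "\n"))
    }
    tmp2 <- tempfile(fileext = ".fasta")
    on.exit(unlink(tmp2), add = TRUE)
    writeLines(out, tmp2)
    m <- read_alignment_fasta(tmp2, attr(records, "alphabet") %||% "aa")
  } else {
    m <- center_star_align(seqs)
  }
  got <- gsub("-", "", alignment_strings(m), fixed = TRUE)
  if (!identical(sort(names(got)), sort(names(seqs))) ||
      !all(got[names(seqs)] == seqs)) {
    stop("aligner output does not degap back to its input")
  }
  m <- m[records$id, , drop = FALSE]
  attr(m, "alphabet") <- attr(records, "alphabet") %||% "aa"
  attr(m, "meta") <- records[, c("id", "taxon", "gene_label")]
  m
}
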