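#' @keywords internal
"_PACKAGE"

## Shared constants -----------------------------------------------------------

#' The 20-letter amino-acid alphabet used throughout the package
#'
#' Order is alphabetical by one-letter code.  `X` is accepted in sequences as
#' an unknown residue; `-` is the only gap character (`.` is normalized to `-`
#' on read).
#' @export
AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

NT_ALPHABET <- c("A", "C", "G", "T", "U", "N")

KNOWN_GENE_LABELS <- c("APP", "APLP1", "APLP2", "APL-1", "APPL-1", "other")

## Sequence records ------------------------------------------------------------

#' Construct a set of sequence records
#'
#' A sequence set is a plain `data.frame` with columns `id`, `taxon`,
#' `gene_label` and `residues`; `length` is derived.  Ids must be unique,
#' residues non-empty and drawn from the declared alphabet plus `X`
#' (amino-acid) or `N` (nucleotide).
#'
#' @param id character vector of accession-like identifiers.
#' @param taxon character vector of species names.
#' @param gene_label one of `APP`, `APLP1`, `APLP2`, `APL-1`, `APPL-1`,
#'   `other`.  Unknown labels are coerced to `other` with a warning.
#' @param residues character vector of sequences.
#' @param alphabet `"aa"` or `"nt"`.
#' @return data.frame with class `c("seq_set", "data.frame")` and attribute
#'   `alphabet`.
#' @export
seq_set <- function(id, taxon, gene_label, residues, alphabet = "aa") {
  alphabet <- match.arg(alphabet, c("aa", "nt"))
  id <- as.character(id)
  taxon <- as.character(taxon)
  gene_label <- as.character(gene_label)
  residues <- toupper(as.character(residues))
  if (anyDuplicated(id)) {
    stop("duplicate sequence ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(residues))) stop("residues must be non-empty")
  bad <- !gene_label %in% KNOWN_GENE_LABELS
  if (any(bad)) {
    warning("unknown gene_label(s) coerced to 'other': ",
            paste(unique(gene_label[bad]), collapse = ", "))
    gene_label[bad] <- "other"
  }
  ok <- c(if (alphabet == "aa") AA_ALPHABET20 else NT_ALPHABET,
          if (alphabet == "aa") "X")
  resid_chars <- unique(unlist(strsplit(residues, "")))
  stray <- setdiff(resid_chars, ok)
  if (length(stray)) {
    stop("residues contain characters outside the ", alphabet,
         " alphabet: ", paste(stray, collapse = ""))
  }
  out <- data.frame(id = id, taxon = taxon, gene_label = gene_label,
                    residues = residues, length = nchar(residues),
                    stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  class(out) <- c("seq_set", "data.frame")
  out
}

#' Read sequences from FASTA with the `id|taxon|gene_label` header dialect
#'
#' Headers are split on `|`.  A missing third field yields
#' `gene_label = "other"` with a warning; a missing second field is a parse
#' error.  `*` stop symbols are stripped, `.` gaps normalized to `-`, and any
#' residue outside the alphabet (plus `X`) is replaced by `X` with a warning.
#' Gapped input sequences are rejected here; use [read_alignment_fasta()]
#' for alignments.
#'
#' @param path FASTA file.
#' @param alphabet `"aa"` or `"nt"`.
#' @return a [seq_set()].
#' @export
read_fasta <- function(path, alphabet = "aa") {
  alphabet <- match.arg(alphabet, c("aa", "nt"))
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA input: ", path)
  headers <- names(ss)
  parts <- strsplit(headers, "|", fixed = TRUE)
  nfields <- lengths(parts)
  if (any(nfields < 2L)) {
    bad <- which(nfields < 2L)[1L]
    stop("malformed FASTA header (need 'id|taxon[|gene_label]') at entry ",
         bad, ": ", headers[bad])
  }
  gene <- vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else NA_character_,
                 "")
  if (anyNA(gene)) {
    warning(sum(is.na(gene)),
            " FASTA header(s) missing gene_label field; set to 'other'")
    gene[is.na(gene)] <- "other"
  }
  seqs <- toupper(gsub("*", "", as.character(ss), fixed = TRUE))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (any(grepl("-", seqs, fixed = TRUE))) {
    stop("gapped sequences in ", path,
         "; use read_alignment_fasta() for alignments")
  }
  seqs <- sanitize_residues(seqs, alphabet)
  seq_set(id = trimws(vapply(parts, `[[`, "", 1L)),
          taxon = trimws(vapply(parts, `[[`, "", 2L)),
          gene_label = trimws(gene), residues = seqs, alphabet = alphabet)
}

sanitize_residues <- function(seqs, alphabet, extra_ok = "-") {
  ok <- c(if (alphabet == "aa") c(AA_ALPHABET20, "X") else NT_ALPHABET,
          strsplit(extra_ok, "")[[1]])
  chars <- unique(unlist(strsplit(seqs, "")))
  stray <- setdiff(chars, ok)
  if (length(stray)) {
    warning("residues outside the alphabet replaced by 'X': ",
            paste(stray, collapse = ""))
    for (s in stray) seqs <- gsub(s, "X", seqs, fixed = TRUE)
  }
  seqs
}

#' Write a sequence set (or alignment) to FASTA
#'
#' Headers use the `id|taxon|gene_label` dialect; lines wrap at 80 columns.
#'
#' @param x a [seq_set()] or an aligned matrix (see [aligned_matrix()]).
#' @param path output file.
#' @export
write_fasta <- function(x, path) {
  if (is.matrix(x)) {
    s <- alignment_strings(x)
    meta <- attr(x, "meta")
    if (is.null(meta)) {
      meta <- data.frame(id = names(s), taxon = names(s), gene_label = "other")
    }
    meta <- meta[match(names(s), meta$id), , drop = FALSE]
    ss <- Biostrings::BStringSet(unname(s))
    names(ss) <- paste(meta$id, meta$taxon, meta$gene_label, sep = "|")
    Biostrings::writeXStringSet(ss, path, width = 80L)
    return(invisible(path))
  }
  stopifnot(inherits(x, "seq_set"))
  ss <- Biostrings::BStringSet(x$residues)
  names(ss) <- paste(x$id, x$taxon, x$gene_label, sep = "|")
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

## Aligned matrices ------------------------------------------------------------

#' Build an aligned character matrix from equal-length gapped strings
#'
#' @param seqs named character vector (names = row ids) of equal-length
#'   strings; gaps are `-` (`.` normalized).
#' @param alphabet `"aa"` or `"nt"`.
#' @param meta optional `seq_set`-like data.frame with `id`, `taxon`,
#'   `gene_label` carried along as attribute `meta`.
#' @return character matrix, rows = sequences, one column per alignment
#'   column, with attribute `alphabet`.
#' @export
aligned_matrix <- function(seqs, alphabet = "aa", meta = NULL) {
  alphabet <- match.arg(alphabet, c("aa", "nt"))
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  seqs <- gsub(".", "-", toupper(seqs), fixed = TRUE)
  n <- unique(nchar(seqs))
  if (length(n) != 1L) stop("aligned rows have unequal lengths")
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  attr(m, "alphabet") <- alphabet
  if (!is.null(meta)) attr(m, "meta") <- meta
  m
}

#' Read an alignment from FASTA (gapped rows allowed)
#' @inheritParams read_fasta
#' @return aligned character matrix (see [aligned_matrix()]).
#' @export
read_alignment_fasta <- function(path, alphabet = "aa") {
  alphabet <- match.arg(alphabet, c("aa", "nt"))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA input: ", path)
  headers <- names(ss)
  parts <- strsplit(headers, "|", fixed = TRUE)
  ids <- trimws(vapply(parts, `[[`, "", 1L))
  seqs <- gsub(".", "-", toupper(gsub("*", "", as.character(ss), fixed = TRUE)),
               fixed = TRUE)
  seqs <- sanitize_residues(seqs, alphabet)
  names(seqs) <- ids
  meta <- data.frame(
    id = ids,
    taxon = vapply(parts, function(p) if (length(p) >= 2) trimws(p[[2]]) else NA_character_, ""),
    gene_label = vapply(parts, function(p) if (length(p) >= 3) trimws(p[[3]]) else "other", ""),
    stringsAsFactors = FALSE)
  aligned_matrix(seqs, alphabet, meta = meta)
}

#' Collapse an aligned matrix back to row strings
#' @param m aligned matrix.
#' @param degap drop gap characters.
#' @return named character vector.
#' @export
alignment_strings <- function(m, degap = FALSE) {
  out <- apply(m, 1L, paste0, collapse = "")
  if (degap) out <- gsub("-", "", out, fixed = TRUE)
  out
}

alignment_to_seq_set <- function(m, degap = TRUE) {
  s <- alignment_strings(m, degap = degap)
  meta <- attr(m, "meta")
  if (is.null(meta)) {
    meta <- data.frame(id = names(s), taxon = names(s), gene_label = "other",
                       stringsAsFactors = FALSE)
  }
  meta <- meta[match(names(s), meta$id), , drop = FALSE]
  seq_set(names(s), meta$taxon, meta$gene_label, s,
          alphabet = attr(m, "alphabet") %||% "aa")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Domain maps -----------------------------------------------------------------

#' Construct a domain map
#'
#' Named intervals on a reference sequence, 0-based half-open internally
#' (on-disk TSV is 1-based inclusive, see [read_domain_map()]).  Overlapping
#' entries are rejected unless `allow_overlap = TRUE` (the beta-A4 region
#' overlaps the C-terminal E3 region and both are kept explicitly).
#'
#' @param name,start,end parallel vectors; `0 <= start < end`.
#' @param reference_id id of the reference sequence the coordinates refer to.
#' @param reference_length optional length used to validate `end`.
#' @param allow_overlap keep overlapping intervals.
#' @return data.frame with class `domain_map` and attribute `reference_id`.
#' @export
domain_map <- function(name, start, end, reference_id,
                       reference_length = NULL, allow_overlap = FALSE) {
  name <- as.character(name)
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(name) == length(start), length(start) == length(end))
  if (anyDuplicated(name)) stop("domain names must be unique")
  if (any(start < 0L) || any(start >= end)) {
    stop("domain intervals must satisfy 0 <= start < end")
  }
  if (!is.null(reference_length) && any(end > reference_length)) {
    stop("domain interval end exceeds reference length ", reference_length)
  }
  if (!allow_overlap && length(name) > 1L) {
    o <- order(start)
    if (any(end[o][-length(o)] > start[o][-1L])) {
      stop("overlapping domain intervals; pass allow_overlap = TRUE ",
           "if intended (e.g. betaA4 within E3)")
    }
  }
  out <- data.frame(name = name, start = start, end = end,
                    stringsAsFactors = FALSE)
  attr(out, "reference_id") <- reference_id
  class(out) <- c("domain_map", "data.frame")
  out
}

#' Read / write a domain map TSV (1-based inclusive on disk)
#'
#' File format: three tab-separated columns `name`, `start`, `end` with a
#' header line; a comment line `# reference=<id>` records the reference
#' sequence.
#' @param path TSV file.
#' @param reference_id overrides the `# reference=` comment if given.
#' @param allow_overlap passed to [domain_map()].
#' @return a [domain_map()].
#' @export
read_domain_map <- function(path, reference_id = NULL, allow_overlap = TRUE) {
  lines <- readLines(path)
  refline <- grep("^#\\s*reference=", lines, value = TRUE)
  if (is.null(reference_id)) {
    if (length(refline)) {
      reference_id <- sub("^#\\s*reference=", "", refline[1L])
    } else {
      stop("domain map ", path, " lacks a '# reference=' line; ",
           "pass reference_id explicitly")
    }
  }
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                           stringsAsFactors = FALSE)
  if (!all(c("name", "start", "end") %in% names(tab))) {
    stop("domain map needs columns name/start/end: ", path)
  }
  domain_map(tab$name, tab$start - 1L, tab$end, reference_id,
             allow_overlap = allow_overlap)
}

#' @rdname read_domain_map
#' @param map a [domain_map()].
#' @export
write_domain_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# reference=", attr(map, "reference_id")), con)
  utils::write.table(
    data.frame(name = map$name, start = map$start + 1L, end = map$end),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Alignment coordinate mapping ------------------------------------------------

#' Map a reference-sequence interval through an alignment
#'
#' Converts a 0-based half-open residue interval on the reference row into
#' alignment columns, then reports for every row the degapped subsequence
#' under those columns together with its own 0-based half-open residue
#' coordinates.  Rows entirely gapped under the window get an empty interval
#' (`start == end`) and `all_gap = TRUE`.
#'
#' @param m aligned matrix.
#' @param interval integer `c(start, end)`, 0-based half-open on the
#'   reference row's degapped sequence.
#' @param reference_id row id of the reference sequence.
#' @return list with `columns` (0-based half-open alignment-column interval)
#'   and `rows`, a data.frame (`id`, `start`, `end`, `subseq`, `all_gap`).
#' @export
map_reference_interval <- function(m, interval, reference_id) {
  if (!reference_id %in% rownames(m)) {
    stop("reference id not in alignment: ", reference_id)
  }
  start <- as.integer(interval[[1]]); end <- as.integer(interval[[2]])
  ref <- m[reference_id, ]
  ref_res_cols <- which(ref != "-")          # alignment column of each residue
  nref <- length(ref_res_cols)
  if (start < 0L || end > nref || start > end) {
    stop("interval [", start, ",", end, ") outside reference degapped length ",
         nref)
  }
  if (start == end) {
    return(list(columns = c(0L, 0L),
                rows = data.frame(id = rownames(m), start = 0L, end = 0L,
                                  subseq = "", all_gap = TRUE)))
  }
  col_lo <- ref_res_cols[start + 1L]         # first column, 1-based
  col_hi <- ref_res_cols[end]                # last column, 1-based
  rows <- lapply(rownames(m), function(rid) {
    row <- m[rid, ]
    ngaps_before <- sum(row[seq_len(col_lo - 1L)] != "-")
    win <- row[col_lo:col_hi]
    res <- win[win != "-"]
    data.frame(id = rid,
               start = ngaps_before,
               end = ngaps_before + length(res),
               subseq = paste0(res, collapse = ""),
               all_gap = length(res) == 0L,
               stringsAsFactors = FALSE)
  })
  list(columns = c(col_lo - 1L, col_hi),
       rows = do.call(rbind, rows))
}

#' Alignment columns covered by each domain of a map
#'
#' @param m aligned matrix containing the map's reference row.
#' @param map a [domain_map()].
#' @return named list of integer vectors of 1-based alignment columns.
#' @export
domain_columns <- function(m, map) {
  ref_id <- attr(map, "reference_id")
  out <- lapply(seq_len(nrow(map)), function(i) {
    cols <- map_reference_interval(m, c(map$start[i], map$end[i]), ref_id)$columns
    if (cols[2] > cols[1]) seq.int(cols[1] + 1L, cols[2]) else integer()
  })
  names(out) <- map$name
  out
}
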