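## Extraction of beta-A4-homologous regions from an alignment.
##
## Per-taxon region boundaries come, in order of preference, from (1) the
## taxon's own annotated cleavage sites, (2) the nearest annotated taxon on
## the tree ("similar species"), or (3) projection of the reference
## (human Abeta42) coordinates through the alignment.  The region is split
## into an N-terminal and a C-terminal window at the alpha-secretase site.

#' Read / write a cleavage-site annotation table
#'
#' TSV columns: `id`, `start`, `end`, `alpha` -- 1-based inclusive residue
#' coordinates on that sequence (converted to the package-internal 0-based
#' half-open convention on read).  `alpha` is the first residue of the
#' C-terminal window.
#' @param path TSV file.
#' @return data.frame with 0-based half-open `start`, `end` and 0-based
#'   `alpha`.
#' @export
read_cleavage_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("id", "start", "end", "alpha")
  if (!all(need %in% names(tab))) {
    stop("cleavage table needs columns ", paste(need, collapse = "/"))
  }
  data.frame(id = tab$id, start = tab$start - 1L, end = tab$end,
             alpha = tab$alpha - 1L, stringsAsFactors = FALSE)
}

## residue index (0-based) -> alignment column (1-based)
residue_to_column <- function(m, id, rpos) {
  row <- m[id, ]
  res_cols <- which(row != "-")
  if (rpos < 0L || rpos >= length(res_cols)) {
    stop("residue position ", rpos, " outside ", id)
  }
  res_cols[rpos + 1L]
}

## alignment column (1-based) -> number of residues strictly before it
column_to_residue <- function(m, id, col) {
  row <- m[id, ]
  sum(row[seq_len(col - 1L)] != "-")
}

#' Extract per-taxon beta-A4 N-/C-terminal windows from an alignment
#'
#' @param m aligned matrix containing the domain map's reference row.
#' @param map [domain_map()] containing the beta-A4 interval.
#' @param cleavage optional [read_cleavage_table()] data.frame giving
#'   per-taxon region boundaries and alpha-site in the taxon's own residue
#'   coordinates; must contain the reference row for the fallback split.
#' @param tree optional `phylo` used to borrow boundaries from the nearest
#'   annotated taxon (patristic distance); without it unannotated taxa fall
#'   straight through to the reference projection.
#' @param ba4_name name of the beta-A4 interval in `map`.
#' @return data.frame per row of `m`: `id`, `n_start`, `n_end`, `c_start`,
#'   `c_end` (0-based half-open, own residue coordinates), `n_seq`,
#'   `c_seq`, `full_seq`, `provenance`.
#' @export
extract_ba4_regions <- function(m, map, cleavage = NULL, tree = NULL,
                                ba4_name = "bA4") {
  ref_id <- attr(map, "reference_id")
  if (!ref_id %in% rownames(m)) {
    stop("reference row ", ref_id, " missing from alignment")
  }
  if (!ba4_name %in% map$name) stop("domain map lacks interval ", ba4_name)
  iv <- map[map$name == ba4_name, ]
  annotated <- if (is.null(cleavage)) character(0) else cleavage$id
  dist <- NULL
  if (!is.null(tree) && length(annotated)) {
    if (is.null(tree$edge.length)) {
      tree$edge.length <- rep(1, nrow(tree$edge))  # topology distance
    }
    dist <- as.matrix(stats::as.dist(ape::cophenetic.phylo(tree)))
  }
  # reference projection, used by fallback rule (3)
  proj <- map_reference_interval(m, c(iv$start, iv$end), ref_id)
  ref_cl <- if (!is.null(cleavage) && ref_id %in% annotated) {
    cleavage[cleavage$id == ref_id, ]
  } else NULL
  region_cols <- function(id) {
    # (start, end, alpha) columns for taxon `id` following the fallback chain
    if (!is.null(cleavage) && id %in% annotated) {
      cl <- cleavage[cleavage$id == id, ]
      return(list(start_col = residue_to_column(m, id, cl$start),
                  end_col = residue_to_column(m, id, cl$end - 1L),
                  alpha_col = residue_to_column(m, id, cl$alpha),
                  provenance = "annotated"))
    }
    if (!is.null(dist) && id %in% rownames(dist)) {
      cand <- intersect(annotated, colnames(dist))
      cand <- setdiff(cand, id)
      if (length(cand)) {
        nb <- cand[which.min(dist[id, cand])]
        cl <- cleavage[cleavage$id == nb, ]
        return(list(start_col = residue_to_column(m, nb, cl$start),
                    end_col = residue_to_column(m, nb, cl$end - 1L),
                    alpha_col = residue_to_column(m, nb, cl$alpha),
                    provenance = paste0("neighbor:", nb)))
      }
    }
    if (is.null(ref_cl)) {
      stop("no cleavage annotation for reference row ", ref_id,
           "; cannot apply the reference-projection fallback")
    }
    list(start_col = residue_to_column(m, ref_id, ref_cl$start),
         end_col = residue_to_column(m, ref_id, ref_cl$end - 1L),
         alpha_col = residue_to_column(m, ref_id, ref_cl$alpha),
         provenance = "fallback-reference")
  }
  rows <- lapply(rownames(m), function(id) {
    rc <- region_cols(id)
    row <- m[id, ]
    start_res <- column_to_residue(m, id, rc$start_col)
    end_res <- column_to_residue(m, id, rc$end_col) +
      as.integer(row[rc$end_col] != "-")
    alpha_res <- column_to_residue(m, id, rc$alpha_col)
    degapped <- paste0(row[row != "-"], collapse = "")
    n_start <- start_res; n_end <- max(start_res, min(alpha_res, end_res))
    c_start <- n_end; c_end <- max(n_end, end_res)
    data.frame(
      id = id, n_start = n_start, n_end = n_end,
      c_start = c_start, c_end = c_end,
      n_seq = substr(degapped, n_start + 1L, n_end),
      c_seq = substr(degapped, c_start + 1L, c_end),
      full_seq = substr(degapped, n_start + 1L, c_end),
      provenance = rc$provenance, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' End-to-end per-taxon amyloid classification
#'
#' Runs the energy profile and consensus predictor on each taxon's
#' N-terminal and C-terminal beta-A4 windows, classifies segments, and
#' applies the two-region rule.
#'
#' @param regions [extract_ba4_regions()] output.
#' @param table [pairing_energy_table()].
#' @param scorers,k consensus predictor configuration.
#' @param t_high,t_low,min_run segment classification thresholds.
#' @param min_strand_len pairing window minimum.
#' @return data.frame `id`, `class`, `n_segments`, `c_segments` plus a
#'   `detail` attribute holding per-taxon profiles and segments.
#' @export
classify_taxa_amyloid <- function(regions, table = pairing_energy_table(),
                                  scorers = default_scorers(), k = 2,
                                  t_high = -4, t_low = -3, min_run = 3,
                                  min_strand_len = 4) {
  detail <- list()
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    seg <- function(s) {
      if (!nzchar(s)) {
        return(data.frame(start = integer(0), end = integer(0),
                          class = character(0)))
      }
      prof <- pasta_energy_profile(s, table, min_strand_len)
      cons <- consensus_predict(s, scorers, k)
      classify_segments(prof, cons, t_high, t_low, min_run)
    }
    ns <- seg(r$n_seq); cs <- seg(r$c_seq)
    detail[[r$id]] <<- list(n_segments = ns, c_segments = cs)
    data.frame(id = r$id, class = classify_taxon(ns, cs),
               n_segments = nrow(ns), c_segments = nrow(cs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "detail") <- detail
  out
}
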