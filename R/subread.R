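# Sub-read chaining: per TARGET hit, greedy bidirectional extension through
# grammar-compatible neighbouring hits.

#' Build concatemer sub-reads from seed hits
#'
#' For each TARGET hit, walks left and right through neighbouring hits,
#' incorporating each neighbour whose adjacency to the chain is allowed by
#' the grammar. Extension stops at the first violating neighbour, at another
#' TARGET hit, or at the read end. Neighbours may be separated by up to
#' `max_gap` bp of unexplained sequence and may overlap by up to
#' `max_overlap` bp. Sub-reads never share TARGET hits but may share
#' flanking hits.
#'
#' @param read DNA string.
#' @param hits data.frame from [find_hits()] (sorted by position).
#' @param grammar a [build_grammar()] result.
#' @param max_gap,max_overlap adjacency tolerances in bp.
#' @param read_id identifier recorded on the sub-reads.
#' @return list of `sub_read` objects, each with fields `source_read_id`,
#'   `interval` (0-based half-open on the read), `orientation` (strand of its
#'   TARGET hit), `hits` (constituent hit rows, position-ordered), and
#'   `sequence` (extracted, target-forward DNA).
#' @export
build_subreads <- function(read, hits, grammar, max_gap = 25L,
                           max_overlap = 5L, read_id = "read") {
  tgt_idx <- which(hits$label == "TARGET")
  if (!length(tgt_idx)) return(list())
  lapply(tgt_idx, function(ti) {
    chain <- ti
    # leftward
    cur <- ti
    repeat {
      nb <- nearest_neighbor(hits, cur, "left", max_gap, max_overlap)
      if (is.na(nb) || hits$label[nb] == "TARGET") break
      ok <- grammar_allows(grammar, hits$label[nb], hits$strand[nb],
                           hits$label[cur], hits$strand[cur])
      if (!ok) break
      chain <- c(nb, chain); cur <- nb
    }
    # rightward
    cur <- ti
    repeat {
      nb <- nearest_neighbor(hits, cur, "right", max_gap, max_overlap)
      if (is.na(nb) || hits$label[nb] == "TARGET") break
      ok <- grammar_allows(grammar, hits$label[cur], hits$strand[cur],
                           hits$label[nb], hits$strand[nb])
      if (!ok) break
      chain <- c(chain, nb); cur <- nb
    }
    chain_hits <- hits[chain, , drop = FALSE]
    rownames(chain_hits) <- NULL
    interval <- c(min(chain_hits$start), max(chain_hits$end))
    orientation <- hits$strand[ti]
    sr <- structure(list(source_read_id = read_id, interval = interval,
                         orientation = orientation, hits = chain_hits,
                         sequence = NA_character_), class = "sub_read")
    sr$sequence <- extract_subread(read, sr)
    sr
  })
}

# index of nearest hit on one side satisfying the gap/overlap window, NA if
# none; candidates must not be fully contained in the current hit
nearest_neighbor <- function(hits, cur, side, max_gap, max_overlap) {
  if (side == "left") {
    cand <- which(hits$end <= hits$start[cur] + max_overlap &
                    hits$end >= hits$start[cur] - max_gap &
                    hits$start < hits$start[cur])
    if (!length(cand)) return(NA_integer_)
    cand[which.max(hits$end[cand])]
  } else {
    cand <- which(hits$start >= hits$end[cur] - max_overlap &
                    hits$start <= hits$end[cur] + max_gap &
                    hits$end > hits$end[cur])
    if (!length(cand)) return(NA_integer_)
    cand[which.min(hits$start[cand])]
  }
}

#' Extract a sub-read's sequence from its source read
#'
#' Substring of the read over the sub-read interval, reverse-complemented
#' when the orientation is `-` so that every extracted sub-read is
#' target-forward.
#'
#' @param read DNA string.
#' @param subread a `sub_read` from [build_subreads()].
#' @return DNA string.
#' @export
extract_subread <- function(read, subread) {
  iv <- subread$interval
  if (iv[1] < 0 || iv[2] > nchar(read) || iv[1] >= iv[2])
    stop("sub-read interval out of read bounds (internal error)", call. = FALSE)
  s <- substr0(read, iv[1], iv[2])
  if (subread$orientation == "-") revcomp(s) else s
}

#' Write extracted sub-reads to FASTA
#'
#' Ids are `readid/index`.
#'
#' @param subreads list from [build_subreads()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
subreads_to_fasta <- function(subreads, path) {
  seqs <- vapply(subreads, `[[`, character(1), "sequence")
  ids <- sprintf("%s/%d", vapply(subreads, `[[`, character(1),
                                 "source_read_id"), seq_along(subreads))
  x <- Biostrings::DNAStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
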