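# Per-read consensus: align sub-reads to the target reference, read the
# hotspot base off each edit path, and call the plurality.

#' Align a sub-read to the target reference
#'
#' Local alignment (forward strand only: extracted sub-reads are already
#' target-forward). The alignment is accepted when identity >= `min_identity`
#' over at least `min_columns` aligned columns.
#'
#' The hotspot call is allele-aware to avoid reference bias: the sub-read is
#' re-scored against the wildtype reference and against each declared
#' mutant haplotype (reference with the mutant base substituted), and the
#' strictly best-scoring allele is called. Without re-alignment, a read
#' carrying the mutant base pays a guaranteed mismatch at the hotspot, so
#' nearby sequencing errors make the aligner route around the locus (gap
#' placement over the hotspot) more often for mutant than for wildtype
#' reads, deflating the measured allele fraction. When the allele scores
#' tie (hotspot base is neither allele, deleted, or uncovered) the call is
#' read off the wildtype alignment's edit path.
#'
#' @param seq extracted sub-read DNA.
#' @param assay a [lamp_assay()].
#' @param min_identity,min_columns acceptance thresholds.
#' @param scoring see [default_scoring()].
#' @return list: `aligned` (logical), `identity`, `score`, `ref_interval`
#'   (0-based half-open on target_ref), `cigar`, `locus_call` in
#'   {A,C,G,T,DEL,NOCALL}. `locus_call != "NOCALL"` implies `aligned` and the
#'   hotspot inside `ref_interval`.
#' @export
align_subread <- function(seq, assay, min_identity = 0.70, min_columns = 50L,
                          scoring = default_scoring()) {
  stopifnot(nzchar(seq))
  al <- local_align(seq, assay$target_ref, scoring, both_strands = FALSE)
  aligned <- al$columns >= min_columns && al$identity >= min_identity
  locus <- "NOCALL"
  if (aligned) {
    mut_scores <- vapply(assay$mutant_alleles, function(mut) {
      mref <- assay$target_ref
      substr(mref, assay$hotspot_pos + 1L, assay$hotspot_pos + 1L) <- mut
      local_align(seq, mref, scoring, both_strands = FALSE)$score
    }, numeric(1))
    best_mut <- max(mut_scores)
    if (al$score > best_mut) {
      locus <- assay$wildtype_allele
    } else if (best_mut > al$score) {
      locus <- assay$mutant_alleles[which.max(mut_scores)]
    } else {
      # tied allele scores: read the call off both edit paths; disagreement
      # (e.g. an inserted base mimicking one allele) is ambiguous evidence
      # and is dropped rather than resolved in favour of the reference
      call_wt <- call_at(al$cigar, q_start = al$query_interval[1],
                         r_start = al$interval[1], query = seq,
                         pos = assay$hotspot_pos)
      mref <- assay$target_ref
      mut <- assay$mutant_alleles[which.max(mut_scores)]
      substr(mref, assay$hotspot_pos + 1L, assay$hotspot_pos + 1L) <- mut
      alm <- local_align(seq, mref, scoring, both_strands = FALSE)
      call_mut <- call_at(alm$cigar, q_start = alm$query_interval[1],
                          r_start = alm$interval[1], query = seq,
                          pos = assay$hotspot_pos)
      locus <- if (identical(call_wt, call_mut)) call_wt else "NOCALL"
    }
  }
  list(aligned = aligned, identity = al$identity, score = al$score,
       ref_interval = al$interval, cigar = al$cigar, locus_call = locus)
}

# walk a query-relative M/I/D cigar and return the query base aligned to
# reference position `pos`, "DEL" if a deletion spans it, "NOCALL" if outside
call_at <- function(cigar, q_start, r_start, query, pos) {
  ops <- parse_cigar(cigar)
  q <- q_start; r <- r_start
  for (k in seq_len(nrow(ops))) {
    len <- ops$len[k]
    op <- ops$op[k]
    if (op == "M") {
      if (pos >= r && pos < r + len)
        return(substr0(query, q + (pos - r), q + (pos - r) + 1L))
      q <- q + len; r <- r + len
    } else if (op == "D") {
      if (pos >= r && pos < r + len) return("DEL")
      r <- r + len
    } else { # I
      q <- q + len
    }
  }
  "NOCALL"
}

parse_cigar <- function(cigar) {
  if (!nzchar(cigar)) return(data.frame(len = integer(), op = character()))
  m <- gregexpr("[0-9]+[MID]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MID]", cigar))[[1]]
  data.frame(len = as.integer(sub("[MID]", "", toks)),
             op = sub("[0-9]+", "", toks), stringsAsFactors = FALSE)
}

#' Plurality consensus over a per-read pileup
#'
#' @param pileup character vector of locus calls from one read's sub-read
#'   alignments (values in A/C/G/T/DEL; NOCALLs should be excluded upstream).
#' @return list: `call` (A/C/G/T/DEL/NOCALL), `support` (count of agreeing
#'   sub-reads), `tie_broken` (logical). Ties are resolved uniformly at
#'   random among the tied plurality choices using the session RNG (seed it
#'   for reproducibility). An empty pileup yields NOCALL with support 0.
#' @export
consensus_call <- function(pileup) {
  pileup <- pileup[!is.na(pileup) & pileup != "NOCALL"]
  if (!length(pileup))
    return(list(call = "NOCALL", support = 0L, tie_broken = FALSE))
  tab <- table(pileup)
  top <- names(tab)[tab == max(tab)]
  tie <- length(top) > 1
  call <- if (tie) sample(top, 1L) else top
  list(call = call, support = as.integer(max(tab)), tie_broken = tie)
}

#' Per-read error-correction (polish) summary
#'
#' @param calls character vector of locus calls from the read's aligned
#'   sub-reads (NOCALL excluded).
#' @param consensus result of [consensus_call()] on the same pileup.
#' @return list: `n_subreads`, `n_overridden` (discordant sub-read calls
#'   overridden by the plurality), `polished` (consensus differs from at
#'   least one sub-read call).
#' @export
polish_stats <- function(calls, consensus) {
  calls <- calls[!is.na(calls) & calls != "NOCALL"]
  n_over <- if (consensus$call == "NOCALL") 0L else
    sum(calls != consensus$call)
  list(n_subreads = length(calls), n_overridden = as.integer(n_over),
       polished = n_over > 0L)
}
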