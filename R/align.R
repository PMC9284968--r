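#' Default alignment scoring scheme
#'
#' Match +2, mismatch -4, gap open -4, gap extend -2 (a gap of length L costs
#' open + L x extend), mirroring common long-read aligner defaults.
#'
#' @return named list of the four scores.
#' @export
default_scoring <- function() {
  list(match = 2L, mismatch = -4L, gap_open = -4L, gap_extend = -2L)
}

#' Best local alignment of a query against a read
#'
#' Affine-gap Smith-Waterman over both strands of the query; the better
#' strand is reported. Identity is matches / aligned columns where gap
#' columns count toward the denominator.
#'
#' @param query,read DNA strings (non-empty).
#' @param scoring see [default_scoring()].
#' @param both_strands also try the reverse complement of `query`.
#' @return list: `score`, `identity`, `interval` (0-based half-open on the
#'   read), `strand`, `query_interval` (on the query as given), `cigar`
#'   (M/I/D, query-relative), `matches`, `columns`.
#' @export
local_align <- function(query, read, scoring = default_scoring(),
                        both_strands = TRUE) {
  if (!nzchar(query) || !nzchar(read)) stop("empty sequence", call. = FALSE)
  fw <- sw_align_cpp(query, read, scoring$match, scoring$mismatch,
                     scoring$gap_open, scoring$gap_extend)
  best <- fw; strand <- "+"
  if (both_strands) {
    rv <- sw_align_cpp(revcomp(query), read, scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend)
    if (rv$score > fw$score) { best <- rv; strand <- "-" }
  }
  qlen <- nchar(query)
  qint <- c(best$q_start, best$q_end)
  if (strand == "-") qint <- c(qlen - best$q_end, qlen - best$q_start)
  list(score = best$score,
       identity = if (best$columns > 0) best$matches / best$columns else 0,
       interval = c(best$s_start, best$s_end),
       strand = strand,
       query_interval = qint,
       cigar = best$cigar,
       matches = best$matches,
       columns = best$columns)
}

#' Locate the best local alignment within a long subject
#'
#' Linear-memory variant for long subjects (e.g. a background contig):
#' returns score and coordinates, no edit path.
#'
#' @inheritParams local_align
#' @param subject DNA string, may be long.
#' @return list: `score`, `q_interval`, `s_interval` (0-based half-open),
#'   `strand`.
#' @export
locate_align <- function(query, subject, scoring = default_scoring(),
                         both_strands = TRUE) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence", call. = FALSE)
  fw <- sw_locate_cpp(query, subject, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
  best <- fw; strand <- "+"
  if (both_strands) {
    rv <- sw_locate_cpp(revcomp(query), subject, scoring$match,
                        scoring$mismatch, scoring$gap_open, scoring$gap_extend)
    if (rv$score > fw$score) { best <- rv; strand <- "-" }
  }
  list(score = best$score,
       q_interval = c(best$q_start, best$q_end),
       s_interval = c(best$s_start, best$s_end),
       strand = strand)
}

# Candidate subject windows for a read via exact k-mer seeding: k-mers are
# sampled across the read, located exactly in the subject (fast fixed-string
# search), and their subject-minus-read offsets clustered; each cluster with
# >= min_seeds agreeing k-mers yields one window. Standard seed-and-extend
# prefilter so long subjects never see a full DP.
kmer_windows <- function(read, subject, k = 13L, n_kmers = 40L,
                         min_seeds = 2L) {
  L <- nchar(read)
  if (L < k) return(list())
  starts <- unique(as.integer(seq(0L, L - k, length.out = min(n_kmers, L - k + 1L))))
  offs <- integer(0)
  for (s in starts) {
    km <- substr0(read, s, s + k)
    if (grepl("N", km, fixed = TRUE)) next
    m <- gregexpr(km, subject, fixed = TRUE)[[1]]
    if (m[1] != -1L) offs <- c(offs, (as.integer(m) - 1L) - s)
  }
  if (length(offs) < min_seeds) return(list())
  offs <- sort(offs)
  tol <- as.integer(0.3 * L + 50L)
  splits <- c(0L, which(diff(offs) > tol), length(offs))
  out <- list()
  for (i in seq_len(length(splits) - 1L)) {
    grp <- offs[(splits[i] + 1L):splits[i + 1L]]
    if (length(grp) < min_seeds) next
    out[[length(out) + 1L]] <- c(max(0L, min(grp) - 50L),
                                 min(nchar(subject), max(grp) + L + 50L))
  }
  out
}

#' Primary alignment of a read against a long reference
#'
#' Seed-and-extend stand-in for a read mapper's primary alignment: exact
#' k-mer seeds are clustered into candidate windows on both strands and the
#' read is locally aligned within each window; the highest-scoring window
#' wins. Returns score 0 when no window attracts enough seeds.
#'
#' @inheritParams local_align
#' @param reference DNA string (may be long).
#' @param k,n_kmers,min_seeds seeding parameters.
#' @return list: `score`, `identity`, `s_interval` (0-based half-open on the
#'   reference), `q_interval` (on the read as given), `strand`.
#' @export
primary_locate <- function(read, reference, scoring = default_scoring(),
                           k = 13L, n_kmers = 40L, min_seeds = 2L) {
  best <- list(score = 0L, identity = 0, s_interval = c(0L, 0L),
               q_interval = c(0L, 0L), strand = "+")
  for (strand in c("+", "-")) {
    r <- if (strand == "+") read else revcomp(read)
    for (w in kmer_windows(r, reference, k, n_kmers, min_seeds)) {
      al <- local_align(r, substr0(reference, w[1], w[2]), scoring,
                        both_strands = FALSE)
      if (al$score > best$score) {
        qi <- al$query_interval
        if (strand == "-") qi <- c(nchar(read) - qi[2], nchar(read) - qi[1])
        best <- list(score = al$score, identity = al$identity,
                     s_interval = w[1] + al$interval,
                     q_interval = qi, strand = strand)
      }
    }
  }
  best
}
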