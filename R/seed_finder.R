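# Seeding: mark every design-sequence and target-seed occurrence on a read.

#' Find all seed hits on a read
#'
#' For the target seed and every design sequence (both strands), extracts all
#' non-overlapping local matches with identity >= `min_identity` and query
#' coverage >= `min_query_cov` by iterated best-hit-then-mask: the best local
#' alignment is recorded, its read span masked with `N`, and the search
#' repeated until the best remaining hit fails the filters.
#'
#' @param read DNA string.
#' @param assay a [lamp_assay()].
#' @param min_identity identity threshold in [0,1] (default 0.70); identity
#'   counts gap columns in the denominator.
#' @param min_query_cov minimum fraction of the query that must be consumed
#'   by the alignment (default 0.80); guards against micro-hits that pass the
#'   identity filter.
#' @param include_loops also seed the loop sites FLP/BLP when present.
#' @param scoring see [default_scoring()].
#' @return data.frame of hits sorted by read position: `label` (design label
#'   or "TARGET"), `start`, `end` (0-based half-open), `strand`, `identity`,
#'   `score`. Zero rows is a valid result.
#' @export
find_hits <- function(read, assay, min_identity = 0.70, min_query_cov = 0.80,
                      include_loops = TRUE, scoring = default_scoring()) {
  stopifnot(nchar(read) >= 1)
  queries <- c(TARGET = target_seed(assay), assay$designs)
  if (!include_loops) queries <- queries[!names(queries) %in% c("FLP", "BLP")]
  hits <- lapply(names(queries), function(lab) {
    find_query_hits(read, queries[[lab]], lab, min_identity, min_query_cov,
                    scoring)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0) return(empty_hits())
  hits <- hits[order(hits$start, hits$end, hits$label), ]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(label = character(), start = integer(), end = integer(),
             strand = character(), identity = numeric(), score = integer(),
             stringsAsFactors = FALSE)
}

find_query_hits <- function(read, query, label, min_identity, min_query_cov,
                            scoring, max_iter = 64L) {
  if (nchar(read) < 1) return(empty_hits())
  masked <- read
  out <- list()
  for (i in seq_len(max_iter)) {
    al <- local_align(query, masked, scoring)
    if (al$score <= 0) break
    cov <- (al$query_interval[2] - al$query_interval[1]) / nchar(query)
    if (al$identity < min_identity || cov < min_query_cov) break
    out[[length(out) + 1L]] <- data.frame(
      label = label, start = al$interval[1], end = al$interval[2],
      strand = al$strand, identity = al$identity, score = al$score,
      stringsAsFactors = FALSE)
    masked <- mask_span(masked, al$interval[1], al$interval[2])
  }
  if (!length(out)) return(empty_hits())
  do.call(rbind, out)
}

mask_span <- function(x, start, end) {
  paste0(substr(x, 1, start), strrep("N", end - start),
         substr(x, end + 1L, nchar(x)))
}

#' Dump seed hits in BED format
#'
#' One line per hit: read id as chrom, 0-based half-open interval, label as
#' name, identity x 1000 as score, strand.
#'
#' @param hits result of [find_hits()].
#' @param read_id read identifier.
#' @param con file path or connection; omit to return the lines.
#' @return character vector of BED lines, invisibly if written.
#' @export
hits_to_bed <- function(hits, read_id, con = NULL) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", read_id, hits$start, hits$end,
                   hits$label, as.integer(round(hits$identity * 1000)),
                   hits$strand)
  if (is.null(con)) return(lines)
  writeLines(lines, con)
  invisible(lines)
}
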