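# Read classification: every read gets exactly one class by a fixed
# precedence chain: SHORT -> ONT -> TARGET -> FRAGMENT -> SPURIOUS ->
# BACKGROUND -> UNKNOWN. Length and adapter checks are cheap and
# unambiguous; TARGET outranks SPURIOUS because genuine target reads also
# carry many design hits; the (expensive) background alignment runs last and
# only for reads nothing else explains.

#' Classify one read
#'
#' Runs the full per-read pipeline (seeding, chaining, sub-read alignment,
#' consensus) and assigns one of TARGET, FRAGMENT, SPURIOUS, BACKGROUND,
#' ONT, SHORT, UNKNOWN.
#'
#' @param read DNA string.
#' @param assay a [lamp_assay()].
#' @param grammar a [build_grammar()] result (rebuilt if omitted).
#' @param config a [lamp_config()].
#' @param background_ref optional background genome as a single DNA string;
#'   when absent the Background test is skipped and such reads fall through
#'   to UNKNOWN.
#' @param ont_sequences character vector of adapter/barcode sequences.
#' @param read_id identifier; `start_time` seconds since run start (NA ok).
#' @return `read_diagnosis` list: `read_id`, `class`, `consensus` (only for
#'   TARGET), `n_subreads`, `n_design_hits`, `start_time`, plus `hits`,
#'   `subreads`, `alignments`, `polish` for inspection.
#' @export
classify_read <- function(read, assay, grammar = build_grammar(assay),
                          config = lamp_config(), background_ref = NULL,
                          ont_sequences = character(), read_id = "read",
                          start_time = NA_real_) {
  res <- list(read_id = read_id, class = "UNKNOWN", consensus = NULL,
              n_subreads = 0L, n_design_hits = 0L, start_time = start_time,
              hits = empty_hits(), subreads = list(), alignments = list(),
              polish = NULL)
  class(res) <- "read_diagnosis"

  if (nchar(read) < config$short_len) {
    res$class <- "SHORT"
    return(res)
  }

  if (length(ont_sequences) && is_ont_read(read, ont_sequences, config)) {
    res$class <- "ONT"
    return(res)
  }

  hits <- find_hits(read, assay, config$min_identity, config$min_query_cov,
                    config$include_loops, config$scoring)
  res$hits <- hits
  res$n_design_hits <- sum(hits$label != "TARGET")

  subreads <- build_subreads(read, hits, grammar, config$max_gap,
                             config$max_overlap, read_id)
  res$subreads <- subreads
  res$n_subreads <- length(subreads)
  alns <- lapply(subreads, function(sr)
    align_subread(sr$sequence, assay, config$align_min_identity,
                  config$align_min_columns, config$scoring))
  res$alignments <- alns

  calls <- vapply(alns, `[[`, character(1), "locus_call")
  callable <- calls[calls != "NOCALL"]
  if (length(callable)) {
    res$class <- "TARGET"
    res$consensus <- consensus_call(callable)
    res$polish <- polish_stats(callable, res$consensus)
    return(res)
  }

  # Fragment: the read itself (or a sub-read) aligns to the amplicon
  # reference but the hotspot is not covered
  whole <- local_align(read, assay$target_ref, config$scoring,
                       both_strands = TRUE)
  frag <- (whole$columns >= config$fragment_min_columns &&
             whole$identity >= config$align_min_identity) ||
    any(vapply(alns, `[[`, logical(1), "aligned"))
  if (frag) {
    res$class <- "FRAGMENT"
    return(res)
  }

  if (res$n_design_hits >= config$spurious_min_hits) {
    res$class <- "SPURIOUS"
    return(res)
  }

  if (!is.null(background_ref) &&
      is_background_read(read, background_ref, config)) {
    res$class <- "BACKGROUND"
    return(res)
  }

  res
}

is_ont_read <- function(read, ont_sequences, config) {
  for (ad in ont_sequences) {
    al <- local_align(ad, read, config$scoring)
    cov <- (al$interval[2] - al$interval[1]) / nchar(read)
    if (al$identity >= config$ont_min_identity && cov >= config$ont_min_cov)
      return(TRUE)
  }
  FALSE
}

is_background_read <- function(read, background_ref, config) {
  loc <- primary_locate(read, background_ref, config$scoring)
  if (loc$score <= 0) return(FALSE)
  cov <- (loc$q_interval[2] - loc$q_interval[1]) / nchar(read)
  loc$identity >= config$bg_min_identity && cov >= config$bg_min_cov
}

#' Alignment-position amplicon classifier
#'
#' The simple classifier used for PCR amplicon runs (no concatemer
#' awareness): the read's best ("primary") local alignment against the
#' supplied reference decides the class. TARGET iff the alignment covers the
#' hotspot; FRAGMENT iff it overlaps the amplicon span but misses the
#' hotspot; BACKGROUND iff it aligns elsewhere; SHORT below the length
#' floor; UNKNOWN otherwise.
#'
#' @param read DNA string.
#' @param reference genome/reference DNA string containing the amplicon.
#' @param amplicon_span 0-based half-open span of the amplicon on
#'   `reference`.
#' @param hotspot_pos 0-based hotspot position on `reference`.
#' @param config a [lamp_config()]; reuses `short_len`, `bg_min_cov` and the
#'   scoring scheme. A minimum score of `min_score` filters noise
#'   alignments.
#' @param min_score minimum primary-alignment score.
#' @return one of "TARGET", "FRAGMENT", "BACKGROUND", "SHORT", "UNKNOWN".
#' @export
classify_amplicon <- function(read, reference, amplicon_span, hotspot_pos,
                              config = lamp_config(), min_score = 60L) {
  if (nchar(read) < config$short_len) return("SHORT")
  loc <- primary_locate(read, reference, config$scoring)
  if (loc$score < min_score) return("UNKNOWN")
  s <- loc$s_interval
  if (hotspot_pos >= s[1] && hotspot_pos < s[2]) return("TARGET")
  if (s[1] < amplicon_span[2] && s[2] > amplicon_span[1]) return("FRAGMENT")
  "BACKGROUND"
}
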