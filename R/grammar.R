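# Concatemer adjacency grammar.
#
# A proper LAMP concatemer is modelled as alternating forward / reverse-
# complement copies of the core amplified unit. On the forward strand of the
# amplicon the unit reads F2 F1 TARGET B1 B2 (all sites in reference
# orientation), so a forward unit contributes the token run
# (F2,+) (F1,+) (TARGET,+) (B1,+) (B2,+) and a reversed unit its mirror.
# Units meet at inverted-repeat junctions (B2,+)(B2,-) and (F2,-)(F2,+);
# loop-primer sequences may sit inside those junctions and the outer sites
# F3/B3 occur only at read extremities. The grammar is the set of ordered
# (label,strand) pairs that may abut, closed under reverse-complement
# symmetry of the whole read.

#' Token layout of an idealized concatemer
#'
#' @param n_units number of tandem units (>= 1).
#' @param start_strand strand of the first unit, "+" or "-".
#' @param loops insert loop tokens (FLP/BLP) at unit junctions.
#' @param terminal add outer-primer tokens (F3/B3) at the read ends.
#' @return data.frame with columns `label`, `strand`, one row per token in
#'   read order.
#' @export
concatemer_layout <- function(n_units, start_strand = "+", loops = FALSE,
                              terminal = FALSE) {
  stopifnot(n_units >= 1, start_strand %in% c("+", "-"))
  unit_fwd <- data.frame(label = c("F2", "F1", "TARGET", "B1", "B2"),
                         strand = "+", stringsAsFactors = FALSE)
  unit_rev <- data.frame(label = rev(unit_fwd$label), strand = "-",
                         stringsAsFactors = FALSE)
  strands <- rep(c(start_strand, setdiff(c("+", "-"), start_strand)),
                 length.out = n_units)
  out <- list()
  for (k in seq_len(n_units)) {
    unit <- if (strands[k] == "+") unit_fwd else unit_rev
    if (k > 1 && loops) {
      # junction loop token: BLP inside a (B2,+)(B2,-) junction,
      # FLP inside a (F2,-)(F2,+) junction
      prev_last <- out[[length(out)]]
      tok <- if (prev_last$label[nrow(prev_last)] == "B2") "BLP" else "FLP"
      st <- if (tok == "BLP") "-" else "+"
      out[[length(out) + 1L]] <- data.frame(label = tok, strand = st,
                                            stringsAsFactors = FALSE)
    }
    out[[length(out) + 1L]] <- unit
  }
  toks <- do.call(rbind, out)
  if (terminal) {
    lead <- if (strands[1] == "+") c("F3", "+") else c("B3", "-")
    trail <- if (strands[n_units] == "+") c("B3", "+") else c("F3", "-")
    toks <- rbind(data.frame(label = lead[1], strand = lead[2]),
                  toks,
                  data.frame(label = trail[1], strand = trail[2]))
  }
  rownames(toks) <- NULL
  toks
}

#' Build the concatemer adjacency grammar for an assay
#'
#' Enumerates adjacent token pairs over idealized concatemer layouts (both
#' starting strands, with terminals, and with loop tokens when the assay
#' defines loop sites) and closes the pair set under reverse-complement
#' symmetry. Deterministic for identical assays.
#'
#' @param assay a [lamp_assay()].
#' @return object of class `lamp_grammar`: data.frame of allowed ordered
#'   pairs (`from_label`, `from_strand`, `to_label`, `to_strand`).
#' @export
build_grammar <- function(assay) {
  has_loops <- all(c("FLP", "BLP") %in% names(assay$designs))
  pairs <- list()
  add_layout <- function(toks) {
    n <- nrow(toks)
    if (n < 2) return()
    pairs[[length(pairs) + 1L]] <<- data.frame(
      from_label = toks$label[-n], from_strand = toks$strand[-n],
      to_label = toks$label[-1], to_strand = toks$strand[-1],
      stringsAsFactors = FALSE)
  }
  for (st in c("+", "-")) {
    add_layout(concatemer_layout(4, st, loops = FALSE, terminal = TRUE))
    add_layout(concatemer_layout(4, st, loops = FALSE, terminal = FALSE))
    if (has_loops) {
      add_layout(concatemer_layout(4, st, loops = TRUE, terminal = TRUE))
      add_layout(concatemer_layout(4, st, loops = TRUE, terminal = FALSE))
    }
  }
  g <- do.call(rbind, pairs)
  flip <- function(s) ifelse(s == "+", "-", "+")
  mirror <- data.frame(from_label = g$to_label, from_strand = flip(g$to_strand),
                       to_label = g$from_label, to_strand = flip(g$from_strand),
                       stringsAsFactors = FALSE)
  g <- unique(rbind(g, mirror))
  g <- g[order(g$from_label, g$from_strand, g$to_label, g$to_strand), ]
  rownames(g) <- NULL
  class(g) <- c("lamp_grammar", "data.frame")
  g
}

#' Test whether one token may directly follow another
#'
#' @param grammar a [build_grammar()] result.
#' @param from_label,from_strand left token.
#' @param to_label,to_strand right token.
#' @return logical scalar.
#' @export
grammar_allows <- function(grammar, from_label, from_strand,
                           to_label, to_strand) {
  any(grammar$from_label == from_label & grammar$from_strand == from_strand &
        grammar$to_label == to_label & grammar$to_strand == to_strand)
}
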