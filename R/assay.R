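#' LAMP assay definition
#'
#' Constructs and validates a LAMP assay: the six design-sequence sites
#' (F3, F2, F1, B1, B2, B3, plus optional loop sites FLP/BLP), the amplicon
#' reference sequence, the target-seed span and the interrogated hotspot.
#'
#' All design sequences are stored in the orientation of the forward strand
#' of `target_ref` (reference orientation). Assay files written in primer
#' orientation are converted on load (see [load_assay()]).
#'
#' Coordinates are 0-based half-open throughout; only VCF output is 1-based.
#'
#' @param name assay name.
#' @param target_ref DNA string: the amplicon-region reference.
#' @param designs named character vector of design sites in reference
#'   orientation; names from F3, F2, F1, B1, B2, B3, FLP, BLP. The six core
#'   labels are required, loop sites optional.
#' @param hotspot_pos 0-based offset of the hotspot on `target_ref`.
#' @param mutant_alleles one or more single-base mutant alleles.
#' @param target_span optional `c(start, end)` 0-based half-open span of the
#'   target seed on `target_ref`. Default: the region strictly between the F1
#'   and B1 sites extended by 5 bp on each side (the sites must then occur
#'   exactly once, forward, in `target_ref`).
#' @param wildtype_allele optional; must equal `target_ref[hotspot_pos]`
#'   (derived when missing).
#' @param linker poly-T linker joining the halves of the inner primers.
#' @return object of class `lamp_assay`.
#' @export
lamp_assay <- function(name, target_ref, designs, hotspot_pos, mutant_alleles,
                       target_span = NULL, wildtype_allele = NULL,
                       linker = "TTTT") {
  required <- c("F3", "F2", "F1", "B1", "B2", "B3")
  optional <- c("FLP", "BLP")
  if (!is.character(target_ref) || length(target_ref) != 1 || !is_dna(target_ref))
    abort_field("target_ref", "must be a non-empty A/C/G/T string")
  designs <- unlist(designs)
  if (anyDuplicated(names(designs)))
    abort_field("designs", "duplicate design labels")
  missing_lab <- setdiff(required, names(designs))
  if (length(missing_lab))
    abort_field("designs", paste("missing label(s):",
                                 paste(missing_lab, collapse = ", ")))
  bad_lab <- setdiff(names(designs), c(required, optional))
  if (length(bad_lab))
    abort_field("designs", paste("unknown label(s):",
                                 paste(bad_lab, collapse = ", ")))
  if (!all(is_dna(designs)))
    abort_field("designs", "sequences must be non-empty A/C/G/T strings")

  if (is.null(target_span)) {
    f1 <- locate_once(designs[["F1"]], target_ref, "F1")
    b1 <- locate_once(designs[["B1"]], target_ref, "B1")
    target_span <- c(f1[2] - 5L, b1[1] + 5L)
  }
  target_span <- as.integer(target_span)
  if (length(target_span) != 2 || target_span[1] < 0 ||
      target_span[2] > nchar(target_ref) || target_span[1] >= target_span[2])
    abort_field("target_span", "must be a 0-based half-open span within target_ref")

  hotspot_pos <- as.integer(hotspot_pos)
  if (hotspot_pos < target_span[1] || hotspot_pos >= target_span[2])
    abort_field("hotspot_pos", "hotspot must lie inside target_span")

  ref_base <- substr0(target_ref, hotspot_pos, hotspot_pos + 1L)
  if (is.null(wildtype_allele)) wildtype_allele <- ref_base
  if (!identical(wildtype_allele, ref_base))
    abort_field("wildtype_allele",
                sprintf("'%s' does not match target_ref[%d] = '%s'",
                        wildtype_allele, hotspot_pos, ref_base))
  mutant_alleles <- toupper(mutant_alleles)
  if (!all(mutant_alleles %in% c("A", "C", "G", "T")) ||
      any(mutant_alleles == wildtype_allele))
    abort_field("mutant_alleles", "must be single non-wildtype bases")

  structure(list(
    name = as.character(name),
    target_ref = target_ref,
    target_span = target_span,
    hotspot_pos = hotspot_pos,
    wildtype_allele = wildtype_allele,
    mutant_alleles = mutant_alleles,
    designs = designs[order(match(names(designs), c(required, optional)))],
    linker = linker
  ), class = "lamp_assay")
}

locate_once <- function(pattern, subject, label) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1L)
    abort_field(label, "design site not found in target_ref; supply target_span")
  if (length(hits) > 1)
    abort_field(label, "design site occurs more than once in target_ref")
  c(hits[1] - 1L, hits[1] - 1L + nchar(pattern))  # 0-based half-open
}

#' Derived target seed sequence
#' @param assay a [lamp_assay()].
#' @return DNA string `target_ref[target_span]`.
#' @export
target_seed <- function(assay) {
  substr0(assay$target_ref, assay$target_span[1], assay$target_span[2])
}

#' @export
print.lamp_assay <- function(x, ...) {
  cat(sprintf("LAMP assay '%s': %d bp reference, hotspot %d (%s>%s), seed %d bp\n",
              x$name, nchar(x$target_ref), x$hotspot_pos, x$wildtype_allele,
              paste(x$mutant_alleles, collapse = "/"),
              x$target_span[2] - x$target_span[1]))
  for (lab in names(x$designs)) cat(sprintf("  %-3s %s\n", lab, x$designs[[lab]]))
  invisible(x)
}

#' Split inner primers at the poly-T linker
#'
#' FIP and BIP each fuse two design roles joined by a poly-T linker
#' (FIP = F1c + linker + F2; BIP = B1c + linker + B2, primer orientation).
#' The linker must occur exactly once in each primer.
#'
#' @param fip,bip inner primer sequences (primer orientation).
#' @param linker linker text, default "TTTT".
#' @return list with `fip = c(left, right)` and `bip = c(left, right)`,
#'   linker removed.
#' @export
split_inner_primers <- function(fip, bip, linker = "TTTT") {
  split1 <- function(primer, which) {
    n_occ <- length(gregexpr(linker, primer, fixed = TRUE)[[1]])
    if (gregexpr(linker, primer, fixed = TRUE)[[1]][1] == -1L) n_occ <- 0L
    if (n_occ != 1L)
      stop(sprintf("linker '%s' occurs %d times in %s (must be exactly once)",
                   linker, n_occ, which), call. = FALSE)
    at <- regexpr(linker, primer, fixed = TRUE)[1]
    c(substr(primer, 1, at - 1L), substr(primer, at + nchar(linker), nchar(primer)))
  }
  list(fip = split1(fip, "FIP"), bip = split1(bip, "BIP"))
}

#' Write an assay definition file
#'
#' Flat `key: value` text format, one entry per line, `#` comments allowed.
#' Design sequences are written in reference orientation
#' (`orientation: reference`).
#'
#' @param assay a [lamp_assay()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_assay <- function(assay, path) {
  lines <- c(
    sprintf("name: %s", assay$name),
    "orientation: reference",
    sprintf("target_ref: %s", assay$target_ref),
    sprintf("target_span: %d-%d", assay$target_span[1], assay$target_span[2]),
    sprintf("hotspot: %d", assay$hotspot_pos),
    sprintf("wildtype: %s", assay$wildtype_allele),
    sprintf("mutant: %s", paste(assay$mutant_alleles, collapse = ",")),
    sprintf("linker: %s", assay$linker),
    sprintf("%s: %s", names(assay$designs), unname(assay$designs))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Load an assay definition file
#'
#' Accepts design sequences either in reference orientation (labels
#' F1/F2/F3/B1/B2/B3, optional FLP/BLP) or in primer orientation
#' (`orientation: primer`; entries F3, B3, FIP, BIP, FLP, BLP as ordered from
#' a synthesis vendor). In primer orientation, FIP/BIP are split at the
#' linker and B-side entries are reverse-complemented onto the reference
#' forward strand. `target_ref` may be given inline or via
#' `target_ref_fasta: <path>` (relative to the assay file; read with
#' Biostrings).
#'
#' @param path assay definition file.
#' @return validated [lamp_assay()].
#' @export
load_assay <- function(path) {
  if (!file.exists(path)) stop("assay file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", lines))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) stop("unparseable assay line: ", lines[bad][1], call. = FALSE)
  kv <- setNames(vapply(m, `[`, character(1), 3), vapply(m, `[`, character(1), 2))
  kv <- trimws(kv)
  kvget <- function(key) if (key %in% names(kv)) kv[[key]] else NULL
  names(kv) <- ifelse(names(kv) %in% c("F1","F2","F3","B1","B2","B3","FLP","BLP",
                                        "FIP","BIP"),
                      toupper(names(kv)), tolower(names(kv)))

  target_ref <- kvget("target_ref") %||% NULL
  if (is.null(target_ref) && !is.null(kvget("target_ref_fasta") %||% NULL)) {
    fa <- file.path(dirname(path), kvget("target_ref_fasta"))
    seqs <- Biostrings::readDNAStringSet(fa)
    target_ref <- as.character(seqs[[1]])
  }
  if (is.null(target_ref)) abort_field("target_ref", "missing")
  target_ref <- toupper(target_ref)

  linker <- kvget("linker") %||% "TTTT"
  orientation <- kvget("orientation") %||% "reference"

  labs <- c("F1","F2","F3","B1","B2","B3","FLP","BLP")
  designs <- kv[names(kv) %in% labs]
  if (identical(orientation, "primer")) {
    if (is.null(kvget("FIP") %||% NULL) || is.null(kvget("BIP") %||% NULL))
      abort_field("FIP/BIP", "required in primer orientation")
    halves <- split_inner_primers(kvget("FIP"), kvget("BIP"), linker)
    designs <- c(
      F3 = kvget("F3") %||% abort_field("F3", "missing"),
      F2 = halves$fip[2],
      F1 = revcomp(halves$fip[1]),       # FIP 5' half is F1c
      B1 = halves$bip[1],                # BIP 5' half is the forward B1 site
      B2 = revcomp(halves$bip[2]),
      B3 = revcomp(kvget("B3") %||% abort_field("B3", "missing")))
    if (!is.null(kvget("FLP"))) designs <- c(designs, FLP = kvget("FLP"))
    if (!is.null(kvget("BLP")))
      designs <- c(designs, BLP = revcomp(kvget("BLP")))
  }

  span <- NULL
  if (!is.null(kvget("target_span") %||% NULL)) {
    parts <- as.integer(strsplit(kvget("target_span"), "-", fixed = TRUE)[[1]])
    if (length(parts) != 2 || anyNA(parts))
      abort_field("target_span", "expected 'start-end'")
    span <- parts
  }
  if (is.null(kvget("hotspot") %||% NULL)) abort_field("hotspot", "missing")

  lamp_assay(
    name = kvget("name") %||% basename(path),
    target_ref = target_ref,
    designs = toupper(designs),
    hotspot_pos = as.integer(kvget("hotspot")),
    mutant_alleles = strsplit(kvget("mutant") %||%
                                abort_field("mutant", "missing"), ",")[[1]],
    target_span = span,
    wildtype_allele = kvget("wildtype") %||% NULL,
    linker = linker)
}

#' Bundled example assay (synthetic amplicon backbone)
#'
#' A K27M-style assay built from a published-style H3F3A LAMP primer set laid
#' onto a synthetic amplicon: the seven design sites abut directly with a
#' 31 bp spacer between F1 and B1 carrying the interrogated A>T hotspot at
#' its centre. The reference is synthetic; only the primer sequences are
#' real-world-like. Used as the default fixture throughout the test-suite and
#' the simulator.
#'
#' @return a [lamp_assay()].
#' @export
example_assay <- function() {
  f3 <- "GTTTGGTAGTTGCATATGGTG"
  fip <- "GCGGGCAGTCTGCTTTGTATTTTATGCTGGTAGGTAAGTAAGGA"
  bip <- "CGACCGGTGGTAAAGCACCTTTTCACCCCTCCAGTAGAG"
  b3 <- "ATACCTGTAACGATGAGGTTTC"
  flp <- "CGAGCCATGGTACAGAGAC"
  blp <- "CAGGAAGCAACTGGCTACA"
  halves <- split_inner_primers(fip, bip)
  # synthetic spacer; hotspot A at centre with non-degenerate neighbours
  # (G.A.G) so indel gap placement at the locus is unambiguous
  spacer <- "GGTAAACTCGCCACGAGCGGAGCTTCACCTG"
  designs <- c(F3 = f3, F2 = halves$fip[2], F1 = revcomp(halves$fip[1]),
               B1 = halves$bip[1], B2 = revcomp(halves$bip[2]),
               B3 = revcomp(b3), FLP = flp, BLP = revcomp(blp))
  target_ref <- paste0(designs[["F3"]], designs[["F2"]], designs[["F1"]],
                       spacer, designs[["B1"]], designs[["B2"]], designs[["B3"]])
  hotspot <- nchar(f3) + nchar(halves$fip[2]) + nchar(halves$fip[1]) + 15L
  lamp_assay("h3f3a_k27m_synthetic", target_ref, designs,
             hotspot_pos = hotspot, mutant_alleles = "T")
}
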