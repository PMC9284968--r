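#' Reverse-complement a DNA string
#'
#' Plain-character implementation; tolerates masked (`N`) bases.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgtN", "TGCAtgcaN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_dna <- function(x) {
  nzchar(x) & !grepl("[^ACGT]", x)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substring by 0-based half-open interval
substr0 <- function(x, start, end) substr(x, start + 1L, end)

abort_field <- function(field, msg) {
  stop(sprintf("invalid assay field '%s': %s", field, msg), call. = FALSE)
}

# draw one element uniformly; safe for length-1 vectors (unlike sample())
sample1 <- function(x) x[sample.int(length(x), 1L)]
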