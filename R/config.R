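#' Pipeline configuration
#'
#' Collects every tunable threshold with its documented default. Any subset
#' can be overridden by name.
#'
#' @param ... named overrides of the defaults below.
#' @return named list of class `lamp_config`.
#'
#' @details Defaults:
#' \describe{
#'   \item{min_identity (0.70)}{seed identity threshold (gap columns count).}
#'   \item{min_query_cov (0.80)}{fraction of the query a seed hit must cover.}
#'   \item{include_loops (TRUE)}{seed loop sites FLP/BLP when defined.}
#'   \item{max_gap (25), max_overlap (5)}{chaining adjacency tolerances, bp.}
#'   \item{align_min_identity (0.70), align_min_columns (50)}{sub-read to
#'     reference alignment acceptance.}
#'   \item{fragment_min_columns (60)}{whole-read alignment columns required
#'     before a target-less read may be called Fragment.}
#'   \item{short_len (60)}{reads shorter than this are Short.}
#'   \item{spurious_min_hits (3)}{design hits required for Spurious.}
#'   \item{ont_min_identity (0.80), ont_min_cov (0.50)}{adapter match
#'     identity, and fraction of the read an adapter hit must cover.}
#'   \item{bg_min_identity (0.80), bg_min_cov (0.60)}{background-genome match
#'     identity and read coverage (stand-in for a mapper MAPQ filter).}
#'   \item{support_target (250)}{diagnostic support threshold.}
#'   \item{ci_level (0.95), ci_method ("wald")}{proportion CI settings.}
#' }
#' @export
lamp_config <- function(...) {
  cfg <- list(
    min_identity = 0.70,
    min_query_cov = 0.80,
    include_loops = TRUE,
    max_gap = 25L,
    max_overlap = 5L,
    align_min_identity = 0.70,
    align_min_columns = 50L,
    fragment_min_columns = 60L,
    short_len = 60L,
    spurious_min_hits = 3L,
    ont_min_identity = 0.80,
    ont_min_cov = 0.50,
    bg_min_identity = 0.80,
    bg_min_cov = 0.60,
    support_target = 250L,
    ci_level = 0.95,
    ci_method = "wald",
    scoring = default_scoring()
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = "lamp_config")
}
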