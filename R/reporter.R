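# Diagnostic accumulation: VAF with proportion CIs, support-over-time,
# time-to-support, and the binomial sensitivity/specificity operating point.

#' Confidence interval for a population proportion
#'
#' Two-sided interval at confidence level `cl`. The default is the
#' normal-approximation (Wald) interval clamped to [0,1]; Wilson is
#' available because Wald degenerates at k near 0 or n.
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (>= 1).
#' @param cl confidence level, default 0.95.
#' @param method "wald" or "wilson".
#' @return numeric `c(low, high)`.
#' @export
proportion_ci <- function(k, n, cl = 0.95, method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (k < 0 || k > n) stop("k must be in [0, n]", call. = FALSE)
  z <- qnorm(1 - (1 - cl) / 2)
  p <- k / n
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- p - half; hi <- p + half
  } else {
    den <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / den
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    lo <- centre - half; hi <- centre + half
  }
  c(low = max(0, lo), high = min(1, hi))
}

#' Accumulate per-read diagnoses into a VAF report and support timeline
#'
#' Counts only TARGET reads whose consensus call is the wildtype allele or a
#' declared mutant allele; other bases are tallied as `n_other` and do not
#' count toward support. Reads without a start time are excluded from the
#' timeline (with a warning) but counted in the totals.
#'
#' @param diagnoses list of `read_diagnosis` objects (or the `$diagnoses`
#'   element of a pipeline report).
#' @param assay a [lamp_assay()].
#' @param cl,method proportion CI settings, see [proportion_ci()].
#' @return list with `vaf_report` (n_mut, n_wt, n_other, n_del, support,
#'   vaf, ci, call) and `timeline` (data.frame start_time,
#'   cumulative_support, running_vaf, sorted by time). `vaf` is NA and the
#'   overall `call` "NOCALL" when support is 0.
#' @export
accumulate <- function(diagnoses, assay, cl = 0.95, method = "wald") {
  is_target <- vapply(diagnoses, function(d) d$class == "TARGET", logical(1))
  calls <- vapply(diagnoses, function(d)
    if (d$class == "TARGET") d$consensus$call else NA_character_, character(1))
  times <- vapply(diagnoses, function(d) d$start_time %||% NA_real_, numeric(1))

  mut <- is_target & calls %in% assay$mutant_alleles
  wt <- is_target & calls == assay$wildtype_allele
  del <- is_target & calls == "DEL"
  supp <- mut | wt
  other <- is_target & !supp & !del & calls != "NOCALL"

  n_mut <- sum(mut, na.rm = TRUE)
  n_wt <- sum(wt, na.rm = TRUE)
  support <- n_mut + n_wt
  vaf <- if (support > 0) n_mut / support else NA_real_
  ci <- if (support > 0) proportion_ci(n_mut, support, cl, method)
        else c(low = NA_real_, high = NA_real_)

  keep <- which(supp)
  miss_t <- keep[is.na(times[keep])]
  if (length(miss_t))
    warning(length(miss_t), " supporting read(s) lack start_time; excluded",
            " from the timeline", call. = FALSE)
  keep <- keep[!is.na(times[keep])]
  keep <- keep[order(times[keep])]
  timeline <- data.frame(
    start_time = times[keep],
    cumulative_support = seq_along(keep),
    running_vaf = if (length(keep)) cumsum(mut[keep]) / seq_along(keep)
                  else numeric(0))

  list(vaf_report = list(
         n_mut = n_mut, n_wt = n_wt,
         n_other = sum(other, na.rm = TRUE), n_del = sum(del, na.rm = TRUE),
         support = support, vaf = vaf, ci = ci,
         call = if (support == 0) "NOCALL" else
           if (!is.null(vaf) && vaf > 0.5) "MUTANT" else "CALLED"),
       timeline = timeline)
}

#' Time to reach a support threshold
#'
#' @param timeline data.frame from [accumulate()] (sorted by time).
#' @param threshold required cumulative support, default 250.
#' @return seconds (start time of the threshold-th supporting read), or `NA`
#'   when the threshold is never reached.
#' @export
time_to_support <- function(timeline, threshold = 250L) {
  idx <- which(timeline$cumulative_support >= threshold)
  if (!length(idx)) return(NA_real_)
  timeline$start_time[idx[1]]
}

#' Binomial sensitivity/specificity at an operating point
#'
#' Exact binomial tails for a fixed-depth decision rule "call mutant when at
#' least `ceil(decision_threshold * depth)` of `depth` calls are mutant":
#' sensitivity is the probability a true VAF of `true_vaf` reaches the cut;
#' specificity the probability a pure-error sample stays below it.
#'
#' @param depth number of hotspot calls (>= 1).
#' @param true_vaf true mutant allele fraction in (0,1).
#' @param per_read_error probability an error read is miscalled mutant,
#'   in (0,1).
#' @param decision_threshold mutant-fraction cut in (0,1), default 0.05.
#' @return named numeric `c(sensitivity, specificity)`.
#' @export
detection_power <- function(depth, true_vaf, per_read_error,
                            decision_threshold = 0.05) {
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  fr <- c(true_vaf, per_read_error)
  if (any(fr <= 0 | fr >= 1)) stop("fractions must be in (0,1)", call. = FALSE)
  if (decision_threshold <= 0 || decision_threshold >= 1)
    stop("degenerate decision_threshold", call. = FALSE)
  kmin <- ceiling(decision_threshold * depth)
  sens <- pbinom(kmin - 1, depth, true_vaf, lower.tail = FALSE)
  spec <- pbinom(kmin - 1, depth, per_read_error)
  c(sensitivity = sens, specificity = spec)
}

#' Write a minimal single-record VCF for the hotspot call
#'
#' One record at the hotspot (1-based position) with AF and DP INFO fields.
#'
#' @param report the `vaf_report` element of [accumulate()].
#' @param assay a [lamp_assay()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hotspot_vcf <- function(report, assay, path) {
  alt <- paste(assay$mutant_alleles, collapse = ",")
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", assay$name, nchar(assay$target_ref)),
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Support depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tAF=%s;DP=%d",
            assay$name, assay$hotspot_pos + 1L, assay$wildtype_allele, alt,
            format(report$vaf %||% 0, digits = 6), report$support))
  writeLines(lines, path)
  invisible(path)
}
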