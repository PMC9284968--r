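# Sequencer performance model: a transparent rate product. Useful calls
# arrive at rate active_pores x participation(t) x per_pore_read_rate x
# (1 - barcode_loss) x target_fraction x call_yield, where participation
# ramps linearly from ramp_start x steady to steady over ramp_duration
# seconds (pore participation is low in the first minutes of a run).

#' Sequencer performance model
#'
#' @param active_pores pores available to sequence.
#' @param per_pore_read_rate reads per second per pore.
#' @param participation steady-state fraction of pores sequencing, in [0,1].
#' @param call_yield probability a target-class read yields a countable
#'   consensus call.
#' @param barcode_loss fraction of reads lost to barcode misassignment.
#' @param ramp_start initial participation as a fraction of the steady value.
#' @param ramp_duration seconds over which participation ramps up linearly.
#' @return object of class `sequencer_model`.
#' @export
sequencer_model <- function(active_pores, per_pore_read_rate,
                            participation = 1, call_yield = 1,
                            barcode_loss = 0, ramp_start = 0.3,
                            ramp_duration = 120) {
  fr <- c(participation, call_yield, barcode_loss, ramp_start)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0,1]", call. = FALSE)
  if (active_pores <= 0 || per_pore_read_rate <= 0)
    stop("rates must be > 0", call. = FALSE)
  structure(list(active_pores = active_pores,
                 per_pore_read_rate = per_pore_read_rate,
                 participation = participation, call_yield = call_yield,
                 barcode_loss = barcode_loss, ramp_start = ramp_start,
                 ramp_duration = ramp_duration), class = "sequencer_model")
}

#' Predicted sequencing time to a support threshold
#'
#' Inverts the cumulative useful-call curve. With no ramp the answer is
#' `support / (active_pores x participation x per_pore_read_rate x
#' (1 - barcode_loss) x target_fraction x call_yield)`; during the ramp the
#' piecewise-linear participation is integrated in closed form.
#'
#' @param model a [sequencer_model()].
#' @param target_fraction fraction of reads that contribute a hotspot call.
#' @param support required number of calls, default 250.
#' @return seconds; `Inf` when `target_fraction` is 0.
#' @export
sequencing_time <- function(model, target_fraction, support = 250) {
  if (target_fraction < 0 || target_fraction > 1)
    stop("target_fraction must be in [0,1]", call. = FALSE)
  if (target_fraction == 0) return(Inf)
  base <- model$active_pores * model$per_pore_read_rate *
    (1 - model$barcode_loss) * target_fraction * model$call_yield *
    model$participation
  r0 <- model$ramp_start
  Tr <- model$ramp_duration
  if (r0 >= 1 || Tr <= 0) return(support / base)
  # cumulative calls during ramp: base * (r0 t + (1 - r0) t^2 / (2 Tr))
  ramp_total <- base * Tr * (1 + r0) / 2
  if (support <= ramp_total) {
    a <- (1 - r0) / (2 * Tr); b <- r0; cc <- -support / base
    (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  } else {
    Tr + (support - ramp_total) / base
  }
}

#' Amplification characterization curve
#'
#' An ordered sweep of (amplification amount, useful target fraction)
#' points, e.g. PCR cycle counts or LAMP minutes; `dna_mass` optional.
#'
#' @param amount strictly increasing amplification amounts.
#' @param target_fraction fractions in [0,1], same length.
#' @param dna_mass optional ng measurements.
#' @return data.frame of class `amplification_curve`.
#' @export
amplification_curve <- function(amount, target_fraction, dna_mass = NULL) {
  if (!length(amount) || length(amount) != length(target_fraction))
    stop("amount and target_fraction must be equal-length, non-empty",
         call. = FALSE)
  if (any(diff(amount) <= 0))
    stop("amounts must be strictly increasing", call. = FALSE)
  if (any(target_fraction < 0 | target_fraction > 1))
    stop("fractions must be in [0,1]", call. = FALSE)
  d <- data.frame(amount = amount, target_fraction = target_fraction)
  if (!is.null(dna_mass)) d$dna_mass <- dna_mass
  class(d) <- c("amplification_curve", "data.frame")
  d
}

#' Read an amplification curve from TSV
#'
#' Columns: amount, target_fraction[, dna_mass]; header required.
#'
#' @param path TSV file.
#' @return an [amplification_curve()].
#' @export
read_amplification_curve <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t")
  amplification_curve(d$amount, d$target_fraction, d$dna_mass %||% NULL)
}

#' Optimal amplification amount
#'
#' Minimizes total time = amplification time + fixed overhead + predicted
#' sequencing time over the sweep range, interpolating the target fraction
#' linearly between sweep points and evaluating on a dense grid. Returns the
#' full total-time curve, not just the argmin.
#'
#' @param curve an [amplification_curve()].
#' @param model a [sequencer_model()].
#' @param per_unit_amp_time seconds of amplification per unit of `amount`
#'   (e.g. seconds per PCR cycle); 1 when `amount` is already in seconds.
#' @param fixed_overhead seconds of amount-independent protocol time.
#' @param support required call support, default 250.
#' @param grid_n grid resolution over the amount range.
#' @return list: `optimum_amount`, `optimum_total_time`, and `table`
#'   (data.frame amount, target_fraction, amp_time, seq_time, total_time).
#' @export
optimal_amplification <- function(curve, model, per_unit_amp_time = 1,
                                  fixed_overhead = 0, support = 250,
                                  grid_n = 1001L) {
  if (!nrow(curve)) stop("empty curve", call. = FALSE)
  if (all(curve$target_fraction == 0))
    stop("no feasible amplification: all target fractions are zero",
         call. = FALSE)
  amounts <- seq(min(curve$amount), max(curve$amount), length.out = grid_n)
  frac <- approx(curve$amount, curve$target_fraction, xout = amounts,
                 rule = 2)$y
  seq_t <- vapply(frac, function(f) sequencing_time(model, f, support),
                  numeric(1))
  amp_t <- amounts * per_unit_amp_time
  total <- amp_t + fixed_overhead + seq_t
  i <- which.min(total)
  list(optimum_amount = amounts[i], optimum_total_time = total[i],
       table = data.frame(amount = amounts, target_fraction = frac,
                          amp_time = amp_t, seq_time = seq_t,
                          total_time = total))
}
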