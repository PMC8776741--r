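# Irradiation protocols: timed sequences of dose fractions.

#' Irradiation protocol
#'
#' A protocol is an ordered sequence of dose fractions, each with an
#' absorbed dose, a start time and a beam-on duration. Acute delivery is a
#' fraction of zero duration. Inter-fraction separation is measured from
#' the end of one fraction to the start of the next; within-fraction
#' protraction is handled by the per-fraction Lea-Catcheside factor.
#'
#' @param dose Numeric vector of fraction doses in Gy (>= 0).
#' @param start Numeric vector of fraction start times in h from the
#'   protocol origin (strictly increasing).
#' @param duration Numeric vector of beam-on durations in h (>= 0).
#'   Defaults to 0 (instantaneous fractions).
#' @return An object of class `irradiation_protocol`: a data frame with
#'   columns `dose`, `start`, `duration` and an attribute `total_dose`.
#' @examples
#' # 2 Gy + 2 Gy split by 3 h, both acute
#' irradiation_protocol(dose = c(2, 2), start = c(0, 3))
#' @export
irradiation_protocol <- function(dose, start = 0, duration = 0) {
  n <- length(dose)
  start <- rep_len(start, n)
  duration <- rep_len(duration, n)
  if (n < 1L) stop("protocol needs at least one fraction", call. = FALSE)
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("fraction doses must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(duration)) || any(duration < 0))
    stop("fraction durations must be finite and >= 0", call. = FALSE)
  if (n > 1L && any(diff(start) <= 0))
    stop("fraction start times must be strictly increasing", call. = FALSE)
  ends <- start + duration
  if (n > 1L && any(start[-1L] < ends[-n] - 1e-12))
    stop("invalid protocol: fractions overlap in time", call. = FALSE)
  out <- data.frame(dose = dose, start = start, duration = duration)
  class(out) <- c("irradiation_protocol", "data.frame")
  attr(out, "total_dose") <- sum(dose)
  out
}

#' Total dose of a protocol
#' @param protocol An [irradiation_protocol()].
#' @return Sum of fraction doses in Gy.
#' @export
total_dose <- function(protocol) {
  stopifnot(inherits(protocol, "irradiation_protocol"))
  sum(protocol$dose)
}

#' Multi-fractionated protocol achieving a prescribed average dose rate
#'
#' Builds the equal-fraction, equal-gap protocol used to realise low
#' average dose rates with a fixed-output beam: `n = total_dose /
#' fraction_size` fractions, each delivered at `beam_rate`, separated by
#' equal gaps chosen so the total elapsed time (first beam-on to last
#' beam-off) equals `total_dose / average_rate`. With `average_rate ==
#' beam_rate` the gaps are zero and the protocol degenerates to one
#' continuous delivery.
#'
#' @param total_dose Total absorbed dose, Gy.
#' @param fraction_size Dose per fraction, Gy (must divide `total_dose`).
#' @param beam_rate Beam-on dose rate, Gy/min.
#' @param average_rate Average dose rate over the whole delivery, Gy/min
#'   (<= `beam_rate`).
#' @return An [irradiation_protocol()] (times in h).
#' @examples
#' # 10 Gy in 1-Gy fractions at 1 Gy/min beam rate, 0.1 Gy/min average:
#' # elapsed time 100 min, inter-fraction gap 10 min
#' p <- make_fractionation_protocol(10, 1, 1.0, 0.1)
#' @export
make_fractionation_protocol <- function(total_dose, fraction_size,
                                        beam_rate, average_rate) {
  stopifnot(total_dose > 0, fraction_size > 0, beam_rate > 0,
            average_rate > 0)
  if (average_rate > beam_rate + 1e-12)
    stop("infeasible protocol: average_rate exceeds beam_rate", call. = FALSE)
  n <- total_dose / fraction_size
  if (abs(n - round(n)) > 1e-9)
    stop("'total_dose' must be an integer multiple of 'fraction_size'",
         call. = FALSE)
  n <- as.integer(round(n))
  dur_h <- fraction_size / beam_rate / 60          # beam-on time per fraction
  elapsed_h <- total_dose / average_rate / 60      # first beam-on to last beam-off
  if (n == 1L)
    return(irradiation_protocol(total_dose, 0, elapsed_h))
  gap_h <- (elapsed_h - n * dur_h) / (n - 1)
  if (gap_h < -1e-12)
    stop("infeasible protocol: elapsed time shorter than total beam-on time",
         call. = FALSE)
  if (gap_h <= 1e-12)  # back-to-back fractions: one continuous block
    return(irradiation_protocol(total_dose, 0, elapsed_h))
  gap_h <- max(gap_h, 0)
  starts <- (seq_len(n) - 1L) * (dur_h + gap_h)
  irradiation_protocol(rep(fraction_size, n), starts, rep(dur_h, n))
}

#' @export
print.irradiation_protocol <- function(x, ...) {
  n <- nrow(x)
  elapsed <- x$start[n] + x$duration[n] - x$start[1L]
  cat(sprintf("Irradiation protocol: %d fraction(s), %.4g Gy total, %.4g h elapsed\n",
              n, attr(x, "total_dose"), elapsed))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (n > 10L) cat("  ... (", n - 10L, " more fractions)\n", sep = "")
  invisible(x)
}
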