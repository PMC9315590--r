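#' Dynamic 4D-CTA acquisition protocol
#'
#' Frame times for a whole-brain one-stop dynamic angiography/perfusion
#' acquisition: a baseline non-contrast volume at 0 s, 2-s intermittent
#' scans through the arterial window (11-36 s) and 5-s intermittent scans
#' through the venous window (40-60 s), for 19 volumes in total.
#'
#' @param arterial_window,venous_window numeric length-2 vectors, seconds.
#' @param arterial_step,venous_step sampling interval within each window, s.
#' @return An `acq_protocol` object: a strictly increasing numeric vector of
#'   acquisition times in seconds whose first element is 0 (the baseline
#'   non-contrast scan).
#' @examples
#' p <- make_protocol()
#' length(p)          # 19
#' contrast_times(p)  # the 18 contrast frame times
#' @export
make_protocol <- function(arterial_window = c(11, 36), venous_window = c(40, 60),
                          arterial_step = 2, venous_step = 5) {
  stopifnot(arterial_step > 0, venous_step > 0,
            arterial_window[1] > 0, venous_window[1] > arterial_window[2])
  times <- c(0,
             seq(arterial_window[1], arterial_window[2], by = arterial_step),
             seq(venous_window[1], venous_window[2], by = venous_step))
  stopifnot(all(diff(times) > 0))
  structure(times, class = "acq_protocol")
}

#' Contrast frame times of a protocol
#'
#' Drops the baseline (t = 0) non-contrast scan.
#' @param protocol an `acq_protocol` vector from [make_protocol()].
#' @return Numeric vector of the contrast acquisition times, seconds.
#' @export
contrast_times <- function(protocol) {
  unclass(protocol)[-1]
}

#' @export
print.acq_protocol <- function(x, ...) {
  cat("<acq_protocol> ", length(x), " volumes, ",
      length(x) - 1L, " contrast frames, t = ",
      x[1], "..", x[length(x)], " s\n", sep = "")
  invisible(x)
}

#' Gamma-variate contrast bolus curve
#'
#' The standard first-pass bolus model: zero before onset `t0`, then
#' `A * ((t - t0) / (alpha * beta))^alpha * exp(alpha - (t - t0) / beta)`.
#' Parameterised so the curve peaks at exactly `t0 + alpha * beta` with
#' peak value `A`, which makes the analytic landmark locations available in
#' closed form.
#'
#' @param t time(s) in seconds (vectorised).
#' @param t0 bolus onset time, s.
#' @param alpha shape parameter (> 0, dimensionless).
#' @param beta scale parameter (> 0, s).
#' @param A peak enhancement in HU (> 0).
#' @return Enhancement in HU at each `t`.
#' @examples
#' gamma_variate(20, t0 = 10, alpha = 3, beta = 10 / 3, A = 200)  # = 200
#' @export
gamma_variate <- function(t, t0, alpha, beta, A) {
  if (!(alpha > 0 && beta > 0 && A > 0)) {
    stop("gamma-variate parameters alpha, beta, A must all be positive")
  }
  dt <- t - t0
  out <- numeric(length(t))
  pos <- dt > 0
  out[pos] <- A * (dt[pos] / (alpha * beta))^alpha * exp(alpha - dt[pos] / beta)
  out
}

# Evaluate a gamma-variate from a params list(t0, alpha, beta, A).
gv_eval <- function(t, p) {
  gamma_variate(t, p$t0, p$alpha, p$beta, p$A)
}

# Analytic peak time of a gamma-variate.
gv_peak_time <- function(p) p$t0 + p$alpha * p$beta
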