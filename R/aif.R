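#' Population arterial input function
#'
#' Analytic plasma contrast-agent concentration curve shared by all simulated
#' subjects: a linear bolus ramp starting at `t_onset`, reaching `peak` at
#' `t_onset + ramp`, followed by a bi-exponential washout
#' \eqn{C_p(t) = peak \, (a_1 e^{-m_1 \tau} + a_2 e^{-m_2 \tau})} with
#' \eqn{a_1 + a_2 = 1}, so the curve is continuous at the peak. A fixed
#' analytic curve keeps the simulator reproducible; patient-specific arterial
#' sampling is out of scope.
#'
#' @param times numeric vector of acquisition times (minutes, `times[1] = 0`).
#' @param peak peak plasma concentration (mM).
#' @param t_onset bolus arrival time (min).
#' @param ramp ramp duration to peak (min).
#' @param a1,m1 amplitude fraction and rate (min^-1) of the fast washout term.
#' @param m2 rate (min^-1) of the slow washout term (amplitude `1 - a1`).
#' @return Numeric vector of plasma concentrations (mM), same length as
#'   `times`.
#' @examples
#' t <- seq(0, 5, length.out = 60)
#' cp <- population_aif(t)
#' @export
population_aif <- function(times, peak = 5, t_onset = 0.2, ramp = 0.2,
                           a1 = 0.8, m1 = 1.7, m2 = 0.05) {
  stopifnot(peak > 0, ramp > 0, a1 >= 0, a1 <= 1, m1 > 0, m2 > 0)
  tp <- t_onset + ramp
  cp <- numeric(length(times))
  rising <- times > t_onset & times <= tp
  cp[rising] <- peak * (times[rising] - t_onset) / ramp
  post <- times > tp
  tau <- times[post] - tp
  cp[post] <- peak * (a1 * exp(-m1 * tau) + (1 - a1) * exp(-m2 * tau))
  cp
}
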