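#' Gamma-variate bolus model
#'
#' The canonical first-pass model for dynamic susceptibility contrast:
#' `K * (t - t0)^alpha * exp(-(t - t0)/b)` for `t > t0`, zero before arrival.
#'
#' @param t times, s.
#' @param K amplitude.
#' @param t0 bolus arrival time, s.
#' @param alpha shape parameter (> 0).
#' @param b scale parameter, s (> 0).
#' @return Curve values at `t`.
#' @export
gamma_variate <- function(t, K, t0, alpha, b) {
  dt <- t - t0
  out <- numeric(length(t))
  pos <- dt > 0
  out[pos] <- K * dt[pos]^alpha * exp(-dt[pos] / b)
  out
}

# Closed-form area under the full gamma-variate (shift-invariant):
# integral_0^Inf K u^alpha exp(-u/b) du = K b^(alpha+1) Gamma(alpha+1)
gamma_variate_area <- function(K, alpha, b) K * b^(alpha + 1) * gamma(alpha + 1)

# Peak value, attained at t = t0 + alpha * b
gamma_variate_peak <- function(K, alpha, b) K * (alpha * b)^alpha * exp(-alpha)
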