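#' Sigmoidal transfer functions of the Wilson-Cowan populations
#'
#' `S(x) = 1/(1 + exp(-a (x - theta))) - 1/(1 + exp(a theta))`, shifted so
#' that `S(0) = 0`. The function is strictly increasing and bounded above by
#' `sigmoid_max(a, theta) = 1 - 1/(1 + exp(a theta))`.
#'
#' @param x input (net synaptic drive).
#' @param a slope parameter.
#' @param theta position of the maximum slope.
#' @return Numeric of the same shape as `x`.
#' @export
wc_sigmoid <- function(x, a, theta) {
  1 / (1 + exp(-a * (x - theta))) - 1 / (1 + exp(a * theta))
}

#' @rdname wc_sigmoid
#' @export
sigmoid_E <- function(x, a = 1.3, theta = 4) wc_sigmoid(x, a, theta)

#' @rdname wc_sigmoid
#' @export
sigmoid_I <- function(x, a = 2, theta = 3.7) wc_sigmoid(x, a, theta)

#' @rdname wc_sigmoid
#' @export
sigmoid_max <- function(a, theta) 1 - 1 / (1 + exp(a * theta))

#' Wilson-Cowan model parameters
#'
#' Constructs the parameter set of the delay-coupled stochastic Wilson-Cowan
#' network. Defaults are the standard whole-brain values: time constant
#' `tau` = 8 ms for both populations; local couplings `c_EE` = 16,
#' `c_IE` = 12, `c_EI` = 15, `c_II` = 3; sigmoid slopes `a_E` = 1.3,
#' `a_I` = 2 at positions `theta_E` = 4, `theta_I` = 3.7 (giving transfer
#' maxima 0.9945 and 0.9994); conduction velocity `v` = 10 m/s; integration
#' step `dt` = 5e-6 s. The global coupling `c` scales all long-range
#' excitatory connections and `sigma` scales the additive Gaussian noise on
#' both populations. All state variables start from the constant
#' `init_value`.
#'
#' @param c global coupling strength.
#' @param sigma noise amplitude (>= 0).
#' @param tau time constant (s).
#' @param c_EE,c_IE,c_EI,c_II local coupling strengths.
#' @param a_E,a_I sigmoid slopes.
#' @param theta_E,theta_I sigmoid positions.
#' @param v conduction velocity (m/s).
#' @param dt integration step (s); must satisfy `dt < tau`.
#' @param init_value constant initial condition for all E and I.
#' @return An object of class `wc_params`.
#' @export
wc_params <- function(c = 0.1, sigma = 0, tau = 0.008, c_EE = 16, c_IE = 12,
                      c_EI = 15, c_II = 3, a_E = 1.3, a_I = 2, theta_E = 4,
                      theta_I = 3.7, v = 10, dt = 5e-6, init_value = 0.1) {
  stopifnot(tau > 0, dt > 0, v > 0, sigma >= 0, dt < tau)
  structure(
    list(c = c, sigma = sigma, tau = tau, c_EE = c_EE, c_IE = c_IE,
         c_EI = c_EI, c_II = c_II, a_E = a_E, a_I = a_I, theta_E = theta_E,
         theta_I = theta_I, SE_max = sigmoid_max(a_E, theta_E),
         SI_max = sigmoid_max(a_I, theta_I), v = v, dt = dt,
         init_value = init_value),
    class = "wc_params")
}

#' Focal stimulation protocol
#'
#' A constant external input of strength `amplitude` added to the excitatory
#' sigmoid argument of region `site` during `[onset, offset)`. The default
#' protocol is the standard one: no input for the first two seconds, then
#' intensity 1.25 during the third second. `site = NULL` means no
#' stimulation (the onset still defines the before-stimulation segment).
#'
#' @param site region index to stimulate, or `NULL` for none.
#' @param amplitude input strength (>= 0).
#' @param onset,offset stimulation window (s), `onset < offset`.
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(site = NULL, amplitude = 1.25, onset = 2,
                          offset = 3) {
  stopifnot(onset < offset, amplitude >= 0)
  structure(list(site = site, amplitude = amplitude, onset = onset,
                 offset = offset),
            class = "stim_protocol")
}
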