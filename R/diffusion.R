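#' Kramers–Moyal drift and diffusion of the geometric-burst model
#'
#' First and second jump moments of the GB model in concentration units
#' `x = N/K`. With transcription propensity `a` (events/cycle) and
#' geometric burst sizes of mean `B` (second moment `E[k^2] = 2B^2 + B`):
#'
#' \deqn{v_x(x,y) = (B\,a_X - \gamma_0 K x)/K,\qquad
#'   D_x(x,y) = (a_X\,(2B^2+B) + \gamma_0 K x)/K^2,}
#'
#' and symmetrically for `y`. The `1/K` scaling of `D` makes the noise
#' vanish in the thermodynamic limit. For the toggle form
#' `a_X = K (r0 + r f(K y))`, so `v_x = B (r0 + r f(K y)) - gamma0 x`.
#'
#' @param params a [model_params()] object.
#' @param include_degradation_noise keep the demographic `gamma0 x / K`
#'   term in `D` (the default, matching the full diffusion approximation).
#'   Setting `FALSE` isolates the production (bursting) noise, which is
#'   what the PDMP Hamiltonian retains.
#' @param burst_second_moment `"geometric"` uses `E[k^2] = 2B^2 + B`;
#'   `"exponential"` uses the exponential-kernel analogue `2B^2` (i.e.
#'   `K^2 * 2b^2`), the weak-noise limit in which the diffusion and PDMP
#'   Hamiltonians coincide to quadratic order in the momenta.
#' @return A list of class `bs_drift_diffusion` with vectorised functions
#'   `v(x, y)` and `D(x, y)` (each returning an `n x 2` matrix), and the
#'   scales `K` and `B`.
#' @export
km_coefficients <- function(params,
                            include_degradation_noise = TRUE,
                            burst_second_moment = c("geometric", "exponential")) {
  stopifnot(inherits(params, "model_params"))
  burst_second_moment <- match.arg(burst_second_moment)
  B <- params$B; K <- params$K; g0 <- params$gamma0
  m2 <- if (burst_second_moment == "geometric") 2 * B^2 + B else 2 * B^2
  rates <- function(x, y) {
    cbind(transcription_propensity(params, N_other = K * y, N_self = K * x),
          transcription_propensity(params, N_other = K * x, N_self = K * y))
  }
  v <- function(x, y) {
    a <- rates(x, y)
    cbind((B * a[, 1] - g0 * K * x) / K, (B * a[, 2] - g0 * K * y) / K)
  }
  D <- function(x, y) {
    a <- rates(x, y)
    dem <- if (include_degradation_noise) cbind(g0 * K * x, g0 * K * y) else 0
    (a * m2 + dem) / K^2
  }
  structure(list(v = v, D = D, K = K, B = B,
                 second_moment = burst_second_moment,
                 degradation_noise = include_degradation_noise),
            class = "bs_drift_diffusion")
}

#' Integrate the diffusion approximation (convenience wrapper)
#'
#' Euler–Maruyama integration of the Itō SDE with the Kramers–Moyal
#' coefficients of [km_coefficients()]; equivalent to
#' `simulate_engine("DA-GB", ...)`.
#'
#' @inheritParams simulate_engine
#' @param initial concentrations `(x, y)`, non-negative.
#' @return A `bs_trajectory` data.frame with columns `t`, `x`, `y`.
#' @export
integrate_sde <- function(params, initial = NULL, t_end, dt = 1e-3, seed,
                          thin = 10L) {
  simulate_engine("DA-GB", params, initial = initial, t_end = t_end,
                  seed = seed, dt = dt, thin = thin)
}
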