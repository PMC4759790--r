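#' Packaged test scenarios with closed-form references
#'
#' Small, fast scenarios used throughout the test suite, each bundled with
#' its analytic reference law:
#'
#' * `"negbin_oracle"` — one species of the GB engine with frozen
#'   regulation (`r = 0`, so bursts fire at the constant rate
#'   `lambda = K*r0`): the stationary protein law is negative binomial with
#'   shape `lambda/gamma0` and success parameter `B/(1+B)`.
#' * `"gamma_oracle"` — the same scenario under the shot-noise engine: the
#'   stationary concentration is Gamma with shape `lambda/gamma0` and
#'   scale `b = B/K`.
#' * `"trimodal_hist"` — a synthetic three-blob histogram (modes at
#'   `(8,2)`, `(2,8)`, `(5,5)` with weights 0.4/0.4/0.2) with known mode
#'   count 3.
#' * `"mini_toggle"` — a reduced toggle (`K = 50`, `B = 5`, transcription
#'   rates raised so the small circuit is still bistable) for fast
#'   end-to-end runs.
#'
#' @param name fixture name (see above).
#' @return A list; contents depend on the fixture (always includes either
#'   `params` or `hist`).
#' @export
make_fixture <- function(name = c("negbin_oracle", "gamma_oracle",
                                  "trimodal_hist", "mini_toggle")) {
  name <- match.arg(name)
  frozen <- function() model_params(B = 5, gamma = 150, gamma0 = 1, r = 0,
                                    r0 = 0.2, K = 50, n = 3)
  switch(name,
    negbin_oracle = {
      p <- frozen()
      lam <- p$K * p$r0
      list(params = p, rate = lam,
           pmf = function(k) stats::dnbinom(k, size = lam / p$gamma0,
                                            prob = 1 / (1 + p$B)))
    },
    gamma_oracle = {
      p <- frozen()
      lam <- p$K * p$r0
      b <- burst_scale(p)
      list(params = p, rate = lam, shape = lam / p$gamma0, scale = b,
           density = function(x) stats::dgamma(x, shape = lam / p$gamma0,
                                               scale = b),
           # exact mass of the molecule bin centred at integer N
           bin_prob = function(N, K = p$K) {
             stats::pgamma((N + 0.5) / K, shape = lam / p$gamma0, scale = b) -
               stats::pgamma(pmax(N - 0.5, 0) / K, shape = lam / p$gamma0,
                             scale = b)
           })
    },
    trimodal_hist = {
      n <- 12
      g <- expand.grid(i = 0:n, j = 0:n)
      blob <- function(cx, cy, w)
        w * exp(-((g$i - cx)^2 + (g$j - cy)^2) / 2)
      w <- blob(8, 2, 0.4) + blob(2, 8, 0.4) + blob(5, 5, 0.2)
      list(hist = hist2d(matrix(w, n + 1, n + 1)),
           modes = rbind(c(8, 2), c(2, 8), c(5, 5)))
    },
    mini_toggle = list(params = model_params(B = 5, gamma = 150, K = 50,
                                             r = 0.4, r0 = 1 / 150)))
}
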