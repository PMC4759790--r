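test_that("PDMP flow is exact between switches", {
  # gamma0 = 0: in the X-mode, x grows linearly at rate gamma*b
  p <- suppressWarnings(model_params(B = 5, gamma = 150, gamma0 = 1e-12,
                                     r = 0, r0 = 0.2, K = 50))
  tr <- simulate_engine("PDMP", p, initial = c(1, 1), t_end = 2, seed = 4,
                        mode0 = 1L)
  gb <- p$gamma * burst_scale(p)
  i <- which(tr$mode[-nrow(tr)] == 1)
  dx <- tr$x[i + 1] - tr$x[i]
  dt <- tr$t[i + 1] - tr$t[i]
  expect_equal(dx, gb * dt, tolerance = 1e-6)
  # in the 0-state nothing is produced
  i0 <- which(tr$mode[-nrow(tr)] == 0)
  expect_true(all(tr$x[i0 + 1] - tr$x[i0] <= 1e-9))
})

test_that("X-mode sojourns are exponential with mean 1/gamma", {
  p <- frozen_params(rate = 10, B = 5, gamma = 150)
  tr <- simulate_engine("PDMP", p, initial = c(1, 1), t_end = 400, seed = 5)
  i <- which(tr$mode[-nrow(tr)] == 1)
  soj <- tr$t[i + 1] - tr$t[i]
  expect_gt(length(soj), 300)
  se <- sd(soj) / sqrt(length(soj))
  expect_lt(abs(mean(soj) - 1 / p$gamma), 3 * se)
  # mean concentration gained per 0 -> X -> 0 cycle is b = gamma*b * (1/gamma)
  gain <- (tr$x[i + 1] - tr$x[i] * exp(-p$gamma0 * soj))
  seg <- sd(gain) / sqrt(length(gain))
  expect_lt(abs(mean(gain) - burst_scale(p)), 3 * seg + 1e-3)
})

test_that("mode occupancy outside ZERO vanishes as gamma grows", {
  occ <- sapply(c(100, 1000), function(g) {
    p <- frozen_params(rate = 10, B = 5, gamma = g)
    h <- stationary_histogram("PDMP", p, 10, 510, seed = 6, nmax = 200,
                              initial = c(1, 1))
    mt <- attr(h, "meta")$mode_time
    1 - mt[1] / sum(mt)
  })
  expect_gt(occ[1], occ[2])
  # two independent activation channels at rate ~ a each, sojourn 1/gamma
  expect_lt(occ[2], 2 * 10 / 1000 * 1.5)
})

test_that("shot-noise stationary law is Gamma (frozen rate)", {
  fx <- make_fixture("gamma_oracle")
  h <- stationary_histogram("PDMP-SN", fx$params, 30, 2e4, seed = 7,
                            nmax = 300, initial = c(1, 1), dt_occ = 0.002)
  m <- marginal(h, 1)
  ref <- fx$bin_prob(0:300); ref <- ref / sum(ref)
  expect_lt(js_distance(matrix(m), matrix(ref)), 0.05)
  emp_mean <- sum(m * 0:300) / fx$params$K
  expect_lt(abs(emp_mean - fx$shape * fx$scale) / (fx$shape * fx$scale),
            0.05)
})

test_that("weak-noise limit concentrates at lambda*b/gamma0", {
  # b -> 0 at fixed lambda*b: mass concentrates, variance ~ b
  p <- model_params(B = 0.5, gamma = 3000, gamma0 = 1, r = 0, r0 = 2,
                    K = 50)  # lambda = 100, b = 0.01, lambda*b = 1
  h <- stationary_histogram("PDMP-SN", p, 10, 2010, seed = 8, nmax = 150,
                            initial = c(1, 1), dt_occ = 0.002)
  m <- marginal(h, 1)
  mu <- sum(m * 0:150) / p$K
  v <- sum(m * (0:150 / p$K - mu)^2)
  expect_equal(mu, 1, tolerance = 0.03)
  # Gamma variance = lambda * b^2 = 0.01 (plus ~1/K^2/12 binning noise)
  expect_lt(v, 0.02)
})

test_that("exponential bursts are the continuum analogue of geometric bursts", {
  # closed forms at Table-1 burst statistics: negative binomial vs binned
  # Gamma with the same shape lambda/gamma0 = 10
  lam <- 10; B <- 30; K <- 200
  nb <- dnbinom(0:2000, size = lam, prob = 1 / (1 + B))
  gm <- pgamma((0:2000 + 0.5) / K, shape = lam, scale = B / K) -
    pgamma(pmax(0:2000 - 0.5, 0) / K, shape = lam, scale = B / K)
  expect_lt(js_distance(matrix(nb / sum(nb)), matrix(gm / sum(gm))), 0.05)
})

test_that("finite-gamma PDMP converges towards the shot-noise law in gamma", {
  mk <- function(g) model_params(B = 5, gamma = g, gamma0 = 1, r = 0,
                                 r0 = 0.2, K = 50)
  ref <- stationary_histogram("PDMP-SN", mk(1000), 30, 1.5e4, seed = 42,
                              nmax = 300, initial = c(1, 1), dt_occ = 0.002)
  js <- sapply(c(100, 1000), function(g) {
    h <- stationary_histogram("PDMP", mk(g), 30, 1.5e4, seed = 41,
                              nmax = 300, initial = c(1, 1), dt_occ = 0.002)
    js_distance(matrix(marginal(h, 1)), matrix(marginal(ref, 1)))
  })
  expect_gt(js[1], js[2])
  expect_lt(js[2], 0.05)
})

test_that("shot-noise trajectories record pre- and post-burst states", {
  p <- make_fixture("mini_toggle")$params
  tr <- simulate_engine("PDMP-SN", p, t_end = 5, seed = 9)
  dup <- which(diff(tr$t) == 0)
  expect_gt(length(dup), 0)
  # at each event time the second record differs by the burst increment
  jumps <- (tr$x[dup + 1] - tr$x[dup]) + (tr$y[dup + 1] - tr$y[dup])
  expect_true(all(jumps > 0))
})
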