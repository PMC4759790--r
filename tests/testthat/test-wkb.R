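test_that("Hamiltonians vanish on the zero-momentum characteristic", {
  p <- table1()
  hp <- pdmp_hamiltonian(p)
  hd <- diffusion_hamiltonian(km_coefficients(p))
  set.seed(5)
  x <- runif(30, 0, 3); y <- runif(30, 0, 3); z <- numeric(30)
  expect_equal(hp$H(x, y, z, z), z)
  expect_equal(hd$H(x, y, z, z), z)
  expect_error(hp$H(1, 1, 1, 0), "admissible")
  expect_error(hp$H(1, 1, 0.2, 1.3), "admissible")
})

test_that("PDMP Hamiltonian is convex in momenta on the admissible domain", {
  hp <- pdmp_hamiltonian(table1())
  th <- seq(-0.8, 0.9, by = 0.05)
  Hs <- hp$H(rep(1.5, length(th)), rep(0.5, length(th)), th, 0.3 * th)
  expect_true(all(diff(Hs, differences = 2) > -1e-10))
})

test_that("1-species quasi-potential matches the Gamma-law closed form", {
  fx <- make_fixture("gamma_oracle")
  ham <- pdmp_hamiltonian(fx$params, one_species = TRUE)
  xstar <- fx$rate * burst_scale(fx$params) / fx$params$gamma0
  s0 <- function(x) (x - xstar) - xstar * log(x / xstar)
  for (xe in c(0.5, 2, 3)) {
    res <- minimize_action(ham, c(xstar, 0), c(xe, 0), path_points = 128)
    expect_true(res$converged)
    expect_equal(res$S0, s0(xe), tolerance = 0.01)
  }
})

test_that("action is monotone along a ray leaving the attractor", {
  fx <- make_fixture("gamma_oracle")
  ham <- pdmp_hamiltonian(fx$params, one_species = TRUE)
  vals <- sapply(c(1.5, 2, 2.5, 3), function(xe)
    minimize_action(ham, c(1, 0), c(xe, 0), path_points = 64)$S0)
  expect_true(all(diff(vals) > 0))
})

test_that("H = 0 holds along returned minimising paths", {
  fx <- make_fixture("gamma_oracle")
  ham <- pdmp_hamiltonian(fx$params, one_species = TRUE)
  res <- minimize_action(ham, c(1, 0), c(2.5, 0), path_points = 64)
  nd <- res$path
  d <- diff(nd); len <- sqrt(rowSums(d^2)); ok <- len > 1e-12
  E <- d[ok, , drop = FALSE] / len[ok]
  mid <- pmax((nd[-nrow(nd), ][ok, , drop = FALSE] +
                 nd[-1, ][ok, , drop = FALSE]) / 2, 0)
  th <- burstswitch:::theta_root(ham, mid, E)
  Hs <- ham$H(mid[, 1], mid[, 2], th * E[, 1], th * E[, 2])
  expect_lt(max(abs(Hs)), 1e-8)
})

test_that("quadratic momentum truncation recovers the diffusion Hamiltonian", {
  # with the exponential-kernel second moment 2b^2 (i.e. 2B^2 molecules^2)
  # and no degradation noise, the diffusion Hamiltonian equals the PDMP one
  # up to the cubic kernel terms
  p <- table1()
  hp <- pdmp_hamiltonian(p)
  hq <- diffusion_hamiltonian(
    km_coefficients(p, include_degradation_noise = FALSE,
                    burst_second_moment = "exponential"))
  set.seed(6)
  x <- runif(40, 0.2, 3); y <- runif(40, 0.1, 2)
  px <- runif(40, -0.15, 0.15); py <- runif(40, -0.15, 0.15)
  diffH <- abs(hp$H(x, y, px, py) - hq$H(x, y, px, py))
  # exact remainder bound: sum_i a_i |p_i|^3 / (1 - |p_i|)
  b <- burst_scale(p)
  aX <- b * transcription_propensity(p, p$K * y)
  aY <- b * transcription_propensity(p, p$K * x)
  bound <- aX * abs(px)^3 / (1 - abs(px)) + aY * abs(py)^3 / (1 - abs(py))
  expect_true(all(diffH <= bound + 1e-12))
  expect_gt(max(diffH), 0)  # the cubic terms are genuinely there
})

test_that("diffusion action reproduces OU and detailed-balance closed forms", {
  # constant-coefficient OU: S0 = gamma0 * ((x-x*)^2 + (y-y*)^2) / sigma^2
  dd <- list(v = function(x, y) cbind(1 - x, 1 - y),
             D = function(x, y) cbind(x * 0 + 1, y * 0 + 1), K = 1, B = 1)
  hd <- diffusion_hamiltonian(dd)
  res <- minimize_action(hd, c(1, 1), c(2, 1.5), path_points = 64)
  expect_equal(res$S0, 1^2 + 0.5^2, tolerance = 1e-4)
  # gradient drift v = -grad V: Freidlin-Wentzell action = 2 * delta V
  V <- function(x, y) 0.5 * (x - 1)^2 + (y - 0.5)^2
  ddg <- list(v = function(x, y) cbind(-(x - 1), -2 * (y - 0.5)),
              D = function(x, y) cbind(x * 0 + 1, y * 0 + 1), K = 1, B = 1)
  hg <- diffusion_hamiltonian(ddg)
  res2 <- minimize_action(hg, c(1, 0.5), c(1.8, 1.1), path_points = 64)
  expect_equal(res2$S0, 2 * (V(1.8, 1.1) - V(1, 0.5)), tolerance = 2e-3)
})

test_that("endpoint at the attractor costs nothing", {
  hd <- diffusion_hamiltonian(km_coefficients(table1()))
  res <- minimize_action(hd, c(1.8, 0.4), c(1.8, 0.4))
  expect_equal(res$S0, 0)
  expect_true(res$converged)
})

test_that("toggle quasi-potential is exchange symmetric between attractors", {
  p <- table1()
  hd <- diffusion_hamiltonian(km_coefficients(p))
  atX <- TABLE1_ATTR / p$K
  rX <- minimize_action(hd, atX, c(2.4, 0.6), path_points = 32,
                        maxit_outer = 4, maxit_inner = 12, tol = 1e-4)
  rY <- minimize_action(hd, rev(atX), c(0.6, 2.4), path_points = 32,
                        maxit_outer = 4, maxit_inner = 12, tol = 1e-4)
  expect_equal(rX$S0, rY$S0, tolerance = 1e-8)
})

test_that("quasi-potential surface matches the OU closed form on a grid", {
  dd <- list(v = function(x, y) cbind(1 - x, 1 - y),
             D = function(x, y) cbind(x * 0 + 1, y * 0 + 1), K = 1, B = 1)
  hd <- diffusion_hamiltonian(dd)
  xs <- c(1, 1.5, 2); ys <- c(1, 1.4)
  qs <- quasipotential_surface(hd, c(1, 1), xs, ys, path_points = 48,
                               maxit_outer = 8)
  ref <- outer(xs, ys, function(x, y) (x - 1)^2 + (y - 1)^2)
  expect_equal(qs$S0[1, 1], 0, tolerance = 1e-10)
  expect_lt(max(abs(qs$S0 - ref)), 0.02)
  expect_true(all(qs$converged))
  expect_equal(sum(qs$wkb_density), 1)
})

test_that("the bursting quasi-potential is shallower than the diffusion one", {
  p <- table1()
  at <- TABLE1_ATTR / p$K
  hp <- pdmp_hamiltonian(p)
  hd <- diffusion_hamiltonian(km_coefficients(p))
  rp <- minimize_action(hp, at, c(3.2, at[2]), path_points = 48,
                        maxit_outer = 8, maxit_inner = 20, tol = 1e-4)
  rd <- minimize_action(hd, at, c(3.2, at[2]), path_points = 48,
                        maxit_outer = 8, maxit_inner = 20, tol = 1e-4)
  expect_lt(rp$S0, rd$S0)
})
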