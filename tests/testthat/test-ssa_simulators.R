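test_that("single-mRNA lifecycles produce geometric protein counts", {
  p <- table1()
  set.seed(11)
  counts <- burstswitch:::cpp_mrna_lifecycle(300000L, p$B, p$gamma)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - p$B), 3 * se)          # mean B = 30
  # variance of the geometric law on {0,1,...}: B(B+1) = 930; the
  # variance-of-variance estimator is heavy-tailed, hence the wider band
  vse <- sd((counts - mean(counts))^2) / sqrt(length(counts))
  expect_lt(abs(var(counts) - p$B * (p$B + 1)), 4 * vse)
})

test_that("burst sampling matches the geometric and constant laws", {
  set.seed(3)
  k <- sample_burst("geometric", B = 30, n = 1e6)
  expect_lt(abs(mean(k) - 30), 0.1)
  expect_lt(abs(mean(k == 0) - 1 / 31), 5e-4)          # P(0) = 1/(1+B)
  expect_lt(abs(mean(k^2) - (2 * 30^2 + 30)) / (2 * 30^2 + 30), 0.01)
  expect_true(all(sample_burst("constant", B = 30, n = 100) == 30))
  expect_error(sample_burst("constant", B = 2.5), "integer")
})

test_that("trajectories are seed-reproducible and respect model structure", {
  p <- make_fixture("mini_toggle")$params
  tr1 <- simulate_engine("GB", p, t_end = 5, seed = 42)
  tr2 <- simulate_engine("GB", p, t_end = 5, seed = 42)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  tr3 <- simulate_engine("GB", p, t_end = 5, seed = 43)
  expect_false(identical(as.data.frame(tr1), as.data.frame(tr3)))
  expect_true(all(diff(tr1$t) > 0))
  # protein-only engines have structurally-zero mRNA
  expect_error(simulate_engine("NB", p, initial = c(10, 10, 1, 0),
                               t_end = 1, seed = 1), "structurally zero")
  fm <- simulate_engine("FM", p, t_end = 5, seed = 7)
  expect_true(all(fm[c("mX", "mY", "NX", "NY")] >= 0))
})

test_that("frozen-rate stationary laws match their closed forms", {
  # GB with constant rate: negative binomial (shape lam/gamma0, p = B/(1+B))
  fx <- make_fixture("negbin_oracle")
  h <- stationary_histogram("GB", fx$params, t_burn = 30, t_total = 2e4,
                            seed = 5, nmax = 300, initial = c(25, 25))
  m <- marginal(h, 1)
  ref <- fx$pmf(0:300); ref <- ref / sum(ref)
  emp_mean <- sum(m * 0:300)
  expect_lt(abs(emp_mean - fx$rate * fx$params$B) / 50, 0.05)
  expect_lt(js_distance(matrix(m), matrix(ref)), 0.05)
  # NB engine with frozen rate is a linear birth-death chain: Poisson law
  pnb <- frozen_params(rate = 4, B = 5)  # birth rate B*lam = 20, Poisson(20)
  hp <- stationary_histogram("NB", pnb, 30, 2e4, seed = 6, nmax = 200,
                             initial = c(20, 20))
  mp <- marginal(hp, 1)
  pois <- dpois(0:200, 20)
  expect_lt(js_distance(matrix(mp), matrix(pois / sum(pois))), 0.05)
  expect_lt(abs(sum(mp * 0:200) - 20) / 20, 0.05)
})

test_that("stationary histograms are normalised, flux-balanced and burn-in checked", {
  p <- table1()
  h <- stationary_histogram("GB", p, t_burn = 20, t_total = 420, seed = 3)
  expect_s3_class(h, "bs_hist2d")
  expect_equal(sum(h$prob), 1, tolerance = 1e-12)
  meta <- attr(h, "meta")
  # production flux equals gamma0 * E[NX] at stationarity
  flux <- meta$prodX / meta$time
  occ <- p$gamma0 * meta$intNX / meta$time
  expect_lt(abs(flux - occ) / occ, 0.05)
  expect_error(stationary_histogram("GB", p, t_burn = 10, t_total = 5,
                                    seed = 1), "t_burn")
  # absorbing origin: no production, start at (0,0)
  p0 <- suppressWarnings(model_params(r = 0, r0 = 0))
  h0 <- stationary_histogram("GB", p0, 1, 11, seed = 2, initial = c(0, 0),
                             nmax = 10)
  expect_equal(h0$prob[1, 1], 1)
})

test_that("bursting broadens the stationary distribution (GB vs NB)", {
  p <- table1()
  hGB <- stationary_histogram("GB", p, 20, 1020, seed = 8, symmetrize = TRUE)
  hNB <- stationary_histogram("NB", p, 20, 1020, seed = 9, symmetrize = TRUE)
  vx <- function(h) {
    m <- marginal(h, 1); mu <- sum(m * 0:h$nmax)
    sum(m * (0:h$nmax - mu)^2)
  }
  expect_gt(vx(hGB), vx(hNB))
})

test_that("the law is X<->Y exchange symmetric (mirrored runs)", {
  p <- make_fixture("mini_toggle")$params
  h1 <- stationary_histogram("GB", p, 20, 2020, seed = 12,
                             initial = c(80, 10), nmax = 300)
  h2 <- stationary_histogram("GB", p, 20, 2020, seed = 13,
                             initial = c(10, 80), nmax = 300)
  m1 <- attr(h1, "meta"); m2 <- attr(h2, "meta")
  # E[NX] started high-X should match E[NY] started high-Y
  ex1 <- m1$intNX / m1$time; ey2 <- m2$intNY / m2$time
  expect_lt(abs(ex1 - ey2) / ex1, 0.1)
})

test_that("FM mRNA marginal with frozen regulation is Poisson(a/gamma)", {
  pf <- frozen_params(rate = 10, B = 5, gamma = 150)
  h <- stationary_histogram("FM", pf, 20, 2020, seed = 14, nmax = 300,
                            initial = c(50, 50))
  meta <- attr(h, "meta")
  mmean <- meta$intmX / meta$time
  expect_lt(abs(mmean - 10 / 150) / (10 / 150), 0.15)
})
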