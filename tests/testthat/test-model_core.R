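test_that("parameter construction enforces invariants and derives b once", {
  p <- table1()
  expect_equal(burst_scale(p), 0.15)
  expect_error(model_params(B = -1), "B > 0")
  expect_error(model_params(K = 0), "K > 0")
  expect_warning(model_params(gamma = 5, gamma0 = 1), "gamma/gamma0")
  expect_error(model_params(regulation = "three_way", r1 = -2),
               "strictly positive")
})

test_that("presets round-trip through JSON and YAML configs", {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(preset = "ecoli_table1", B = 10, K = 100),
                       tmp, auto_unbox = TRUE)
  p <- read_params(tmp)
  expect_equal(p$B, 10)
  expect_equal(p$K, 100)
  expect_equal(p$r0, 1 / 150)  # untouched preset value
  tmp2 <- tempfile(fileext = ".yaml")
  writeLines(c("preset: lu_threeway", "q0: 2.5"), tmp2)
  p2 <- read_params(tmp2)
  expect_equal(p2$regulation, "three_way")
  expect_equal(p2$q0, 2.5)
})

test_that("toggle transcription propensity matches its closed forms", {
  p <- table1()
  # no repressor: maximal rate K*(r0 + r)
  expect_equal(transcription_propensity(p, 0), 200 * (1 / 150 + 6 / 100))
  expect_equal(transcription_propensity(p, 0), 13 + 1 / 3, tolerance = 1e-12)
  # half saturation at N = K
  expect_equal(transcription_propensity(p, p$K), 200 * (1 / 150 + 3 / 100))
  # full repression limit: basal rate K*r0
  expect_equal(transcription_propensity(p, 1e12), 200 / 150,
               tolerance = 1e-6)
  expect_error(transcription_propensity(p, -1), "negative")
})

test_that("toggle propensity is bounded and monotone over random inputs", {
  p <- table1()
  set.seed(1)
  N <- sort(runif(200, 0, 2000))
  a <- transcription_propensity(p, N)
  expect_true(all(diff(a) <= 0))
  expect_true(all(a >= p$K * p$r0 & a <= p$K * (p$r0 + p$r)))
  f <- hill_repression(N, p$K, p$n)
  expect_true(all(diff(f) <= 0) && all(f > 0 & f <= 1))
})

test_that("three-way propensity is strictly positive, self-activating and cross-repressed", {
  p <- threeway()
  set.seed(2)
  Ns <- runif(100, 0, 2000); No <- runif(100, 0, 2000)
  a <- transcription_propensity(p, N_other = No, N_self = Ns)
  expect_true(all(is.finite(a) & a > 0))
  expect_true(all(a >= p$q0 * (1 + p$r1) - 1e-12))
  expect_true(all(a <= p$q0 * (1 + p$r2) + 1e-12))
  # monotone: increasing in self (positive autoregulation, r1 < 0),
  # decreasing in the competitor (repression, r2 > 0)
  Nseq <- seq(0, 1000, by = 50)
  expect_true(all(diff(transcription_propensity(p, 100, Nseq)) >= 0))
  expect_true(all(diff(transcription_propensity(p, Nseq, 100)) <= 0))
})

test_that("mean-field flow has the documented fixed-point structure", {
  p <- table1()
  # unregulated branch: f = 1 gives x* = K*B*(r0+r)/gamma0 = 400
  xstar <- p$K * p$B * (p$r0 + p$r) / p$gamma0
  expect_equal(xstar, 400)
  expect_equal(mean_field_rhs(p, c(xstar, 0))[1],
               p$B * transcription_propensity(p, 0) - p$gamma0 * xstar)
  # all production off: the origin is the unique fixed point
  p0 <- suppressWarnings(model_params(r = 0, r0 = 0))
  expect_equal(mean_field_rhs(p0, c(0, 0)), c(0, 0))
  a0 <- find_attractors(p0)
  expect_equal(nrow(a0), 1)
  expect_equal(unlist(a0[1, c("x", "y")], use.names = FALSE), c(0, 0),
               tolerance = 1e-6)
  # X <-> Y exchange symmetry of the field
  z <- c(312, 57)
  expect_equal(mean_field_rhs(p, z), rev(mean_field_rhs(p, rev(z))))
})

test_that("attractor search classifies the toggle and three-way landscapes", {
  at <- find_attractors(table1())
  expect_equal(sum(at$stable), 2)
  expect_equal(sum(!at$stable), 1)
  st <- at[at$stable, ]
  expect_equal(st$x, rev(st$y), tolerance = 1e-6)  # mirror images
  sad <- at[!at$stable, ]
  expect_equal(sad$x, sad$y, tolerance = 1e-6)     # symmetric saddle
  # r = 0 removes the regulation contrast: single globally stable point
  pr0 <- model_params(r = 0)
  a1 <- find_attractors(pr0)
  expect_equal(nrow(a1), 1)
  expect_true(a1$stable[1])
  # three-way deterministic limit is tristable
  a3 <- find_attractors(threeway())
  expect_equal(sum(a3$stable), 3)
  ctr <- a3[a3$stable & abs(a3$x - a3$y) < 1, ]
  expect_equal(nrow(ctr), 1)  # one of them is the symmetric state
})
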