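#' Deterministic mean-field vector field
#'
#' Rate of change of the mean protein copy numbers when fluctuations are
#' ignored: production `B * a` (transcription events times mean burst size)
#' minus linear degradation `gamma0 * N`, for each species.
#'
#' @param params a [model_params()] object.
#' @param x numeric length-2 vector of protein copy numbers `(N_X, N_Y)`.
#' @return Length-2 vector, molecules per cell cycle.
#' @export
mean_field_rhs <- function(params, x) {
  stopifnot(length(x) == 2)
  if (any(x < 0)) stop("protein numbers must be non-negative")
  aX <- transcription_propensity(params, N_other = x[2], N_self = x[1])
  aY <- transcription_propensity(params, N_other = x[1], N_self = x[2])
  c(params$B * aX - params$gamma0 * x[1],
    params$B * aY - params$gamma0 * x[2])
}

#' Locate the deterministic attractors and saddles
#'
#' Finds all fixed points of [mean_field_rhs()] by damped Newton iteration
#' from a deterministic 9x9 multi-start grid covering
#' `[0, 3 * B * a_max / gamma0]^2` (`a_max` the maximal transcription rate),
#' de-duplicates the roots and classifies their stability by the eigenvalues
#' of the numerically linearised field. For the symmetric toggle at the
#' default preset this yields exactly two stable attractors (mirror images
#' under `(x, y) -> (y, x)`) and one symmetric saddle; the three-way preset
#' yields three stable states.
#'
#' @param params a [model_params()] object.
#' @param tol Newton convergence tolerance on `|rhs|` (molecules/cycle).
#' @return A data.frame with columns `x`, `y`, `stable` (logical),
#'   `eig_max` (largest real part of the Jacobian eigenvalues), sorted by
#'   decreasing `x`. Starting points whose Newton iteration fails to
#'   converge are counted in the `n_failed` attribute (never silently
#'   dropped).
#' @examples
#' find_attractors(preset_params("ecoli_table1"))
#' @export
find_attractors <- function(params, tol = 1e-9) {
  stopifnot(inherits(params, "model_params"))
  lim <- 3 * params$B * propensity_sup(params) / params$gamma0
  starts <- as.matrix(expand.grid(seq(0, lim, length.out = 9),
                                  seq(0, lim, length.out = 9)))
  roots <- list(); n_failed <- 0L
  for (s in seq_len(nrow(starts))) {
    z <- newton2(function(v) mean_field_rhs(params, v), starts[s, ],
                 lower = c(0, 0), upper = c(lim, lim) * 2, tol = tol)
    if (is.null(z)) { n_failed <- n_failed + 1L; next }
    roots[[length(roots) + 1L]] <- z
  }
  if (!length(roots)) stop("no fixed point found; ", n_failed, " starts failed")
  pts <- do.call(rbind, roots)
  # de-duplicate on a scale set by the search box
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!keep[i]) next
    d <- sqrt(rowSums((pts - matrix(pts[i, ], nrow(pts), 2, byrow = TRUE))^2))
    keep[which(d < 1e-5 * max(lim, 1))] <- FALSE
    keep[i] <- TRUE
  }
  pts <- pts[keep, , drop = FALSE]
  eig_max <- apply(pts, 1, function(v) {
    J <- num_jacobian(function(z) mean_field_rhs(params, z), v)
    max(Re(eigen(J, only.values = TRUE)$values))
  })
  out <- data.frame(x = pts[, 1], y = pts[, 2],
                    stable = eig_max < -1e-9, eig_max = eig_max)
  out <- out[order(-out$x, out$y), ]
  rownames(out) <- NULL
  attr(out, "n_failed") <- n_failed
  out
}

# internal: high-X stable attractor (or the stable point with largest x)
high_x_attractor <- function(params) {
  at <- find_attractors(params)
  at <- at[at$stable, , drop = FALSE]
  if (!nrow(at)) stop("no stable attractor found")
  unlist(at[which.max(at$x - at$y), c("x", "y")], use.names = FALSE)
}

# internal: 2-D damped Newton with projection onto [lower, upper]
newton2 <- function(f, x0, lower, upper, tol = 1e-9, maxit = 200) {
  x <- pmin(pmax(x0, lower), upper)
  for (it in seq_len(maxit)) {
    fx <- f(x)
    if (max(abs(fx)) < tol) return(x)
    J <- num_jacobian(f, x)
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lam <- 1
    repeat {
      xn <- pmin(pmax(x - lam * step, lower), upper)
      if (max(abs(f(xn))) < max(abs(fx)) || lam < 1e-6) break
      lam <- lam / 2
    }
    if (max(abs(x - xn)) < 1e-14 * (1 + max(abs(x)))) return(NULL)
    x <- xn
  }
  NULL
}

# internal: central-difference Jacobian
num_jacobian <- function(f, x, h = NULL) {
  if (is.null(h)) h <- pmax(1e-6 * abs(x), 1e-6)
  m <- length(f(x)); J <- matrix(0, m, length(x))
  for (k in seq_along(x)) {
    e <- numeric(length(x)); e[k] <- h[k]
    lo <- pmax(x - e, 0)
    J[, k] <- (f(x + e) - f(lo)) / (x[k] + e[k] - lo[k])
  }
  J
}
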