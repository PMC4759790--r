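#' Finite-difference solution of the shot-noise backward equation
#'
#' Solves the mean-first-switching-time equation of the shot-noise limit on
#' the open half-plane `Ω = {x > y}` (concentration units):
#'
#' \deqn{-\gamma_0 x \partial_x T - \gamma_0 y \partial_y T
#'  + a_X(y)\,(E_Z[T(x+Z,y)] - T) + a_Y(x)\,(E_Z[T(x,y+Z)] - T) = -1,}
#'
#' with `Z ~ Exp(mean b)` and `T = 0` wherever a burst lands outside `Ω`
#' (crossing `y >= x` means exit). The equation is self-consistent on `Ω`:
#' no boundary condition is imposed, and enlarging the truncation box
#' leaves interior values essentially unchanged.
#'
#' Discretisation: first-order upwind differences for the (inward-flowing)
#' advection, and exact per-cell integration of the exponential burst
#' kernel against a piecewise-linear representation of `T` along grid
#' lines. Beyond the box edge in `x` the kernel tail uses constant
#' extrapolation (the deterministic flow points inward and the tail carries
#' weight `e^{-w/b}`). The sparse linear system is solved directly.
#'
#' @param params a [model_params()] object with `regulation = "toggle"`.
#' @param box truncation box edge `L`: the grid covers `[0, L]^2`
#'   (concentration units, i.e. molecules / `K`).
#' @param h grid spacing (concentration units).
#' @param kernel_cut truncate the burst kernel at `kernel_cut * b`,
#'   lumping the remaining `e^{-kernel_cut}` tail mass by constant
#'   extrapolation (default keeps the neglected weight below `5e-5`).
#' @param richardson the semi-Lagrangian/piecewise-linear scheme is first
#'   order in `h`; with `richardson = TRUE` (default) the equation is
#'   solved at `h` and `2h` and extrapolated to `2 T_h - T_{2h}`, removing
#'   the leading error (the band within `2h` of the diagonal, where the
#'   coarse surface cannot be interpolated, keeps the plain `T_h` values).
#' @return An object of class `bs_backward_solution`: list with `T` (a
#'   `(M+1) x (M+1)` matrix of mean switching times over the grid
#'   `x_i = i*h`, `y_j = j*h`, zero on and beyond the diagonal), `h`,
#'   `box`, `params`.
#' @seealso [mfst_at()] to interpolate the surface, [mfst_monte_carlo()]
#'   for the simulation estimate it reproduces.
#' @export
solve_backward_fd <- function(params, box = 4, h = 0.05, kernel_cut = 10,
                              richardson = TRUE) {
  stopifnot(inherits(params, "model_params"))
  if (params$regulation != "toggle")
    stop("the backward solver supports toggle regulation only")
  if (richardson) {
    fine <- solve_backward_fd(params, box, h, kernel_cut, richardson = FALSE)
    coarse <- solve_backward_fd(params, box, 2 * h, kernel_cut,
                                richardson = FALSE)
    M <- nrow(fine$T) - 1L
    g <- expand.grid(i = 0:M, j = 0:M)
    inside <- g$i * h <= box & g$j * h <= box & g$j <= g$i
    Tc <- matrix(0, M + 1, M + 1)
    Tc[cbind(g$i + 1, g$j + 1)[inside, ]] <-
      mfst_at(coarse, pmin(g$i[inside] * h, box), pmin(g$j[inside] * h, box))
    TR <- pmax(2 * fine$T - Tc, 0)
    band <- abs(row(TR) - col(TR)) * h < 2 * (2 * h)
    TR[band] <- fine$T[band]
    TR[row(TR) < col(TR)] <- 0
    fine$T <- TR
    fine$richardson <- TRUE
    return(fine)
  }
  b <- burst_scale(params)
  g0 <- params$gamma0
  K <- params$K
  M <- round(box / h)
  if (M < 4) stop("grid too coarse")
  s <- h / b
  m_max <- max(2L, ceiling(kernel_cut * b / h))

  # Node bookkeeping: unknowns are (i, j) with 0 <= j <= i <= M. Diagonal
  # nodes j == i carry the *interior limit* of T as y -> x from below: T is
  # discontinuous across the exit boundary (the limit is ~ 1/a_Y, the wait
  # for the next exiting y-burst, not 0), and pinning zero there would act
  # as a spurious absorbing layer dragging the whole surface down.
  ID <- matrix(NA_integer_, M + 1, M + 1)  # [i+1, j+1]
  iv <- jv <- integer(0)
  k <- 0L
  for (i in 0:M) {
    js <- 0:i
    ID[i + 1, js + 1] <- k + seq_along(js)
    iv <- c(iv, rep.int(i, length(js))); jv <- c(jv, js)
    k <- k + length(js)
  }
  n <- k
  xg <- iv * h
  yg <- jv * h
  onD <- iv == jv
  aX <- transcription_propensity(params, N_other = K * yg)  # X-burst rate
  aY <- transcription_propensity(params, N_other = K * xg)  # Y-burst rate
  if (max(aY) < 1e-12)
    warning("a_Y is (numerically) zero everywhere: no exit mechanism; ",
            "T diverges with the truncation box")

  # exponential-kernel cell weights (uniform grid): cell m spans
  # [m*h, (m+1)*h]; P_m its mass, Q the linear-part weight per cell
  Q <- (1 / s) * (1 - exp(-s)) - exp(-s)
  expms <- exp(-s * (0:(m_max + 1)))
  P <- expms[1:(m_max + 1)] - expms[2:(m_max + 2)]

  trip_i <- trip_j <- integer(0); trip_x <- numeric(0)
  add <- function(rows, cols, vals) {
    trip_i <<- c(trip_i, rows); trip_j <<- c(trip_j, cols)
    trip_x <<- c(trip_x, vals)
  }

  rows <- 1:n
  diag_val <- numeric(n)
  # Advection: the flow -gamma0 * (x, y) moves along rays of constant y/x
  # and never reaches the diagonal. A semi-Lagrangian step backtracks each
  # node one cell in x along its own characteristic, to
  # ((i-1) h, j (i-1)/i h), which needs only linear interpolation in y
  # between (i-1, j-1) and (i-1, j); upwinding each coordinate separately
  # would add cross-stream numerical diffusion and bleed mass into the
  # exit boundary. The exchange rate is gamma0 / log(i/(i-1)), the exact
  # traversal time of the cell under exponential decay.
  sel <- iv >= 1
  nu <- ifelse(sel, g0 / log(iv / pmax(iv - 1, 1e-300)), 0)
  w0 <- ifelse(iv > 0, jv / iv, 0)   # weight on (i-1, j-1)
  ok <- sel & jv >= 1
  add(rows[ok], ID[cbind(iv[ok], jv[ok])], nu[ok] * w0[ok])
  ok <- sel & (1 - w0) > 0
  add(rows[ok], ID[cbind(iv[ok], jv[ok] + 1)], nu[ok] * (1 - w0[ok]))
  diag_val[sel] <- diag_val[sel] - nu[sel]

  # burst expectation weights: offset-m coefficient of the piecewise-linear
  # kernel integral. 'closing' handles the last represented node: at the
  # box edge / kernel cut the tail mass is lumped there (constant
  # extrapolation); at the diagonal the tail exits and carries T = 0, so
  # only the linear weight of the final cell remains.
  coef_at <- function(m, mm, tail_exits) {
    v <- numeric(length(mm))
    inner <- m < mm
    v[inner] <- if (m == 0) P[1] - Q else
      expms[m] * Q + P[m + 1] - expms[m + 1] * Q
    closing <- m == mm
    v[closing & !tail_exits] <- if (m == 0) 1 else expms[m] * Q + expms[m + 1]
    v[closing & tail_exits] <- if (m == 0) 0 else expms[m] * Q
    v
  }
  mm_x <- pmin(m_max, M - iv)
  mm_y <- pmin(m_max, iv - jv)
  y_reaches_diag <- (iv - jv) <= m_max  # kernel resolved up to the boundary
  for (m in 0:m_max) {
    # x-bursts land at (i+m, j), always inside Omega (tail: box edge)
    sel <- mm_x >= m
    if (any(sel)) {
      cf <- coef_at(m, mm_x[sel], rep(FALSE, sum(sel))) * aX[sel]
      if (m == 0) diag_val[sel] <- diag_val[sel] + cf
      else add(rows[sel], ID[cbind(iv[sel] + m + 1, jv[sel] + 1)], cf)
    }
    # y-bursts land at (i, j+m); mass beyond the diagonal exits (T = 0)
    sel <- !onD & mm_y >= m
    if (any(sel)) {
      cf <- coef_at(m, mm_y[sel], y_reaches_diag[sel]) * aY[sel]
      if (m == 0) diag_val[sel] <- diag_val[sel] + cf
      else {
        nz <- cf != 0
        if (any(nz))
          add(rows[sel][nz],
              ID[cbind(iv[sel][nz] + 1, jv[sel][nz] + m + 1)], cf[nz])
      }
    }
  }
  # every y-burst from a diagonal node exits; burst-loss terms
  diag_val <- diag_val - aX - aY
  add(rows, rows, diag_val)

  A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(n, n))
  Tvec <- tryCatch(
    as.numeric(Matrix::solve(A, rep(-1, n))),
    error = function(e) stop("backward-equation linear solve failed (",
                             conditionMessage(e),
                             "); grid: M = ", M, ", n = ", n))
  if (any(!is.finite(Tvec)) || any(Tvec < -1e-8))
    stop("backward solution is not a valid first-passage surface; ",
         "check discretisation (min T = ", signif(min(Tvec), 3), ")")

  Tm <- matrix(0, M + 1, M + 1)
  Tm[cbind(iv + 1, jv + 1)] <- pmax(Tvec, 0)
  structure(list(T = Tm, h = h, box = box, m_max = m_max, params = params),
            class = "bs_backward_solution")
}

#' @export
print.bs_backward_solution <- function(x, ...) {
  cat("<bs_backward_solution> box = [0,", x$box, "]^2, h =", x$h,
      " max T =", signif(max(x$T), 4), "cycles\n")
  invisible(x)
}

#' Interpolate a backward-equation MFST surface
#'
#' Bilinear interpolation of the finite-difference solution at arbitrary
#' points of `Ω` (the surface is 0 on and beyond the diagonal).
#'
#' @param sol a [solve_backward_fd()] result.
#' @param x,y coordinates, concentration units (vectorised).
#' @return Mean switching times in cell cycles.
#' @export
mfst_at <- function(sol, x, y) {
  stopifnot(inherits(sol, "bs_backward_solution"))
  h <- sol$h; M <- nrow(sol$T) - 1L
  if (any(x < 0 | y < 0 | x > sol$box | y > sol$box))
    stop("point outside the truncation box")
  fi <- pmin(x / h, M - 1e-9); fj <- pmin(y / h, M - 1e-9)
  i0 <- floor(fi); j0 <- floor(fj)
  u <- fi - i0; v <- fj - j0
  g <- function(i, j) sol$T[cbind(i + 1, j + 1)]
  (1 - u) * (1 - v) * g(i0, j0) + u * (1 - v) * g(i0 + 1, j0) +
    (1 - u) * v * g(i0, j0 + 1) + u * v * g(i0 + 1, j0 + 1)
}
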