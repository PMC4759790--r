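#' WKB Hamiltonian of the shot-noise PDMP
#'
#' In the weak-noise limit `b -> 0` the stationary density of the
#' shot-noise process takes the WKB form `p_s ~ exp(-S0(x,y)/b)`. The
#' quasi-potential `S0` solves the Hamilton–Jacobi equation
#' `H(x, y, dS0/dx, dS0/dy) = 0` with the leading-order Hamiltonian
#'
#' \deqn{H = \tilde a_X(x,y)\frac{p_x}{1-p_x}
#'         + \tilde a_Y(x,y)\frac{p_y}{1-p_y}
#'         - \gamma_0 x\,p_x - \gamma_0 y\,p_y,}
#'
#' where `ã_i = b * a_i` is the mean production rate in concentration per
#' cycle. The `1/(1-p)` transform of the exponential burst kernel is only
#' defined for momenta `p < 1` and expands as `p + p^2 + p^3 + ...`: the
#' cubic (and higher) terms distinguish bursting noise from any diffusion
#' approximation, whose Hamiltonian is quadratic in the momenta.
#'
#' @param params a [model_params()] object.
#' @param one_species drop the Y species entirely (its burst rate is set to
#'   zero), leaving the one-dimensional bursting system on the x-axis.
#'   Useful against closed forms: with a frozen rate `lambda` (`r = 0`) the
#'   Hamilton–Jacobi equation is solved exactly by
#'   `S0(x) = (x - x*) - x* log(x/x*)`, `x* = lambda b / gamma0`, the
#'   `-b log` transform of the Gamma stationary law.
#' @return An object of class `bs_hamiltonian` with vectorised fields
#'   `H(x, y, px, py)`, `drift(x, y)` (the zero-momentum characteristic
#'   flow), `b`, and `kind = "pdmp"`. Momenta at or beyond 1 raise a
#'   domain error (not NaN).
#' @export
pdmp_hamiltonian <- function(params, one_species = FALSE) {
  stopifnot(inherits(params, "model_params"))
  b <- burst_scale(params); g0 <- params$gamma0; K <- params$K
  atil <- function(x, y) {
    cbind(b * transcription_propensity(params, N_other = K * y, N_self = K * x),
          if (one_species) 0 else
            b * transcription_propensity(params, N_other = K * x, N_self = K * y))
  }
  H <- function(x, y, px, py) {
    if (any(px >= 1) || any(py >= 1))
      stop("momentum outside the admissible domain (px, py < 1)")
    a <- atil(x, y)
    a[, 1] * px / (1 - px) + a[, 2] * py / (1 - py) - g0 * x * px - g0 * y * py
  }
  drift <- function(x, y) {
    a <- atil(x, y)
    cbind(a[, 1] - g0 * x, a[, 2] - g0 * y)
  }
  structure(list(H = H, drift = drift, b = b, kind = "pdmp",
                 params = params),
            class = "bs_hamiltonian")
}

#' WKB Hamiltonian of a diffusion approximation
#'
#' Freidlin–Wentzell Hamiltonian of the Itō diffusion with drift `v` and
#' diffusion `D`, rescaled so its quasi-potential lives on the same
#' `exp(-S0/b)` axis as the PDMP surface: with noise amplitude `1/K` and
#' `b = B/K`, the density `~ exp(-K S̃)` is rewritten as
#' `exp(-S0/b)` with `S0 = B * S̃`, giving
#'
#' \deqn{H = \sum_i v_i p_i + \frac{K D_i}{2B} p_i^2.}
#'
#' @param drift_diffusion a [km_coefficients()] object (or any list with
#'   vectorised `v(x,y)`, `D(x,y)` and scalars `K`, `B`).
#' @return A `bs_hamiltonian` with `kind = "diffusion"`; field `sigma2`
#'   returns the rescaled noise matrix `K D / B`.
#' @export
diffusion_hamiltonian <- function(drift_diffusion) {
  dd <- drift_diffusion
  stopifnot(is.function(dd$v), is.function(dd$D),
            is.numeric(dd$K), is.numeric(dd$B))
  sigma2 <- function(x, y) dd$K * dd$D(x, y) / dd$B
  H <- function(x, y, px, py) {
    v <- dd$v(x, y); s2 <- sigma2(x, y)
    v[, 1] * px + v[, 2] * py + 0.5 * (s2[, 1] * px^2 + s2[, 2] * py^2)
  }
  structure(list(H = H, drift = dd$v, sigma2 = sigma2, b = dd$B / dd$K,
                 kind = "diffusion"),
            class = "bs_hamiltonian")
}

# internal: root of H(x, theta * e) = 0 in theta > 0, vectorised over path
# nodes. X, E are n x 2 matrices (positions, unit directions). Segments
# moving with the deterministic flow (e . v >= 0) cost nothing: theta = 0.
theta_root <- function(ham, X, E, tol = 1e-12) {
  n <- nrow(X)
  v <- ham$drift(X[, 1], X[, 2])
  c1 <- rowSums(E * v)
  theta <- numeric(n)
  act <- which(c1 < -1e-14)
  if (!length(act)) return(theta)
  if (ham$kind == "diffusion") {
    s2 <- ham$sigma2(X[act, 1], X[act, 2])
    c2 <- 0.5 * (s2[, 1] * E[act, 1]^2 + s2[, 2] * E[act, 2]^2)
    theta[act] <- ifelse(c2 > 0, -c1[act] / c2, 0)
    return(theta)
  }
  # PDMP kernel: H is convex in theta, -> +Inf at the admissible edge
  hi <- rep(Inf, length(act))
  for (d in 1:2) {
    pos <- E[act, d] > 0
    hi[pos] <- pmin(hi[pos], (1 - 1e-9) / E[act, d][pos])
  }
  Heval <- function(th) ham$H(X[act, 1], X[act, 2],
                              th * E[act, 1], th * E[act, 2])
  # unbounded directions (both components <= 0): grow until H > 0
  free <- !is.finite(hi)
  if (any(free)) {
    g <- rep(1, sum(free))
    idx <- which(free)
    for (it in 1:60) {
      bad <- ham$H(X[act, 1][idx], X[act, 2][idx],
                   g * E[act, 1][idx], g * E[act, 2][idx]) < 0
      if (!any(bad)) break
      g[bad] <- g[bad] * 2
    }
    hi[free] <- g
  }
  lo <- rep(0, length(act))
  for (it in 1:70) {
    mid <- (lo + hi) / 2
    pos <- Heval(mid) > 0
    hi[pos] <- mid[pos]; lo[!pos] <- mid[!pos]
    if (max(hi - lo) < tol) break
  }
  theta[act] <- (lo + hi) / 2
  theta
}

# internal: per-segment costs theta * len for segments (A_k -> B_k);
# A, B are n x 2 matrices of segment endpoints
seg_cost <- function(ham, A, B) {
  d <- B - A
  len <- sqrt(rowSums(d^2))
  out <- numeric(nrow(A))
  ok <- len > 1e-13
  if (!any(ok)) return(out)
  E <- d[ok, , drop = FALSE] / len[ok]
  mid <- pmax((A[ok, , drop = FALSE] + B[ok, , drop = FALSE]) / 2, 0)
  out[ok] <- theta_root(ham, mid, E) * len[ok]
  out
}

# internal: geometric action of a discrete path (nodes: (M+1) x 2)
path_action <- function(ham, nodes) {
  m <- nrow(nodes)
  sum(seg_cost(ham, nodes[-m, , drop = FALSE], nodes[-1, , drop = FALSE]))
}

# internal: central-difference action gradient w.r.t. the interior nodes.
# Perturbing node k only changes segments k-1 and k, so the full gradient
# costs 8 batched segment sweeps instead of ~4 * path_points action
# evaluations.
path_action_grad <- function(ham, nodes, eps = 1e-6) {
  m <- nrow(nodes)
  A <- nodes[-m, , drop = FALSE]; B <- nodes[-1, , drop = FALSE]
  G <- matrix(0, m, 2)
  for (d in 1:2) {
    for (sgn in c(1, -1)) {
      Ap <- A; Ap[, d] <- Ap[, d] + sgn * eps
      Bp <- B; Bp[, d] <- Bp[, d] + sgn * eps
      cL <- seg_cost(ham, Ap, B)   # left endpoint (node s) perturbed
      cR <- seg_cost(ham, A, Bp)   # right endpoint (node s+1) perturbed
      # node k is left endpoint of segment k and right endpoint of k-1
      contrib <- c(cL, 0) + c(0, cR)
      G[, d] <- G[, d] + sgn * contrib / (2 * eps)
    }
  }
  G[2:(m - 1), , drop = FALSE]
}

# internal: resample a path to equal arc length
reparam_path <- function(nodes) {
  d <- sqrt(rowSums(diff(nodes)^2))
  s <- c(0, cumsum(d))
  if (s[length(s)] < 1e-12) return(nodes)
  su <- seq(0, s[length(s)], length.out = nrow(nodes))
  cbind(stats::approx(s, nodes[, 1], xout = su, ties = "ordered")$y,
        stats::approx(s, nodes[, 2], xout = su, ties = "ordered")$y)
}

#' Quasi-potential by the geometric minimum action method
#'
#' Minimises the geometric (Maupertuis) action associated with a
#' Hamiltonian over reparametrised paths from an attractor to an endpoint:
#' the converged action equals the quasi-potential `S0(endpoint)` relative
#' to the attractor. Momenta are recovered pointwise along the path by a
#' one-dimensional root-find of `H(x, theta * e) = 0` with `e` the local
#' direction of travel, which avoids a Legendre transform of the
#' non-quadratic bursting Hamiltonian (segments moving with the
#' deterministic flow cost nothing). Each outer iteration re-distributes
#' the nodes to equal arc length; the result is deterministic given the
#' initialisation (a straight line by default).
#'
#' @param hamiltonian a [pdmp_hamiltonian()] or [diffusion_hamiltonian()].
#' @param attractor start point `(x, y)`, concentration units; `S0 = 0`
#'   there.
#' @param endpoint target point `(x, y)`.
#' @param path_points number of path nodes (`>= 32`).
#' @param tol stop when the action improves by less than `tol *
#'   max(1, |S0|)` between outer iterations.
#' @param maxit_outer,maxit_inner outer reparametrisation cycles and BFGS
#'   iterations per cycle.
#' @param init_path optional starting path (matrix, `path_points x 2`),
#'   e.g. a warm start from a neighbouring endpoint.
#' @return A list: `S0` (action value), `path` (node matrix), `converged`
#'   (logical; non-convergence returns the best value found, flagged).
#' @examples
#' # 1-species escape against constant production: S0 has the closed form
#' # (x - x*) - x* log(x/x*)
#' @export
minimize_action <- function(hamiltonian, attractor, endpoint,
                            path_points = 128, tol = 1e-6,
                            maxit_outer = 40, maxit_inner = 25,
                            init_path = NULL) {
  stopifnot(inherits(hamiltonian, "bs_hamiltonian"), path_points >= 32)
  a <- as.numeric(attractor); z <- as.numeric(endpoint)
  if (sqrt(sum((a - z)^2)) < 1e-12)
    return(list(S0 = 0, path = rbind(a, z), converged = TRUE))
  nodes <- if (is.null(init_path)) {
    cbind(seq(a[1], z[1], length.out = path_points),
          seq(a[2], z[2], length.out = path_points))
  } else {
    stopifnot(nrow(init_path) == path_points)
    init_path
  }
  act_prev <- path_action(hamiltonian, nodes)
  converged <- FALSE
  for (outer in seq_len(maxit_outer)) {
    nodes <- reparam_path(nodes)
    free <- 2:(path_points - 1)
    fn <- function(par) {
      nd <- nodes
      nd[free, ] <- pmax(matrix(par, ncol = 2), 0)
      path_action(hamiltonian, nd)
    }
    gr <- function(par) {
      nd <- nodes
      nd[free, ] <- pmax(matrix(par, ncol = 2), 0)
      as.numeric(path_action_grad(hamiltonian, nd))
    }
    opt <- stats::optim(as.numeric(nodes[free, ]), fn, gr, method = "BFGS",
                        control = list(maxit = maxit_inner, reltol = 1e-10))
    nodes[free, ] <- pmax(matrix(opt$par, ncol = 2), 0)
    act <- opt$value
    if (abs(act_prev - act) < tol * max(1, abs(act))) {
      act_prev <- act
      converged <- TRUE
      break
    }
    act_prev <- act
  }
  list(S0 = act_prev, path = reparam_path(nodes), converged = converged)
}

#' Quasi-potential surface on a grid
#'
#' Repeated [minimize_action()] calls over a grid of endpoints, each
#' warm-started from the nearest already-computed neighbour's path. Also
#' returns the WKB stationary-distribution estimate `exp(-S0/b)`
#' (normalised over the grid).
#'
#' @inheritParams minimize_action
#' @param xs,ys grid coordinates (concentration units).
#' @param path_points nodes per path (smaller than the single-path default
#'   because the surface loop dominates the cost).
#' @return A list of class `bs_quasipotential`: matrices `S0` (relative to
#'   the attractor, `>= 0`) and `wkb_density`, the grid, the attractor,
#'   and a logical `converged` matrix (non-convergence flags propagate per
#'   grid point).
#' @export
quasipotential_surface <- function(hamiltonian, attractor, xs, ys,
                                   path_points = 48, tol = 1e-5,
                                   maxit_outer = 12, maxit_inner = 15) {
  S0 <- conv <- matrix(NA_real_, length(xs), length(ys))
  paths <- vector("list", length(xs) * length(ys))
  dim(paths) <- c(length(xs), length(ys))
  # visit grid points by increasing distance from the attractor so warm
  # starts are always available inward
  ord <- order(outer(xs, ys, function(x, y)
    (x - attractor[1])^2 + (y - attractor[2])^2))
  for (k in ord) {
    i <- (k - 1) %% length(xs) + 1
    j <- (k - 1) %/% length(xs) + 1
    z <- c(xs[i], ys[j])
    init <- NULL
    done <- which(!is.na(S0), arr.ind = TRUE)
    if (nrow(done)) {
      dd <- (xs[done[, 1]] - z[1])^2 + (ys[done[, 2]] - z[2])^2
      nb <- done[which.min(dd), ]
      prev <- paths[[nb[1], nb[2]]]
      if (!is.null(prev) && nrow(prev) == path_points) {
        w <- seq(0, 1, length.out = path_points)
        shift <- z - prev[nrow(prev), ]
        init <- prev + cbind(w * shift[1], w * shift[2])
        init <- pmax(init, 0)
      }
    }
    res <- minimize_action(hamiltonian, attractor, z,
                           path_points = path_points, tol = tol,
                           maxit_outer = maxit_outer,
                           maxit_inner = maxit_inner, init_path = init)
    S0[i, j] <- res$S0
    conv[i, j] <- res$converged
    paths[[i, j]] <- res$path
  }
  dens <- exp(-S0 / hamiltonian$b)
  structure(list(S0 = S0, wkb_density = dens / sum(dens), xs = xs, ys = ys,
                 attractor = attractor, converged = conv == 1),
            class = "bs_quasipotential")
}
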