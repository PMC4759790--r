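#' Mean first switching time by Monte Carlo
#'
#' Estimates, for every initial condition in a grid inside the half-plane
#' `Ω = {x > y}`, the mean first time at which a sample path reaches (or
#' jumps across) the symmetric boundary: `N_Y >= N_X` for the discrete
#' engines, `y >= x` for the continuous ones. Bursts may overshoot the
#' diagonal, so "reach" is interpreted as reach-or-cross.
#'
#' Paths still inside `Ω` at the horizon `t_cap` are right-censored. When
#' any replicate of a cell is censored, the cell's estimate pools the
#' censored times at `t_cap` and is flagged as a lower bound — censoring is
#' always reported, never silently averaged away.
#'
#' @inheritParams simulate_engine
#' @param initial_grid matrix or data.frame of initial protein states, one
#'   `(NX, NY)` row per cell, in molecules for every engine (continuous
#'   engines convert through `x = N/K`). All rows must satisfy `NX > NY`
#'   strictly.
#' @param n_rep replicates per grid cell (`>= 1`).
#' @param t_cap truncation horizon in cell cycles.
#' @return A data.frame of class `bs_mfst_grid`: columns `x`, `y`
#'   (molecules), `mfst` (cell cycles), `se` (standard error, `NA` when any
#'   replicate was censored), `n_censored`, `lower_bound` (logical).
#' @examples
#' \donttest{
#' p <- preset_params("ecoli_table1")
#' g <- matrix(c(380, 80), nrow = 1)
#' mfst_monte_carlo("PDMP-SN", p, g, n_rep = 20, seed = 1, t_cap = 2000)
#' }
#' @export
mfst_monte_carlo <- function(engine, params, initial_grid, n_rep, seed,
                             t_cap = 2000, dt = 1e-3, mode0 = 0L) {
  engine <- match_engine(engine, params)
  stopifnot(inherits(params, "model_params"), n_rep >= 1, t_cap > 0)
  g <- as.matrix(initial_grid)
  if (ncol(g) < 2) stop("initial_grid needs (NX, NY) columns")
  if (any(g[, 1] <= g[, 2]))
    stop("all initial conditions must lie strictly inside Omega = {x > y}")
  pp <- pack_params(params)
  res <- with_seed(seed, {
    if (engine %in% c("FM", "GB", "CB", "NB")) {
      gi <- cbind(round(g[, 1]), round(g[, 2]), 0, 0)
      cpp_ssa_fpt(discrete_model_code(engine), pp, gi,
                  as.integer(n_rep), t_cap)
    } else if (engine == "DA-GB") {
      cpp_sde_fpt(pp, g[, 1:2, drop = FALSE] / params$K,
                  as.integer(n_rep), t_cap, dt)
    } else if (engine == "PDMP") {
      cpp_pdmp_fpt(pp, g[, 1:2, drop = FALSE] / params$K,
                   as.integer(mode0), as.integer(n_rep), t_cap)
    } else {
      cpp_shotnoise_fpt(pp, g[, 1:2, drop = FALSE] / params$K,
                        as.integer(n_rep), t_cap)
    }
  })
  sums <- res$sums
  ncen <- sums[, 2]
  nhit <- n_rep - ncen
  mfst <- (sums[, 1] + ncen * t_cap) / n_rep
  se <- ifelse(ncen == 0 & nhit > 1,
               sqrt(pmax(0, sums[, 3] / nhit - (sums[, 1] / nhit)^2) /
                      pmax(1, nhit - 1)),
               NA_real_)
  out <- data.frame(x = g[, 1], y = g[, 2], mfst = mfst, se = se,
                    n_censored = as.integer(ncen),
                    lower_bound = ncen > 0)
  structure(out, engine = engine, n_rep = n_rep, t_cap = t_cap,
            seed = seed, class = c("bs_mfst_grid", "data.frame"))
}
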