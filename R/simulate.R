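ENGINE_TAGS <- c("FM", "GB", "CB", "NB", "DA-GB", "PDMP", "PDMP-SN")

discrete_model_code <- function(engine) {
  switch(engine, GB = 0L, CB = 1L, NB = 2L, FM = 3L,
         stop("not a discrete engine: ", engine))
}

match_engine <- function(engine, params = NULL) {
  if (!is.character(engine) || length(engine) != 1 || !(engine %in% ENGINE_TAGS))
    stop("unknown engine '", paste(engine, collapse = ","),
         "'; valid tags: ", paste(ENGINE_TAGS, collapse = ", "))
  if (engine == "CB" && !is.null(params) && params$B != round(params$B))
    stop("the constant-burst engine requires integer B (got ", params$B, ")")
  engine
}

# default initial state: the deterministic high-X attractor
default_initial <- function(engine, params) {
  at <- high_x_attractor(params)
  if (engine %in% c("FM", "GB", "CB", "NB")) round(at) else at / params$K
}

#' Simulate a sample path of one model engine
#'
#' Statistically exact simulation of the chosen model:
#' * `"FM"` — full mRNA + protein Gillespie dynamics;
#' * `"GB"`, `"CB"`, `"NB"` — protein-only Gillespie reductions with
#'   geometric, constant, or no bursts (the NB engine fires single-protein
#'   events at a `B`-fold rate);
#' * `"DA-GB"` — Euler–Maruyama integration of the Kramers–Moyal diffusion
#'   approximation of the GB model (Itō interpretation, reflection at 0);
#' * `"PDMP"` — the three-state piecewise deterministic Markov process with
#'   finite mRNA degradation rate `gamma` (exact, via thinning);
#' * `"PDMP-SN"` — its shot-noise limit: instantaneous exponential
#'   concentration bursts of mean `b = B/K`.
#'
#' @param engine one of `"FM"`, `"GB"`, `"CB"`, `"NB"`, `"DA-GB"`,
#'   `"PDMP"`, `"PDMP-SN"`.
#' @param params a [model_params()] object.
#' @param initial initial state. Discrete engines: protein copy numbers
#'   `(NX, NY)` or `(NX, NY, mX, mY)`. Continuous engines: concentrations
#'   `(x, y)`. Default: the deterministic high-X attractor (mode `ZERO` for
#'   the PDMP).
#' @param t_end run length in cell cycles.
#' @param seed integer seed; identical `(seed, params, initial)` give
#'   identical trajectories.
#' @param dt Euler–Maruyama step (DA-GB only), cell cycles.
#' @param thin record every `thin`-th SDE step (DA-GB only).
#' @param mode0 initial PDMP mode, `0` (no mRNA), `1` (X) or `2` (Y).
#' @param max_events guard against runaway event counts.
#' @return A data.frame of class `bs_trajectory` with the time-stamped
#'   state (columns depend on the engine) and attributes `engine`, `seed`,
#'   `params`.
#' @examples
#' p <- preset_params("ecoli_table1")
#' tr <- simulate_engine("GB", p, t_end = 5, seed = 1)
#' head(tr)
#' @export
simulate_engine <- function(engine, params, initial = NULL, t_end, seed,
                            dt = 1e-3, thin = 10L, mode0 = 0L,
                            max_events = 2e7) {
  engine <- match_engine(engine, params)
  stopifnot(inherits(params, "model_params"), t_end > 0)
  if (is.null(initial)) initial <- default_initial(engine, params)
  if (any(initial < 0)) stop("initial state must be non-negative")
  pp <- pack_params(params)
  m <- with_seed(seed, {
    if (engine %in% c("FM", "GB", "CB", "NB")) {
      ini <- c(initial, 0, 0)[1:4]
      if (engine != "FM" && any(ini[3:4] != 0))
        stop("mRNA counts are structurally zero for the protein-only engines")
      cpp_ssa_trajectory(discrete_model_code(engine), pp, ini, t_end,
                         as.integer(max_events))
    } else if (engine == "DA-GB") {
      cpp_sde_trajectory(pp, initial, t_end, dt, as.integer(thin))
    } else if (engine == "PDMP") {
      cpp_pdmp_trajectory(pp, initial, as.integer(mode0), t_end,
                          as.integer(max_events))
    } else {
      cpp_shotnoise_trajectory(pp, initial, t_end, as.integer(max_events))
    }
  })
  out <- as.data.frame(m)
  if (engine %in% c("GB", "CB", "NB")) out <- out[, c("t", "NX", "NY")]
  structure(out, engine = engine, seed = seed, params = params,
            class = c("bs_trajectory", "data.frame"))
}

#' @export
print.bs_trajectory <- function(x, ...) {
  cat("<bs_trajectory> engine =", attr(x, "engine"),
      " events =", nrow(x) - 1L,
      " t_end =", signif(max(x$t), 6),
      " seed =", attr(x, "seed"), "\n")
  NextMethod()
}

#' Time-weighted stationary histogram of protein numbers
#'
#' Runs one (or several pooled) long simulations and accumulates the
#' time-weighted occupancy of the protein copy-number pair `(NX, NY)` after
#' a burn-in period, normalised to total mass 1. Continuous engines are
#' binned through `N = round(K * x)` so all models share one molecule axis.
#'
#' For the symmetric toggle the stationary law is exactly `(x,y)`-exchange
#' symmetric while single runs mix between basins only on the (long)
#' switching timescale; `symmetrize = TRUE` averages the histogram with its
#' transpose, which is exact in law for symmetric circuits.
#'
#' @inheritParams simulate_engine
#' @param t_burn burn-in discarded before accumulation (cell cycles).
#' @param t_total total simulated time per start (cell cycles).
#' @param initial a vector, or a matrix with one starting state per row;
#'   multiple starts are pooled with equal time weight (each run gets a
#'   sub-stream derived from `seed`).
#' @param nmax histogram axis limit: unit bins `0..nmax` molecules; mass
#'   beyond is clamped into the last bin.
#' @param dt_occ occupancy sampling interval for the deterministic flow of
#'   the PDMP engines (cell cycles).
#' @param symmetrize average with the mirror histogram (see Details).
#' @return A [hist2d()] object. Attribute `meta` carries occupancy time,
#'   production and occupancy integrals (flux diagnostics), and for `"FM"`
#'   the time-averaged mRNA means, and for `"PDMP"` the mode occupancies.
#' @export
stationary_histogram <- function(engine, params, t_burn = 50, t_total,
                                 seed, initial = NULL, nmax = 900,
                                 dt = 1e-3, dt_occ = 0.005, mode0 = 0L,
                                 symmetrize = FALSE) {
  engine <- match_engine(engine, params)
  stopifnot(inherits(params, "model_params"))
  if (t_burn >= t_total) stop("t_burn must be smaller than t_total")
  if (is.null(initial)) initial <- default_initial(engine, params)
  if (is.null(dim(initial))) initial <- matrix(initial, nrow = 1)
  pp <- pack_params(params)
  H <- matrix(0, nmax + 1, nmax + 1)
  meta <- list(time = 0, prodX = 0, prodY = 0, intNX = 0, intNY = 0,
               intmX = 0, intmY = 0, mode_time = c(0, 0, 0))
  for (s in seq_len(nrow(initial))) {
    ini <- initial[s, ]
    res <- with_seed(child_seed(seed, s), {
      if (engine %in% c("FM", "GB", "CB", "NB")) {
        cpp_ssa_histogram(discrete_model_code(engine), pp,
                          c(ini, 0, 0)[1:4], t_burn, t_total, as.integer(nmax))
      } else if (engine == "DA-GB") {
        cpp_sde_histogram(pp, ini, t_burn, t_total, dt, as.integer(nmax))
      } else if (engine == "PDMP") {
        cpp_pdmp_histogram(pp, ini, as.integer(mode0), t_burn, t_total,
                           dt_occ, as.integer(nmax))
      } else {
        cpp_shotnoise_histogram(pp, ini, t_burn, t_total, dt_occ,
                                as.integer(nmax))
      }
    })
    H <- H + res$H
    meta$time <- meta$time + res$time
    K <- params$K
    if (engine %in% c("FM", "GB", "CB", "NB")) {
      meta$prodX <- meta$prodX + res$prodX
      meta$prodY <- meta$prodY + res$prodY
      meta$intNX <- meta$intNX + res$intNX
      meta$intNY <- meta$intNY + res$intNY
      meta$intmX <- meta$intmX + res$intmX
      meta$intmY <- meta$intmY + res$intmY
    } else {
      meta$intNX <- meta$intNX + K * res$intx
      meta$intNY <- meta$intNY + K * res$inty
      if (engine == "PDMP-SN") {
        meta$prodX <- meta$prodX + K * res$prodx
        meta$prodY <- meta$prodY + K * res$prody
      }
      if (engine == "PDMP")
        meta$mode_time <- meta$mode_time + res$mode_time
    }
  }
  if (symmetrize) H <- (H + t(H)) / 2
  h <- hist2d(H, model = engine)
  attr(h, "meta") <- meta
  h
}
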