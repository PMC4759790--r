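#' Two-dimensional protein-number histogram
#'
#' Normalised probability masses on unit molecule bins `0..nmax` for each
#' species; rows index `NX`, columns `NY`. Any non-negative weight matrix is
#' accepted and normalised to total mass 1.
#'
#' @param w non-negative square weight matrix.
#' @param model optional engine tag for provenance.
#' @return An object of class `bs_hist2d`.
#' @export
hist2d <- function(w, model = NA_character_) {
  w <- as.matrix(w)
  stopifnot(nrow(w) == ncol(w), all(w >= 0), sum(w) > 0)
  structure(list(prob = w / sum(w), nmax = nrow(w) - 1L, model = model),
            class = "bs_hist2d")
}

#' @export
print.bs_hist2d <- function(x, ...) {
  mx <- marginal(x, 1); my <- marginal(x, 2)
  cat("<bs_hist2d>", if (!is.na(x$model)) paste0("model = ", x$model),
      " bins 0..", x$nmax,
      sprintf("  E[NX] = %.1f  E[NY] = %.1f\n",
              sum(mx * 0:x$nmax), sum(my * 0:x$nmax)))
  invisible(x)
}

#' Marginal mass function of one species
#' @param h a [hist2d()] object.
#' @param species 1 for `NX` (rows), 2 for `NY`.
#' @return Numeric vector of masses over `0..nmax`.
#' @export
marginal <- function(h, species = 1) {
  stopifnot(inherits(h, "bs_hist2d"))
  if (species == 1) rowSums(h$prob) else colSums(h$prob)
}

#' Jensen–Shannon distance between stationary distributions
#'
#' Square root of the Jensen–Shannon divergence with base-2 logarithms, so
#' the distance lies in `[0, 1]` (0 for identical distributions, 1 for
#' disjoint supports). Zero-mass bins contribute zero (`0 * log 0 = 0`).
#'
#' @param p,q [hist2d()] objects (or bare probability vectors/matrices)
#'   on identical binning.
#' @return Dimensionless distance in `[0, 1]`.
#' @export
js_distance <- function(p, q) {
  if (inherits(p, "bs_hist2d")) p <- p$prob
  if (inherits(q, "bs_hist2d")) q <- q$prob
  if (!identical(dim(p), dim(q)) || length(p) != length(q))
    stop("histograms must share identical binning")
  p <- as.numeric(p) / sum(p); q <- as.numeric(q) / sum(q)
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / m[i]))
  }
  sqrt(pmax(0, (kl(p) + kl(q)) / 2))
}

#' Detect modes of a protein-number histogram
#'
#' Smooths the mass with an isotropic Gaussian kernel, finds local maxima
#' of the smoothed surface exceeding `rel_threshold` times the global
#' maximum, and merges candidates closer than one bandwidth (keeping the
#' highest). Deterministic.
#'
#' @param h a [hist2d()] object.
#' @param smoothing_bw Gaussian standard deviation in molecules.
#' @param rel_threshold minimum height relative to the global smoothed
#'   maximum.
#' @return A list with `n_modes` and a data.frame `modes` of bin
#'   coordinates `(NX, NY)` and smoothed heights, ordered by height.
#' @examples
#' h <- make_fixture("trimodal_hist")$hist
#' count_modes(h, smoothing_bw = 1)$n_modes  # 3
#' @export
count_modes <- function(h, smoothing_bw = 15, rel_threshold = 0.05) {
  stopifnot(inherits(h, "bs_hist2d"), smoothing_bw > 0)
  S <- gauss_smooth(h$prob, smoothing_bw)
  n <- nrow(S)
  # strict interior comparison against the 8-neighbourhood (ties broken by
  # >=, plateau duplicates removed by the merge step)
  pad <- matrix(-Inf, n + 2, n + 2)
  pad[2:(n + 1), 2:(n + 1)] <- S
  is_max <- matrix(TRUE, n, n)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[2:(n + 1) + di, 2:(n + 1) + dj]
    is_max <- is_max & (S >= nb)
  }
  thr <- rel_threshold * max(S)
  idx <- which(is_max & S > thr, arr.ind = TRUE)
  if (!nrow(idx)) return(list(n_modes = 0L, modes = data.frame()))
  cand <- data.frame(NX = idx[, 1] - 1L, NY = idx[, 2] - 1L,
                     height = S[idx])
  cand <- cand[order(-cand$height), ]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1) { keep[1] <- TRUE; next }
    d <- sqrt((cand$NX[i] - cand$NX[keep])^2 + (cand$NY[i] - cand$NY[keep])^2)
    keep[i] <- all(d > smoothing_bw)
  }
  modes <- cand[keep, ]
  rownames(modes) <- NULL
  list(n_modes = nrow(modes), modes = modes)
}

# internal: separable Gaussian smoothing via banded matrix products
gauss_smooth <- function(M, bw) {
  n <- nrow(M)
  half <- max(1L, ceiling(4 * bw))
  off <- -half:half
  k <- exp(-off^2 / (2 * bw^2))
  k <- k / sum(k)
  i <- rep(seq_len(n), each = length(off)) + rep(off, n)
  j <- rep(seq_len(n), each = length(off))
  v <- rep(k, n)
  ok <- i >= 1 & i <= n
  Ksm <- Matrix::sparseMatrix(i = i[ok], j = j[ok], x = v[ok], dims = c(n, n))
  as.matrix(Ksm %*% M %*% Matrix::t(Ksm))
}

#' Compare coarse-grained engines against the full model along a parameter
#' sweep
#'
#' For each sweep value (of the mean burst size `B` or the population scale
#' `K`; `b = B/K` is recomputed per point) the full model's stationary
#' histogram is simulated, then each requested engine is simulated on
#' matched binning: the Jensen–Shannon distance to the FM and the mean
#' first switching time from the high-X attractor are tabulated.
#'
#' @param engines character vector of engine tags (FM is always run as the
#'   reference and need not be listed).
#' @param params baseline [model_params()].
#' @param sweep `"B"` or `"K"`.
#' @param values positive sweep values.
#' @param seed integer; per-point sub-streams are derived from it.
#' @param t_total,t_burn stationary run control (cell cycles).
#' @param n_rep replicates for the MFST estimate.
#' @param t_cap MFST truncation horizon (cell cycles).
#' @param nmax histogram axis limit (molecules).
#' @return A data.frame with one row per (sweep value, engine): columns
#'   `sweep`, `value`, `engine`, `js_to_fm`, `mfst`, `mfst_censored`.
#'   Engine failures at individual sweep points are recorded as `NA` rows
#'   and the sweep continues.
#' @export
sweep_compare <- function(engines, params, sweep = c("B", "K"), values,
                          seed, t_total = 500, t_burn = 50, n_rep = 50,
                          t_cap = 500, nmax = 900) {
  sweep <- match.arg(sweep)
  stopifnot(all(values > 0))
  engines <- vapply(engines, match_engine, character(1))
  rows <- list()
  for (iv in seq_along(values)) {
    pl <- as.list(params)[names(formals(model_params))[
      names(formals(model_params)) %in% names(as.list(params))]]
    pl[[sweep]] <- values[iv]
    pv <- do.call(model_params, pl)
    fm <- stationary_histogram("FM", pv, t_burn = t_burn, t_total = t_total,
                               seed = child_seed(seed, 1000 + iv),
                               nmax = nmax, symmetrize = TRUE)
    for (ie in seq_along(engines)) {
      eng <- engines[ie]
      res <- tryCatch({
        h <- stationary_histogram(eng, pv, t_burn = t_burn,
                                  t_total = t_total,
                                  seed = child_seed(seed, 100 * iv + ie),
                                  nmax = nmax, symmetrize = TRUE)
        at <- high_x_attractor(pv)
        grid <- matrix(at, nrow = 1)
        mf <- mfst_monte_carlo(eng, pv, grid, n_rep = n_rep,
                               seed = child_seed(seed, 7000 + 100 * iv + ie),
                               t_cap = t_cap)
        data.frame(sweep = sweep, value = values[iv], engine = eng,
                   js_to_fm = js_distance(h, fm), mfst = mf$mfst[1],
                   mfst_censored = mf$n_censored[1])
      }, error = function(e) {
        warning("engine ", eng, " failed at ", sweep, " = ", values[iv],
                ": ", conditionMessage(e))
        data.frame(sweep = sweep, value = values[iv], engine = eng,
                   js_to_fm = NA_real_, mfst = NA_real_,
                   mfst_censored = NA_integer_)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
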