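#' Repressive Hill function
#'
#' `f(N) = 1 / (1 + (N/K)^n)`, the fraction of maximal transcription that
#' survives repression by `N` copies of the repressor. Monotone
#' non-increasing, `f(0) = 1`, `f(K) = 1/2`.
#'
#' @param N repressor copy number (vectorised, must be `>= 0`).
#' @param K half-saturation copy number.
#' @param n Hill coefficient (`> 0`), modelling cooperative binding.
#' @return Dimensionless multiplier in `(0, 1]`.
#' @export
hill_repression <- function(N, K, n) {
  if (any(N < 0)) stop("negative copy numbers are not allowed")
  1 / (1 + (N / K)^n)
}

#' Transcription propensity
#'
#' Rate (events per cell cycle) at which transcription of one gene fires,
#' given the current protein copy numbers.
#'
#' For `regulation = "toggle"` the rate is `K * (r0 + r * f(N_other))` with
#' the repressive Hill function `f(N) = 1/(1 + (N/K)^n)`: it is bounded
#' between the basal rate `K*r0` (full repression) and the maximal rate
#' `K*(r0 + r)` (no repressor).
#'
#' For `regulation = "three_way"` the rate is the shifted-Hill product
#' `q0 * (1 + r1/(1 + (N_self/K1)^n1)) * (1 + r2/(1 + (N_other/K2)^n2))`:
#' the negative `r1` makes the first factor increase with the gene's own
#' protein (positive autoregulation) while the positive `r2` makes the
#' second factor decrease with the competing protein (repression). The rate
#' is finite and strictly positive on the whole non-negative quadrant, with
#' infimum `q0 * (1 + r1)` and supremum `q0 * (1 + r2)`.
#'
#' @param params a [model_params()] object.
#' @param N_other copy number of the competing (repressing) protein.
#' @param N_self copy number of the gene's own protein (used only by the
#'   three-way form).
#' @return Transcription rate in 1/cell cycle (vectorised over inputs).
#' @examples
#' p <- preset_params("ecoli_table1")
#' transcription_propensity(p, N_other = 0)    # K*(r0 + r) = 13.333...
#' transcription_propensity(p, N_other = p$K)  # K*(r0 + r/2)
#' @export
transcription_propensity <- function(params, N_other, N_self = 0) {
  stopifnot(inherits(params, "model_params"))
  if (any(N_other < 0) || any(N_self < 0))
    stop("negative copy numbers are not allowed")
  if (params$regulation == "toggle") {
    params$K * (params$r0 + params$r * hill_repression(N_other, params$K, params$n))
  } else {
    h1 <- 1 / (1 + (N_self / params$K1)^params$n1)
    h2 <- 1 / (1 + (N_other / params$K2)^params$n2)
    params$q0 * (1 + params$r1 * h1) * (1 + params$r2 * h2)
  }
}

#' Draw protein burst sizes
#'
#' Burst sizes for the protein-only engines: geometric on `{0, 1, 2, ...}`
#' with mean `B` (the number of proteins a single mRNA produces before it
#' degrades, `P(k) = B^k / (1+B)^(k+1)`), or the constant `B` used by the
#' constant-burst reduction.
#'
#' @param kind `"geometric"` or `"constant"`.
#' @param B mean burst size (`> 0`; an integer for `kind = "constant"`).
#' @param n number of draws.
#' @return Integer vector of burst sizes.
#' @examples
#' set.seed(1)
#' mean(sample_burst("geometric", B = 30, n = 1e4))  # ~ 30
#' @export
sample_burst <- function(kind = c("geometric", "constant"), B, n = 1) {
  kind <- match.arg(kind)
  stopifnot(B > 0, n >= 1)
  if (kind == "geometric") {
    stats::rgeom(n, prob = 1 / (1 + B))
  } else {
    if (B != round(B)) stop("constant bursts require integer B")
    rep.int(as.integer(B), n)
  }
}
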