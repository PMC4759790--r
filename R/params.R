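#' Model parameters for the toggle / three-way switch
#'
#' Single source of truth for the rate constants shared by every engine
#' (full model, protein-only reductions, diffusion approximation, PDMP and
#' its shot-noise limit). Time is measured in cell cycles, protein and mRNA
#' abundances in molecules.
#'
#' @param B mean burst size: average number of proteins one mRNA produces
#'   during its lifetime (molecules).
#' @param gamma mRNA degradation rate (1/cell cycle). Must be much larger
#'   than `gamma0` for the burst-limit engines (GB, shot-noise PDMP) to be
#'   meaningful; a warning is issued when `gamma/gamma0 < 10`.
#' @param gamma0 protein degradation rate (1/cell cycle).
#' @param r maximum suppressed transcription rate (1/cell cycle); the
#'   maximal transcription rate of the toggle is `K*(r0 + r)`.
#' @param r0 basal transcription rate (1/cell cycle); the minimal
#'   transcription rate is `K*r0`.
#' @param K typical protein population scale (molecules). Concentrations
#'   used by the continuous engines are `x = N/K`.
#' @param n Hill coefficient of the repressive regulation (dimensionless).
#' @param regulation `"toggle"` for the mutually repressing two-gene switch
#'   or `"three_way"` for the self-activating toggle whose deterministic
#'   limit has three stable states.
#' @param q0,r1,r2,n1,n2,K1,K2 parameters of the three-way regulation
#'   function (ignored for `regulation = "toggle"`): `q0` sets the overall
#'   transcription rate scale (1/cell cycle), the shifted Hill factor
#'   `1 + r1/(1+(N_self/K1)^n1)` encodes self-activation (negative `r1`),
#'   and `1 + r2/(1+(N_other/K2)^n2)` encodes cross-repression
#'   (positive `r2`).
#'
#' @return An object of class `model_params`.
#'
#' @details The derived mean burst size in concentration units,
#' `b = B/K`, is computed in exactly one place ([burst_scale()]); for the
#' packaged `"ecoli_table1"` preset it equals 0.15.
#'
#' The `"ecoli_table1"` preset carries literature estimates for *E. coli*:
#' `B = 30`, `gamma = 30`, `gamma0 = 1`, `r = 6/100`, `r0 = 1/150`,
#' `K = 200`, `n = 3`. (One source normalises rates by a burst size of 39
#' molecules rather than 30; the preset follows the tabulated `B = 30`.)
#'
#' @seealso [preset_params()], [transcription_propensity()], [burst_scale()]
#' @examples
#' p <- preset_params("ecoli_table1")
#' burst_scale(p)  # 0.15
#' @export
model_params <- function(B = 30, gamma = 30, gamma0 = 1, r = 6 / 100,
                         r0 = 1 / 150, K = 200, n = 3,
                         regulation = c("toggle", "three_way"),
                         q0 = 4, r1 = -4 / 5, r2 = 7 / 3,
                         n1 = 3, n2 = 1, K1 = 160, K2 = 320) {
  regulation <- match.arg(regulation)
  stopifnot(B > 0, gamma > 0, gamma0 > 0, r >= 0, r0 >= 0, K > 0, n > 0)
  if (regulation == "three_way") {
    stopifnot(q0 > 0, n1 > 0, n2 > 0, K1 > 0, K2 > 0)
    if (1 + r1 <= 0 || 1 + r2 <= 0)
      stop("three-way regulation requires 1 + r1 > 0 and 1 + r2 > 0 so the rate stays strictly positive")
  }
  if (gamma / gamma0 < 10)
    warning("gamma/gamma0 = ", signif(gamma / gamma0, 3),
            " < 10: the burst-limit engines assume fast mRNA degradation")
  structure(
    list(B = as.numeric(B), gamma = as.numeric(gamma),
         gamma0 = as.numeric(gamma0), r = as.numeric(r),
         r0 = as.numeric(r0), K = as.numeric(K), n = as.numeric(n),
         regulation = regulation,
         q0 = as.numeric(q0), r1 = as.numeric(r1), r2 = as.numeric(r2),
         n1 = as.numeric(n1), n2 = as.numeric(n2), K1 = as.numeric(K1),
         K2 = as.numeric(K2)),
    class = "model_params")
}

#' Packaged parameter presets
#'
#' @param name `"ecoli_table1"` (literature *E. coli* toggle estimates) or
#'   `"lu_threeway"` (the three-way switch: same rate constants with the
#'   regulation replaced by the shifted-Hill product with `q0 = 4`,
#'   `r1 = -4/5`, `r2 = 7/3`, `n1 = 3`, `n2 = 1`, `K1 = 160`, `K2 = 320`).
#' @return A [model_params()] object.
#' @export
preset_params <- function(name = c("ecoli_table1", "lu_threeway")) {
  name <- match.arg(name)
  switch(name,
    ecoli_table1 = model_params(),
    lu_threeway = model_params(regulation = "three_way"))
}

#' Mean burst size in concentration units
#'
#' The derived quantity `b = B/K`, the mean protein-concentration increment
#' per burst. This is the sole place where `b` is computed.
#'
#' @param params a [model_params()] object.
#' @return `B/K` (dimensionless concentration).
#' @export
burst_scale <- function(params) {
  stopifnot(inherits(params, "model_params"))
  params$B / params$K
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> regulation =", x$regulation, "\n")
  cat(sprintf("  B = %g, gamma = %g, gamma0 = %g, r = %g, r0 = %g, K = %g, n = %g\n",
              x$B, x$gamma, x$gamma0, x$r, x$r0, x$K, x$n))
  cat(sprintf("  b = B/K = %g\n", burst_scale(x)))
  if (x$regulation == "three_way")
    cat(sprintf("  q0 = %g, r1 = %g, r2 = %g, n1 = %g, n2 = %g, K1 = %g, K2 = %g\n",
                x$q0, x$r1, x$r2, x$n1, x$n2, x$K1, x$K2))
  invisible(x)
}

#' Read model parameters from a JSON or YAML config file
#'
#' Keys match the argument names of [model_params()]; a key `preset` may
#' name a packaged preset, with the remaining keys applied as overrides.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A [model_params()] object.
#' @export
read_params <- function(path) {
  cfg <- read_config(path)
  params_from_list(cfg)
}

params_from_list <- function(cfg) {
  base <- if (!is.null(cfg$preset)) as.list(preset_params(cfg$preset)) else list()
  cfg$preset <- NULL
  # numeric fields may arrive as full-precision strings (see params_to_json)
  cfg <- lapply(cfg, function(v)
    if (is.character(v) && !anyNA(suppressWarnings(as.numeric(v))))
      as.numeric(v) else v)
  keep <- names(formals(model_params))
  base[names(cfg)] <- cfg
  base <- base[intersect(names(base), keep)]
  do.call(model_params, base)
}

# internal: parse a JSON/YAML file into a plain list
read_config <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::yaml.load_file(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

# internal: flatten params for the C++ engines.
# Layout (doubles): B, gamma, gamma0, r, r0, K, n, regtype(0/1),
#                   q0, r1, r2, n1, n2, K1, K2
pack_params <- function(params) {
  stopifnot(inherits(params, "model_params"))
  c(params$B, params$gamma, params$gamma0, params$r, params$r0, params$K,
    params$n, if (params$regulation == "toggle") 0 else 1,
    params$q0, params$r1, params$r2, params$n1, params$n2,
    params$K1, params$K2)
}

# internal: exact upper bound for the transcription propensity
# (sup over the non-negative quadrant); used as thinning majorant.
propensity_sup <- function(params) {
  if (params$regulation == "toggle") {
    params$K * (params$r0 + params$r)
  } else {
    params$q0 * max(1, 1 + params$r1) * max(1, 1 + params$r2)
  }
}

# internal: derive a child seed from a base seed and stream index,
# keeping the result strictly inside the 32-bit signed range.
child_seed <- function(seed, i) {
  (as.double(seed) * 48271 + 1103515245 * as.double(i)) %% 2147483629
}

# internal: evaluate expr with a local RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
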