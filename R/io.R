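fmt_num <- function(x) {
  # full-precision text so files round-trip bit-exactly
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

write_header <- function(con, fields) {
  for (nm in names(fields))
    writeLines(paste0("# ", nm, ": ", fields[[nm]]), con)
}

read_header <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  out <- list()
  for (l in hdr) {
    m <- regmatches(l, regexec("^# ([^:]+): (.*)$", l))[[1]]
    if (length(m) == 3) out[[m[2]]] <- m[3]
  }
  out
}

params_to_json <- function(params) {
  # numerics as %.17g strings: decimal JSON round-trips bit-exactly
  jsonlite::toJSON(lapply(unclass(params), function(v)
    if (is.numeric(v)) fmt_num(v) else v), auto_unbox = TRUE)
}

params_from_json <- function(txt) {
  params_from_list(jsonlite::fromJSON(txt))
}

#' Write / read a trajectory as tab-separated text
#'
#' Plain-text interchange format: commented header lines carrying the
#' engine tag, seed and full parameter set (JSON), followed by
#' tab-separated state columns. Files round-trip through [read_trajectory()]
#' with full equality.
#'
#' @param tr a `bs_trajectory` from [simulate_engine()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(tr, path) {
  stopifnot(inherits(tr, "bs_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, list(engine = attr(tr, "engine"),
                         seed = fmt_num(attr(tr, "seed")),
                         params = params_to_json(attr(tr, "params")),
                         columns = paste(names(tr), collapse = "\t")))
  body <- do.call(paste, c(lapply(as.data.frame(tr), fmt_num), sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  hdr <- read_header(path)
  cols <- strsplit(hdr$columns, "\t")[[1]]
  d <- utils::read.table(path, sep = "\t", comment.char = "#",
                         col.names = cols,
                         colClasses = rep("numeric", length(cols)))
  structure(d, engine = hdr$engine, seed = as.numeric(hdr$seed),
            params = params_from_json(hdr$params),
            class = c("bs_trajectory", "data.frame"))
}

#' Write / read a stationary histogram as tab-separated text
#'
#' Sparse triplet format `(NX_bin, NY_bin, probability)` with a commented
#' header; zero-mass bins are omitted.
#'
#' @param h a [hist2d()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(h, path) {
  stopifnot(inherits(h, "bs_hist2d"))
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, list(model = h$model, nmax = h$nmax,
                         columns = "NX_bin\tNY_bin\tprobability"))
  nz <- which(h$prob > 0, arr.ind = TRUE)
  writeLines(paste(nz[, 1] - 1L, nz[, 2] - 1L,
                   fmt_num(h$prob[nz]), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_histogram
#' @export
read_histogram <- function(path) {
  hdr <- read_header(path)
  nmax <- as.integer(hdr$nmax)
  d <- utils::read.table(path, sep = "\t", comment.char = "#",
                         col.names = c("i", "j", "p"))
  w <- matrix(0, nmax + 1, nmax + 1)
  w[cbind(d$i + 1L, d$j + 1L)] <- d$p
  hist2d(w, model = hdr$model)
}

#' Write / read an MFST grid as tab-separated text
#'
#' Columns `(x, y, value, stderr_or_nan)` plus censoring counts.
#'
#' @param g a `bs_mfst_grid` from [mfst_monte_carlo()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mfst_grid <- function(g, path) {
  stopifnot(inherits(g, "bs_mfst_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, list(engine = attr(g, "engine"),
                         n_rep = attr(g, "n_rep"),
                         t_cap = fmt_num(attr(g, "t_cap")),
                         seed = fmt_num(attr(g, "seed")),
                         columns = "x\ty\tvalue\tstderr_or_nan\tn_censored"))
  writeLines(paste(fmt_num(g$x), fmt_num(g$y), fmt_num(g$mfst),
                   fmt_num(g$se), g$n_censored, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_mfst_grid
#' @export
read_mfst_grid <- function(path) {
  hdr <- read_header(path)
  d <- utils::read.table(path, sep = "\t", comment.char = "#",
                         col.names = c("x", "y", "mfst", "se", "n_censored"),
                         colClasses = c(rep("numeric", 4), "integer"))
  d$lower_bound <- d$n_censored > 0
  structure(d, engine = hdr$engine, n_rep = as.integer(hdr$n_rep),
            t_cap = as.numeric(hdr$t_cap), seed = as.numeric(hdr$seed),
            class = c("bs_mfst_grid", "data.frame"))
}
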