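# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Linear (open) convolution of two mass distributions
#'
#' Index 1 corresponds to mass shift 0.  Used for combining isotope
#' distributions and for EMU condensation products; vectors are short
#' (< 10 entries) so a direct loop beats FFT-based `convolve()`.
#' @noRd
conv_mass <- function(x, y) {
  nx <- length(x); ny <- length(y)
  out <- numeric(nx + ny - 1L)
  for (i in seq_len(nx)) {
    idx <- i:(i + ny - 1L)
    out[idx] <- out[idx] + x[i] * y
  }
  out
}

#' Convolve a list of mass distributions, truncating at `nmax` shifts
#' @noRd
conv_mass_list <- function(dists, nmax = Inf) {
  out <- 1
  for (d in dists) {
    out <- conv_mass(out, d)
    if (length(out) > nmax + 1L) out <- out[seq_len(nmax + 1L)]
  }
  out
}

stop_tcf <- function(..., class = "tcellflux_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Evaluate an expression with a locally fixed RNG seed
#'
#' Restores the caller's `.Random.seed` on exit so library code never
#' disturbs the user's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# stable number formatting for serialized model/result files
fmt_num <- function(x) {
  s <- formatC(x, format = "g", digits = 15)
  gsub("\\s+", "", s)
}
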