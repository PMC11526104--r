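#' Natural isotope abundances used for MID correction
#'
#' Standard IUPAC terrestrial abundances for the elements occurring in
#' MOX-TBDMS derivatized fragments.  Each element maps to a numeric
#' vector of mass-shift probabilities; index 1 is shift 0 (the
#' monoisotopic species), index 2 a +1 shift, and so on.  Phosphorus is
#' monoisotopic.  Values can be overridden by supplying a modified list
#' to [correction_matrix()].
#'
#' @return Named list of per-element mass-shift distributions.
#' @export
#' @examples
#' default_isotope_abundances()$C
default_isotope_abundances <- function() {
  list(
    C  = c(1 - 0.0107, 0.0107),
    H  = c(1 - 0.000115, 0.000115),
    N  = c(1 - 0.00364, 0.00364),
    O  = c(1 - 0.00038 - 0.00205, 0.00038, 0.00205),
    Si = c(1 - 0.04685 - 0.03092, 0.04685, 0.03092),
    S  = c(1 - 0.0075 - 0.0425, 0.0075, 0.0425),
    P  = 1
  )
}

#' Parse an elemental formula string such as "C11H26NO2Si2"
#'
#' @param formula character scalar; element symbols with optional counts.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  toks <- toks[nzchar(toks)]
  if (!nzchar(formula) || sum(nchar(toks)) != nchar(formula))
    stop_tcf("cannot parse formula: ", formula)
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(ifelse(grepl("[0-9]$", toks),
                          sub("^[A-Za-z]+", "", toks), "1"))
  counts <- tapply(ct, el, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Natural-abundance mass distribution of a set of atoms
#'
#' Convolves the per-element isotope distributions of `counts` atoms,
#' truncated at mass shift `nmax`.
#'
#' @param counts named integer vector (element -> atom count).
#' @param abundances per-element distributions, see
#'   [default_isotope_abundances()].
#' @param nmax highest retained mass shift.
#' @return numeric vector of length `nmax + 1`.
#' @export
natural_mass_dist <- function(counts, abundances = default_isotope_abundances(),
                              nmax = 8L) {
  dists <- list()
  for (el in names(counts)) {
    n <- counts[[el]]
    if (n == 0L) next
    d <- abundances[[el]]
    if (is.null(d)) stop_tcf("no abundance entry for element ", el)
    if (any(d < 0)) stop_tcf("negative abundance for element ", el)
    if (abs(sum(d) - 1) > 1e-9)
      stop_tcf("abundances for ", el, " do not sum to 1")
    for (i in seq_len(n)) dists[[length(dists) + 1L]] <- d
  }
  out <- conv_mass_list(dists, nmax = nmax)
  length(out) <- nmax + 1L
  out[is.na(out)] <- 0
  out
}
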