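#' Tracer specification
#'
#' Describes the labeled substrate mixture.  The default is the
#' [U-13C]glucose design used for activated T cells: 15 mM uniformly
#' labeled tracer added to medium already containing 5 mM unlabeled
#' glucose, i.e. a 0.75 / 0.25 mixture, with 99% per-atom isotopic
#' purity of the labeled positions.
#'
#' Simulation happens in "tracer-atom space": natural 13C abundance of
#' unlabeled material is not part of the tracer model and is handled by
#' the measurement-correction step instead.
#'
#' @param metabolite tracer metabolite id (default "GLC.x")
#' @param n_carbons number of carbons of the tracer metabolite
#' @param mixture list of components, each `list(pattern, fraction)`;
#'   `pattern` is a 0/1 vector over the tracer carbons (1 = 13C
#'   labeled position)
#' @param purity per-atom probability that a nominally labeled position
#'   actually carries 13C, in (0, 1]
#' @return an `nm_tracer`
#' @export
#' @examples
#' tr <- tracer_spec()            # 75% [U-13C]glucose
#' tracer_emu_mid(tr, 1:3)        # MID of glucose carbons 1..3
tracer_spec <- function(metabolite = "GLC.x", n_carbons = 6L,
                        mixture = list(
                          list(pattern = rep(1L, n_carbons), fraction = 0.75),
                          list(pattern = rep(0L, n_carbons), fraction = 0.25)),
                        purity = 0.99) {
  fr <- vapply(mixture, `[[`, 0, "fraction")
  if (abs(sum(fr) - 1) > 1e-9)
    stop_tcf("tracer mixture fractions must sum to 1")
  if (purity <= 0 || purity > 1) stop_tcf("purity must lie in (0, 1]")
  for (cmp in mixture)
    if (length(cmp$pattern) != n_carbons || !all(cmp$pattern %in% 0:1))
      stop_tcf("tracer pattern must be a 0/1 vector over ", n_carbons,
               " carbons")
  structure(list(metabolite = metabolite, n_carbons = as.integer(n_carbons),
                 mixture = mixture, purity = purity),
            class = "nm_tracer")
}

#' MID of a tracer EMU (subset of tracer carbons)
#' @param tracer an `nm_tracer`
#' @param atoms 1-based carbon indices
#' @return numeric vector M0..M|atoms|
#' @export
tracer_emu_mid <- function(tracer, atoms) {
  n <- length(atoms)
  out <- numeric(n + 1L)
  p <- tracer$purity
  for (cmp in tracer$mixture) {
    k <- sum(cmp$pattern[atoms])
    # k labeled positions, each 13C with probability = purity
    d <- if (k == 0L) 1 else stats::dbinom(0:k, k, p)
    mid <- numeric(n + 1L)
    mid[seq_along(d)] <- d
    out <- out + cmp$fraction * mid
  }
  out
}

#' Full isotopomer distribution of the tracer metabolite
#'
#' Probability of each of the 2^n labeling patterns (bit i of the
#' pattern index = carbon i labeled).  Used by the brute-force oracle.
#' @param tracer an `nm_tracer`
#' @param n number of carbons (defaults to the tracer's)
#' @return numeric vector of length `2^n`
#' @export
tracer_isotopomer_dist <- function(tracer, n = tracer$n_carbons) {
  out <- numeric(2^n)
  p <- tracer$purity
  for (cmp in tracer$mixture) {
    probs <- rep(1, 2^n)
    for (i in seq_len(n)) {
      bit <- bitwAnd(seq_len(2^n) - 1L, bitwShiftL(1L, i - 1L)) > 0L
      pi1 <- if (cmp$pattern[i] == 1L) p else 0
      probs <- probs * ifelse(bit, pi1, 1 - pi1)
    }
    out <- out + cmp$fraction * probs
  }
  out
}
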