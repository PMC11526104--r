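# flux-carrying reactions: everything except the flux-free
# extraction-mixing and measurement-pool pseudo-reactions
is_flux_reaction <- function(r) !(r$kind %in% c("mixing", "measurement-pool"))

#' Stoichiometric matrix over balanced metabolites
#'
#' Rows are the balanced metabolites, columns the flux-carrying
#' reactions (mixing pseudo-reactions are excluded: extraction mixing
#' happens after quenching and carries no metabolic flux), both sorted
#' by id.  Entry (i, j) is the net stoichiometric coefficient of
#' metabolite i in reaction j.
#'
#' @param model an `nm_model`
#' @return numeric matrix with dimnames (metabolite id, reaction id)
#' @export
stoichiometric_matrix <- function(model) {
  mets <- sort(model$metabolites$id[model$metabolites$balanced])
  rxns <- sort(names(model$reactions)[
    vapply(model$reactions, is_flux_reaction, TRUE)])
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (id in rxns) {
    r <- model$reactions[[id]]
    for (t in r$lhs) if (t$species %in% mets)
      S[t$species, id] <- S[t$species, id] - t$coef
    for (t in r$rhs) if (t$species %in% mets)
      S[t$species, id] <- S[t$species, id] + t$coef
  }
  S
}

#' Free-flux parameterization of the flux null space
#'
#' Row-reduces S and designates the non-pivot columns as free fluxes.
#' Any assignment x of the free fluxes extends to a full net-flux
#' vector v = N x with S v = 0; the map is deterministic for a given
#' model (columns are scanned in sorted id order).
#'
#' @param model an `nm_model`
#' @param pinned named numeric vector of reaction fluxes held at fixed
#'   values (e.g. biomass drains assumed from growth requirements);
#'   names not present in the model are ignored
#' @param tol pivot tolerance for row reduction
#' @return list with `free` (reaction ids of the free fluxes), `N`
#'   (reactions x free basis matrix, rownames = sorted reaction ids),
#'   `v0` (particular solution honouring the pinned fluxes; zero when
#'   nothing is pinned), and `rank`.  Any net-flux vector is
#'   `v0 + N %*% x`.
#' @export
free_flux_basis <- function(model, pinned = numeric(0), tol = 1e-10) {
  S <- stoichiometric_matrix(model)
  pinned <- pinned[names(pinned) %in% colnames(S)]
  E <- matrix(0, length(pinned), ncol(S))
  if (length(pinned))
    E[cbind(seq_along(pinned), match(names(pinned), colnames(S)))] <- 1
  A <- rbind(S, E)
  b <- c(numeric(nrow(S)), unname(pinned))
  m <- nrow(A); n <- ncol(A)
  pivots <- integer(0)
  row <- 1L
  scale_ref <- max(1, max(abs(A)))
  for (col in seq_len(n)) {
    if (row > m) break
    piv <- which.max(abs(A[row:m, col])) + row - 1L
    if (abs(A[piv, col]) <= tol * scale_ref) next
    if (piv != row) {
      A[c(row, piv), ] <- A[c(piv, row), ]
      b[c(row, piv)] <- b[c(piv, row)]
    }
    b[row] <- b[row] / A[row, col]
    A[row, ] <- A[row, ] / A[row, col]
    others <- setdiff(seq_len(m), row)
    b[others] <- b[others] - A[others, col] * b[row]
    A[others, ] <- A[others, ] - outer(A[others, col], A[row, ])
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  if (row <= m && any(abs(b[row:m]) > 1e-8))
    stop_tcf("pinned fluxes are inconsistent with the balance constraints")
  free <- setdiff(seq_len(n), pivots)
  if (length(free) == 0L)
    stop_tcf("no degrees of freedom: the flux null space is empty")
  N <- matrix(0, n, length(free),
              dimnames = list(colnames(S), colnames(S)[free]))
  N[free, ] <- diag(length(free))
  v0 <- stats::setNames(numeric(n), colnames(S))
  for (i in seq_along(pivots)) {
    N[pivots[i], ] <- -A[i, free]
    v0[pivots[i]] <- b[i]
  }
  if (max(abs(S %*% N)) > 1e-8 || max(abs(S %*% v0)) > 1e-8)
    stop_tcf("internal error: null-space basis inaccurate")
  list(free = colnames(S)[free], N = N, v0 = v0, rank = length(pivots))
}

#' Construct and validate a flux state
#'
#' A flux state carries net fluxes for every flux-carrying reaction,
#' exchange (bidirectional) fluxes for the reversible ones, and a
#' mixing fraction per `.obs` measurement pool (the cytosolic share,
#' i.e. the weight of the first reactant of the mixing reaction).
#' Units are nmol per 1e6 cells per hour throughout.
#'
#' @param model an `nm_model`
#' @param net named numeric vector of net fluxes (reaction id -> value);
#'   reactions not named default to 0.
#' @param exchange named numeric vector of exchange fluxes (>= 0) for
#'   reversible reactions; missing entries default to 0.
#' @param mixing named numeric vector in `[0, 1]`, names are chemical
#'   species of the measurement pools (e.g. "PYR"); missing default 0.5.
#' @param tol tolerance for the steady-state balance check
#' @return an `nm_fluxstate`
#' @export
flux_state <- function(model, net, exchange = numeric(0),
                       mixing = numeric(0), tol = 1e-6) {
  S <- stoichiometric_matrix(model)
  rxns <- colnames(S)
  v <- stats::setNames(numeric(length(rxns)), rxns)
  unknown <- setdiff(names(net), rxns)
  if (length(unknown))
    stop_tcf("net flux for unknown reaction(s): ",
             paste(unknown, collapse = ", "))
  v[names(net)] <- net
  rev_ids <- sort(names(model$reactions)[vapply(
    model$reactions, function(r) r$reversible && is_flux_reaction(r), TRUE)])
  ex <- stats::setNames(numeric(length(rev_ids)), rev_ids)
  if (length(exchange)) {
    unknown <- setdiff(names(exchange), rev_ids)
    if (length(unknown))
      stop_tcf("exchange flux for irreversible/unknown reaction(s): ",
               paste(unknown, collapse = ", "))
    ex[names(exchange)] <- exchange
  }
  if (any(ex < 0)) stop_tcf("exchange fluxes must be >= 0")
  mix_species <- sort(species_of(
    model$metabolites$id[model$metabolites$compartment == "observation"]))
  mx <- stats::setNames(rep(0.5, length(mix_species)), mix_species)
  if (length(mixing)) {
    unknown <- setdiff(names(mixing), mix_species)
    if (length(unknown))
      stop_tcf("mixing fraction for unknown measurement pool(s): ",
               paste(unknown, collapse = ", "))
    mx[names(mixing)] <- mixing
  }
  if (any(mx < 0 | mx > 1)) stop_tcf("mixing fractions must lie in [0, 1]")
  resid <- max(abs(S %*% v))
  if (resid > tol)
    stop_tcf("flux state violates steady-state balance: max |S v| = ",
             signif(resid, 3))
  irrev <- setdiff(rxns, rev_ids)
  if (any(v[irrev] < -tol))
    stop_tcf("negative net flux on irreversible reaction(s): ",
             paste(irrev[v[irrev] < -tol], collapse = ", "))
  structure(list(net = v, exchange = ex, mixing = mx),
            class = "nm_fluxstate")
}

#' Forward/backward decomposition of a flux state
#'
#' forward = exchange + max(net, 0), backward = exchange + max(-net, 0)
#' for reversible reactions; forward = net (floored at `floor`) and
#' backward = 0 for irreversible ones.
#'
#' @param model an `nm_model`
#' @param flux an `nm_fluxstate`
#' @param floor lower bound applied to forward fluxes so EMU level
#'   systems stay nonsingular
#' @return list of named vectors `fwd` and `bwd`
#' @export
flux_directions <- function(model, flux, floor = 1e-9) {
  v <- flux$net
  fwd <- pmax(v, 0)
  bwd <- pmax(-v, 0)
  ex <- pmax(flux$exchange, floor)  # exchange floor avoids singular levels
  fwd[names(ex)] <- fwd[names(ex)] + ex
  bwd[names(ex)] <- bwd[names(ex)] + ex
  irrev <- setdiff(names(v), names(ex))
  bwd[irrev] <- 0
  fwd <- pmax(fwd, floor)
  list(fwd = fwd, bwd = bwd)
}

#' @export
print.nm_fluxstate <- function(x, ...) {
  cat(sprintf("<nm_fluxstate> %d net fluxes, %d exchange, %d mixing\n",
              length(x$net), length(x$exchange), length(x$mixing)))
  invisible(x)
}
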