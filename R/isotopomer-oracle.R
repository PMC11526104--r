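#' Brute-force full-isotopomer simulation (verification oracle)
#'
#' Solves the complete isotopomer balance equations of a model by
#' iterated direct linear solves: all single-substrate transitions are
#' kept in one sparse linear operator, while condensation terms
#' (bilinear in the unknowns) are re-evaluated from the previous
#' iterate until the fixed point is reached.  This is exponentially
#' more expensive than the EMU route (2^n unknowns per metabolite) and
#' exists purely as an independent check of [simulate_mids()].
#'
#' @param model an `nm_model`
#' @param flux an `nm_fluxstate`
#' @param tracer an `nm_tracer`
#' @param floor flux floor matching the EMU simulator
#' @param tol fixed-point convergence tolerance (max abs change)
#' @param max_iter iteration cap
#' @return named list metabolite -> MID vector (balanced metabolites
#'   and `.obs` pools).  The full isotopomer vectors are attached as
#'   attribute `"isotopomers"` for subset marginalization.
#' @export
brute_force_isotopomer_mids <- function(model, flux, tracer, floor = 1e-9,
                                        tol = 1e-13, max_iter = 2000L) {
  md <- model$metabolites
  bal_ids <- md$id[md$balanced]
  ncb <- stats::setNames(md$n_carbons, md$id)
  if (sum(2^ncb[bal_ids]) > 2^20)
    stop_tcf("isotopomer enumeration guard exceeded (sum 2^n > 2^20)")
  offs <- c(0, cumsum(2^ncb[bal_ids]))
  names(offs) <- c(bal_ids, "_end")
  ntot <- offs[["_end"]]
  idx_of <- function(met, s) offs[[met]] + s + 1L

  input_dist <- function(met) {
    n <- ncb[[met]]
    if (met == tracer$metabolite) tracer_isotopomer_dist(tracer, n)
    else c(1, numeric(2^n - 1L))
  }

  dirs <- reaction_dirs(model)
  vd <- dir_fluxes(structure(list(
    dir_rxn = vapply(dirs, `[[`, "", "rxn"),
    dir_dir = vapply(dirs, `[[`, "", "dir")), class = "nm_emusystem"),
    flux, floor)

  # consumption totals per balanced metabolite
  cons <- stats::setNames(numeric(length(bal_ids)), bal_ids)
  for (di in seq_along(dirs)) {
    d <- dirs[[di]]
    sd <- dir_sides(model$reactions[[d$rxn]], d$dir)
    for (t in sd$from) if (t$species %in% bal_ids)
      cons[t$species] <- cons[t$species] + vd[di]
  }

  A <- matrix(0, ntot, ntot)     # linear (single-substrate) transitions
  bconst <- numeric(ntot)
  cond_terms <- list()           # bilinear terms, re-evaluated per iteration

  for (di in seq_along(dirs)) {
    d <- dirs[[di]]
    rxn <- model$reactions[[d$rxn]]
    sd <- dir_sides(rxn, d$dir)
    k <- reaction_variants(rxn)
    for (occ in seq_along(sd$to)) {
      pmet <- sd$to[[occ]]$species
      if (!pmet %in% bal_ids) next
      np <- ncb[[pmet]]
      for (v in seq_len(k)) {
        pa <- strsplit(atoms_of(sd$to[[occ]], v), "")[[1]]
        srcs <- list()
        for (t in sd$from) {
          ra <- strsplit(atoms_of(t, v), "")[[1]]
          pos <- which(ra %in% pa)
          if (length(pos))
            srcs[[length(srcs) + 1L]] <- list(
              met = t$species, n = ncb[[t$species]],
              # product carbon indices receiving each source carbon
              to = match(ra, pa))
        }
        w <- vd[di] / k
        if (length(srcs) == 1L) {
          s <- srcs[[1]]
          sidx <- 0:(2^s$n - 1L)
          tgt <- integer(2^s$n)
          for (j in seq_len(s$n)) {
            bit <- bitwAnd(sidx, bitwShiftL(1L, j - 1L)) > 0L
            if (!is.na(s$to[j]))
              tgt[bit] <- tgt[bit] + bitwShiftL(1L, s$to[j] - 1L)
          }
          if (s$met %in% bal_ids) {
            cells <- cbind(idx_of(pmet, tgt), idx_of(s$met, sidx))
            for (r in seq_len(nrow(cells)))
              A[cells[r, 1], cells[r, 2]] <- A[cells[r, 1], cells[r, 2]] + w
          } else {
            xin <- input_dist(s$met)
            acc <- rowsum(w * xin, tgt)
            bconst[idx_of(pmet, as.integer(rownames(acc)))] <-
              bconst[idx_of(pmet, as.integer(rownames(acc)))] + acc[, 1]
          }
        } else if (length(srcs) == 2L) {
          s1 <- srcs[[1]]; s2 <- srcs[[2]]
          map_tgt <- function(s) {
            sidx <- 0:(2^s$n - 1L)
            tgt <- integer(2^s$n)
            for (j in seq_len(s$n)) {
              bit <- bitwAnd(sidx, bitwShiftL(1L, j - 1L)) > 0L
              if (!is.na(s$to[j]))
                tgt[bit] <- tgt[bit] + bitwShiftL(1L, s$to[j] - 1L)
            }
            tgt
          }
          cond_terms[[length(cond_terms) + 1L]] <- list(
            pmet = pmet, w = w, s1 = s1, s2 = s2,
            t1 = map_tgt(s1), t2 = map_tgt(s2))
        } else {
          stop_tcf("more than two atom-mapped reactants in ", rxn$id)
        }
      }
    }
  }

  Mlin <- diag(rep(cons, 2^ncb[bal_ids])) - A
  lu <- tryCatch(solve(Mlin), error = function(e)
    stop_tcf("singular isotopomer balance system"))

  get_block <- function(x, met) x[(offs[[met]] + 1L):(offs[[met]] + 2^ncb[[met]])]
  eval_cond <- function(x) {
    b <- numeric(ntot)
    for (ct in cond_terms) {
      x1 <- if (ct$s1$met %in% bal_ids) get_block(x, ct$s1$met)
            else input_dist(ct$s1$met)
      x2 <- if (ct$s2$met %in% bal_ids) get_block(x, ct$s2$met)
            else input_dist(ct$s2$met)
      # target index = OR of the two mapped patterns (disjoint bits);
      # rowsum accumulates duplicates (carbons lost to co-products)
      tgt <- as.vector(outer(ct$t1, ct$t2, `+`))
      acc <- rowsum(ct$w * as.vector(outer(x1, x2)), tgt)
      ii <- idx_of(ct$pmet, as.integer(rownames(acc)))
      b[ii] <- b[ii] + acc[, 1]
    }
    b
  }

  x <- rep(0, ntot)
  # start every pool unlabeled
  for (met in bal_ids) x[idx_of(met, 0L)] <- 1
  delta <- Inf
  for (it in seq_len(max_iter)) {
    xn <- as.vector(lu %*% (bconst + eval_cond(x)))
    # the physical solution is normalized per metabolite; renormalizing
    # every sweep keeps the iteration away from the spurious
    # mass-deficient roots of the bilinear system
    for (met in bal_ids) {
      ii <- (offs[[met]] + 1L):(offs[[met]] + 2^ncb[[met]])
      s <- sum(xn[ii])
      if (s > 0) xn[ii] <- xn[ii] / s
    }
    delta <- max(abs(xn - x))
    x <- xn
    if (delta < tol) break
  }
  if (delta >= tol)
    warning("isotopomer fixed point not fully converged: delta = ",
            signif(delta, 3))
  resid <- max(abs(Mlin %*% x - (bconst + eval_cond(x))))
  if (resid > 1e-8 * max(1, max(abs(vd))))
    warning("isotopomer balance residual ", signif(resid, 3))

  iso <- new.env(parent = emptyenv())
  out <- list()
  for (met in bal_ids) {
    xb <- get_block(x, met)
    iso[[met]] <- xb
    out[[met]] <- mid_from_isotopomers(xb, seq_len(ncb[[met]]))
  }
  for (r in model$reactions) {
    if (r$kind == "measurement-pool") {
      obs <- r$rhs[[1]]$species
      p1 <- r$lhs[[1]]$species
      out[[obs]] <- out[[p1]]
      iso[[obs]] <- iso[[p1]]
    } else if (r$kind == "mixing") {
      obs <- r$rhs[[1]]$species
      f <- flux$mixing[[species_of(obs)]]
      p1 <- r$lhs[[1]]$species; p2 <- r$lhs[[2]]$species
      out[[obs]] <- f * out[[p1]] + (1 - f) * out[[p2]]
      iso[[obs]] <- f * iso[[p1]] + (1 - f) * iso[[p2]]
    }
  }
  attr(out, "isotopomers") <- iso
  out
}

#' Marginalize an isotopomer vector to the MID of an atom subset
#' @param x isotopomer fraction vector of length 2^n
#' @param atoms 1-based carbon indices to keep
#' @return numeric vector M0..M|atoms|
#' @export
mid_from_isotopomers <- function(x, atoms) {
  n <- round(log2(length(x)))
  sidx <- 0:(length(x) - 1L)
  kk <- integer(length(x))
  for (a in atoms)
    kk <- kk + (bitwAnd(sidx, bitwShiftL(1L, a - 1L)) > 0L)
  as.vector(rowsum(x, kk))
}

#' MID of an arbitrary EMU from an oracle result
#' @param oracle result of [brute_force_isotopomer_mids()]
#' @param met metabolite id
#' @param atoms carbon subset
#' @export
oracle_emu_mid <- function(oracle, met, atoms) {
  iso <- attr(oracle, "isotopomers")
  if (is.null(iso[[met]])) stop_tcf("no isotopomer vector for ", met)
  mid_from_isotopomers(iso[[met]], atoms)
}
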