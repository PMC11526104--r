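#' @title EMU decomposition and steady-state MID simulation
#'
#' @description
#' The simulator uses the elementary metabolite unit (EMU)
#' decomposition: for every measured fragment it derives the minimal
#' set of carbon-atom subsets whose mass distributions must be
#' balanced, groups them by subset size, and solves one linear system
#' per size level.  Condensation reactions couple a level to products
#' of smaller EMUs (convolution of their MIDs), so levels are solved in
#' ascending size order.  Extraction-mixing pools (`.obs`) are formed
#' after the solve as f * cytosolic + (1 - f) * mitochondrial MID.
#'
#' @name emu-engine
NULL

emu_key <- function(met, atoms) paste0(met, "[", paste(atoms, collapse = ","), "]")

#' Define an EMU (metabolite + carbon subset)
#' @param met metabolite id
#' @param atoms sorted 1-based carbon indices
#' @return list with class `nm_emu`
#' @export
emu <- function(met, atoms) {
  atoms <- sort(as.integer(atoms))
  if (length(atoms) == 0L || anyDuplicated(atoms) || any(atoms < 1L))
    stop_tcf("EMU atom subset must be non-empty unique positive indices")
  structure(list(met = met, atoms = atoms, key = emu_key(met, atoms)),
            class = "nm_emu")
}

# directions of flux-carrying reactions, in deterministic order
reaction_dirs <- function(model) {
  ids <- sort(names(model$reactions)[
    vapply(model$reactions, is_flux_reaction, TRUE)])
  out <- list()
  for (id in ids) {
    out[[length(out) + 1L]] <- list(rxn = id, dir = "f")
    if (model$reactions[[id]]$reversible)
      out[[length(out) + 1L]] <- list(rxn = id, dir = "b")
  }
  out
}

# reactant/product term lists of one reaction direction
dir_sides <- function(rxn, dir) {
  if (dir == "f") list(from = rxn$lhs, to = rxn$rhs)
  else list(from = rxn$rhs, to = rxn$lhs)
}

# trace EMU atoms of `met` across one (reaction, direction, variant):
# returns list of source EMUs (met, atoms), one per contributing
# reactant occurrence
trace_sources <- function(rxn, dir, variant, met, atoms) {
  sd <- dir_sides(rxn, dir)
  out <- list()
  for (occ in which(vapply(sd$to, `[[`, "", "species") == met)) {
    pa <- strsplit(atoms_of(sd$to[[occ]], variant), "")[[1]]
    letters_needed <- pa[atoms]
    srcs <- list()
    for (t in sd$from) {
      ra <- strsplit(atoms_of(t, variant), "")[[1]]
      pos <- which(ra %in% letters_needed)
      if (length(pos))
        srcs[[length(srcs) + 1L]] <- list(met = t$species, atoms = sort(pos))
    }
    if (sum(vapply(srcs, function(s) length(s$atoms), 0L)) != length(atoms))
      stop_tcf("atom bookkeeping failure in reaction ", rxn$id)
    out[[length(out) + 1L]] <- srcs
  }
  out
}

#' EMU decomposition of a model for a set of target EMUs
#'
#' @param model an `nm_model`
#' @param targets list of [emu()] objects (or `list(met, atoms)` pairs).
#'   Targets on `.obs` pools are expanded through their mixing reaction.
#' @return an `nm_emusystem` ready for [simulate_mids()]
#' @export
emu_decompose <- function(model, targets) {
  md <- model$metabolites
  nc <- stats::setNames(md$n_carbons, md$id)
  bal <- stats::setNames(md$balanced, md$id)
  dirs <- reaction_dirs(model)
  dir_keys <- vapply(dirs, function(d) paste0(d$rxn, "|", d$dir), "")

  # expand .obs targets through mixing reactions
  combos <- list()
  work <- list()
  for (tg in targets) {
    if (!tg$met %in% md$id) stop_tcf("unknown target metabolite ", tg$met)
    if (any(tg$atoms > nc[[tg$met]]))
      stop_tcf("target atoms out of range for ", tg$met)
    pool_rxn <- NULL
    for (r in model$reactions)
      if (r$kind %in% c("mixing", "measurement-pool") &&
          r$rhs[[1]]$species == tg$met) pool_rxn <- r
    if (!is.null(pool_rxn)) {
      pa <- strsplit(pool_rxn$rhs[[1]]$atoms[1], "")[[1]]
      pools <- lapply(pool_rxn$lhs, function(t) {
        ra <- strsplit(t$atoms[1], "")[[1]]
        list(met = t$species, atoms = sort(match(pa[tg$atoms], ra)))
      })
      if (pool_rxn$kind == "mixing") {
        combos[[emu_key(tg$met, tg$atoms)]] <- list(
          species = species_of(tg$met),
          cyt = emu_key(pools[[1]]$met, pools[[1]]$atoms),
          mit = emu_key(pools[[2]]$met, pools[[2]]$atoms))
      } else {
        combos[[emu_key(tg$met, tg$atoms)]] <- list(
          single = TRUE,
          parent = emu_key(pools[[1]]$met, pools[[1]]$atoms))
      }
      work <- c(work, pools)
    } else if (compartment_of(tg$met) == "observation") {
      stop_tcf("no mixing reaction produces ", tg$met)
    } else {
      work <- c(work, list(list(met = tg$met, atoms = sort(tg$atoms))))
    }
  }

  unknowns <- list()   # key -> list(met, atoms, terms)
  inputs <- list()     # key -> list(met, atoms)
  queue <- work
  while (length(queue)) {
    e <- queue[[1]]; queue <- queue[-1]
    key <- emu_key(e$met, e$atoms)
    if (!is.null(unknowns[[key]]) || !is.null(inputs[[key]])) next
    if (!bal[[e$met]]) { inputs[[key]] <- e; next }
    terms <- list()
    for (di in seq_along(dirs)) {
      d <- dirs[[di]]
      rxn <- model$reactions[[d$rxn]]
      sd <- dir_sides(rxn, d$dir)
      if (!e$met %in% vapply(sd$to, `[[`, "", "species")) next
      k <- reaction_variants(rxn)
      for (v in seq_len(k)) {
        for (srcs in trace_sources(rxn, d$dir, v, e$met, e$atoms)) {
          if (length(srcs) > 2L)
            stop_tcf("condensations with more than two reactant EMUs are",
                     " not supported (reaction ", rxn$id, ")")
          terms[[length(terms) + 1L]] <- list(
            dir = di, w = 1 / k, sources = srcs)
          for (s in srcs) queue <- c(queue, list(s))
        }
      }
    }
    if (!length(terms))
      stop_tcf("EMU ", key, " has no producing reactions; atoms are",
               " untraceable to the tracer")
    # consumption directions of the host metabolite
    cons <- integer(0)
    for (di in seq_along(dirs)) {
      d <- dirs[[di]]
      sd <- dir_sides(model$reactions[[d$rxn]], d$dir)
      cons <- c(cons, rep(di, sum(
        vapply(sd$from, `[[`, "", "species") == e$met)))
    }
    unknowns[[key]] <- list(met = e$met, atoms = e$atoms,
                            terms = terms, cons = cons)
  }

  # organize by level (EMU size), ascending
  sizes <- vapply(unknowns, function(u) length(u$atoms), 0L)
  levels <- list()
  for (k in sort(unique(sizes))) {
    keys <- sort(names(unknowns)[sizes == k])
    idx <- stats::setNames(seq_along(keys), keys)
    ti <- tj <- tdir <- integer(0); tw <- numeric(0)       # matrix terms
    bi <- bdir <- bsrc <- integer(0); bw <- numeric(0)     # RHS terms
    knowns <- list(); kidx <- character(0)
    add_known <- function(spec) {
      id <- spec$id
      if (!id %in% kidx) {
        knowns[[length(knowns) + 1L]] <<- spec
        kidx[length(kidx) + 1L] <<- id
      }
      match(id, kidx)
    }
    for (key in keys) {
      u <- unknowns[[key]]
      i <- idx[[key]]
      # diagonal: total consumption of the host metabolite
      ti <- c(ti, rep(i, length(u$cons))); tj <- c(tj, rep(i, length(u$cons)))
      tdir <- c(tdir, u$cons); tw <- c(tw, rep(1, length(u$cons)))
      for (tm in u$terms) {
        srcs <- tm$sources
        if (length(srcs) == 1L) {
          sk <- emu_key(srcs[[1]]$met, srcs[[1]]$atoms)
          if (!is.null(unknowns[[sk]])) {
            stopifnot(length(srcs[[1]]$atoms) == k)  # same level
            ti <- c(ti, i); tj <- c(tj, idx[[sk]])
            tdir <- c(tdir, tm$dir); tw <- c(tw, -tm$w)
          } else {
            l <- add_known(list(id = sk, kind = "input",
                                met = srcs[[1]]$met, atoms = srcs[[1]]$atoms))
            bi <- c(bi, i); bdir <- c(bdir, tm$dir)
            bw <- c(bw, tm$w); bsrc <- c(bsrc, l)
          }
        } else {
          k1 <- emu_key(srcs[[1]]$met, srcs[[1]]$atoms)
          k2 <- emu_key(srcs[[2]]$met, srcs[[2]]$atoms)
          l <- add_known(list(id = paste(k1, "x", k2), kind = "conv",
                              parts = c(k1, k2),
                              part_specs = srcs))
          bi <- c(bi, i); bdir <- c(bdir, tm$dir)
          bw <- c(bw, tm$w); bsrc <- c(bsrc, l)
        }
      }
    }
    levels[[as.character(k)]] <- list(
      size = k, keys = keys,
      ti = ti, tj = tj, tdir = tdir, tw = tw,
      bi = bi, bdir = bdir, bw = bw, bsrc = bsrc,
      knowns = knowns)
  }

  # ---- precompile flux-to-matrix maps for the C++ level solver ----
  ndir <- length(dirs)
  where <- list()                       # key -> c(level position, row)
  for (lp in seq_along(levels))
    for (r in seq_along(levels[[lp]]$keys))
      where[[levels[[lp]]$keys[r]]] <- c(lp, r)
  for (lp in seq_along(levels)) {
    lev <- levels[[lp]]
    n <- length(lev$keys)
    # aggregate duplicate (cell, direction) matrix contributions
    tcell_all <- (lev$tj - 1L) * n + (lev$ti - 1L)     # 0-based col-major
    ucell <- sort(unique(tcell_all))
    Tmat <- matrix(0, length(ucell), ndir)
    rowidx <- match(tcell_all, ucell)
    for (q in seq_along(tcell_all))
      Tmat[rowidx[q], lev$tdir[q]] <- Tmat[rowidx[q], lev$tdir[q]] + lev$tw[q]
    nk <- length(lev$knowns)
    if (length(lev$bi)) {
      bcell_all <- (lev$bsrc - 1L) * n + (lev$bi - 1L)
      ubcell <- sort(unique(bcell_all))
      Bmat <- matrix(0, length(ubcell), ndir)
      rowidx <- match(bcell_all, ubcell)
      for (q in seq_along(bcell_all))
        Bmat[rowidx[q], lev$bdir[q]] <- Bmat[rowidx[q], lev$bdir[q]] + lev$bw[q]
    } else {
      ubcell <- integer(0); Bmat <- matrix(0, 0, ndir)
    }
    ktype <- integer(nk)
    p1lev <- p1row <- p2lev <- p2row <- rep(-1L, nk)
    pspec1 <- pspec2 <- vector("list", nk)
    for (kk in seq_len(nk)) {
      kn <- lev$knowns[[kk]]
      if (kn$kind == "conv") {
        ktype[kk] <- 1L
        for (side in 1:2) {
          s <- kn$part_specs[[side]]
          skey <- emu_key(s$met, s$atoms)
          loc <- where[[skey]]
          if (!is.null(loc)) {
            if (side == 1L) { p1lev[kk] <- loc[1] - 1L; p1row[kk] <- loc[2] - 1L }
            else            { p2lev[kk] <- loc[1] - 1L; p2row[kk] <- loc[2] - 1L }
          } else {
            if (side == 1L) pspec1[[kk]] <- s else pspec2[[kk]] <- s
          }
        }
      }
    }
    levels[[lp]]$compiled <- list(
      n = n, size = lev$size, tcell = as.integer(ucell), Tmat = Tmat,
      bcell = as.integer(ubcell), Bmat = Bmat, nk = nk, ktype = ktype,
      p1lev = p1lev, p1row = p1row, p2lev = p2lev, p2row = p2row,
      pspec1 = pspec1, pspec2 = pspec2,
      input_specs = lapply(lev$knowns, function(kn)
        if (kn$kind == "input") kn else NULL))
  }

  dir_rxn <- vapply(dirs, `[[`, "", "rxn")
  rxn_ids <- sort(unique(dir_rxn))
  rev_ids <- sort(names(model$reactions)[vapply(
    model$reactions, function(r) r$reversible && r$kind != "mixing", TRUE)])
  structure(list(
    levels = levels, combos = combos, where = where,
    targets = vapply(targets, `[[`, "", "key"),
    dir_rxn = dir_rxn,
    dir_dir = vapply(dirs, `[[`, "", "dir"),
    dir_keys = dir_keys,
    # integer maps for the fast flux-to-direction path
    dir_is_f = vapply(dirs, `[[`, "", "dir") == "f",
    dir_net_idx = match(dir_rxn, rxn_ids),
    rev_in_net = match(rev_ids, rxn_ids),
    n_unknown = length(unknowns)),
    class = "nm_emusystem")
}

#' Bind a tracer to an EMU system for repeated fast simulation
#'
#' Computes the tracer-dependent fixed inputs once; the result can be
#' passed to [simulate_prepared()] inside optimization loops.
#' @param system an `nm_emusystem`
#' @param tracer an `nm_tracer`
#' @return an opaque prepared-system list
#' @export
emu_prepare <- function(system, tracer) {
  input_mid <- function(met, atoms) {
    if (met == tracer$metabolite) tracer_emu_mid(tracer, atoms)
    else c(1, numeric(length(atoms)))
  }
  clist <- vector("list", length(system$levels))
  for (lp in seq_along(system$levels)) {
    cc <- system$levels[[lp]]$compiled
    kfixed <- matrix(0, cc$nk, cc$size + 1L)
    pfix1 <- pfix2 <- vector("list", max(cc$nk, 1L))
    for (kk in seq_len(cc$nk)) {
      if (cc$ktype[kk] == 0L) {
        sp <- cc$input_specs[[kk]]
        kfixed[kk, ] <- input_mid(sp$met, sp$atoms)
      } else {
        if (!is.null(cc$pspec1[[kk]]))
          pfix1[[kk]] <- input_mid(cc$pspec1[[kk]]$met, cc$pspec1[[kk]]$atoms)
        if (!is.null(cc$pspec2[[kk]]))
          pfix2[[kk]] <- input_mid(cc$pspec2[[kk]]$met, cc$pspec2[[kk]]$atoms)
      }
    }
    clist[[lp]] <- list(
      n = cc$n, size = cc$size, tcell = cc$tcell, Tmat = cc$Tmat,
      bcell = cc$bcell, Bmat = cc$Bmat, nk = cc$nk, ktype = cc$ktype,
      kfixed = kfixed, p1lev = cc$p1lev, p1row = cc$p1row,
      p2lev = cc$p2lev, p2row = cc$p2row, pfix1 = pfix1, pfix2 = pfix2)
  }
  # precompute how each target is read back out of the level solutions
  mix_specs <- Filter(function(cb) is.null(cb$single), system$combos)
  mix_names <- sort(unique(vapply(mix_specs, `[[`, "", "species")))
  key_len <- function(key) {
    spec <- regmatches(key, regexec("^(.*)\\[(.*)\\]$", key))[[1]]
    length(strsplit(spec[3], ",")[[1]]) + 1L
  }
  out_specs <- lapply(system$targets, function(key) {
    len <- key_len(key)
    if (!is.null(system$combos[[key]]) &&
        isTRUE(system$combos[[key]]$single)) {
      loc <- system$where[[system$combos[[key]]$parent]]
      list(kind = 1L, len = len, l1 = loc[1] - 1L, r1 = loc[2] - 1L)
    } else if (!is.null(system$combos[[key]])) {
      cb <- system$combos[[key]]
      l1 <- system$where[[cb$cyt]]; l2 <- system$where[[cb$mit]]
      list(kind = 2L, len = len, mixidx = match(cb$species, mix_names) - 1L,
           l1 = l1[1] - 1L, r1 = l1[2] - 1L, l2 = l2[1] - 1L, r2 = l2[2] - 1L)
    } else if (!is.null(system$where[[key]])) {
      loc <- system$where[[key]]
      list(kind = 1L, len = len, l1 = loc[1] - 1L, r1 = loc[2] - 1L)
    } else {
      spec <- regmatches(key, regexec("^(.*)\\[(.*)\\]$", key))[[1]]
      atoms <- as.integer(strsplit(spec[3], ",")[[1]])
      fixed <- if (spec[2] == tracer$metabolite)
        tracer_emu_mid(tracer, atoms)
      else c(1, numeric(length(atoms)))
      list(kind = 0L, len = len, fixed = fixed)
    }
  })
  lens <- vapply(out_specs, `[[`, 0L, "len")
  ptr <- emu_build_cpp(clist, out_specs)
  list(ptr = ptr, system = system, tracer = tracer,
       mix_names = mix_names, lens = lens,
       starts = cumsum(c(0L, lens[-length(lens)])) + 1L)
}

#' Simulate MIDs with a prepared system (fast path)
#' @param prep result of [emu_prepare()]
#' @param flux an `nm_fluxstate`
#' @param floor flux floor
#' @return named list target key -> MID vector
#' @export
simulate_prepared <- function(prep, flux, floor = 1e-9) {
  flat <- simulate_concat(prep, flux, floor)
  out <- stats::setNames(vector("list", length(prep$lens)),
                         prep$system$targets)
  for (q in seq_along(prep$lens))
    out[[q]] <- flat[prep$starts[q]:(prep$starts[q] + prep$lens[q] - 1L)]
  out
}

# concatenated target MIDs, the fitter's inner loop
simulate_concat <- function(prep, flux, floor = 1e-9) {
  system <- prep$system
  net <- flux$net
  fwd <- pmax(net, 0); bwd <- pmax(-net, 0)
  ex <- pmax(flux$exchange, floor)
  ri <- system$rev_in_net
  fwd[ri] <- fwd[ri] + ex; bwd[ri] <- bwd[ri] + ex
  fwd <- pmax(fwd, floor)
  vdir <- numeric(length(system$dir_net_idx))
  isf <- system$dir_is_f
  vdir[isf] <- fwd[system$dir_net_idx[isf]]
  vdir[!isf] <- bwd[system$dir_net_idx[!isf]]
  mixv <- if (length(prep$mix_names))
    as.numeric(flux$mixing[prep$mix_names]) else numeric(0)
  emu_run_cpp(prep$ptr, vdir, mixv)
}

#' @export
print.nm_emusystem <- function(x, ...) {
  cat(sprintf("<nm_emusystem> %d EMUs in %d levels, %d targets\n",
              x$n_unknown, length(x$levels), length(x$targets)))
  invisible(x)
}

# effective per-direction fluxes for a flux state
dir_fluxes <- function(system, flux, floor = 1e-9) {
  v <- flux$net
  ex <- pmax(flux$exchange, floor)
  fwd <- pmax(v, 0); bwd <- pmax(-v, 0)
  fwd[names(ex)] <- fwd[names(ex)] + ex
  bwd[names(ex)] <- bwd[names(ex)] + ex
  fwd <- pmax(fwd, floor)
  ifelse(system$dir_dir == "f", fwd[system$dir_rxn], bwd[system$dir_rxn])
}

#' Simulate steady-state MIDs of the system's target EMUs
#'
#' @param system an `nm_emusystem` from [emu_decompose()]
#' @param flux an `nm_fluxstate`
#' @param tracer an `nm_tracer`
#' @param floor exchange/forward flux floor guarding against singular
#'   level systems
#' @return named list, target EMU key -> MID vector (sums to 1)
#' @export
simulate_mids <- function(system, flux, tracer, floor = 1e-9) {
  simulate_prepared(emu_prepare(system, tracer), flux, floor)
}
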