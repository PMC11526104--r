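# Small fixture networks built in code.  All are valid models in the
# package dialect; carbon counts stay small enough for the brute-force
# isotopomer oracle.

chain_model <- function() parse_model(c(
  "metabolite A.x carbons=2 balanced=no",
  "metabolite B.c carbons=2 balanced=yes",
  "metabolite C.c carbons=2 balanced=yes",
  "metabolite C.x carbons=2 balanced=no",
  "tracer A.x",
  "v1: A.x (ab) -> B.c (ab)",
  "v2: B.c (ab) -> C.c (ba) reversible",
  "v3: C.c (ab) -> C.x (ab)"))

chain3_model <- function() parse_model(c(
  "metabolite A.x carbons=3 balanced=no",
  "metabolite B.c carbons=3 balanced=yes",
  "metabolite C.c carbons=3 balanced=yes",
  "metabolite D.x carbons=3 balanced=no",
  "tracer A.x",
  "v1: A.x (abc) -> B.c (abc)",
  "v2: B.c (abc) -> C.c (abc)",
  "v3: C.c (abc) -> D.x (abc)"))

diamond_model <- function() parse_model(c(
  "metabolite A.x carbons=1 balanced=no",
  "metabolite B.c carbons=1 balanced=yes",
  "metabolite C.c carbons=1 balanced=yes",
  "metabolite D.x carbons=1 balanced=no",
  "tracer A.x",
  "v1: A.x (a) -> B.c (a)",
  "v2: A.x (a) -> C.c (a)",
  "v3: B.c (a) -> D.x (a)",
  "v4: C.c (a) -> D.x (a)"))

condensation_model <- function() parse_model(c(
  "metabolite A.x carbons=2 balanced=no",
  "metabolite B.x carbons=1 balanced=no",
  "metabolite C.c carbons=3 balanced=yes",
  "metabolite C.x carbons=3 balanced=no",
  "tracer A.x",
  "vc: A.x (ab) + B.x (c) -> C.c (abc)",
  "vo: C.c (abc) -> C.x (abc)"))

self_condensation_model <- function() parse_model(c(
  "metabolite A.x carbons=2 balanced=no",
  "metabolite C.c carbons=4 balanced=yes",
  "metabolite C.x carbons=4 balanced=no",
  "tracer A.x",
  "vc: A.x (ab) + A.x (cd) -> C.c (abcd)",
  "vo: C.c (abcd) -> C.x (abcd)"))

# condensation cycle with CO2-like single carbon and a reversible,
# carbon-rotating split -- a miniature TCA
cycle_model <- function() parse_model(c(
  "metabolite S.x carbons=2 balanced=no",
  "metabolite A.c carbons=2 balanced=yes",
  "metabolite C.c carbons=1 balanced=yes",
  "metabolite T.c carbons=3 balanced=yes",
  "metabolite W.x carbons=2 balanced=no",
  "tracer S.x",
  "v1: S.x (ab) -> A.c (ab)",
  "v2: A.c (ab) + C.c (c) -> T.c (abc)",
  "v3: T.c (abc) -> A.c (bc) + C.c (a) reversible",
  "v4: A.c (ab) -> W.x (ab)"))

cycle_flux <- function(model = cycle_model()) {
  flux_state(model, c(v1 = 1, v2 = 2, v3 = 2, v4 = 1), c(v3 = 0.5))
}

# random valid flux state for any model (free fluxes scaled by `scale`).
# If a draw violates irreversibility it is blended toward the feasible
# `base` state just far enough to restore nonnegative forward fluxes.
random_flux_state <- function(model, scale = 100, ex_scale = 50,
                              base = NULL) {
  fb <- free_flux_basis(model)
  rev_ids <- sort(names(model$reactions)[vapply(
    model$reactions, function(r) r$reversible && r$kind != "mixing", TRUE)])
  for (try in 1:50) {
    x <- stats::runif(length(fb$free), 0.05, 1) * scale
    v <- as.vector(fb$N %*% x)
    names(v) <- rownames(fb$N)
    irrev <- setdiff(names(v), rev_ids)
    if (all(v[irrev] > 0)) break
  }
  if (!all(v[irrev] > 0)) {
    stopifnot(!is.null(base))
    vb <- base$net[names(v)]
    d <- v - vb
    # largest t in (0, 1] keeping irreversible fluxes >= 2% of base
    tmax <- 1
    for (id in irrev) {
      if (d[id] < 0) tmax <- min(tmax, (0.02 * vb[id] - vb[id]) / d[id])
    }
    v <- vb + max(min(tmax, 1), 0) * d
  }
  ex <- stats::setNames(stats::rlnorm(length(rev_ids), log(ex_scale), 1),
                        rev_ids)
  mix_sp <- sort(species_of(model$metabolites$id[
    model$metabolites$compartment == "observation"]))
  mx <- stats::setNames(stats::runif(length(mix_sp)), mix_sp)
  structure(list(net = v, exchange = ex, mixing = mx),
            class = "nm_fluxstate")
}

# all-full-skeleton EMU targets of the balanced + observation pools
all_targets <- function(model) {
  ids <- model$metabolites$id[model$metabolites$balanced |
                                model$metabolites$compartment == "observation"]
  lapply(ids, function(id) emu(id, seq_len(n_carbons_of(model, id))))
}

# compare EMU simulation against the brute-force oracle
max_oracle_dev <- function(model, flux, tracer, targets = all_targets(model)) {
  sys <- emu_decompose(model, targets)
  mids <- simulate_mids(sys, flux, tracer)
  orc <- brute_force_isotopomer_mids(model, flux, tracer)
  max(vapply(names(mids), function(k) {
    sp <- regmatches(k, regexec("^(.*)\\[(.*)\\]$", k))[[1]]
    atoms <- as.integer(strsplit(sp[3], ",")[[1]])
    full <- seq_len(n_carbons_of(model, sp[2]))
    ref <- if (identical(atoms, full)) orc[[sp[2]]]
           else oracle_emu_mid(orc, sp[2], atoms)
    max(abs(mids[[k]] - ref))
  }, 0))
}

skeleton_mid <- function(n) {
  x <- stats::runif(n + 1)
  x / sum(x)
}

# exact integer rank by Bareiss fraction-free Gaussian elimination --
# an oracle independent of floating-point row reduction
bareiss_rank <- function(S) {
  A <- matrix(as.numeric(S), nrow(S), ncol(S))
  stopifnot(all(A == round(A)))
  n <- nrow(A); m <- ncol(A)
  prev <- 1; r <- 0L; row <- 1L
  for (col in seq_len(m)) {
    if (row > n) break
    piv <- which(A[row:n, col] != 0)
    if (!length(piv)) next
    piv <- piv[1] + row - 1L
    if (piv != row) A[c(row, piv), ] <- A[c(piv, row), ]
    for (i in setdiff(seq_len(n), row)) {
      A[i, ] <- (A[i, ] * A[row, col] - A[row, ] * A[i, col]) / prev
    }
    prev <- A[row, col]
    r <- r + 1L; row <- row + 1L
  }
  r
}
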