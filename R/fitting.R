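#' @title Flux estimation by variance-weighted least squares
#'
#' @description
#' Fluxes are estimated by minimizing the sum of squared
#' variance-weighted residuals between simulated and measured fragment
#' MIDs (one redundant mass fraction dropped per normalized MID block)
#' and between predicted and measured exchange rates.  The search is
#' parameterized by the free net fluxes of the stoichiometric null
#' space, compactified exchange fluxes u = vex/(vex + c), and the
#' extraction mixing fractions; it is repeated from many random start
#' points and the lowest-SSR solution is kept.  A two-sided chi-square
#' test at the stated degrees of freedom judges goodness of fit.
#'
#' @name flux-fitting
NULL

#' Fitting configuration
#'
#' @param n_starts number of random multi-start optimizations (the
#'   protocol repeats estimation at least 50 times)
#' @param seed RNG seed for the start points (mandatory determinism)
#' @param free_ub bound on |free net fluxes| (nmol/1e6 cells/h)
#' @param ex_ub upper bound on exchange fluxes
#' @param ex_c compactification constant c in u = vex/(vex + c)
#' @param ex_lb lower bound for random initial exchange fluxes
#' @param tol_ssr SSR-change convergence tolerance
#' @param tol_step step-norm convergence tolerance
#' @param max_iter iteration cap per start
#' @param alpha chi-square significance level (two-sided)
#' @param ci_level confidence level for profile CIs
#' @param fixed_mixing named fractions for measurement pools whose
#'   mixing is structurally unidentifiable and therefore not fitted.
#'   For the bundled model: citrate (its cytosolic pool is a pure
#'   transport image of the mitochondrial pool) and aspartate and
#'   glutamate (the observed MID constrains only a product of the
#'   mixing fraction with unidentifiable pool-composition exchanges)
#' @param pinned_fluxes named net fluxes held fixed during fitting.
#'   Defaults to the bundled model's biomass/secretion drains (alanine,
#'   aspartate, glutamate efflux and lipogenic acetyl-CoA), which carry
#'   no isotope-labeling signature and are therefore constrained from
#'   assumed growth requirements, the standard practice; names absent
#'   from a model are ignored
#' @param early_stop_ssr stop the multi-start loop early once a
#'   solution reaches this SSR (NULL = never)
#' @param chi2_upper_only if TRUE use an upper-tail-only acceptance
#'   region instead of the default two-sided one
#' @param chain_restarts damping-reset re-runs after each start's first
#'   stall (sloppy-valley recovery)
#' @param polish_top how many of the best multi-start candidates get a
#'   deep chained polish
#' @param polish_budget iteration budget of each deep polish
#' @param interior_phase if TRUE each start is first optimized with
#'   all parameters held strictly inside their bounds (free fluxes
#'   >= 1, exchanges >= 1, mixing in `[0.02, 0.98]`) before the true
#'   bounds are released -- a continuation that avoids premature
#'   collapse onto boundary traps
#' @param weighting `"covariance"` (default) whitens each corrected
#'   MID block with its propagated covariance -- the natural-abundance
#'   correction and the renormalization correlate the mass channels,
#'   and ignoring that overstates the information content and shrinks
#'   confidence intervals; `"diagonal"` uses plain per-channel
#'   z-scores
#' @param verbose emit per-start progress messages
#' @return a list of class `nm_fitconfig`
#' @export
fit_config <- function(n_starts = 50L, seed = 20241030L, free_ub = 1000,
                       ex_ub = 1000, ex_c = 100, ex_lb = 1e-3,
                       tol_ssr = 1e-9, tol_step = 1e-8, max_iter = 500L,
                       alpha = 0.05, ci_level = 0.95,
                       fixed_mixing = c(ASP = 0.5, CIT = 0.5, GLU = 0.5),
                       pinned_fluxes = c(v_alas = 15, v_asps = 10,
                                         v_glus = 30, v_lip = 15),
                       early_stop_ssr = NULL, chi2_upper_only = FALSE,
                       chain_restarts = 2L, polish_top = 2L,
                       polish_budget = 3000L, interior_phase = TRUE,
                       weighting = c("covariance", "diagonal"),
                       verbose = FALSE) {
  weighting <- match.arg(weighting)
  stopifnot(n_starts >= 1L, alpha > 0, alpha < 1, ci_level > 0, ci_level < 1)
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 free_ub = free_ub, ex_ub = ex_ub, ex_c = ex_c, ex_lb = ex_lb,
                 tol_ssr = tol_ssr, tol_step = tol_step,
                 max_iter = as.integer(max_iter), alpha = alpha,
                 ci_level = ci_level, fixed_mixing = fixed_mixing,
                 pinned_fluxes = pinned_fluxes,
                 early_stop_ssr = early_stop_ssr,
                 chi2_upper_only = chi2_upper_only,
                 chain_restarts = as.integer(chain_restarts),
                 polish_top = as.integer(polish_top),
                 polish_budget = as.integer(polish_budget),
                 interior_phase = interior_phase,
                 weighting = weighting,
                 verbose = verbose),
            class = "nm_fitconfig")
}

#' Bundle corrected MIDs and exchange rates for fitting
#'
#' @param mids corrected measurements from [prepare_mids()]
#' @param rates data.frame with columns `metabolite`, `rate`, `sd`
#'   (uptake positive), as from [estimate_rates()]
#' @param condition label (e.g. "WT")
#' @return an `nm_measurements`
#' @export
measurement_set <- function(mids, rates, condition = "unnamed") {
  structure(list(mids = mids, rates = rates, condition = condition),
            class = "nm_measurements")
}

# ---- parameterization ------------------------------------------------

build_param_spec <- function(model, config) {
  basis <- free_flux_basis(model, pinned = config$pinned_fluxes)
  rxn_ids <- rownames(basis$N)
  rev_ids <- sort(names(model$reactions)[vapply(
    model$reactions, function(r) r$reversible && is_flux_reaction(r), TRUE)])
  irrev_ids <- setdiff(rxn_ids, rev_ids)
  mix_all <- sort(species_of(
    model$metabolites$id[model$metabolites$compartment == "observation"]))
  mix_fit <- setdiff(mix_all, names(config$fixed_mixing))
  free_rev <- basis$free %in% rev_ids
  nf <- length(basis$free); nx <- length(rev_ids); nm <- length(mix_fit)
  u_of <- function(ve) ve / (ve + config$ex_c)
  lower <- c(ifelse(free_rev, -config$free_ub, 0),
             rep(0, nx), rep(0, nm))
  upper <- c(rep(config$free_ub, nf),
             rep(u_of(config$ex_ub), nx), rep(1, nm))
  list(basis = basis, rxn_ids = rxn_ids, rev_ids = rev_ids,
       irrev_ids = irrev_ids, irrev_idx = match(irrev_ids, rxn_ids),
       mix_all = mix_all, mix_fit = mix_fit, nf = nf, nx = nx, nm = nm,
       lower = lower, upper = upper, ex_c = config$ex_c,
       npar = nf + nx + nm)
}

params_to_flux <- function(theta, ps, config) {
  x <- theta[seq_len(ps$nf)]
  u <- theta[ps$nf + seq_len(ps$nx)]
  fm <- theta[ps$nf + ps$nx + seq_len(ps$nm)]
  v <- ps$basis$v0 + as.vector(ps$basis$N %*% x)
  names(v) <- ps$rxn_ids
  ve <- ps$ex_c * u / (1 - pmin(u, 1 - 1e-12))
  names(ve) <- ps$rev_ids
  mixing <- stats::setNames(rep(0.5, length(ps$mix_all)), ps$mix_all)
  mixing[ps$mix_fit] <- fm
  fx <- names(config$fixed_mixing)[names(config$fixed_mixing) %in% ps$mix_all]
  mixing[fx] <- config$fixed_mixing[fx]
  structure(list(net = v, exchange = ve, mixing = mixing),
            class = "nm_fluxstate")
}

flux_to_params <- function(flux, ps) {
  x <- flux$net[ps$basis$free]
  u <- flux$exchange[ps$rev_ids] /
    (flux$exchange[ps$rev_ids] + ps$ex_c)
  fm <- flux$mixing[ps$mix_fit]
  unname(c(x, u, fm))
}

# ---- objective -------------------------------------------------------

# Precompute the residual bookkeeping: which entries of the
# concatenated simulation output compare to which measured values.
build_objective_ctx <- function(model, meas, fragments, tracer, config,
                                rate_map = rate_reaction_map()) {
  ps <- build_param_spec(model, config)
  frag_used <- unique(vapply(meas$mids, `[[`, "", "fragment_id"))
  frag_defs <- fragments[frag_used]
  tkeys <- unique(vapply(frag_defs, function(f)
    emu_key(f$metabolite, f$atoms), ""))
  targets <- lapply(tkeys, function(k) {
    sp <- regmatches(k, regexec("^(.*)\\[(.*)\\]$", k))[[1]]
    emu(sp[2], as.integer(strsplit(sp[3], ",")[[1]]))
  })
  system <- emu_decompose(model, targets)
  prep <- emu_prepare(system, tracer)
  offsets <- stats::setNames(prep$starts, system$targets)

  sim_idx <- integer(0); mid_meas <- mid_sd <- numeric(0)
  mid_label <- character(0)
  blocks <- list()
  for (mm in meas$mids) {
    f <- fragments[[mm$fragment_id]]
    key <- emu_key(f$metabolite, f$atoms)
    n <- f$n_skeleton
    keep <- seq_len(n)              # drop the last (redundant) fraction
    sim_idx <- c(sim_idx, offsets[[key]] + keep - 1L)
    mid_meas <- c(mid_meas, mm$mid[keep])
    mid_sd <- c(mid_sd, mm$sd[keep])
    rep_tag <- if (is.na(mm$replicate)) "" else paste0("/r", mm$replicate)
    mid_label <- c(mid_label,
                   paste0(mm$fragment_id, rep_tag, ":M", keep - 1L))
    # per-block whitener: inverse Cholesky factor of the propagated
    # covariance (falls back to 1/SD when no covariance is available)
    if (config$weighting == "covariance" && !is.null(mm$cov)) {
      covB <- mm$cov[keep, keep, drop = FALSE]
      Wb <- tryCatch(forwardsolve(t(chol(covB)), diag(n)),
                     error = function(e) diag(1 / mm$sd[keep], n))
    } else {
      Wb <- diag(1 / mm$sd[keep], n)
    }
    blocks[[length(blocks) + 1L]] <- Wb
  }
  n_mid <- length(mid_meas)
  W_mid <- matrix(0, n_mid, n_mid)
  off <- 0L
  for (Wb in blocks) {
    nb <- nrow(Wb)
    W_mid[off + seq_len(nb), off + seq_len(nb)] <- Wb
    off <- off + nb
  }

  rmap <- rate_map
  rates <- meas$rates
  ri <- match(rates$metabolite, rmap$metabolite)
  if (any(is.na(ri)))
    stop_tcf("no reaction mapping for rate metabolite(s): ",
             paste(rates$metabolite[is.na(ri)], collapse = ", "))
  rate_rxn <- match(rmap$reaction[ri], ps$rxn_ids)
  rate_sign <- rmap$sign[ri]

  list(ps = ps, prep = prep, config = config,
       sim_idx = sim_idx, mid_meas = mid_meas, mid_sd = mid_sd,
       W_mid = W_mid, mid_label = mid_label,
       rate_rxn = rate_rxn, rate_sign = rate_sign,
       rate_val = rates$rate, rate_sd = rates$sd,
       rate_label = paste0("rate:", rates$metabolite),
       n_resid = length(mid_meas) + nrow(rates),
       pen_w = 10)
}

# residuals plus analytic Jacobian via forward sensitivities.  The
# kinks (net-flux sign switches, exchange floor, bound clipping) are
# handled here by subgradient masks; the smooth part is propagated
# through the EMU cascade in compiled code.
objective_resid_jac <- function(theta, ctx, floor = 1e-9) {
  ps <- ctx$ps
  config <- ctx$config
  prep <- ctx$prep
  system <- prep$system
  nf <- ps$nf; nx <- ps$nx; nm <- ps$nm
  npar <- ps$npar
  x <- theta[seq_len(nf)]
  u <- theta[nf + seq_len(nx)]
  fm <- theta[nf + nx + seq_len(nm)]

  v <- ps$basis$v0 + as.vector(ps$basis$N %*% x)
  ve_raw <- config$ex_c * u / (1 - pmin(u, 1 - 1e-12))
  dve <- config$ex_c / (1 - pmin(u, 1 - 1e-12))^2
  ex <- pmax(ve_raw, floor)
  dex <- ifelse(ve_raw > floor, dve, 0)

  fwd <- pmax(v, 0); bwd <- pmax(-v, 0)
  ri <- system$rev_in_net
  fwd[ri] <- fwd[ri] + ex; bwd[ri] <- bwd[ri] + ex
  fwd_fl <- pmax(fwd, floor)

  # d(fwd)/dtheta and d(bwd)/dtheta, reactions x parameters
  nrxn <- length(v)
  dfwd <- matrix(0, nrxn, npar)
  dbwd <- matrix(0, nrxn, npar)
  dfwd[, seq_len(nf)] <- ps$basis$N * (v > 0)
  dbwd[, seq_len(nf)] <- -ps$basis$N * (v < 0)
  if (nx) {
    dfwd[cbind(ri, nf + seq_len(nx))] <-
      dfwd[cbind(ri, nf + seq_len(nx))] + dex
    dbwd[cbind(ri, nf + seq_len(nx))] <-
      dbwd[cbind(ri, nf + seq_len(nx))] + dex
  }
  dfwd[fwd <= floor, ] <- 0

  isf <- system$dir_is_f
  ni <- system$dir_net_idx
  vdir <- numeric(length(ni))
  vdir[isf] <- fwd_fl[ni[isf]]
  vdir[!isf] <- bwd[ni[!isf]]
  dvdir <- matrix(0, length(ni), npar)
  dvdir[isf, ] <- dfwd[ni[isf], , drop = FALSE]
  dvdir[!isf, ] <- dbwd[ni[!isf], , drop = FALSE]

  nmix <- length(prep$mix_names)
  dmix <- matrix(0, max(nmix, 1L), npar)
  mixing <- stats::setNames(rep(0.5, length(ps$mix_all)), ps$mix_all)
  mixing[ps$mix_fit] <- fm
  fx <- names(config$fixed_mixing)[names(config$fixed_mixing) %in% ps$mix_all]
  mixing[fx] <- config$fixed_mixing[fx]
  if (nmix) {
    mixv <- as.numeric(mixing[prep$mix_names])
    hit <- match(ps$mix_fit, prep$mix_names)
    ok <- which(!is.na(hit))
    if (length(ok))
      dmix[cbind(hit[ok], nf + nx + ok)] <- 1
  } else mixv <- numeric(0)

  sens <- emu_run_sens_cpp(prep$ptr, vdir, mixv,
                           dvdir, dmix[seq_len(max(nmix, 1L)), ,
                                       drop = FALSE])
  sim <- sens$out
  dsim <- sens$dout

  r_mid <- as.vector(ctx$W_mid %*% (sim[ctx$sim_idx] - ctx$mid_meas))
  J_mid <- ctx$W_mid %*% dsim[ctx$sim_idx, , drop = FALSE]
  pred <- v[ctx$rate_rxn] * ctx$rate_sign
  r_rate <- (pred - ctx$rate_val) / ctx$rate_sd
  J_rate <- (ps$basis$N[ctx$rate_rxn, , drop = FALSE] * ctx$rate_sign /
               ctx$rate_sd)
  J_rate <- cbind(J_rate, matrix(0, length(r_rate), nx + nm))
  vi <- v[ps$irrev_idx]
  pen <- pmin(vi, 0) * ctx$pen_w
  J_pen <- ps$basis$N[ps$irrev_idx, , drop = FALSE] * (vi < 0) * ctx$pen_w
  J_pen <- cbind(J_pen, matrix(0, length(pen), nx + nm))

  list(r = c(r_mid, r_rate, pen), J = rbind(J_mid, J_rate, J_pen))
}

# residual vector: MID z-scores, rate z-scores, then irreversibility
# penalties (zero whenever the candidate point is feasible)
objective_residuals <- function(theta, ctx) {
  flux <- params_to_flux(theta, ctx$ps, ctx$config)
  sim <- simulate_concat(ctx$prep, flux)
  r_mid <- as.vector(ctx$W_mid %*% (sim[ctx$sim_idx] - ctx$mid_meas))
  pred <- flux$net[ctx$rate_rxn] * ctx$rate_sign
  r_rate <- (pred - ctx$rate_val) / ctx$rate_sd
  pen <- pmin(flux$net[ctx$ps$irrev_idx], 0) * ctx$pen_w
  c(r_mid, r_rate, pen)
}

#' Weighted SSR and residual vector at a parameter point
#'
#' @param theta parameter vector (free fluxes, compactified exchange,
#'   fitted mixing fractions)
#' @param model,meas,fragments,tracer,config,rate_map as in [fit_fluxes()]
#' @return list with `ssr` (penalties excluded) and `residuals`
#' @export
objective <- function(theta, model, meas, fragments,
                      tracer = tracer_spec(), config = fit_config(),
                      rate_map = rate_reaction_map()) {
  ctx <- build_objective_ctx(model, meas, fragments, tracer, config, rate_map)
  r <- objective_residuals(theta, ctx)
  rr <- r[seq_len(ctx$n_resid)]
  list(ssr = sum(rr^2), residuals = rr)
}

# ---- Levenberg-Marquardt with box constraints ------------------------

# Box-constrained Levenberg-Marquardt on a residual vector.
# Ingredients that matter for this problem class (sloppy MFA
# landscapes): Marquardt column scaling (parameter magnitudes span
# 1e-3..1e3), an active-set treatment of the bounds, Nielsen's damping
# schedule, and a stopping rule that only fires after several
# consecutive sub-tolerance improvements (single tiny steps are common
# halfway down the curved valleys of these models).
lm_least_squares <- function(par, fn, lower, upper,
                             tol_ssr = 1e-9, tol_step = 1e-8,
                             max_iter = 500L, fnj = NULL) {
  npar <- length(par)
  par <- pmin(pmax(par, lower), upper)
  r <- fn(par)
  ssr <- sum(r^2)
  lambda <- 1e-3; nu <- 2
  nstall <- 0L
  reason <- "max_iter"
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    if (!is.null(fnj)) {
      J <- fnj(par)$J
    } else {
      J <- matrix(0, length(r), npar)
      for (j in seq_len(npar)) {
        h <- 1e-6 * max(abs(par[j]), 0.01)
        if (par[j] + h > upper[j]) h <- -h
        pj <- par; pj[j] <- pj[j] + h
        J[, j] <- (fn(pj) - r) / h
      }
    }
    scl <- sqrt(pmax(colSums(J^2), 1e-12))
    Js <- sweep(J, 2, scl, "/")
    g <- crossprod(Js, r)
    eps_b <- 1e-10
    act <- (par <= lower + eps_b & g > 0) | (par >= upper - eps_b & g < 0)
    free_j <- which(!act)
    if (!length(free_j)) { reason <- "all_bound"; break }
    JtJ <- crossprod(Js[, free_j, drop = FALSE])
    gf <- g[free_j]
    improved <- FALSE
    for (inner in 1:40) {
      A <- JtJ + lambda * diag(length(free_j))
      ch <- tryCatch(chol(A), error = function(e) NULL)
      if (is.null(ch)) { lambda <- lambda * nu; nu <- nu * 2; next }
      df <- -backsolve(ch, forwardsolve(t(ch), gf))
      delta <- numeric(npar)
      delta[free_j] <- as.vector(df) / scl[free_j]
      trial <- pmin(pmax(par + delta, lower), upper)
      rt <- fn(trial)
      ssrt <- sum(rt^2)
      if (is.finite(ssrt) && ssrt < ssr) {
        step <- sqrt(sum((trial - par)^2))
        dssr <- ssr - ssrt
        par <- trial; r <- rt; ssr <- ssrt
        lambda <- max(lambda / 3, 1e-14); nu <- 2
        improved <- TRUE
        if (dssr < tol_ssr * max(1, ssr) || step < tol_step)
          nstall <- nstall + 1L
        else nstall <- 0L
        if (nstall >= 4L) reason <- "ssr_tol"
        break
      }
      lambda <- lambda * nu; nu <- nu * 2
      if (lambda > 1e14) break
    }
    if (!improved) { reason <- "no_progress"; break }
    if (reason == "ssr_tol") break
  }
  list(par = par, ssr = ssr, residuals = r, iterations = iter,
       reason = reason)
}

# LM with restart chaining: re-running from the endpoint with a reset
# damping parameter recovers from premature stalls on sloppy valleys
lm_chained <- function(par, fn, lower, upper, tol_ssr, tol_step,
                       max_iter, chains = 2L, fnj = NULL) {
  out <- lm_least_squares(par, fn, lower, upper, tol_ssr, tol_step,
                          max_iter, fnj = fnj)
  total_it <- out$iterations
  for (ch in seq_len(chains)) {
    prev <- out$ssr
    nxt <- lm_least_squares(out$par, fn, lower, upper, tol_ssr, tol_step,
                            max_iter, fnj = fnj)
    total_it <- total_it + nxt$iterations
    if (nxt$ssr < out$ssr) out <- nxt
    if (prev - out$ssr < 1e-6 * max(1, out$ssr)) break
  }
  out$iterations <- total_it
  out
}

# ---- multi-start fit -------------------------------------------------

random_start <- function(ps, config) {
  x <- stats::runif(ps$nf,
                    ifelse(ps$basis$free %in% ps$rev_ids, -config$free_ub, 0),
                    config$free_ub)
  # exchange fluxes log-uniform in [ex_lb, ex_ub], then compactified
  ve <- exp(stats::runif(ps$nx, log(config$ex_lb), log(config$ex_ub)))
  u <- ve / (ve + config$ex_c)
  fm <- stats::runif(ps$nm)
  c(x, u, fm)
}

#' Estimate fluxes from a measurement set
#'
#' Runs `config$n_starts` local bounded least-squares optimizations
#' from seeded random initial parameter values and keeps the best
#' solution (ties broken by earliest start).  Results are deterministic
#' for a given seed.
#'
#' @param model an `nm_model`
#' @param meas an `nm_measurements`
#' @param fragments fragment library (named list of [fragment_def()])
#' @param tracer an `nm_tracer`
#' @param config an `nm_fitconfig`
#' @param rate_map mapping from rate metabolites to model reactions
#'   (see [rate_reaction_map()])
#' @return an `nm_fit` with the best flux state, SSR, chi-square
#'   verdict, per-start trace and residual table
#' @export
fit_fluxes <- function(model, meas, fragments, tracer = tracer_spec(),
                       config = fit_config(),
                       rate_map = rate_reaction_map()) {
  ctx <- build_objective_ctx(model, meas, fragments, tracer, config, rate_map)
  ps <- ctx$ps
  dof <- ctx$n_resid - ps$npar
  if (dof <= 0)
    stop_tcf("model not identifiable from measurements (dof = ", dof, ")")
  fn <- function(p) objective_residuals(p, ctx)
  fnj <- function(p) objective_resid_jac(p, ctx)

  starts <- with_seed(config$seed,
    t(vapply(seq_len(config$n_starts), function(i) random_start(ps, config),
             numeric(ps$npar))))
  starts <- matrix(starts, ncol = ps$npar)

  results <- vector("list", config$n_starts)
  t0 <- Sys.time()
  n_run <- 0L
  # interior-continuation bounds (used when config$interior_phase)
  low_in <- ps$lower; up_in <- ps$upper
  low_in[seq_len(ps$nf)] <- ifelse(ps$lower[seq_len(ps$nf)] == 0, 1,
                                   ps$lower[seq_len(ps$nf)])
  low_in[ps$nf + seq_len(ps$nx)] <- 1 / (1 + config$ex_c)
  low_in[ps$nf + ps$nx + seq_len(ps$nm)] <- 0.02
  up_in[ps$nf + ps$nx + seq_len(ps$nm)] <- 0.98

  run_one <- function(p0) {
    if (config$interior_phase) {
      a <- lm_chained(pmin(pmax(p0, low_in), up_in), fn, low_in, up_in,
                      tol_ssr = config$tol_ssr, tol_step = config$tol_step,
                      max_iter = config$max_iter, chains = 1L, fnj = fnj)
      p0 <- a$par
    }
    lm_chained(p0, fn, ps$lower, ps$upper,
               tol_ssr = config$tol_ssr, tol_step = config$tol_step,
               max_iter = config$max_iter, chains = config$chain_restarts,
               fnj = fnj)
  }

  for (i in seq_len(config$n_starts)) {
    res <- tryCatch(
      run_one(starts[i, ]),
      error = function(e) list(par = starts[i, ], ssr = Inf,
                               residuals = NULL, iterations = 0L,
                               reason = paste("error:", conditionMessage(e))))
    results[[i]] <- res
    n_run <- i
    if (config$verbose)
      message(sprintf("start %d/%d: SSR = %.6g (%s, %d it)", i,
                      config$n_starts, res$ssr, res$reason, res$iterations))
    if (!is.null(config$early_stop_ssr) && res$ssr <= config$early_stop_ssr)
      break
  }
  results <- results[seq_len(n_run)]
  ssrs_pen <- vapply(results, `[[`, 0, "ssr")
  if (all(!is.finite(ssrs_pen)))
    stop_tcf("all optimization starts failed; per-start reasons: ",
             paste(vapply(results, `[[`, "", "reason"), collapse = "; "))
  best_i <- which(ssrs_pen <= min(ssrs_pen) + 1e-9)[1]
  best <- results[[best_i]]

  # deep polish: the lowest-SSR candidates are chained further.  These
  # models have long, curved, ill-conditioned valleys; the global
  # optimum is often reached only by continuing well past the first
  # stall of the local solver.
  if (config$polish_top > 0 && is.finite(best$ssr) &&
      (is.null(config$early_stop_ssr) ||
         best$ssr > config$early_stop_ssr)) {
    ord <- order(ssrs_pen)
    cand <- ord[seq_len(min(config$polish_top, length(ord)))]
    for (k in cand) {
      b <- results[[k]]
      if (!is.finite(b$ssr)) next
      spent <- 0L
      repeat {
        prev <- b$ssr
        nxt <- tryCatch(
          lm_least_squares(b$par, fn, ps$lower, ps$upper,
                           tol_ssr = config$tol_ssr,
                           tol_step = config$tol_step,
                           max_iter = config$max_iter, fnj = fnj),
          error = function(e) NULL)
        if (is.null(nxt)) break
        spent <- spent + nxt$iterations
        if (nxt$ssr < b$ssr) b <- nxt
        if (prev - b$ssr < 1e-9 * max(1, b$ssr) ||
            spent >= config$polish_budget) break
        if (!is.null(config$early_stop_ssr) &&
            b$ssr <= config$early_stop_ssr) break
      }
      if (b$ssr < best$ssr - 1e-12) { best <- b; best_i <- k }
    }
    if (config$verbose)
      message(sprintf("polish: best SSR = %.6g (start #%d)",
                      best$ssr, best_i))
  }

  rr <- best$residuals[seq_len(ctx$n_resid)]
  ssr <- sum(rr^2)
  chi2_lo <- if (config$chi2_upper_only) 0
             else stats::qchisq(config$alpha / 2, dof)
  chi2_hi <- stats::qchisq(1 - config$alpha /
                             (if (config$chi2_upper_only) 1 else 2), dof)
  flux <- params_to_flux(best$par, ps, config)

  sim_best <- simulate_concat(ctx$prep, flux)
  resid_table <- data.frame(
    label = c(ctx$mid_label, ctx$rate_label),
    measured = c(ctx$mid_meas, ctx$rate_val),
    simulated = c(sim_best[ctx$sim_idx],
                  flux$net[ctx$rate_rxn] * ctx$rate_sign),
    sd = c(ctx$mid_sd, ctx$rate_sd),
    residual = rr,     # whitened residuals (MID blocks decorrelated)
    stringsAsFactors = FALSE)

  structure(list(
    flux = flux, theta = best$par, ssr = ssr, dof = dof,
    chi2_lo = chi2_lo, chi2_hi = chi2_hi,
    passed = ssr >= chi2_lo && ssr <= chi2_hi,
    start_ssr = ssrs_pen, best_start = best_i,
    convergence = vapply(results, `[[`, "", "reason"),
    iterations = vapply(results, `[[`, 0L, "iterations"),
    residuals = resid_table, condition = meas$condition,
    n_resid = ctx$n_resid, config = config, ctx = ctx,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    ci = NULL),
    class = "nm_fit")
}

#' @export
print.nm_fit <- function(x, ...) {
  cat(sprintf("<nm_fit> condition %s: SSR = %.4g on %d dof (chi2 accept [%.2f, %.2f]: %s)\n",
              x$condition, x$ssr, x$dof, x$chi2_lo, x$chi2_hi,
              if (x$passed) "PASS" else "FAIL"))
  cat(sprintf("  %d starts, best = #%d, wall %.1fs\n",
              length(x$start_ssr), x$best_start, x$wall_time_s))
  invisible(x)
}
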