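#' @title SSR-profile confidence intervals and condition comparison
#'
#' @description
#' Confidence intervals follow the SSR-sensitivity construction: a flux
#' is stepped away from its optimum while all other parameters are
#' re-optimized, and the interval ends where the re-optimized SSR
#' exceeds SSR_min + chi-square quantile (3.841 for 95%, 1 dof).
#' Because any net flux is a linear function of the free fluxes, the
#' constraint "flux = value" is imposed exactly by eliminating one free
#' flux, keeping the profile optimization well conditioned.
#'
#' @name profile-ci
NULL

# minimize SSR subject to net flux `rxn` = val.  Several warm starts
# are tried; when the result still looks suboptimal near the decision
# threshold, the solve escalates to an interior-continuation restart
# (large constrained displacements require coordinated rerouting that
# a single warm-started local solve often fails to find).
profile_refit <- function(ctx, rxn, val, starts, base_ssr = NULL,
                          max_iter = 200L, escalate = TRUE) {
  ps <- ctx$ps
  trow <- ps$basis$N[rxn, ]
  j <- which.max(abs(trow))
  if (abs(trow[j]) < 1e-12)
    stop_tcf("flux ", rxn, " is structurally zero; cannot profile")
  v0t <- ps$basis$v0[[rxn]]
  rebuild <- function(red) {
    x <- numeric(ps$npar)
    x[-j] <- red
    xf <- x[seq_len(ps$nf)]
    xf[j] <- (val - v0t - sum(trow[-j] * xf[-j])) / trow[j]
    x[seq_len(ps$nf)] <- xf
    x
  }
  fn <- function(red) objective_residuals(rebuild(red), ctx)
  # chain rule for the analytic Jacobian under the linear elimination
  R <- diag(ps$npar)[, -j, drop = FALSE]
  R[j, seq_len(ps$nf - 1)] <- -trow[-j] / trow[j]
  fnj <- function(red) {
    o <- objective_resid_jac(rebuild(red), ctx)
    list(r = o$r, J = o$J %*% R)
  }
  if (!is.list(starts)) starts <- list(starts)
  lo <- ps$lower[-j]; hi <- ps$upper[-j]
  run <- function(p0, lo_run = lo) {
    res <- lm_chained(pmin(pmax(p0, lo_run), hi), fn, lo_run, hi,
                      tol_ssr = 1e-9, tol_step = 1e-8,
                      max_iter = max_iter, chains = 2L, fnj = fnj)
    rr <- res$residuals[seq_len(ctx$n_resid)]
    list(ssr = sum(rr^2), par = res$par)
  }
  best <- NULL
  for (th in starts) {
    cand <- run(th[-j])
    if (is.null(best) || cand$ssr < best$ssr) best <- cand
  }
  if (escalate && !is.null(base_ssr) && best$ssr > base_ssr + 2.5) {
    # interior continuation: free fluxes and exchanges held strictly
    # inside their bounds first
    nfr <- ps$nf - 1L
    lo_in <- lo
    lo_in[seq_len(nfr)] <- ifelse(lo[seq_len(nfr)] == 0, 1,
                                  lo[seq_len(nfr)])
    lo_in[nfr + seq_len(ps$nx)] <- 1 / (1 + ps$ex_c)
    for (th in starts) {
      a <- run(th[-j], lo_run = lo_in)
      cand <- run(a$par)
      if (cand$ssr < best$ssr) best <- cand
    }
  }
  list(ssr = best$ssr, theta = rebuild(best$par))
}

#' Does the SSR-profile confidence region contain a value?
#'
#' Performs one strong constrained re-optimization at `value` and
#' compares the SSR rise against the chi-square threshold -- the
#' membership test of the profile CI without bracketing its ends.
#' @param fit an `nm_fit`
#' @param flux_id reaction id
#' @param value net-flux value to test
#' @param level confidence level
#' @return TRUE if `value` lies inside the profile confidence region
#' @export
profile_contains <- function(fit, flux_id, value, level = NULL) {
  ctx <- fit$ctx
  level <- level %||% fit$config$ci_level
  pr <- profile_refit(ctx, flux_id, value, list(fit$theta),
                      base_ssr = fit$ssr)
  (pr$ssr - fit$ssr) <= stats::qchisq(level, 1)
}

#' SSR-profile confidence interval for one net flux
#'
#' @param fit an `nm_fit` from [fit_fluxes()] (carries its objective
#'   context)
#' @param flux_id reaction id of the net flux to profile
#' @param level confidence level (default from the fit's config)
#' @param step0 initial bracketing step; defaults to an estimate from
#'   the local quadratic approximation, else 5% of the flux (floor 1)
#' @param max_expand bracketing expansions (factor 1.7)
#' @return list with `lower`, `upper`, `value`, flags
#'   `lower_at_bound`/`upper_at_bound`, and the threshold used
#' @export
confidence_interval <- function(fit, flux_id, level = NULL, step0 = NULL,
                                max_expand = 30L) {
  ctx <- fit$ctx
  if (is.null(ctx)) stop_tcf("fit carries no objective context")
  level <- level %||% fit$config$ci_level
  thr <- fit$ssr + stats::qchisq(level, 1)
  v0 <- fit$flux$net[[flux_id]]
  tol <- max(0.005 * abs(v0), 0.01)
  bound <- fit$config$free_ub

  if (is.null(step0)) {
    step0 <- max(0.05 * abs(v0), 1)
    # quadratic guess from the Jacobian at the optimum
    se <- tryCatch({
      J <- objective_resid_jac(fit$theta, ctx)$J
      JtJ <- crossprod(J)
      scl <- sqrt(pmax(diag(JtJ), 1e-12))
      covx <- diag(1 / scl) %*%
        solve(JtJ / outer(scl, scl) + 1e-10 * diag(ncol(J))) %*%
        diag(1 / scl)
      trow <- c(ctx$ps$basis$N[flux_id, ], numeric(ctx$ps$nx + ctx$ps$nm))
      sqrt(max(drop(t(trow) %*% covx %*% trow), 0))
    }, error = function(e) NA_real_)
    if (is.finite(se) && se > 0) step0 <- max(1.5 * se, tol)
  }

  one_side <- function(dirn) {
    theta <- fit$theta
    prev_val <- v0; prev_ssr <- fit$ssr
    step <- step0
    val <- v0
    hit_bound <- FALSE
    for (e in seq_len(max_expand)) {
      val <- prev_val + dirn * step
      if (abs(val) > bound) { val <- sign(val) * bound; hit_bound <- TRUE }
      pr <- profile_refit(ctx, flux_id, val, list(theta, fit$theta),
                          base_ssr = fit$ssr)
      if (pr$ssr > thr) break
      prev_val <- val; prev_ssr <- pr$ssr; theta <- pr$theta
      if (hit_bound)
        return(list(limit = val, at_bound = TRUE))
      step <- step * 1.7
    }
    if (pr$ssr <= thr)  # never crossed inside bounds
      return(list(limit = val, at_bound = TRUE))
    lo <- prev_val; hi <- val
    while (abs(hi - lo) > tol) {
      mid <- (lo + hi) / 2
      pr <- profile_refit(ctx, flux_id, mid, list(theta, fit$theta),
                          base_ssr = fit$ssr)
      if (pr$ssr > thr) hi <- mid
      else { lo <- mid; theta <- pr$theta }
    }
    list(limit = (lo + hi) / 2, at_bound = FALSE)
  }

  up <- one_side(+1)
  dn <- one_side(-1)
  list(flux = flux_id, value = v0, lower = dn$limit, upper = up$limit,
       lower_at_bound = dn$at_bound, upper_at_bound = up$at_bound,
       threshold = thr, level = level)
}

#' Profile CIs for several fluxes, attached to the fit
#' @param fit an `nm_fit`
#' @param flux_ids reaction ids (default: all reactions carrying a
#'   measured exchange rate)
#' @param level confidence level
#' @return the fit with a `ci` data.frame attached
#' @export
add_confidence_intervals <- function(fit, flux_ids, level = NULL) {
  rows <- lapply(flux_ids, function(id) {
    ci <- confidence_interval(fit, id, level = level)
    data.frame(flux = id, value = ci$value, lower = ci$lower,
               upper = ci$upper, lower_at_bound = ci$lower_at_bound,
               upper_at_bound = ci$upper_at_bound,
               stringsAsFactors = FALSE)
  })
  fit$ci <- do.call(rbind, rows)
  fit
}

#' Compare two fitted conditions
#'
#' Per-reaction net-flux differences; where both fits carry profile
#' CIs for a reaction, the pair is called distinguishable iff the
#' intervals are disjoint.
#'
#' @param fit_a,fit_b `nm_fit` objects for the same model
#' @return data.frame (one row per reaction) of class `nm_fluxcmp`
#' @export
compare_conditions <- function(fit_a, fit_b) {
  if (!identical(names(fit_a$flux$net), names(fit_b$flux$net)))
    stop_tcf("fits use different models")
  out <- data.frame(
    flux = names(fit_a$flux$net),
    net_a = unname(fit_a$flux$net),
    net_b = unname(fit_b$flux$net),
    diff = unname(fit_b$flux$net - fit_a$flux$net),
    stringsAsFactors = FALSE)
  out$distinguishable <- NA
  if (!is.null(fit_a$ci) && !is.null(fit_b$ci)) {
    common <- intersect(fit_a$ci$flux, fit_b$ci$flux)
    for (id in common) {
      a <- fit_a$ci[fit_a$ci$flux == id, ]
      b <- fit_b$ci[fit_b$ci$flux == id, ]
      out$distinguishable[out$flux == id] <-
        a$upper < b$lower || b$upper < a$lower
    }
  }
  attr(out, "conditions") <- c(fit_a$condition, fit_b$condition)
  class(out) <- c("nm_fluxcmp", class(out))
  out
}
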