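#' @title Uptake/secretion rates from spent-media time courses
#'
#' @description
#' Extracellular rates are estimated by regressing cumulative
#' consumption (nmol, per culture) against integrated viable cell
#' density (1e6 cell hours) through the origin, pooling replicates.
#' The slope is the cell-specific rate in nmol per 1e6 cells per hour;
#' positive = uptake, negative = secretion.  Growth between sampled
#' timepoints is interpolated exponentially.
#'
#' @name exchange-rates
NULL

#' Integrated cell density over a time window
#'
#' Piecewise-exponential interpolation of the growth curve; each
#' segment contributes N0 (e^(mu dt) - 1)/mu cell hours in closed form
#' (linear limit when |mu| < 1e-9).
#'
#' @param growth data.frame with columns `time_h`, `cells_e6`
#' @param t0,t1 window bounds (h), within the curve's range
#' @return integral of N(t) dt in 1e6 cell hours
#' @export
integrate_cell_density <- function(growth, t0, t1) {
  if (t1 <= t0) stop_tcf("t1 must exceed t0")
  tt <- growth$time_h; nn <- growth$cells_e6
  if (any(nn <= 0)) stop_tcf("cell counts must be positive")
  if (t0 < min(tt) || t1 > max(tt))
    stop_tcf("window outside the growth curve range")
  o <- order(tt); tt <- tt[o]; nn <- nn[o]
  total <- 0
  for (i in seq_len(length(tt) - 1L)) {
    a <- max(tt[i], t0); b <- min(tt[i + 1L], t1)
    if (b <= a) next
    mu <- (log(nn[i + 1L]) - log(nn[i])) / (tt[i + 1L] - tt[i])
    na <- nn[i] * exp(mu * (a - tt[i]))
    dt <- b - a
    total <- total + if (abs(mu) < 1e-9) na * dt
                     else na * (exp(mu * dt) - 1) / mu
  }
  total
}

#' Estimate one metabolite's exchange rate from spent media
#'
#' @param media data.frame with columns `replicate`, `time_h`,
#'   `conc_mM`, `volume_mL` for a single metabolite; must include the
#'   t = 0 sample per replicate.  The t = 0 concentrations are pooled
#'   across replicates (they sample one shared starting medium)
#' @param growth growth curve data.frame (`time_h`, `cells_e6`)
#' @param cv optional known/pooled concentration noise CV; when given,
#'   the SD is propagated analytically from it instead of the (noisy,
#'   few-degrees-of-freedom) per-metabolite residual estimate
#' @return list with `rate` (nmol per 1e6 cells per h; positive =
#'   uptake), `sd` (regression SE), `n` (points used)
#' @export
estimate_rate <- function(media, growth, cv = NULL) {
  reps <- sort(unique(media$replicate))
  # the t = 0 sample measures the shared starting medium, so its
  # replicate measurements are pooled; this removes the common-offset
  # error that would otherwise correlate all of a replicate's
  # consumption values
  c0 <- mean(media$conc_mM[media$time_h == 0])
  xs <- ys <- numeric(0)
  for (r in reps) {
    sub <- media[media$replicate == r, , drop = FALSE]
    sub <- sub[order(sub$time_h), ]
    if (sub$time_h[1] != 0) stop_tcf("replicate ", r, " lacks a t=0 sample")
    if (any(diff(sub$time_h) <= 0)) stop_tcf("times must strictly increase")
    if (any(sub$conc_mM < 0)) stop_tcf("negative concentration")
    for (i in 2:nrow(sub)) {
      # consumed amount in nmol: mM * mL = umol -> x1000
      ys <- c(ys, (c0 - sub$conc_mM[i]) * sub$volume_mL[i] * 1000)
      xs <- c(xs, integrate_cell_density(growth, 0, sub$time_h[i]))
    }
  }
  sxx <- sum(xs^2)
  if (sxx <= 0) stop_tcf("zero integrated cell density: singular regressor")
  rate <- sum(xs * ys) / sxx
  res <- ys - rate * xs
  n <- length(xs)
  # Two corrections to the naive residual-based SE:
  # (1) concentration noise is heteroscedastic and the late timepoints
  #     carry almost all the leverage, which shrinks their residuals;
  #     an HC2 sandwich (residuals inflated by 1/(1-h)) restores an
  #     honest variance;
  # (2) the pooled-C0 error shifts every consumption value together,
  #     moving the slope without leaving residuals; it is propagated
  #     from the scatter of the t = 0 samples.
  c0s <- media$conc_mM[media$time_h == 0]
  v_ml <- mean(media$volume_mL)
  if (!is.null(cv)) {
    # analytic propagation under the shared CV noise model
    cpred <- pmax(c0 - rate * xs / v_ml / 1000, 0)
    var_pt <- sum(xs^2 * (cv * cpred * v_ml * 1000)^2) / sxx^2
    var_shift <- (sum(xs) / sxx * v_ml * 1000)^2 *
      (cv * c0)^2 / max(length(c0s), 1L)
    sd <- sqrt(var_pt + var_shift)
  } else {
    h <- xs^2 / sxx
    var_hc2 <- sum((xs * res)^2 / pmax(1 - h, 0.1)) / sxx^2
    var_c0 <- if (length(c0s) > 1L) stats::var(c0s) / length(c0s) else 0
    var_shift <- (sum(xs) / sxx * v_ml * 1000)^2 * var_c0
    sd <- if (n > 1L) sqrt(var_hc2 + var_shift) else NA_real_
  }
  list(rate = rate, sd = sd, n = n)
}

#' Read a spent-media table (CSV)
#'
#' Columns: `metabolite, replicate, time_h, conc_mM, volume_mL`.
#' @param path CSV file
#' @export
read_media_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "replicate", "time_h", "conc_mM", "volume_mL")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_tcf("media table is missing column(s): ",
             paste(miss, collapse = ", "))
  df
}

#' Read a growth-curve table (CSV, columns `time_h`, `cells_e6`)
#' @param path CSV file
#' @export
read_growth_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_h", "cells_e6") %in% names(df)))
    stop_tcf("growth table needs columns time_h, cells_e6")
  df
}

#' Estimate all exchange rates in a media table
#'
#' A single concentration-noise CV is estimated by pooling relative
#' residuals over all metabolites and timepoints (media assays share
#' one measurement process), then propagated analytically into each
#' rate's SD.  Pooling matters: per-metabolite residual SEs have only
#' a few degrees of freedom, and plugging such noisy SDs into
#' downstream weighting inflates the dispersion of the standardized
#' errors several-fold.
#'
#' @param media_df table from [read_media_table()]
#' @param growth growth curve data.frame
#' @return data.frame with metabolite, rate, sd, n
#' @export
estimate_rates <- function(media_df, growth) {
  mets <- sort(unique(media_df$metabolite))
  first <- lapply(mets, function(m)
    estimate_rate(media_df[media_df$metabolite == m, , drop = FALSE],
                  growth))
  names(first) <- mets
  # pooled relative residuals -> shared concentration CV
  rels <- numeric(0)
  for (m in mets) {
    sub <- media_df[media_df$metabolite == m, , drop = FALSE]
    c0 <- mean(sub$conc_mM[sub$time_h == 0])
    for (k in seq_len(nrow(sub))) {
      tK <- sub$time_h[k]
      cpred <- if (tK == 0) c0 else
        c0 - first[[m]]$rate *
          integrate_cell_density(growth, 0, tK) / sub$volume_mL[k] / 1000
      if (is.finite(cpred) && cpred > 0.05)
        rels <- c(rels, (sub$conc_mM[k] - cpred) / cpred)
    }
  }
  dof <- max(length(rels) - 2L * length(mets), 1L)
  cv <- sqrt(sum(rels^2) / dof)
  rows <- lapply(mets, function(m) {
    r <- estimate_rate(media_df[media_df$metabolite == m, , drop = FALSE],
                       growth, cv = cv)
    data.frame(metabolite = m, rate = r$rate, sd = r$sd, n = r$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
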