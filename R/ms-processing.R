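#' Define a GC-MS fragment
#'
#' @param fragment_id identifier
#' @param metabolite parent metabolite id in the model
#' @param atoms 1-based parent carbons contained in the ion (the
#'   "skeleton" carbons)
#' @param formula elemental formula of the detected derivatized ion;
#'   its carbon count includes the skeleton carbons
#' @param model optional `nm_model` for id/atom validation
#' @return an `nm_fragment`
#' @export
fragment_def <- function(fragment_id, metabolite, atoms, formula,
                         model = NULL) {
  atoms <- sort(as.integer(atoms))
  counts <- parse_formula(formula)
  n <- length(atoms)
  if (n == 0L) stop_tcf("fragment ", fragment_id, ": zero skeleton carbons")
  if (is.na(counts["C"]) || counts[["C"]] < n)
    stop_tcf("fragment ", fragment_id,
             ": formula has fewer carbons than the skeleton")
  if (!is.null(model)) {
    nc <- n_carbons_of(model, metabolite)
    if (any(atoms > nc))
      stop_tcf("fragment ", fragment_id, ": atoms out of range for ",
               metabolite)
  }
  structure(list(fragment_id = fragment_id, metabolite = metabolite,
                 atoms = atoms, formula = counts, n_skeleton = n),
            class = "nm_fragment")
}

#' Natural-abundance correction matrix of a fragment
#'
#' Builds the convolution matrix C with `raw = C %*% skeleton_mid`.
#' Column j (j = 0..n skeleton labels) is the natural-isotope mass
#' distribution of all non-skeleton atoms -- derivatization carbons
#' (natural 13C), H, N, O, Si, S, P -- shifted by j.  Skeleton carbons
#' live in tracer-atom space and carry no natural-abundance term here;
#' the simulator and the correction share that convention.
#'
#' @param fragment an `nm_fragment`
#' @param abundances per-element isotope distributions
#' @param n_extra extra mass channels beyond the skeleton carbons
#'   retained in the raw measurement (default 3)
#' @return matrix with `n + n_extra + 1` rows and `n + 1` columns
#' @export
correction_matrix <- function(fragment,
                              abundances = default_isotope_abundances(),
                              n_extra = 3L) {
  n <- fragment$n_skeleton
  counts <- fragment$formula
  counts["C"] <- counts["C"] - n
  nmax <- n + n_extra
  nat <- natural_mass_dist(counts, abundances, nmax = nmax)
  C <- matrix(0, nmax + 1L, n + 1L)
  for (j in 0:n) {
    len <- min(length(nat), nmax + 1L - j)
    C[(j + 1L):(j + len), j + 1L] <- nat[seq_len(len)]
  }
  if (any(colSums(C) > 1 + 1e-12))
    stop_tcf("correction matrix column sums exceed 1")
  C
}

#' Lawson-Hanson non-negative least squares
#'
#' Minimizes ||A x - b|| subject to x >= 0 by the classic active-set
#' algorithm.  A is small and well conditioned here (a few mass
#' channels), so the dense textbook formulation is adequate.
#' @param A matrix, b vector
#' @return list with `x` and `deviance`
#' @export
nnls_solve <- function(A, b) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- crossprod(A, b - A %*% x)
  for (outer in seq_len(10L * n)) {
    if (all(passive) || max(w[!passive]) <= 1e-12) break
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      z[is.na(z)] <- 0
      if (all(z[passive] > 1e-12)) { x <- z; break }
      neg <- passive & z <= 1e-12
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= 1e-12] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  list(x = x, deviance = sum((b - A %*% x)^2))
}

#' Correct a raw fragment MID for natural isotope abundance
#'
#' Solves `C x = raw` by non-negatively constrained least squares and
#' renormalizes to a proper mass isotopomer distribution.  SDs are
#' propagated linearly through the unconstrained pseudo-inverse (the
#' active-set truncation and renormalization are ignored for the
#' uncertainty, a standard approximation).
#'
#' @param raw numeric vector of raw mass fractions M0..M(n+k)
#' @param fragment an `nm_fragment`
#' @param sd per-channel SDs of `raw` (same length), or NULL
#' @param abundances isotope table
#' @return list with `mid` (length n+1, sums to 1), `sd`, and the full
#'   propagated covariance `cov` of the unnormalized solution
#' @export
correct_mid <- function(raw, fragment, sd = NULL,
                        abundances = default_isotope_abundances()) {
  n <- fragment$n_skeleton
  if (length(raw) < n + 1L)
    stop_tcf("measurement shorter than skeleton carbons + 1")
  if (all(raw == 0)) stop_tcf("all-zero measurement")
  C <- correction_matrix(fragment, abundances,
                         n_extra = length(raw) - n - 1L)
  if (kappa(C, exact = TRUE) > 1e8)
    stop_tcf("ill-conditioned correction matrix for ",
             fragment$fragment_id)
  x <- nnls_solve(C, raw)$x
  s <- sum(x)
  if (s <= 0) stop_tcf("correction produced an all-zero MID")
  mid <- x / s
  out <- list(mid = mid, sd = NULL, cov = NULL)
  if (!is.null(sd)) {
    P <- solve(crossprod(C), t(C))     # pseudo-inverse
    covx <- P %*% diag(sd^2, length(sd)) %*% t(P)
    # delta method through the renormalization y = x / sum(x)
    Jn <- (diag(length(mid)) - outer(mid, rep(1, length(mid)))) / s
    out$cov <- Jn %*% covx %*% t(Jn)
    out$sd <- sqrt(pmax(diag(out$cov), 0))
  }
  out
}

#' Read a MID measurement table (CSV)
#'
#' Expected columns: `fragment_id, replicate, time_h, mass_shift,
#' fraction, sd`.  Rows are grouped into one measurement per
#' (fragment, replicate, timepoint), ordered by mass shift.
#'
#' @param path CSV file
#' @param fragments fragment library used to validate ids
#' @return data.frame of validated rows (long format)
#' @export
read_mid_table <- function(path, fragments = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fragment_id", "replicate", "time_h", "mass_shift",
            "fraction", "sd")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_tcf("MID table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$fraction < 0))
    stop_tcf("negative mass fraction in row(s) ",
             paste(which(df$fraction < 0), collapse = ", "))
  key <- paste(df$fragment_id, df$replicate, df$time_h, df$mass_shift)
  if (anyDuplicated(key))
    stop_tcf("duplicate (fragment, replicate, time, mass_shift) row(s): ",
             paste(which(duplicated(key)), collapse = ", "))
  if (!is.null(fragments)) {
    unknown <- setdiff(unique(df$fragment_id), names(fragments))
    if (length(unknown))
      stop_tcf("unknown fragment id(s): ", paste(unknown, collapse = ", "))
  }
  df[order(df$fragment_id, df$replicate, df$time_h, df$mass_shift), ,
     drop = FALSE]
}

#' Write a MID measurement table
#' @param df long-format MID data.frame (see [read_mid_table()])
#' @param path output CSV
#' @export
write_mid_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average replicates and correct measured MIDs for fitting
#'
#' Two replicate handling modes: `"average"` pools replicates in raw
#' space (SD = max(sample SD / sqrt(n), floor)); `"blocks"` keeps each
#' replicate as its own residual block with SD = max(reported SD,
#' floor), which matches fitting all replicate experiments jointly.
#'
#' @param mid_df long-format table from [read_mid_table()]
#' @param fragments fragment library
#' @param time_h timepoint to fit (default 24, isotopic steady state)
#' @param replicate_mode `"average"` or `"blocks"`
#' @param sd_floor minimum mol-fraction SD (GC-MS accuracy floor)
#' @param abundances isotope table
#' @return list of corrected measurements: each has `fragment_id`,
#'   `replicate`, `mid`, `sd`, and the propagated covariance `cov` of
#'   the normalized MID (diagonal floored at `sd_floor^2`)
#' @export
prepare_mids <- function(mid_df, fragments, time_h = 24,
                         replicate_mode = c("average", "blocks"),
                         sd_floor = 0.003,
                         abundances = default_isotope_abundances()) {
  replicate_mode <- match.arg(replicate_mode)
  df <- mid_df[mid_df$time_h == time_h, , drop = FALSE]
  if (!nrow(df)) stop_tcf("no MID rows at time ", time_h, " h")
  out <- list()
  for (fid in sort(unique(df$fragment_id))) {
    frag <- fragments[[fid]]
    if (is.null(frag)) stop_tcf("fragment ", fid, " not in library")
    sub <- df[df$fragment_id == fid, , drop = FALSE]
    reps <- sort(unique(sub$replicate))
    mat <- sapply(reps, function(r) {
      s <- sub[sub$replicate == r, ]
      s$fraction[order(s$mass_shift)]
    })
    mat <- matrix(mat, ncol = length(reps))
    if (replicate_mode == "average") {
      raw <- rowMeans(mat)
      if (length(reps) > 1L) {
        sdr <- apply(mat, 1, stats::sd) / sqrt(length(reps))
      } else {
        s <- sub[sub$replicate == reps[1], ]
        sdr <- s$sd[order(s$mass_shift)]
      }
      sdr <- pmax(sdr, sd_floor)
      cr <- correct_mid(raw, frag, sd = sdr, abundances = abundances)
      covf <- cr$cov + diag(pmax(sd_floor^2 - diag(cr$cov), 0))
      out[[length(out) + 1L]] <- list(
        fragment_id = fid, replicate = NA_integer_,
        mid = cr$mid, sd = pmax(cr$sd, sd_floor), cov = covf)
    } else {
      for (k in seq_along(reps)) {
        s <- sub[sub$replicate == reps[k], ]
        sdr <- pmax(s$sd[order(s$mass_shift)], sd_floor)
        cr <- correct_mid(mat[, k], frag, sd = sdr, abundances = abundances)
        covf <- cr$cov + diag(pmax(sd_floor^2 - diag(cr$cov), 0))
        out[[length(out) + 1L]] <- list(
          fragment_id = fid, replicate = reps[k],
          mid = cr$mid, sd = pmax(cr$sd, sd_floor), cov = covf)
      }
    }
  }
  out
}
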