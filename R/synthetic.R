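#' @title Synthetic tracer experiments with known ground truth
#'
#' @description
#' Generates complete synthetic experiments -- GC-MS fragment MID
#' tables, spent-media concentration time courses and growth curves --
#' from a known flux state, emulating the study design: 75%
#' [U-13C]glucose enrichment (15 mM tracer into 5 mM unlabeled medium
#' glucose), three biological replicates, sampling at 0/6/24 h,
#' isotopic steady state, Gaussian measurement noise, and two flux
#' regimes (glycolysis-high "WT-like" vs OxPhos-high "KO-like").
#' Ground truth travels in a sidecar record that the fitting path
#' never reads.
#'
#' @name synthetic-data
NULL

#' Build a synthetic scenario specification
#'
#' Defaults state the emulated experiment: MID noise SD 0.003 mol
#' fraction (the conventional GC-MS accuracy floor), 2% concentration
#' CV, 5% rate CV carried by the media noise, three replicates,
#' timepoints 0/6/24 h, 0.5e6 cells at t=0 with an 18 h doubling time
#' in 1 mL.
#'
#' @param preset `"WT-like"`, `"KO-like"`, or `"custom"` (then supply
#'   `truth`)
#' @param truth an `nm_fluxstate` for custom scenarios; must satisfy
#'   the balance constraints (validated)
#' @param model network model
#' @param tracer tracer spec
#' @param mid_sd Gaussian SD added to raw MID fractions
#' @param conc_cv concentration noise CV (fraction of the value)
#' @param replicates biological replicates
#' @param timepoints sampling times in h (must start at 0)
#' @param n0_e6 initial viable cells (1e6)
#' @param doubling_h doubling time (h)
#' @param volume_ml culture volume (mL)
#' @param c0_mM named initial concentrations (mM): 20 mM glucose =
#'   5 mM medium + 15 mM tracer
#' @param seed RNG seed
#' @return an `nm_scenario`
#' @export
make_scenario <- function(preset = c("WT-like", "KO-like", "custom"),
                          truth = NULL, model = tcell_model(),
                          tracer = tracer_spec(), mid_sd = 0.003,
                          conc_cv = 0.02, replicates = 3L,
                          timepoints = c(0, 6, 24), n0_e6 = 0.5,
                          doubling_h = 18, volume_ml = 1,
                          c0_mM = c(GLC = 20, GLN = 4, PYR = 1, LAC = 0),
                          seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "custom") {
    if (is.null(truth)) stop_tcf("custom scenario needs a truth flux state")
    # re-validate against the model (rejects unbalanced custom states)
    truth <- flux_state(model, truth$net, truth$exchange, truth$mixing)
  } else {
    truth <- preset_flux_state(preset, model)
  }
  stopifnot(mid_sd >= 0, conc_cv >= 0, replicates >= 1L,
            timepoints[1] == 0, !is.unsorted(timepoints, strictly = TRUE))
  structure(list(preset = preset, truth = truth, model = model,
                 tracer = tracer, mid_sd = mid_sd, conc_cv = conc_cv,
                 replicates = as.integer(replicates),
                 timepoints = timepoints, n0_e6 = n0_e6,
                 doubling_h = doubling_h, volume_ml = volume_ml,
                 c0_mM = c0_mM, seed = as.integer(seed)),
            class = "nm_scenario")
}

#' True exchange rates implied by a scenario's flux state
#' @param scenario an `nm_scenario`
#' @return named vector (uptake positive), nmol/1e6 cells/h
#' @export
scenario_true_rates <- function(scenario) {
  rmap <- rate_reaction_map()
  stats::setNames(scenario$truth$net[rmap$reaction] * rmap$sign,
                  rmap$metabolite)
}

#' Generate a synthetic experiment
#'
#' Simulates true fragment MIDs at isotopic steady state, convolves
#' the natural-abundance signature of each derivatized fragment (the
#' forward direction of the measurement correction), adds truncated
#' Gaussian noise and renormalizes; integrates media concentrations
#' forward from the true exchange rates along the exponential growth
#' curve and adds concentration noise.  Byte-identical for a given
#' scenario (seed included).
#'
#' @param scenario an `nm_scenario`
#' @param fragments fragment library (defaults to the bundled one)
#' @return an `nm_experiment`: data.frames `mids`, `media`, `growth`
#'   plus a `truth` record
#' @export
generate_experiment <- function(scenario,
                                fragments = default_fragment_library()) {
  model <- scenario$model
  targets <- lapply(fragments, function(f) emu(f$metabolite, f$atoms))
  sys <- emu_decompose(model, targets)
  mids_true <- simulate_mids(sys, scenario$truth, scenario$tracer)

  growth <- data.frame(
    time_h = scenario$timepoints,
    cells_e6 = scenario$n0_e6 * 2^(scenario$timepoints / scenario$doubling_h))

  rates <- scenario_true_rates(scenario)
  with_seed(scenario$seed, {
    mid_rows <- list()
    for (fid in names(fragments)) {
      f <- fragments[[fid]]
      key <- emu_key(f$metabolite, f$atoms)
      C <- correction_matrix(f)
      raw_true <- as.vector(C %*% mids_true[[key]])
      for (rep in seq_len(scenario$replicates)) {
        for (t in setdiff(scenario$timepoints, 0)) {
          raw <- raw_true + stats::rnorm(length(raw_true), 0, scenario$mid_sd)
          raw <- pmax(raw, 0)           # truncate, then renormalize
          raw <- raw / sum(raw) * sum(raw_true)
          mid_rows[[length(mid_rows) + 1L]] <- data.frame(
            fragment_id = fid, replicate = rep, time_h = t,
            mass_shift = seq_along(raw) - 1L, fraction = raw,
            sd = scenario$mid_sd, stringsAsFactors = FALSE)
        }
      }
    }
    mids <- do.call(rbind, mid_rows)
    rownames(mids) <- NULL

    media_rows <- list()
    for (met in names(rates)) {
      c0 <- scenario$c0_mM[[met]]
      for (rep in seq_len(scenario$replicates)) {
        for (t in scenario$timepoints) {
          ih <- if (t == 0) 0 else integrate_cell_density(growth, 0, t)
          conc <- c0 - rates[[met]] * ih / scenario$volume_ml / 1000
          if (conc < 0)
            stop_tcf(met, " depleted below zero in the synthetic design")
          noised <- max(conc + stats::rnorm(1, 0, scenario$conc_cv * conc), 0)
          media_rows[[length(media_rows) + 1L]] <- data.frame(
            metabolite = met, replicate = rep, time_h = t,
            conc_mM = noised, volume_mL = scenario$volume_ml,
            stringsAsFactors = FALSE)
        }
      }
    }
    media <- do.call(rbind, media_rows)
    rownames(media) <- NULL
  })

  structure(list(
    mids = mids, media = media, growth = growth,
    truth = list(preset = scenario$preset, seed = scenario$seed,
                 net = scenario$truth$net,
                 exchange = scenario$truth$exchange,
                 mixing = scenario$truth$mixing,
                 rates = rates, mid_sd = scenario$mid_sd,
                 conc_cv = scenario$conc_cv),
    scenario = scenario),
    class = "nm_experiment")
}

#' Write an experiment to a directory
#'
#' Emits `mids.csv`, `media.csv`, `growth.csv`, `tracer.json` and the
#' ground-truth sidecar `_TRUTH.json` (never read by the fitting path).
#' @param exp an `nm_experiment`
#' @param dir output directory (created)
#' @return `dir`, invisibly
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(exp$mids, file.path(dir, "mids.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(exp$media, file.path(dir, "media.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(exp$growth, file.path(dir, "growth.csv"),
                   row.names = FALSE, quote = FALSE)
  tr <- exp$scenario$tracer
  jsonlite::write_json(
    list(metabolite = tr$metabolite, n_carbons = tr$n_carbons,
         purity = tr$purity,
         mixture = lapply(tr$mixture, function(cm)
           list(pattern = cm$pattern, fraction = cm$fraction))),
    file.path(dir, "tracer.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(exp$truth, file.path(dir, "_TRUTH.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a tracer specification back from `tracer.json`
#' @param path JSON file written by [write_experiment()]
#' @export
read_tracer_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tracer_spec(metabolite = x$metabolite, n_carbons = x$n_carbons,
              mixture = lapply(seq_len(nrow(x$mixture)), function(i)
                list(pattern = unlist(x$mixture$pattern[i]),
                     fraction = x$mixture$fraction[i])),
              purity = x$purity)
}

#' Fit a synthetic (or on-disk) experiment end to end
#'
#' Corrects the measured MIDs, estimates exchange rates from the media
#' time courses, and runs the multi-start flux fit.  The ground-truth
#' sidecar of synthetic experiments is never consulted.
#'
#' @param exp an `nm_experiment`, or a directory containing
#'   `mids.csv`, `media.csv`, `growth.csv` (and optionally
#'   `tracer.json`)
#' @param fragments fragment library
#' @param model network model
#' @param tracer tracer spec (overridden by `tracer.json` when reading
#'   a directory that has one)
#' @param config fit configuration
#' @param time_h MID timepoint fitted (24 h = isotopic steady state;
#'   the 6 h data serve as a consistency check)
#' @param replicate_mode `"average"` or `"blocks"` (see
#'   [prepare_mids()])
#' @param condition label for the fit
#' @param rate_sd_floor minimum SD assigned to estimated rates
#' @return an `nm_fit`
#' @export
fit_experiment <- function(exp, fragments = default_fragment_library(),
                           model = tcell_model(), tracer = tracer_spec(),
                           config = fit_config(), time_h = 24,
                           replicate_mode = "average",
                           condition = NULL, rate_sd_floor = 0.01) {
  if (is.character(exp)) {
    dir <- exp
    tj <- file.path(dir, "tracer.json")
    if (file.exists(tj)) tracer <- read_tracer_json(tj)
    exp <- list(mids = read_mid_table(file.path(dir, "mids.csv"), fragments),
                media = read_media_table(file.path(dir, "media.csv")),
                growth = read_growth_table(file.path(dir, "growth.csv")))
    condition <- condition %||% basename(dir)
  } else {
    condition <- condition %||% exp$truth$preset %||% "experiment"
    tracer <- exp$scenario$tracer %||% tracer
  }
  mids <- prepare_mids(exp$mids, fragments, time_h = time_h,
                       replicate_mode = replicate_mode)
  rates <- estimate_rates(exp$media, exp$growth)
  rates$sd[!is.finite(rates$sd)] <- 0
  rates$sd <- pmax(rates$sd, rate_sd_floor)
  meas <- measurement_set(mids, rates, condition = condition)
  fit_fluxes(model, meas, fragments, tracer = tracer, config = config)
}
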