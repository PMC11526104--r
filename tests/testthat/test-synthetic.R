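# synthetic_data: presets, generation, determinism, inverse consistency

test_that("presets encode the two metabolic regimes", {
  m <- tcell_model()
  wt <- preset_flux_state("WT-like", m)
  ko <- preset_flux_state("KO-like", m)
  # glycolysis-high vs OxPhos-high contrasts
  expect_gte(wt$net[["v_glut"]], 3 * ko$net[["v_glut"]])
  expect_gte(wt$net[["v_lacs"]], 3 * ko$net[["v_lacs"]])
  expect_gte(ko$net[["v_pdh"]], 2 * wt$net[["v_pdh"]])
  expect_gte(ko$net[["v_cs"]], 2 * wt$net[["v_cs"]])
  expect_gt(ko$net[["v_glnup"]], wt$net[["v_glnup"]])
  expect_gt(ko$net[["v_pyrx"]], wt$net[["v_pyrx"]])
  # lactate secretion exceeds pyruvate oxidation in the WT regime
  expect_gt(wt$net[["v_lacs"]], wt$net[["v_pdh"]])
  expect_error(make_scenario("nonsense"), "arg")
})

test_that("custom scenarios reject unbalanced flux states", {
  m <- tcell_model()
  wt <- preset_flux_state("WT-like", m)
  broken <- wt
  broken$net[["v_cs"]] <- broken$net[["v_cs"]] + 50
  expect_error(make_scenario("custom", truth = broken, model = m),
               "steady-state balance")
})

test_that("generation is deterministic per seed and regenerable", {
  sc <- make_scenario("WT-like", seed = 42)
  frags <- default_fragment_library()
  e1 <- generate_experiment(sc, frags)
  e2 <- generate_experiment(sc, frags)
  expect_identical(e1$mids, e2$mids)
  expect_identical(e1$media, e2$media)
  d1 <- tempfile(); d2 <- tempfile()
  write_experiment(e1, d1); write_experiment(e2, d2)
  for (f in c("mids.csv", "media.csv", "growth.csv", "tracer.json",
              "_TRUTH.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  e3 <- generate_experiment(make_scenario("WT-like", seed = 43), frags)
  expect_false(identical(e1$mids$fraction, e3$mids$fraction))
})

test_that("noiseless generation is inverse-consistent with correction", {
  sc <- make_scenario("WT-like", mid_sd = 0, conc_cv = 0, seed = 1)
  frags <- default_fragment_library()
  exp <- generate_experiment(sc, frags)
  m <- sc$model
  targets <- lapply(frags, function(f) emu(f$metabolite, f$atoms))
  sys <- emu_decompose(m, targets)
  true_mids <- simulate_mids(sys, sc$truth, sc$tracer)
  corr <- prepare_mids(exp$mids, frags, time_h = 24)
  for (cm in corr) {
    f <- frags[[cm$fragment_id]]
    key <- tcellflux:::emu_key(f$metabolite, f$atoms)
    expect_lt(max(abs(cm$mid - true_mids[[key]])), 1e-10)
  }
  # media concentrations drop by rate x integrated density / volume
  est <- estimate_rates(exp$media, exp$growth)
  truth <- scenario_true_rates(sc)
  glc24 <- exp$media$conc_mM[exp$media$metabolite == "GLC" &
                               exp$media$time_h == 24][1]
  ih <- integrate_cell_density(exp$growth, 0, 24)
  expect_equal(glc24, 20 - truth[["GLC"]] * ih / 1000, tolerance = 1e-9)
  expect_lt(glc24, 20)
})

test_that("tracer json round-trips", {
  sc <- make_scenario("KO-like", seed = 3)
  d <- tempfile()
  write_experiment(generate_experiment(sc), d)
  tr <- read_tracer_json(file.path(d, "tracer.json"))
  expect_equal(tr$purity, sc$tracer$purity)
  expect_equal(tracer_emu_mid(tr, 1:6), tracer_emu_mid(sc$tracer, 1:6))
})

test_that("experiment directories can be fitted end to end", {
  sc <- make_scenario("WT-like", seed = 8)
  d <- tempfile()
  write_experiment(generate_experiment(sc), d)
  cfg <- fit_config(n_starts = 1, max_iter = 10, chain_restarts = 0,
                    polish_top = 0)
  fit <- fit_experiment(d, config = cfg)
  expect_s3_class(fit, "nm_fit")
  expect_identical(fit$condition, basename(d))
  expect_equal(fit$dof, fit$n_resid - fit$ctx$ps$npar)
})
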