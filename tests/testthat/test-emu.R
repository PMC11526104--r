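# emu_engine: decomposition, simulation, brute-force oracle

test_that("decomposition structure matches small examples", {
  m <- chain_model()
  sys <- emu_decompose(m, list(emu("B.c", 1:2)))
  expect_equal(sys$n_unknown, 2)        # B[1,2] and C[1,2] via reversibility
  expect_length(sys$levels, 1)

  mc <- condensation_model()
  sysc <- emu_decompose(mc, list(emu("C.c", 1:3)))
  lev3 <- sysc$levels[["3"]]
  kinds <- vapply(lev3$knowns, `[[`, "", "kind")
  expect_true("conv" %in% kinds)        # A[1,2] (x) B[1] condensation input
  expect_error(emu_decompose(m, list(emu("Z.c", 1))), "unknown target")
})

test_that("unlabeled tracer gives unlabeled MIDs everywhere", {
  m <- tcell_model()
  tr0 <- tracer_spec(mixture = list(list(pattern = rep(0L, 6), fraction = 1)))
  sys <- emu_decompose(m, lapply(measured_metabolites(), function(id)
    emu(id, seq_len(n_carbons_of(m, id)))))
  mids <- simulate_mids(sys, preset_flux_state("WT-like", m), tr0)
  for (mid in mids) expect_equal(mid[1], 1, tolerance = 1e-12)
})

test_that("fully labeled tracer on a linear chain gives M(n) = 1", {
  m <- chain3_model()
  tr <- tracer_spec(metabolite = "A.x", n_carbons = 3, purity = 1,
                    mixture = list(list(pattern = c(1L, 1L, 1L),
                                        fraction = 1)))
  fx <- flux_state(m, c(v1 = 10, v2 = 10, v3 = 10))
  sys <- emu_decompose(m, list(emu("C.c", 1:3)))
  mid <- simulate_mids(sys, fx, tr)[["C.c[1,2,3]"]]
  expect_equal(mid, c(0, 0, 0, 1), tolerance = 1e-12)
})

test_that("self-condensation matches the hand-enumerated binomial", {
  m <- self_condensation_model()
  tr <- tracer_spec(metabolite = "A.x", n_carbons = 2, purity = 1,
                    mixture = list(list(pattern = c(1L, 1L), fraction = 0.5),
                                   list(pattern = c(0L, 0L), fraction = 0.5)))
  fx <- flux_state(m, c(vc = 1, vo = 1))
  orc <- brute_force_isotopomer_mids(m, fx, tr)
  expect_equal(orc[["C.c"]], c(0.25, 0, 0.5, 0, 0.25), tolerance = 1e-12)
  # EMU route agrees
  sys <- emu_decompose(m, list(emu("C.c", 1:4)))
  expect_equal(simulate_mids(sys, fx, tr)[["C.c[1,2,3,4]"]],
               orc[["C.c"]], tolerance = 1e-12)
})

test_that("oracle equivalence holds across fixture networks", {
  tr2 <- tracer_spec(metabolite = "A.x", n_carbons = 2, purity = 0.97,
                     mixture = list(list(pattern = c(1L, 1L), fraction = 0.6),
                                    list(pattern = c(1L, 0L), fraction = 0.1),
                                    list(pattern = c(0L, 0L), fraction = 0.3)))
  trS <- tracer_spec(metabolite = "S.x", n_carbons = 2, purity = 0.99,
                     mixture = list(list(pattern = c(1L, 1L), fraction = 0.75),
                                    list(pattern = c(0L, 0L), fraction = 0.25)))
  set.seed(7)
  for (i in 1:25) {
    expect_lt(max_oracle_dev(chain_model(),
                             random_flux_state(chain_model()), tr2), 1e-10)
    expect_lt(max_oracle_dev(condensation_model(),
                             random_flux_state(condensation_model()), tr2),
              1e-10)
    expect_lt(max_oracle_dev(cycle_model(),
                             random_flux_state(cycle_model()), trS), 1e-10)
  }
})

test_that("oracle equivalence holds on the bundled model", {
  m <- tcell_model()
  tr <- tracer_spec()
  expect_lt(max_oracle_dev(m, preset_flux_state("WT-like", m), tr,
                           targets = lapply(measured_metabolites(),
                                            function(id)
                                              emu(id, seq_len(n_carbons_of(m, id))))),
            1e-10)
  set.seed(3)
  fx <- random_flux_state(m, base = preset_flux_state("WT-like", m))
  expect_lt(max_oracle_dev(m, fx, tr,
                           targets = lapply(measured_metabolites(),
                                            function(id)
                                              emu(id, seq_len(n_carbons_of(m, id))))),
            1e-10)
})

test_that("every simulated MID is normalized for random flux states", {
  m <- tcell_model()
  tr <- tracer_spec()
  sys <- emu_decompose(m, lapply(measured_metabolites(), function(id)
    emu(id, seq_len(n_carbons_of(m, id)))))
  prep <- emu_prepare(sys, tr)
  base <- preset_flux_state("WT-like", m)
  set.seed(11)
  for (i in 1:100) {
    fx <- random_flux_state(m, base = base)
    mids <- simulate_prepared(prep, fx)
    expect_lt(max(abs(vapply(mids, sum, 0) - 1)), 1e-10)
    expect_true(all(unlist(mids) > -1e-12))
  }
})

test_that("convolution property holds for single-pathway condensation", {
  m <- condensation_model()
  tr <- tracer_spec(metabolite = "A.x", n_carbons = 2, purity = 0.99,
                    mixture = list(list(pattern = c(1L, 1L), fraction = 0.75),
                                   list(pattern = c(0L, 0L), fraction = 0.25)))
  fx <- flux_state(m, c(vc = 3, vo = 3))
  sys <- emu_decompose(m, list(emu("C.c", 1:3), emu("C.c", 1:2),
                               emu("C.c", 3)))
  mids <- simulate_mids(sys, fx, tr)
  conv <- tcellflux:::conv_mass(mids[["C.c[1,2]"]], mids[["C.c[3]"]])
  expect_equal(mids[["C.c[1,2,3]"]], conv, tolerance = 1e-12)
})

test_that("CO2 dilution monotonically drains label from carboxylation products", {
  m <- tcell_model()
  tr <- tracer_spec()
  sys <- emu_decompose(m, list(emu("ASP.obs", 1:4), emu("MAL.obs", 1:4)))
  prep <- emu_prepare(sys, tr)
  base <- preset_flux_state("WT-like", m)
  labeled_mass <- vapply(c(0, 5, 20, 100, 500, 2000), function(exch) {
    fx <- base
    fx$exchange["v_co2x"] <- exch
    1 - simulate_prepared(prep, fx)[["ASP.obs[1,2,3,4]"]][1]
  }, 0)
  expect_true(all(diff(labeled_mass) <= 1e-12))
})

test_that("mixing fraction endpoints reproduce the pure pools", {
  m <- tcell_model()
  tr <- tracer_spec()
  sys <- emu_decompose(m, list(emu("PYR.obs", 1:3), emu("PYR.c", 1:3),
                               emu("PYR.m", 1:3)))
  prep <- emu_prepare(sys, tr)
  fx <- preset_flux_state("WT-like", m)
  fx$mixing["PYR"] <- 1
  mids <- simulate_prepared(prep, fx)
  expect_equal(mids[["PYR.obs[1,2,3]"]], mids[["PYR.c[1,2,3]"]],
               tolerance = 1e-14)
  fx$mixing["PYR"] <- 0
  mids <- simulate_prepared(prep, fx)
  expect_equal(mids[["PYR.obs[1,2,3]"]], mids[["PYR.m[1,2,3]"]],
               tolerance = 1e-14)
  # the two pools genuinely differ, so the mixing parameter is live
  expect_gt(max(abs(mids[["PYR.c[1,2,3]"]] - mids[["PYR.m[1,2,3]"]])), 0.01)
})

test_that("isotopomer enumeration guard triggers", {
  atoms21 <- paste(letters[1:21], collapse = "")
  big <- parse_model(c(
    "metabolite A.x carbons=21 balanced=no",
    "metabolite M.c carbons=21 balanced=yes",
    "metabolite Z.x carbons=21 balanced=no",
    sprintf("v1: A.x (%s) -> M.c (%s)", atoms21, atoms21),
    sprintf("v2: M.c (%s) -> Z.x (%s)", atoms21, atoms21)))
  fx <- flux_state(big, c(v1 = 1, v2 = 1))
  tr <- tracer_spec(metabolite = "A.x", n_carbons = 21,
                    mixture = list(list(pattern = rep(1L, 21),
                                        fraction = 1)))
  expect_error(brute_force_isotopomer_mids(big, fx, tr), "guard")
})
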