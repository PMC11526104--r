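# flux_fitting: objective, multi-start determinism, profile CIs

make_noiseless_meas <- function(seed = 7) {
  m <- tcell_model()
  frags <- read_fragment_library(model = m)
  sc <- make_scenario("WT-like", model = m, mid_sd = 0, conc_cv = 0,
                      seed = seed)
  exp <- generate_experiment(sc, frags)
  mids <- prepare_mids(exp$mids, frags, time_h = 24)
  rates <- estimate_rates(exp$media, exp$growth)
  rates$sd[!is.finite(rates$sd)] <- 0
  rates$sd <- pmax(rates$sd, 0.01)
  list(model = m, frags = frags, scenario = sc,
       meas = measurement_set(mids, rates, "WT"))
}

test_that("objective is zero at the generating truth and counts z-scores", {
  w <- make_noiseless_meas()
  # unidentifiable mixing fractions are fixed by convention; for this
  # consistency check the convention is set to the generating values
  cfg <- fit_config(n_starts = 1,
                    fixed_mixing = c(ASP = 0.5, CIT = 0.5, GLU = 0.45))
  ctx <- tcellflux:::build_objective_ctx(w$model, w$meas, w$frags,
                                         tracer_spec(), cfg)
  th <- tcellflux:::flux_to_params(w$scenario$truth, ctx$ps)
  o <- objective(th, w$model, w$meas, w$frags, config = cfg)
  expect_lt(o$ssr, 1e-12)

  # +2 SD on one rate => SSR = 4
  pert <- w$meas
  pert$rates$rate[1] <- pert$rates$rate[1] + 2 * pert$rates$sd[1]
  o2 <- objective(th, w$model, pert, w$frags, config = cfg)
  expect_equal(o2$ssr, 4, tolerance = 1e-6)
})

test_that("objective equals an independent hand-rolled recomputation", {
  w <- make_noiseless_meas()
  # the diagonal weighting contract: SSR is the plain sum of squared
  # z-scores (the default covariance weighting whitens MID blocks)
  cfg <- fit_config(n_starts = 1, weighting = "diagonal")
  ctx <- tcellflux:::build_objective_ctx(w$model, w$meas, w$frags,
                                         tracer_spec(), cfg)
  set.seed(3)
  th <- tcellflux:::random_start(ctx$ps, cfg)
  o <- objective(th, w$model, w$meas, w$frags, config = cfg)

  # independent route: full flux state -> simulate_mids -> loop
  fx <- tcellflux:::params_to_flux(th, ctx$ps, cfg)
  ssr <- 0
  sys <- emu_decompose(w$model, lapply(w$frags, function(f)
    emu(f$metabolite, f$atoms)))
  mids <- simulate_mids(sys, fx, tracer_spec())
  for (mm in w$meas$mids) {
    f <- w$frags[[mm$fragment_id]]
    sim <- mids[[tcellflux:::emu_key(f$metabolite, f$atoms)]]
    keep <- seq_len(f$n_skeleton)
    ssr <- ssr + sum(((sim[keep] - mm$mid[keep]) / mm$sd[keep])^2)
  }
  rmap <- rate_reaction_map()
  for (i in seq_len(nrow(w$meas$rates))) {
    row <- w$meas$rates[i, ]
    j <- match(row$metabolite, rmap$metabolite)
    pred <- fx$net[[rmap$reaction[j]]] * rmap$sign[j]
    ssr <- ssr + ((pred - row$rate) / row$sd)^2
  }
  expect_equal(o$ssr, ssr, tolerance = 1e-12)
})

test_that("fit is deterministic and multi-start SSR has the prefix property", {
  w <- make_noiseless_meas()
  cfg2 <- fit_config(n_starts = 2, seed = 99, max_iter = 40,
                     chain_restarts = 1, polish_top = 1, polish_budget = 80)
  f1 <- fit_fluxes(w$model, w$meas, w$frags, config = cfg2)
  f2 <- fit_fluxes(w$model, w$meas, w$frags, config = cfg2)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$ssr, f2$ssr)
  expect_identical(f1$start_ssr, f2$start_ssr)

  cfg4 <- fit_config(n_starts = 4, seed = 99, max_iter = 40,
                     chain_restarts = 1, polish_top = 1, polish_budget = 80)
  f4 <- fit_fluxes(w$model, w$meas, w$frags, config = cfg4)
  expect_identical(f4$start_ssr[1:2], f1$start_ssr)
  expect_lte(min(f4$start_ssr), min(f1$start_ssr))

  # every returned flux state satisfies the balance constraints
  S <- stoichiometric_matrix(w$model)
  expect_lt(max(abs(S %*% f4$flux$net[colnames(S)])), 1e-8)
  fd <- flux_directions(w$model, f4$flux)
  expect_true(all(fd$fwd >= 0) && all(fd$bwd >= 0))

  # identical config + seed serializes to byte-identical JSON
  p1 <- tempfile(); p2 <- tempfile()
  write_fit_json(f1, p1); write_fit_json(f2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("dof guard rejects under-determined measurement sets", {
  w <- make_noiseless_meas()
  tiny <- w$meas
  tiny$mids <- tiny$mids[1:2]
  expect_error(fit_fluxes(w$model, tiny, w$frags,
                          config = fit_config(n_starts = 1)),
               "not identifiable")
})

test_that("profile CI matches the analytic interval on a linear toy model", {
  # diamond network: two independent branch fluxes, three direct rate
  # measurements -> quadratic SSR with a closed-form covariance
  m <- diamond_model()
  sds <- c(v1 = 2, v2 = 3, v3 = 2.5)
  vals <- c(v1 = 10, v2 = 20, v3 = 11)
  mk_rates <- data.frame(metabolite = names(vals), rate = unname(vals),
                         sd = unname(sds))
  rmap <- data.frame(metabolite = c("v1", "v2", "v3"),
                     reaction = c("v1", "v2", "v3"), sign = c(1, 1, 1))
  cfg <- fit_config(n_starts = 5, seed = 2, polish_budget = 500)
  meas <- measurement_set(list(), mk_rates, "toy")
  fit <- fit_fluxes(m, meas, list(), tracer = tracer_spec("A.x", 1,
                      list(list(pattern = 1L, fraction = 1))),
                    config = cfg, rate_map = rmap)
  # v1 = v3 in the diamond, so the weighted mean of the two
  # measurements with SE = 1/sqrt(1/4 + 1/6.25)
  se <- 1 / sqrt(1 / sds[["v1"]]^2 + 1 / sds[["v3"]]^2)
  mu <- (vals[["v1"]] / sds[["v1"]]^2 + vals[["v3"]] / sds[["v3"]]^2) *
    se^2
  expect_equal(fit$flux$net[["v1"]], mu, tolerance = 1e-6)
  ci <- confidence_interval(fit, "v1")
  expect_equal(ci$upper - ci$value, 1.96 * se, tolerance = 0.02)
  expect_equal(ci$value - ci$lower, 1.96 * se, tolerance = 0.02)

  # a flux measured (essentially) directly: CI half-width ~ 1.96 sd
  ci2 <- confidence_interval(fit, "v2")
  expect_equal((ci2$upper - ci2$lower) / 2, 1.96 * sds[["v2"]],
               tolerance = 0.1 * 1.96 * sds[["v2"]])
})

test_that("compare_conditions flags disjoint CIs", {
  w <- make_noiseless_meas()
  cfg <- fit_config(n_starts = 1, max_iter = 5, chain_restarts = 0,
                    polish_top = 0)
  fa <- fit_fluxes(w$model, w$meas, w$frags, config = cfg)
  fb <- fa
  cmp0 <- compare_conditions(fa, fb)
  expect_true(all(cmp0$diff == 0))
  fa$ci <- data.frame(flux = "v_ldh", value = 1.5, lower = 1, upper = 2,
                      lower_at_bound = FALSE, upper_at_bound = FALSE)
  fb$ci <- data.frame(flux = "v_ldh", value = 3.5, lower = 3, upper = 4,
                      lower_at_bound = FALSE, upper_at_bound = FALSE)
  cmp <- compare_conditions(fa, fb)
  expect_true(cmp$distinguishable[cmp$flux == "v_ldh"])
  fb$ci$lower <- 1.8
  cmp <- compare_conditions(fa, fb)
  expect_false(cmp$distinguishable[cmp$flux == "v_ldh"])
})
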