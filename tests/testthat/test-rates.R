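# exchange_rates: integrated cell density and rate regression

test_that("integrated cell density matches closed forms", {
  const <- data.frame(time_h = c(0, 24), cells_e6 = c(2, 2))
  expect_equal(integrate_cell_density(const, 0, 24), 48, tolerance = 1e-12)

  dbl <- data.frame(time_h = c(0, 24), cells_e6 = c(1, 2))
  expect_equal(integrate_cell_density(dbl, 0, 24), 24 / log(2),
               tolerance = 1e-9)

  # piecewise curve vs adaptive quadrature of the same interpolant
  g <- data.frame(time_h = c(0, 6, 24), cells_e6 = c(0.5, 0.8, 1.9))
  interp <- function(t) {
    sapply(t, function(ti) {
      i <- findInterval(ti, g$time_h, rightmost.closed = TRUE)
      i <- min(i, nrow(g) - 1)
      mu <- (log(g$cells_e6[i + 1]) - log(g$cells_e6[i])) /
        (g$time_h[i + 1] - g$time_h[i])
      g$cells_e6[i] * exp(mu * (ti - g$time_h[i]))
    })
  }
  q <- stats::integrate(interp, 0, 24, rel.tol = 1e-11)$value
  expect_equal(integrate_cell_density(g, 0, 24), q, tolerance = 1e-9)
  expect_error(integrate_cell_density(g, 10, 5), "exceed")
  expect_error(integrate_cell_density(g, 0, 30), "range")
})

test_that("estimate_rate reproduces the worked example and sign convention", {
  growth <- data.frame(time_h = c(0, 24), cells_e6 = c(1, 1))
  media <- data.frame(replicate = 1, time_h = c(0, 24), conc_mM = c(20, 15),
                      volume_mL = 1)
  r <- estimate_rate(media, growth)
  expect_equal(r$rate, 5000 / 24, tolerance = 1e-9)   # ~208.33 uptake

  lact <- data.frame(replicate = 1, time_h = c(0, 24), conc_mM = c(0, 12),
                     volume_mL = 1)
  expect_lt(estimate_rate(lact, growth)$rate, 0)       # secretion
})

test_that("rate estimation is exactly linear in concentration scale", {
  growth <- data.frame(time_h = c(0, 6, 24), cells_e6 = c(0.5, 0.63, 1.26))
  media <- data.frame(replicate = 1, time_h = c(0, 6, 24),
                      conc_mM = c(20, 18.6, 13.1), volume_mL = 1)
  r1 <- estimate_rate(media, growth)$rate
  media$conc_mM <- media$conc_mM * 3.7
  expect_equal(estimate_rate(media, growth)$rate, 3.7 * r1,
               tolerance = 1e-12)
})

test_that("noiseless synthetic media recover the generating rates exactly", {
  sc <- make_scenario("WT-like", mid_sd = 0, conc_cv = 0, seed = 5)
  exp <- generate_experiment(sc)
  est <- estimate_rates(exp$media, exp$growth)
  truth <- scenario_true_rates(sc)
  for (i in seq_len(nrow(est))) {
    expect_lt(abs(est$rate[i] - truth[[est$metabolite[i]]]) /
                max(abs(truth[[est$metabolite[i]]]), 1e-12), 1e-9)
  }
})

test_that("noisy rates land within 3 SD of truth", {
  sc <- make_scenario("WT-like", conc_cv = 0.02, seed = 21)
  exp <- generate_experiment(sc)
  est <- estimate_rates(exp$media, exp$growth)
  truth <- scenario_true_rates(sc)
  for (i in seq_len(nrow(est))) {
    tv <- truth[[est$metabolite[i]]]
    expect_lt(abs(est$rate[i] - tv), 3 * est$sd[i] + 1e-9)
  }
})

test_that("medium-only control wells estimate a rate near zero", {
  growth <- data.frame(time_h = c(0, 6, 24), cells_e6 = c(0.5, 0.63, 1.26))
  set.seed(2)
  conc <- 10 + stats::rnorm(9, 0, 0.1)    # no consumption, pure noise
  media <- data.frame(replicate = rep(1:3, each = 3),
                      time_h = rep(c(0, 6, 24), 3),
                      conc_mM = conc, volume_mL = 1)
  r <- estimate_rate(media, growth)
  expect_lt(abs(r$rate), 4 * r$sd)
})
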