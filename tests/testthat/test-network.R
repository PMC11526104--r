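# network_model: parsing, validation, stoichiometry, free-flux basis

test_that("parse_model handles trivial reactions and atom maps", {
  m <- parse_model(c(
    "metabolite GLC.x carbons=6 balanced=no",
    "metabolite G6P.c carbons=6 balanced=yes",
    "metabolite G6P.x carbons=6 balanced=no",
    "tracer GLC.x",
    "v1: GLC.x (abcdef) -> G6P.c (abcdef)",
    "v2: G6P.c (abcdef) -> G6P.x (abcdef)"))
  expect_s3_class(m, "nm_model")
  expect_length(m$reactions, 2)
  expect_identical(m$reactions$v1$rhs[[1]]$atoms, "abcdef")
})

test_that("carbon conservation violations are rejected", {
  bad <- c(
    "metabolite A.x carbons=6 balanced=no",
    "metabolite B.c carbons=5 balanced=yes",
    "metabolite B.x carbons=5 balanced=no",
    "v1: A.x (abcdef) -> B.c (abcde)",
    "v2: B.c (abcde) -> B.x (abcde)")
  expect_error(parse_model(bad), "carbon-count mismatch")
  expect_error(parse_model(c(
    "metabolite A.x carbons=2 balanced=no",
    "metabolite B.x carbons=2 balanced=no",
    "v1: A.x (aa) -> B.x (aa)")), "twice")
})

test_that("parser reports malformed input with line context", {
  expect_error(parse_model("garbage line here"), "line 1")
  expect_error(parse_model(c(
    "metabolite A.x carbons=1 balanced=no",
    "v1: A.x (a) -> A.x (a)",
    "v1: A.x (a) -> A.x (a)")), "duplicate reaction id")
})

test_that("the bundled T-cell model parses with all measured species", {
  m <- tcell_model()
  # the eleven fitted metabolites, each housed in >= 1 compartment
  species <- c("PYR", "LAC", "ALA", "MAL", "ASP", "GLU", "GLN", "CIT",
               "G3P", "PEP", "PG3")
  for (sp in species)
    expect_true(any(species_of(m$metabolites$id) == sp), info = sp)
  # every measured pool reachable from the tracer through atom maps
  reach <- reachable_from(m, "GLC.x")
  expect_true(all(measured_metabolites() %in% reach))
  # dual-compartment pools exist for the six named metabolites
  for (sp in c("PYR", "CIT", "MAL", "ALA", "GLU", "ASP")) {
    expect_true(paste0(sp, ".c") %in% m$metabolites$id, info = sp)
    expect_true(paste0(sp, ".m") %in% m$metabolites$id, info = sp)
  }
})

test_that("stoichiometric_matrix matches hand-computed examples", {
  m <- parse_model(c(
    "metabolite A.x carbons=1 balanced=yes",
    "metabolite B.c carbons=1 balanced=yes",
    "v1: A.x (a) -> B.c (a) reversible"))
  S <- stoichiometric_matrix(m)
  expect_equal(unname(S[, "v1"]), c(-1, 1))

  chain <- chain3_model()
  S <- stoichiometric_matrix(chain)
  expect_equal(dim(S), c(2L, 3L))
  expect_equal(unname(S["B.c", ]), c(1, -1, 0))
})

test_that("free_flux_basis finds the null space deterministically", {
  chain <- chain3_model()
  fb <- free_flux_basis(chain)
  expect_length(fb$free, 1)
  v <- as.vector(fb$N %*% 5)
  expect_equal(unname(v), c(5, 5, 5))

  fb2 <- free_flux_basis(diamond_model())
  expect_length(fb2$free, 2)

  m <- tcell_model()
  S <- stoichiometric_matrix(m)
  fb3 <- free_flux_basis(m)
  # independent rank oracles: SVD and exact integer (Bareiss) elimination
  sv <- svd(S)$d
  rank_svd <- sum(sv > 1e-9 * sv[1])
  rank_exact <- bareiss_rank(S)
  expect_identical(rank_svd, rank_exact)
  expect_length(fb3$free, ncol(S) - rank_exact)
  # property: ||S N x||_inf tiny for random free vectors
  set.seed(42)
  for (i in 1:20) {
    x <- stats::runif(length(fb3$free), -500, 500)
    expect_lt(max(abs(S %*% (fb3$N %*% x))), 1e-10 * max(1, max(abs(x))))
  }
})

test_that("serialize -> parse round-trips to an identical model", {
  m <- tcell_model()
  txt <- serialize_model(m)
  m2 <- parse_model(strsplit(txt, "\n")[[1]],
                    measured = measured_metabolites())
  expect_identical(serialize_model(m2), txt)
  # canonical ordering: metabolites and reactions sorted
  expect_identical(sort(names(m2$reactions)), names(m2$reactions))
})

test_that("flux_state enforces balance and bounds", {
  m <- tcell_model()
  wt <- preset_flux_state("WT-like", m)
  S <- stoichiometric_matrix(m)
  expect_lt(max(abs(S %*% wt$net[colnames(S)])), 1e-9)
  bad <- wt$net; bad["v_pdh"] <- bad["v_pdh"] + 7
  expect_error(flux_state(m, bad), "steady-state balance")
  expect_error(flux_state(m, wt$net, c(v_ldh = -1)), ">= 0")
  expect_error(flux_state(m, wt$net, mixing = c(PYR = 1.4)), "\\[0, 1\\]")
  expect_error(flux_state(m, wt$net, mixing = c(BOGUS = 0.5)), "unknown")
  # forward/backward decomposition is non-negative
  fd <- flux_directions(m, wt)
  expect_true(all(fd$fwd >= 0) && all(fd$bwd >= 0))
})

test_that("balanced metabolites need producers and consumers", {
  expect_error(parse_model(c(
    "metabolite A.x carbons=1 balanced=no",
    "metabolite B.c carbons=1 balanced=yes",
    "v1: A.x (a) -> B.c (a)")), "lacks a producing or consuming")
})
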