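#' The bundled T-cell central-carbon network model
#'
#' Parses and validates the reconstruction shipped in
#' `inst/extdata/tcell_network.txt`, checking that all eleven measured
#' metabolites (pyruvate, lactate, alanine, malate, aspartate,
#' glutamate, glutamine, citrate, glycerol-3-phosphate, PEP,
#' 3-phosphoglycerate) are reachable from the glucose tracer.
#'
#' @return an `nm_model`
#' @export
tcell_model <- function() {
  path <- system.file("extdata", "tcell_network.txt", package = "tcellflux",
                      mustWork = TRUE)
  parse_model(readLines(path), measured = measured_metabolites())
}

#' Model ids of the measured metabolite pools
#' @export
measured_metabolites <- function() {
  c("PYR.obs", "LAC.c", "ALA.obs", "MAL.obs", "ASP.obs", "GLU.obs",
    "GLN.c", "CIT.obs", "G3P.c", "PEP.c", "PG3.c")
}

#' Map from measured exchange-rate metabolites to model reactions
#'
#' Signs translate the uptake-positive rate convention into the model's
#' flux directions: glucose, glutamine and pyruvate uptake drive their
#' import reactions forward, lactate secretion (a negative rate) drives
#' `v_lacs` forward.
#' @return data.frame with columns metabolite, reaction, sign
#' @export
rate_reaction_map <- function() {
  data.frame(
    metabolite = c("GLC", "GLN", "PYR", "LAC"),
    reaction = c("v_glut", "v_glnup", "v_pyrx", "v_lacs"),
    sign = c(1, 1, 1, -1),
    stringsAsFactors = FALSE)
}

# hand-balanced net-flux vectors for the two preset regimes
preset_net_fluxes <- function(preset) {
  wt <- c(
    v_glut = 360, v_pgi = 360, v_pfk = 360, v_ald = 360, v_tpi = 360,
    v_gapd = 720, v_eno = 720, v_pyk = 720,
    v_ldh = 630, v_lacs = 630, v_alat_c = 15, v_alat_m = 0, v_alas = 15,
    v_pyrx = 10, v_pyrt = 85, v_pdh = 95, v_pc = 10, v_me = 20,
    v_cs = 95, v_idh = 80, v_akgd = 100, v_sdh = 100, v_fum = 100,
    v_mdh = 90, v_got_m = 5, v_glnup = 50, v_glnase = 50, v_glut_t = 20,
    v_gdh = -20, v_glus = 30, v_cit_t = 15, v_acl = 15, v_lip = 15,
    v_mdh_c = 10, v_mal_t = 10, v_got_c = 5, v_asp_t = 5, v_asps = 10,
    v_co2x = -285)
  ko <- c(
    v_glut = 120, v_pgi = 120, v_pfk = 120, v_ald = 120, v_tpi = 120,
    v_gapd = 240, v_eno = 240, v_pyk = 240,
    v_ldh = 125, v_lacs = 125, v_alat_c = 15, v_alat_m = 0, v_alas = 15,
    v_pyrx = 40, v_pyrt = 140, v_pdh = 190, v_pc = 5, v_me = 55,
    v_cs = 190, v_idh = 175, v_akgd = 235, v_sdh = 235, v_fum = 235,
    v_mdh = 190, v_got_m = 5, v_glnup = 90, v_glnase = 90, v_glut_t = 60,
    v_gdh = -60, v_glus = 30, v_cit_t = 15, v_acl = 15, v_lip = 15,
    v_mdh_c = 10, v_mal_t = 10, v_got_c = 5, v_asp_t = 5, v_asps = 10,
    v_co2x = -650)
  switch(preset, "WT-like" = wt, "KO-like" = ko,
         stop_tcf("unknown preset: ", preset))
}

#' Ground-truth flux states for the two synthetic regimes
#'
#' `"WT-like"` is glycolysis-high (high glucose uptake and lactate
#' secretion), `"KO-like"` is OxPhos-high (high PDH/TCA flux, elevated
#' glutamine and pyruvate uptake), mirroring the qualitative contrast
#' between wild-type and HIF1a-deficient hypoxic T cells.  Magnitudes
#' are order-of-magnitude realistic choices for activated T cells, not
#' reproductions of any published flux map.
#'
#' @param preset `"WT-like"` or `"KO-like"`
#' @param model the network model (defaults to [tcell_model()])
#' @return an `nm_fluxstate`
#' @export
preset_flux_state <- function(preset, model = tcell_model()) {
  exchange <- c(
    v_ldh = 100, v_pyrx = 20, v_pyrt = 50, v_alat_c = 20, v_alat_m = 20,
    v_fum = 150, v_mdh = 100, v_got_m = 50, v_gdh = 50, v_glnase = 10,
    v_glut_t = 30, v_got_c = 20, v_co2x = 50)
  mixing <- c(PYR = 0.6, ALA = 0.55, MAL = 0.5, ASP = 0.5, GLU = 0.45,
              CIT = 0.5)
  flux_state(model, preset_net_fluxes(preset), exchange, mixing)
}

#' Read a GC-MS fragment library from TSV
#'
#' Columns: `fragment_id`, `metabolite`, `atoms` (comma-separated
#' 1-based carbon indices), `formula` (derivatized ion formula whose C
#' count includes the skeleton carbons).
#'
#' @param path TSV file; defaults to the bundled library
#' @param model optional model used to check metabolite ids/atoms
#' @return named list of fragment definitions
#' @export
read_fragment_library <- function(path = NULL, model = NULL) {
  path <- path %||% system.file("extdata", "fragments.tsv",
                                package = "tcellflux", mustWork = TRUE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("fragment_id", "metabolite", "atoms", "formula")
  if (!all(need %in% names(df)))
    stop_tcf("fragment library must have columns: ",
             paste(need, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(df))) {
    out[[df$fragment_id[i]]] <- fragment_def(
      df$fragment_id[i], df$metabolite[i],
      as.integer(strsplit(df$atoms[i], ",")[[1]]), df$formula[i],
      model = model)
  }
  out
}

#' Default fragment library for the bundled model
#' @return named list of fragment definitions
#' @export
default_fragment_library <- function() {
  read_fragment_library(model = tcell_model())
}
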