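#' @title Compartmentalized metabolic network models
#'
#' @description
#' A network model is a set of metabolites, each assigned to a
#' compartment by the suffix of its id (`.x` extracellular, `.c`
#' cytosol, `.m` mitochondrion, `.obs` extraction/measurement pool),
#' plus a list of reactions with carbon atom-transition maps.  Models
#' are written in a small line-oriented dialect:
#'
#' ```
#' # comment
#' metabolite GLC.x carbons=6 balanced=no
#' metabolite G6P.c carbons=6 balanced=yes
#' tracer GLC.x
#' v_glut: GLC.x (abcdef) -> G6P.c (abcdef)
#' v_ldh: PYR.c (abc) -> LAC.c (abc) reversible
#' v_akgd: AKG.m (abcde) -> CO2.m (a) + SUC.m (bcde|edcb)
#' m_pyr: PYR.c (abc) + PYR.m (abc) -> PYR.obs (abc) kind=mixing
#' ```
#'
#' Atom strings are lowercase letters, left to right = carbon 1..n; the
#' same letter on both sides of the arrow identifies one carbon.  `|`
#' separates equally weighted atom-map variants (used for the
#' rotational symmetry of succinate/fumarate).  `kind=mixing` marks the
#' flux-free extraction-mixing pseudo-reactions that blend cytosolic
#' and mitochondrial pools of one chemical species into a `.obs`
#' measurement pool; `kind=dilution` tags exchanges with unlabeled
#' extracellular material (CO2, pyruvate).
#'
#' @name network-model
NULL

COMPARTMENTS <- c(x = "extracellular", c = "cytosol", m = "mitochondrion",
                  obs = "observation")

compartment_of <- function(id) {
  sfx <- sub("^.*\\.", "", id)
  cmp <- COMPARTMENTS[sfx]
  if (any(is.na(cmp)))
    stop_tcf("metabolite id without a valid compartment suffix: ",
             paste(id[is.na(cmp)], collapse = ", "))
  unname(cmp)
}

#' The chemical species name of a compartmented metabolite id
#' @param id metabolite id such as "PYR.c"
#' @return the id without its compartment suffix, e.g. "PYR"
#' @export
species_of <- function(id) sub("\\.[a-z]+$", "", id)

parse_side <- function(txt, line_no) {
  terms <- strsplit(txt, "+", fixed = TRUE)[[1]]
  out <- list()
  for (tm in terms) {
    tm <- trimws(tm)
    m <- regmatches(tm, regexec(
      "^(?:([0-9]+)\\s+)?([A-Za-z0-9_]+\\.[a-z]+)\\s*(?:\\(([a-z|]*)\\))?$",
      tm))[[1]]
    if (length(m) == 0L)
      stop_tcf("line ", line_no, ": cannot parse reaction term '", tm, "'")
    coef <- if (nzchar(m[2])) as.integer(m[2]) else 1L
    atoms <- if (nzchar(m[4])) strsplit(m[4], "|", fixed = TRUE)[[1]] else ""
    out[[length(out) + 1L]] <- list(species = m[3], coef = coef, atoms = atoms)
  }
  out
}

#' Parse a metabolic network model from text
#'
#' @param text model source, a single string or character vector of lines.
#' @param measured optional metabolite ids that must be reachable from
#'   the tracer through atom-transition maps (validation of
#'   measurability); `.obs` pools are always checked.
#' @return a validated `nm_model` object.
#' @seealso [serialize_model()], [tcell_model()]
#' @export
parse_model <- function(text, measured = character()) {
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- sub("#.*$", "", text)
  mets <- list(); rxns <- list(); tracer <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("^(met|metabolite)\\s", ln)) {
      m <- regmatches(ln, regexec(
        "^(?:met|metabolite)\\s+([A-Za-z0-9_]+\\.[a-z]+)\\s+carbons=([0-9]+)\\s+balanced=(yes|no)\\s*$",
        ln))[[1]]
      if (length(m) == 0L)
        stop_tcf("line ", i, ": malformed metabolite declaration: ", ln)
      if (m[2] %in% vapply(mets, `[[`, "", "id"))
        stop_tcf("line ", i, ": duplicate metabolite id ", m[2])
      mets[[length(mets) + 1L]] <- list(
        id = m[2], n_carbons = as.integer(m[3]), balanced = m[4] == "yes")
    } else if (grepl("^tracer\\s", ln)) {
      tracer <- trimws(sub("^tracer", "", ln))
    } else if (grepl(":", ln, fixed = TRUE)) {
      id <- trimws(sub(":.*$", "", ln))
      body <- trimws(sub("^[^:]*:", "", ln))
      reversible <- grepl("\\breversible\\b", body)
      body <- sub("\\breversible\\b", "", body)
      kind <- "chemical"
      km <- regmatches(body, regexec("kind=([a-z-]+)", body))[[1]]
      if (length(km)) { kind <- km[2]; body <- sub("kind=[a-z-]+", "", body) }
      sides <- strsplit(body, "->", fixed = TRUE)[[1]]
      if (length(sides) != 2L)
        stop_tcf("line ", i, ": reaction must contain exactly one '->'")
      if (id %in% names(rxns))
        stop_tcf("line ", i, ": duplicate reaction id ", id)
      rxns[[id]] <- list(
        id = id, reversible = reversible, kind = kind,
        lhs = parse_side(sides[1], i), rhs = parse_side(sides[2], i),
        line = i)
    } else {
      stop_tcf("line ", i, ": unrecognized statement: ", ln)
    }
  }
  met_df <- data.frame(
    id = vapply(mets, `[[`, "", "id"),
    n_carbons = vapply(mets, `[[`, 0L, "n_carbons"),
    balanced = vapply(mets, `[[`, TRUE, "balanced"),
    stringsAsFactors = FALSE)
  met_df$compartment <- compartment_of(met_df$id)
  model <- structure(
    list(metabolites = met_df, reactions = rxns,
         tracer_species = tracer %||% NA_character_),
    class = "nm_model")
  validate_model(model, measured = measured)
  model
}

# normalize variant lists so every species carries the same number of
# equally weighted atom-map variants
reaction_variants <- function(rxn) {
  ks <- vapply(c(rxn$lhs, rxn$rhs), function(t) length(t$atoms), 0L)
  k <- max(ks)
  if (!all(ks %in% c(1L, k)))
    stop_tcf("reaction ", rxn$id, ": inconsistent atom-map variant counts")
  k
}

atoms_of <- function(term, v) {
  a <- term$atoms
  if (length(a) == 1L) a[1] else a[v]
}

#' Validate a parsed model (invariants and carbon bookkeeping)
#' @param model an `nm_model`
#' @param measured ids whose tracer reachability is enforced
#' @return the model, invisibly
#' @export
validate_model <- function(model, measured = character()) {
  md <- model$metabolites
  stopifnot(!anyDuplicated(md$id), all(md$n_carbons >= 0))
  nc <- stats::setNames(md$n_carbons, md$id)
  for (rxn in model$reactions) {
    k <- reaction_variants(rxn)
    for (t in c(rxn$lhs, rxn$rhs)) {
      if (!t$species %in% md$id)
        stop_tcf("reaction ", rxn$id, ": undeclared metabolite ", t$species)
      if (t$coef != 1L && any(nzchar(t$atoms)))
        stop_tcf("reaction ", rxn$id,
                 ": stoichiometric coefficients other than 1 are not",
                 " supported for atom-mapped species")
      for (a in t$atoms)
        if (nchar(a) != nc[[t$species]])
          stop_tcf("reaction ", rxn$id, ": atom string '", a, "' does not",
                   " match the ", nc[[t$species]], " carbons of ", t$species)
    }
    if (rxn$kind == "measurement-pool") {
      if (length(rxn$lhs) != 1L || length(rxn$rhs) != 1L)
        stop_tcf("measurement-pool reaction ", rxn$id,
                 " must have one reactant and one product")
      if (is_balanced(model, rxn$rhs[[1]]$species))
        stop_tcf("measurement-pool product ", rxn$rhs[[1]]$species,
                 " must be unbalanced (it carries no flux)")
    }
    if (rxn$kind == "mixing") {
      if (length(rxn$lhs) != 2L || length(rxn$rhs) != 1L)
        stop_tcf("mixing reaction ", rxn$id,
                 " must have exactly two reactants and one product")
      sp <- vapply(rxn$lhs, `[[`, "", "species")
      if (species_of(sp[1]) != species_of(sp[2]) ||
          species_of(sp[1]) != species_of(rxn$rhs[[1]]$species))
        stop_tcf("mixing reaction ", rxn$id,
                 " must blend two pools of one chemical species")
      if (compartment_of(rxn$rhs[[1]]$species) != "observation")
        stop_tcf("mixing reaction ", rxn$id,
                 " must produce a .obs measurement pool")
      next  # mixing is a weighted average, not a mass flow
    }
    for (v in seq_len(k)) {
      la <- unlist(strsplit(vapply(rxn$lhs, atoms_of, "", v), ""))
      ra <- unlist(strsplit(vapply(rxn$rhs, atoms_of, "", v), ""))
      if (anyDuplicated(la) || anyDuplicated(ra))
        stop_tcf("reaction ", rxn$id, ": atom label used twice on one side")
      if (!identical(sort(la), sort(ra)))
        stop_tcf("reaction ", rxn$id, ": carbon-count mismatch (",
                 length(la), " reactant vs ", length(ra),
                 " product carbons, labels must match)")
    }
  }
  # every balanced metabolite needs structural producers and consumers
  for (id in md$id[md$balanced]) {
    prod <- cons <- FALSE
    for (rxn in model$reactions) {
      if (rxn$kind %in% c("mixing", "measurement-pool")) next
      inl <- id %in% vapply(rxn$lhs, `[[`, "", "species")
      inr <- id %in% vapply(rxn$rhs, `[[`, "", "species")
      if (inr || (inl && rxn$reversible)) prod <- TRUE
      if (inl || (inr && rxn$reversible)) cons <- TRUE
    }
    if (!prod || !cons)
      stop_tcf("balanced metabolite ", id,
               " lacks a producing or consuming reaction")
  }
  if (!is.na(model$tracer_species)) {
    if (!model$tracer_species %in% md$id)
      stop_tcf("tracer species ", model$tracer_species, " is not declared")
    obs <- md$id[md$compartment == "observation"]
    need <- union(measured, obs)
    reach <- reachable_from(model, model$tracer_species)
    miss <- setdiff(need, reach)
    if (length(miss))
      stop_tcf("measured metabolite(s) unreachable from tracer: ",
               paste(miss, collapse = ", "))
  }
  invisible(model)
}

#' Metabolites reachable from `start` through atom-transition maps
#'
#' Edges follow carbon flow in the forward direction of every reaction,
#' the backward direction of reversible reactions, and through mixing
#' pseudo-reactions.
#' @param model an `nm_model`
#' @param start metabolite id
#' @return character vector of reachable metabolite ids (includes start)
#' @export
reachable_from <- function(model, start) {
  edges <- list()
  for (rxn in model$reactions) {
    ls <- vapply(rxn$lhs, `[[`, "", "species")
    rs <- vapply(rxn$rhs, `[[`, "", "species")
    for (a in ls) for (b in rs) {
      edges[[length(edges) + 1L]] <- c(a, b)
      if (rxn$reversible) edges[[length(edges) + 1L]] <- c(b, a)
    }
  }
  from <- vapply(edges, `[`, "", 1); to <- vapply(edges, `[`, "", 2)
  seen <- start; frontier <- start
  while (length(frontier)) {
    nxt <- setdiff(unique(to[from %in% frontier]), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  seen
}

#' Serialize a model to its text dialect in canonical order
#'
#' Metabolites and reactions are sorted by id so that
#' parse -> serialize -> parse round-trips to an identical model.
#' @param model an `nm_model`
#' @return a character scalar (the model file content)
#' @export
serialize_model <- function(model) {
  md <- model$metabolites[order(model$metabolites$id), ]
  out <- c("# network model (canonical serialization)",
           sprintf("metabolite %s carbons=%d balanced=%s",
                   md$id, md$n_carbons, ifelse(md$balanced, "yes", "no")))
  if (!is.na(model$tracer_species))
    out <- c(out, paste("tracer", model$tracer_species))
  fmt_side <- function(side) paste(vapply(side, function(t) {
    at <- paste(t$atoms, collapse = "|")
    if (nzchar(at)) sprintf("%s (%s)", t$species, at) else t$species
  }, ""), collapse = " + ")
  for (id in sort(names(model$reactions))) {
    r <- model$reactions[[id]]
    ln <- sprintf("%s: %s -> %s", r$id, fmt_side(r$lhs), fmt_side(r$rhs))
    if (r$reversible) ln <- paste(ln, "reversible")
    if (r$kind != "chemical") ln <- paste0(ln, " kind=", r$kind)
    out <- c(out, ln)
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' @export
print.nm_model <- function(x, ...) {
  cat(sprintf("<nm_model> %d metabolites (%d balanced), %d reactions\n",
              nrow(x$metabolites), sum(x$metabolites$balanced),
              length(x$reactions)))
  cat("  tracer:", x$tracer_species, "\n")
  invisible(x)
}

#' Carbon counts of metabolites
#' @param model an `nm_model`
#' @param id metabolite id(s)
#' @return integer vector of carbon counts
#' @export
n_carbons_of <- function(model, id) {
  i <- match(id, model$metabolites$id)
  if (any(is.na(i))) stop_tcf("unknown metabolite: ",
                              paste(id[is.na(i)], collapse = ", "))
  model$metabolites$n_carbons[i]
}

is_balanced <- function(model, id) {
  model$metabolites$balanced[match(id, model$metabolites$id)]
}
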