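#' Write a fit result to JSON
#'
#' Deterministic (full-precision, no timestamps): identical fits
#' serialize to byte-identical files.
#'
#' @param fit an `nm_fit`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fit_json <- function(fit, path) {
  ci <- fit$ci
  fluxes <- lapply(names(fit$flux$net), function(id) {
    entry <- list(net = fit$flux$net[[id]])
    if (id %in% names(fit$flux$exchange))
      entry$exchange <- fit$flux$exchange[[id]]
    if (!is.null(ci) && id %in% ci$flux) {
      row <- ci[ci$flux == id, ]
      entry$ci_lower <- row$lower
      entry$ci_upper <- row$upper
      entry$ci_lower_at_bound <- row$lower_at_bound
      entry$ci_upper_at_bound <- row$upper_at_bound
    }
    entry
  })
  names(fluxes) <- names(fit$flux$net)
  out <- list(
    condition = fit$condition,
    ssr = fit$ssr, dof = fit$dof,
    chi2_lo = fit$chi2_lo, chi2_hi = fit$chi2_hi, passed = fit$passed,
    n_starts = length(fit$start_ssr), best_start = fit$best_start,
    seed = fit$config$seed,
    fluxes = fluxes,
    mixing = as.list(fit$flux$mixing),
    start_ssr = fit$start_ssr,
    residuals = fit$residuals)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a fit-result JSON back into a summary list
#' @param path file written by [write_fit_json()]
#' @export
read_fit_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Export a flux map as a DOT graph
#'
#' One edge per flux-carrying reaction, labeled with its net flux
#' (and, for measured comparisons, sized by magnitude); bilinear
#' reactions are routed through a small junction node.
#'
#' @param model an `nm_model`
#' @param flux an `nm_fluxstate`
#' @param path optional output file
#' @return the DOT text, invisibly if written to `path`
#' @export
flux_map_dot <- function(model, flux, path = NULL) {
  lines <- c("digraph fluxmap {", "  rankdir=LR;",
             "  node [shape=box, fontsize=10];")
  maxv <- max(abs(flux$net), 1e-9)
  for (id in names(flux$net)) {
    r <- model$reactions[[id]]
    v <- flux$net[[id]]
    w <- 0.5 + 4 * abs(v) / maxv
    lab <- sprintf("%s\\n%.1f", id, v)
    ls <- vapply(r$lhs, `[[`, "", "species")
    rs <- vapply(r$rhs, `[[`, "", "species")
    if (length(ls) == 1L && length(rs) == 1L) {
      lines <- c(lines, sprintf(
        "  \"%s\" -> \"%s\" [label=\"%s\", penwidth=%.2f%s];",
        ls, rs, lab, w, if (r$reversible) ", dir=both" else ""))
    } else {
      j <- paste0("j_", id)
      lines <- c(lines, sprintf("  \"%s\" [shape=point];", j))
      for (a in ls) lines <- c(lines, sprintf(
        "  \"%s\" -> \"%s\" [penwidth=%.2f];", a, j, w))
      for (b in rs) lines <- c(lines, sprintf(
        "  \"%s\" -> \"%s\" [label=\"%s\", penwidth=%.2f];", j, b, lab, w))
    }
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Export the EMU dependency graph as DOT (debugging aid)
#' @param system an `nm_emusystem`
#' @param path optional output file
#' @export
emu_graph_dot <- function(system, path = NULL) {
  lines <- c("digraph emu {", "  node [fontsize=9];")
  for (lev in system$levels) {
    for (key in lev$keys)
      lines <- c(lines, sprintf("  \"%s\" [label=\"%s (L%d)\"];",
                                key, key, lev$size))
  }
  for (lev in system$levels) {
    for (kk in seq_along(lev$bi)) {
      kn <- lev$knowns[[lev$bsrc[kk]]]
      src <- if (kn$kind == "input") kn$id else kn$id
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\";", src,
                                lev$keys[lev$bi[kk]]))
    }
    same <- lev$ti != lev$tj
    for (q in which(same))
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\";",
                                lev$keys[lev$tj[q]], lev$keys[lev$ti[q]]))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}
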