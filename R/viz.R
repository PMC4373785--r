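#' Specification of a hypergraph plot
#'
#' @param reaction_ids Reactions to draw as hyperedges.
#' @param metabolite_ids Metabolites to draw; metabolites of a drawn
#'   reaction that are omitted here are silently not drawn (cofactors are
#'   typically left out for readability).
#' @param layout `"layered"` (substrates above products, the default) or
#'   `"force"`.
#' @param width_scale Edge width in points per mmol/min of flux.
#' @param min_width Minimum edge width in points, so zero fluxes stay
#'   visible.
#' @return An object of class `"plot_spec"`.
#' @export
plot_spec <- function(reaction_ids, metabolite_ids,
                      layout = c("layered", "force"),
                      width_scale = 20, min_width = 0.5) {
  layout <- match.arg(layout)
  stopifnot(width_scale > 0, min_width >= 0)
  structure(list(reaction_ids = reaction_ids, metabolite_ids = metabolite_ids,
                 layout = layout, width_scale = width_scale,
                 min_width = min_width),
            class = "plot_spec")
}

#' Render a metabolic sub-network as an SVG hypergraph
#'
#' Draws the selected metabolites as boxes and each selected reaction as a
#' hyperedge connecting its drawn substrates to its drawn products. Edge
#' width is proportional to the absolute flux
#' (`max(min_width, width_scale * |flux|)`); the arrowhead points in the
#' direction of net flux; reactions carrying negative flux (running in
#' reverse relative to their forward definition) are drawn in red and
#' their value printed as negative. Labels show the reaction id with the
#' flux rounded to two decimals.
#'
#' @param model A [metabolic_model()].
#' @param fluxes Named numeric vector or `flux_vector` with values for the
#'   drawn reactions.
#' @param spec A [plot_spec()].
#' @param path Output SVG path.
#' @return The path, invisibly.
#' @export
render_hypergraph <- function(model, fluxes, spec, path) {
  stopifnot(inherits(model, "metabolic_model"), inherits(spec, "plot_spec"))
  if (inherits(fluxes, "flux_vector")) fluxes <- fluxes$values
  rids <- intersect(spec$reaction_ids, reaction_ids(model))
  mids <- intersect(spec$metabolite_ids, metabolite_ids(model))
  drawable <- Filter(function(rid) {
    st <- model$reactions[[rid]]$stoichiometry
    any(names(st) %in% mids)
  }, rids)
  if (!length(drawable) || !length(mids))
    stop("nothing to draw: no selected reaction references a selected metabolite")
  missing <- setdiff(drawable, names(fluxes))
  if (length(missing))
    stop("fluxes undefined for drawn reaction(s): ", paste(missing, collapse = ", "))

  pos <- layout_metabolites(model, drawable, mids, spec$layout)

  svg <- xml2::xml_new_root("svg", xmlns = "http://www.w3.org/2000/svg",
                            width = "800", height = as.character(max(pos$y) + 80),
                            viewBox = paste(0, 0, 800, max(pos$y) + 80))
  for (k in seq_along(drawable)) {
    rid <- drawable[k]
    v <- unname(fluxes[[rid]])
    st <- model$reactions[[rid]]$stoichiometry
    subs <- intersect(names(st)[st < 0], mids)
    prods <- intersect(names(st)[st > 0], mids)
    if (v < 0) { tmp <- subs; subs <- prods; prods <- tmp }  # arrow follows net flux
    width <- max(spec$min_width, spec$width_scale * abs(v))
    color <- if (v < 0) "red" else "black"
    jx <- mean(pos$x[c(subs, prods)]) + 60
    jy <- mean(pos$y[c(subs, prods)])
    grp <- xml2::xml_add_child(svg, "g", id = rid, class = "hyperedge")
    for (s in subs)
      xml2::xml_add_child(grp, "line",
        x1 = fmt(pos$x[s] + 50), y1 = fmt(pos$y[s]),
        x2 = fmt(jx), y2 = fmt(jy),
        stroke = color, "stroke-width" = fmt(width))
    for (p in prods) {
      ln <- xml2::xml_add_child(grp, "line",
        x1 = fmt(jx), y1 = fmt(jy),
        x2 = fmt(pos$x[p] + 50), y2 = fmt(pos$y[p]),
        stroke = color, "stroke-width" = fmt(width),
        class = "arrowhead")
      add_arrowhead(grp, jx, jy, pos$x[p] + 50, pos$y[p], color, width)
    }
    xml2::xml_add_child(grp, "text",
      x = fmt(jx + 6), y = fmt(jy - 4),
      "font-size" = "10", fill = color,
      paste0(rid, " ", sprintf("%.2f", v)))
  }
  for (mid in mids) {
    grp <- xml2::xml_add_child(svg, "g", class = "metabolite")
    xml2::xml_add_child(grp, "rect",
      x = fmt(pos$x[mid] - 50), y = fmt(pos$y[mid] - 12),
      width = "100", height = "24", fill = "#d3d3d3", stroke = "black")
    xml2::xml_add_child(grp, "text",
      x = fmt(pos$x[mid]), y = fmt(pos$y[mid] + 4),
      "text-anchor" = "middle", "font-size" = "10", mid)
  }
  xml2::write_xml(svg, path)
  invisible(path)
}

fmt <- function(x) format(x, digits = 8, trim = TRUE)

add_arrowhead <- function(grp, x1, y1, x2, y2, color, width) {
  dx <- x2 - x1; dy <- y2 - y1
  len <- sqrt(dx^2 + dy^2); if (len == 0) return(invisible())
  ux <- dx / len; uy <- dy / len
  sz <- max(6, width * 1.5)
  bx <- x2 - ux * sz; by <- y2 - uy * sz
  px <- -uy; py <- ux
  pts <- sprintf("%s,%s %s,%s %s,%s", fmt(x2), fmt(y2),
                 fmt(bx + px * sz / 2), fmt(by + py * sz / 2),
                 fmt(bx - px * sz / 2), fmt(by - py * sz / 2))
  xml2::xml_add_child(grp, "polygon", points = pts, fill = color)
  invisible()
}

## Layered layout: rank metabolites by longest substrate-to-product path
## (substrates above products, matching the vertical pathway reading);
## "force" falls back to a deterministic circle with light spring
## relaxation, useful for non-hierarchical sub-networks.
layout_metabolites <- function(model, rids, mids, layout) {
  n <- length(mids)
  if (layout == "layered") {
    rank <- stats::setNames(rep(0L, n), mids)
    for (iter in seq_len(n + 1L)) {
      changed <- FALSE
      for (rid in rids) {
        st <- model$reactions[[rid]]$stoichiometry
        subs <- intersect(names(st)[st < 0], mids)
        prods <- intersect(names(st)[st > 0], mids)
        if (length(subs) && length(prods)) {
          need <- max(rank[subs]) + 1L
          low <- prods[rank[prods] < need]
          if (length(low)) { rank[low] <- need; changed <- TRUE }
        }
      }
      if (!changed) break
    }
    y <- 40 + rank * 70
    x <- numeric(n); names(x) <- mids
    for (rk in unique(rank)) {
      at <- names(rank)[rank == rk]
      x[at] <- 120 + seq(0, by = 180, length.out = length(at)) %% 600
    }
    return(list(x = x, y = stats::setNames(y, mids)))
  }
  ## force: deterministic circle start, a few repulsion sweeps
  theta <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  x <- 400 + 250 * cos(theta); y <- 300 + 220 * sin(theta)
  names(x) <- names(y) <- mids
  list(x = x, y = y + abs(min(y, 0)) + 40)
}
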