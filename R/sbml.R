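#' Read a metabolic model from SBML
#'
#' Imports an SBML Level 2 or Level 3 document into a [metabolic_model()].
#' One [reaction()] is created per SBML reaction, preserving document order;
#' the `reversible` flag is taken from the SBML attribute (default `TRUE`
#' per the SBML specifications). A species is treated as a boundary
#' metabolite when its `boundaryCondition` attribute is true or when its id
#' matches the boundary convention (id suffix `"_b"` by default, the BiGG
#' export convention).
#'
#' Gene associations are parsed from `GENE_ASSOCIATION:` (or
#' `GENE ASSOCIATION:`) lines in the reaction notes; pathway labels from
#' `SUBSYSTEM:` lines.
#'
#' @param path Path to an SBML file.
#' @param boundary_suffix Id suffix marking boundary species in addition to
#'   the `boundaryCondition` attribute. Set to `NULL` to rely on the
#'   attribute alone.
#' @param boundary_compartment Optional compartment id whose species are all
#'   treated as boundary.
#' @return A [metabolic_model()].
#' @export
read_sbml <- function(path, boundary_suffix = "_b", boundary_compartment = NULL) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse failure in '", path, "': ", conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, "./model")
  if (inherits(mdl, "xml_missing"))
    stop("SBML parse failure in '", path, "': no <model> element", call. = FALSE)

  sp_nodes <- xml2::xml_find_all(mdl, ".//listOfSpecies/species")
  mets <- lapply(sp_nodes, function(s) {
    id <- xml2::xml_attr(s, "id")
    comp <- xml2::xml_attr(s, "compartment")
    bc <- identical(tolower(xml2::xml_attr(s, "boundaryCondition")), "true")
    if (!is.null(boundary_suffix) && nzchar(boundary_suffix))
      bc <- bc || endsWith(id, boundary_suffix)
    if (!is.null(boundary_compartment))
      bc <- bc || identical(comp, boundary_compartment)
    nm <- xml2::xml_attr(s, "name")
    metabolite(id, name = if (is.na(nm)) id else nm,
               compartment = if (is.na(comp)) "default" else comp,
               boundary = bc)
  })
  met_ids <- vapply(mets, `[[`, character(1), "id")

  rx_nodes <- xml2::xml_find_all(mdl, ".//listOfReactions/reaction")
  rxns <- lapply(rx_nodes, function(rx) {
    id <- xml2::xml_attr(rx, "id")
    rev_attr <- xml2::xml_attr(rx, "reversible")
    reversible <- is.na(rev_attr) || identical(tolower(rev_attr), "true")
    st <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(rx, paste0("./", side, "/speciesReference"))
      for (ref in refs) {
        sid <- xml2::xml_attr(ref, "species")
        if (!sid %in% met_ids)
          stop("integrity error in reaction ", id,
               ": species '", sid, "' referenced but not declared", call. = FALSE)
        coef <- suppressWarnings(as.numeric(xml2::xml_attr(ref, "stoichiometry")))
        if (is.na(coef)) coef <- 1
        st[sid] <- (if (sid %in% names(st)) st[[sid]] else 0) + sgn * coef
      }
    }
    note_nodes <- xml2::xml_find_all(rx, ".//notes//*[not(*)]")
    if (!length(note_nodes)) note_nodes <- xml2::xml_find_all(rx, ".//notes")
    notes <- paste(xml2::xml_text(note_nodes), collapse = "\n")
    ga <- extract_note_field(notes, "GENE[_ ]?ASSOCIATION")
    pw <- extract_note_field(notes, "SUBSYSTEM")
    nm <- xml2::xml_attr(rx, "name")
    reaction(id, stoichiometry = st, name = if (is.na(nm)) id else nm,
             reversible = reversible, gene_association = ga, pathway = pw)
  })
  mid <- xml2::xml_attr(mdl, "id")
  mname <- xml2::xml_attr(mdl, "name")
  metabolic_model(metabolites = mets, reactions = rxns,
                  id = if (is.na(mid)) "model" else mid,
                  name = if (is.na(mname)) "model" else mname)
}

extract_note_field <- function(notes, key) {
  m <- regmatches(notes, regexec(paste0(key, "\\s*:\\s*([^\n]*)"), notes,
                                 ignore.case = TRUE))[[1]]
  if (length(m) < 2 || !nzchar(trimws(m[2]))) NA_character_ else trimws(m[2])
}

#' Write a metabolic model as SBML Level 3 Version 1
#'
#' Emits a plain (package-free) SBML L3V1 document. Gene associations and
#' pathway labels are stored as `GENE_ASSOCIATION:` / `SUBSYSTEM:` lines in
#' XHTML reaction notes, the convention used by BiGG database exports, so
#' that [read_sbml()] round-trips the model.
#'
#' @param model A [metabolic_model()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_sbml <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = model$id, name = model$name)

  comps <- unique(vapply(model$metabolites, `[[`, character(1), "compartment"))
  if (length(comps)) {
    lc <- xml2::xml_add_child(mdl, "listOfCompartments")
    for (cp in comps)
      xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")
  }
  if (length(model$metabolites)) {
    ls <- xml2::xml_add_child(mdl, "listOfSpecies")
    for (m in model$metabolites)
      xml2::xml_add_child(ls, "species", id = m$id, name = m$name,
        compartment = m$compartment,
        boundaryCondition = if (m$boundary) "true" else "false",
        hasOnlySubstanceUnits = "false", constant = "false")
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rx <- xml2::xml_add_child(lr, "reaction", id = r$id, name = r$name,
      reversible = if (r$reversible) "true" else "false", fast = "false")
    note_lines <- character(0)
    if (!is.na(r$gene_association) && nzchar(r$gene_association))
      note_lines <- c(note_lines, paste0("GENE_ASSOCIATION: ", r$gene_association))
    if (!is.na(r$pathway) && nzchar(r$pathway))
      note_lines <- c(note_lines, paste0("SUBSYSTEM: ", r$pathway))
    if (length(note_lines)) {
      notes <- xml2::xml_add_child(rx, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      for (ln in note_lines) xml2::xml_add_child(body, "p", ln)
    }
    st <- r$stoichiometry
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      lrt <- xml2::xml_add_child(rx, "listOfReactants")
      for (sid in names(subs))
        xml2::xml_add_child(lrt, "speciesReference", species = sid,
                            stoichiometry = format(-subs[[sid]], digits = 15),
                            constant = "true")
    }
    if (length(prods)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (sid in names(prods))
        xml2::xml_add_child(lpr, "speciesReference", species = sid,
                            stoichiometry = format(prods[[sid]], digits = 15),
                            constant = "true")
    }
  }
  ok <- tryCatch({ xml2::write_xml(doc, path); TRUE },
                 error = function(e) stop("cannot write SBML to '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}
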