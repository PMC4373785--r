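#' Core model of human brain energy metabolism
#'
#' Builds the packaged model of central brain carbon and energy metabolism:
#' 71 reactions over 89 metabolites covering glycolysis, the pentose
#' phosphate pathway, the citric acid cycle, the malate-aspartate shuttle,
#' the glutamate/GABA shunt and oxidative phosphorylation, with Recon-1
#' style identifiers and gene-reaction associations. The reconstruction is
#' a synthetic transcription curated for this package: reaction content and
#' reversibility follow the standard biochemistry of these pathways, and
#' the network is calibrated so that flux balance analysis under the
#' packaged study constraints reproduces the published whole-brain ATP
#' budget (see the package vignette).
#'
#' Blood-side species and the cytosolic NADP/NADPH pair are boundary
#' metabolites: the latter because NADPH-consuming processes (biosynthesis,
#' glutathione turnover) are outside the model boundary.
#'
#' @return A [metabolic_model()] with pathway annotations.
#' @export
build_brain_model <- function() {
  mpath <- system.file("extdata", "brain_model_metabolites.tsv", package = "limfba")
  rpath <- system.file("extdata", "brain_model_reactions.tsv", package = "limfba")
  mdf <- utils::read.delim(mpath, stringsAsFactors = FALSE)
  rdf <- utils::read.delim(rpath, stringsAsFactors = FALSE)
  mets <- lapply(seq_len(nrow(mdf)), function(i)
    metabolite(mdf$id[i], name = mdf$name[i], compartment = mdf$compartment[i],
               boundary = identical(mdf$boundary[i], "true")))
  rxns <- lapply(seq_len(nrow(rdf)), function(i) {
    st <- parse_equation(rdf$equation[i])
    ga <- rdf$gene_association[i]
    reaction(rdf$id[i], stoichiometry = st, name = rdf$name[i],
             reversible = identical(rdf$reversible[i], "true"),
             gene_association = if (nzchar(ga)) ga else NA_character_,
             pathway = rdf$pathway[i])
  })
  metabolic_model(metabolites = mets, reactions = rxns,
                  id = "brain_core_metabolism",
                  name = "Core model of human brain energy metabolism")
}

## "2 M_a_c + M_b_c -> M_d_m" / "<->" reaction equation strings
parse_equation <- function(eq) {
  sides <- strsplit(eq, "<->|->")[[1]]
  if (length(sides) != 2L) stop("malformed equation: ", eq)
  st <- numeric(0)
  for (k in 1:2) {
    sgn <- if (k == 1L) -1 else 1
    terms <- strsplit(sides[k], "\\+")[[1]]
    for (term in terms) {
      term <- trimws(term)
      if (!nzchar(term)) next
      m <- regmatches(term, regexec("^([0-9.]+)\\s+(\\S+)$", term))[[1]]
      if (length(m) == 3L) { coef <- as.numeric(m[2]); id <- m[3] }
      else { coef <- 1; id <- term }
      st[id] <- (if (id %in% names(st)) st[[id]] else 0) + sgn * coef
    }
  }
  st
}

#' Measured study data for the brain model
#'
#' Whole-brain exchange-flux measurements (mmol/min, brain mass 1.4 kg) of
#' glucose, lactate and pyruvate with their standard deviations, and the
#' measured pathway fractions: pentose phosphate pathway flux as a fraction
#' of glycolysis (6.9%) and GABA shunt flux as a fraction of total glucose
#' oxidation (32%). Positive values are uptake, negative release.
#'
#' @return An object of class `"brain_study_data"`.
#' @export
brain_study_data <- function() {
  path <- system.file("extdata", "brain_study.json", package = "limfba")
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  ex <- js$exchange_fluxes
  structure(list(
    glucose_uptake = c(value = ex$R_GLCt1r$value, sd = ex$R_GLCt1r$sd),
    lactate_uptake = c(value = ex$R_L_LACt2r$value, sd = ex$R_L_LACt2r$sd),
    pyruvate_uptake = c(value = ex$R_PYRt2r$value, sd = ex$R_PYRt2r$sd),
    ppp_fraction = js$ppp_fraction,
    gaba_fraction = js$gaba_fraction,
    brain_mass_kg = js$brain_mass_kg,
    exchange_reactions = c(glucose = "R_GLCt1r", lactate = "R_L_LACt2r",
                           pyruvate = "R_PYRt2r"),
    g6pd_reaction = js$g6pd_reaction,
    gad_reaction = js$gad_reaction,
    g3pd_reaction = js$glycerol3p_dehydrogenase_reaction),
    class = "brain_study_data")
}

#' @export
print.brain_study_data <- function(x, ...) {
  cat("Brain study data (mmol/min, whole brain):\n")
  cat(sprintf("  glucose uptake  %6.3f +/- %.3f\n",
              x$glucose_uptake["value"], x$glucose_uptake["sd"]))
  cat(sprintf("  lactate uptake  %6.3f +/- %.3f\n",
              x$lactate_uptake["value"], x$lactate_uptake["sd"]))
  cat(sprintf("  pyruvate uptake %6.3f +/- %.3f\n",
              x$pyruvate_uptake["value"], x$pyruvate_uptake["sd"]))
  cat(sprintf("  PPP fraction %.3f, GABA-shunt fraction %.2f\n",
              x$ppp_fraction, x$gaba_fraction))
  invisible(x)
}

#' Pathway-fraction flux constraints
#'
#' Derives the fixed fluxes of glucose-6-phosphate dehydrogenase (entry
#' into the pentose phosphate pathway) and glutamate decarboxylase (entry
#' into the GABA shunt) as the measured fractions of glucose uptake,
#' rounded to three decimals (the precision at which the constraints are
#' applied).
#'
#' @param data A [brain_study_data()] object (or any list with
#'   `glucose_uptake`, `ppp_fraction`, `gaba_fraction`).
#' @return Named numeric vector with elements `g6pd` and `gad` (mmol/min).
#' @export
derive_fraction_constraints <- function(data = brain_study_data()) {
  glc <- unname(data$glucose_uptake["value"])
  c(g6pd = round(glc * data$ppp_fraction, 3),
    gad = round(glc * data$gaba_fraction, 3))
}

#' Fixed-flux constraint set of the healthy-brain FBA
#'
#' Combines the measured exchange fluxes (as exact equalities) with the
#' fraction-derived pathway constraints.
#'
#' @param data A [brain_study_data()] object.
#' @return Named numeric vector of fixed fluxes, mmol/min.
#' @export
brain_fixed_fluxes <- function(data = brain_study_data()) {
  fc <- derive_fraction_constraints(data)
  out <- c(unname(data$glucose_uptake["value"]),
           unname(data$lactate_uptake["value"]),
           unname(data$pyruvate_uptake["value"]),
           unname(fc["g6pd"]), unname(fc["gad"]))
  names(out) <- c(data$exchange_reactions[["glucose"]],
                  data$exchange_reactions[["lactate"]],
                  data$exchange_reactions[["pyruvate"]],
                  data$g6pd_reaction, data$gad_reaction)
  out
}

#' Net-ATP-production objective of the brain model
#'
#' The maximized profit function: mitochondrial ATP synthase flux minus the
#' mitochondrial NDP-kinase flux (which is negative when converting
#' GTP to ATP), minus hexokinase and phosphofructokinase (ATP consumers),
#' minus phosphoglycerate kinase (negative when producing ATP) plus
#' pyruvate kinase.
#'
#' @return An [objective_spec()].
#' @export
brain_atp_objective <- function() {
  read_objective(system.file("extdata", "atp_objective.json", package = "limfba"))
}

#' Synthetic gene-expression fold-change tables
#'
#' Emulates a microarray-derived disease-vs-control fold-change table for
#' the genes of a model: every gene associated with a reaction in pathway
#' `p` draws its log2 fold change from `Normal(effect_p, noise_sd)`; genes
#' of reactions outside the listed pathways draw from
#' `Normal(0, noise_sd)`. Deterministic for a fixed seed.
#'
#' @param model A [metabolic_model()] with pathway annotations.
#' @param pathway_effects Named numeric vector of mean log2 effects per
#'   pathway (e.g. `c(oxphos = -1)`). Unknown pathway names are an error.
#' @param noise_sd Standard deviation of the log2 noise.
#' @param seed Integer seed.
#' @return A [fold_change_table()] (linear scale), with the log2 values in
#'   attribute `"log2"`.
#' @export
synthetic_fold_changes <- function(model, pathway_effects = numeric(0),
                                   noise_sd = 0.1, seed = 1L) {
  stopifnot(inherits(model, "metabolic_model"))
  unknown <- setdiff(names(pathway_effects), names(model$annotations))
  if (length(unknown))
    stop("unknown pathway(s): ", paste(unknown, collapse = ", "))
  assoc <- extract_gene_associations(model)
  gene_pathway <- list()
  for (rid in names(assoc)) {
    pw <- model$reactions[[rid]]$pathway
    for (g in assoc[[rid]]) {
      gene_pathway[[g]] <- unique(c(gene_pathway[[g]],
                                    if (!is.na(pw)) pw else character(0)))
    }
  }
  genes <- sort(names(gene_pathway))
  effects <- vapply(genes, function(g) {
    hit <- intersect(gene_pathway[[g]], names(pathway_effects))
    if (length(hit)) mean(pathway_effects[hit]) else 0
  }, numeric(1))
  set.seed(seed)
  log2fc <- stats::rnorm(length(genes), mean = effects, sd = noise_sd)
  names(log2fc) <- genes
  out <- fold_change_table(log2fc, scale = "log2")
  attr(out, "log2") <- log2fc
  out
}

#' Write the brain model as an SBML file
#'
#' @param path Output path.
#' @return The path, invisibly.
#' @export
brain_model_sbml <- function(path) write_sbml(build_brain_model(), path)
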