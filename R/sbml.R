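#' SBML Level 3 export and import
#'
#' Serialises a model's compartments, species and numbered reactions as an
#' SBML Level 3 Version 2 document: compartment volumes as sizes, initial
#' concentrations, clamped species as boundary conditions, and each
#' reaction's kinetic law as MathML (rates multiplied by the host
#' compartment volume, so kinetic laws are in extent units as SBML
#' requires). Kinetic parameters are local parameters of each reaction; the
#' law form, host compartment and regulating gene ride along in a package
#' annotation so a re-import reconstructs the reaction table exactly. The
#' unnumbered gene-expression layer is exported as species only (its
#' composite rate equations are not single SBML kinetic laws).
#'
#' @name sbml
NULL

.sbml_ns <- "http://www.sbml.org/sbml/level3/version2/core"
.anlsim_ns <- "https://anlsim.invalid/sbml-annotation"

.sbml_id <- function(key) gsub("@", "_", key, fixed = TRUE)
.fmt <- function(x) sprintf("%.15g", x)

# MathML for one reaction's kinetic law (extent units: J * V_host)
.law_mathml <- function(law, params, subs, prods, mods, host) {
  ci <- function(x) sprintf("<ci> %s </ci>", x)
  cn <- function(x) sprintf("<cn> %s </cn>", .fmt(x))
  times <- function(...) sprintf("<apply><times/>%s</apply>",
                                 paste0(..., collapse = ""))
  plus <- function(...) sprintf("<apply><plus/>%s</apply>",
                                paste0(..., collapse = ""))
  minus <- function(a, b) sprintf("<apply><minus/>%s%s</apply>", a, b)
  divide <- function(a, b) sprintf("<apply><divide/>%s%s</apply>", a, b)
  s_ids <- .sbml_id(paste0(subs$species, "@", subs$compartment))
  p_ids <- .sbml_id(paste0(prods$species, "@", prods$compartment))
  m_ids <- .sbml_id(paste0(mods$species, "@", mods$compartment))
  core <- switch(law,
    passive_diffusion =
      times(ci("gamma"),
            minus(ci(s_ids[1]), times(ci("sigma"), ci(p_ids[1])))),
    facilitated_transport =
      divide(times(ci("v"), ci(s_ids[1])),
             plus(ci("km"), ci(s_ids[1]))),
    michaelis_menten =
      divide(times(ci("v_max"), ci(s_ids[1])),
             plus(ci("km"), ci(s_ids[1]))),
    bimolecular_mm =
      divide(times(ci("j_max"), times(sapply(s_ids, ci))),
             plus(ci("k"), times(sapply(s_ids, ci)))),
    mass_action =
      times(ci("k"), sapply(c(s_ids, m_ids), ci)),
    uncompetitive_inhibition =
      divide(times(ci("v_max"), ci(s_ids[1])),
             plus(ci("km"),
                  times(ci(s_ids[1]),
                        plus(cn(1), divide(ci(m_ids[1]), ci("ki"))))))
  )
  sprintf(paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
                 "%s</math>"), times(ci(host), core))
}

#' Export a model as SBML Level 3
#'
#' @param model An `anlsim_model` (or the skeleton returned by
#'   [import_sbml()]).
#' @param path Optional file; when given, the document is written there.
#' @return An `xml_document` (invisibly when `path` is given).
#' @export
export_sbml <- function(model, path = NULL) {
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<sbml xmlns=\"%s\" level=\"3\" version=\"2\">", .sbml_ns),
    sprintf("<model id=\"anlsim_%s\" timeUnits=\"minute\">",
            model$variant %||% "model")
  )
  lines <- c(lines, "<listOfCompartments>")
  for (i in seq_len(nrow(model$compartments))) {
    cp <- model$compartments[i, ]
    lines <- c(lines, sprintf(
      "<compartment id=\"%s\" name=\"%s\" size=\"%s\" spatialDimensions=\"3\" constant=\"true\"/>",
      cp$id, cp$description, .fmt(cp$volume)))
  }
  lines <- c(lines, "</listOfCompartments>", "<listOfSpecies>")
  for (i in seq_len(nrow(model$species))) {
    s <- model$species[i, ]
    key <- paste0(s$id, "@", s$compartment)
    lines <- c(lines, sprintf(
      paste0("<species id=\"%s\" name=\"%s\" compartment=\"%s\" ",
             "initialConcentration=\"%s\" boundaryCondition=\"%s\" ",
             "constant=\"false\" hasOnlySubstanceUnits=\"false\"/>"),
      .sbml_id(key), key, s$compartment, .fmt(s$initial),
      tolower(as.character(s$clamped))))
  }
  lines <- c(lines, "</listOfSpecies>", "<listOfReactions>")
  rx <- model$reactions
  for (i in seq_len(nrow(rx))) {
    r <- rx[i, ]
    subs <- r$substrates[[1]]; prods <- r$products[[1]]; mods <- r$modifiers[[1]]
    lines <- c(lines, sprintf(
      "<reaction id=\"r%d_%s\" reversible=\"false\">", r$number, r$name))
    reg <- if (is.na(r$regulated_by)) "" else
      sprintf(" regulatedBy=\"%s\"", r$regulated_by)
    lines <- c(lines, sprintf(
      paste0("<annotation><anlsim:reaction xmlns:anlsim=\"%s\" number=\"%d\" ",
             "law=\"%s\" host=\"%s\"%s/></annotation>"),
      .anlsim_ns, r$number, r$law, r$host, reg))
    side <- function(tag, s) {
      if (nrow(s) == 0) return(character())
      c(sprintf("<listOf%ss>", tag),
        sprintf("<speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
                .sbml_id(paste0(s$species, "@", s$compartment)), .fmt(s$stoich)),
        sprintf("</listOf%ss>", tag))
    }
    lines <- c(lines, side("Reactant", subs), side("Product", prods))
    if (nrow(mods) > 0) {
      lines <- c(lines, "<listOfModifiers>",
                 sprintf("<modifierSpeciesReference species=\"%s\"/>",
                         .sbml_id(paste0(mods$species, "@", mods$compartment))),
                 "</listOfModifiers>")
    }
    pars <- r$params[[1]]
    lines <- c(lines, "<kineticLaw>",
               .law_mathml(r$law, pars, subs, prods, mods, r$host),
               "<listOfLocalParameters>",
               sprintf("<localParameter id=\"%s\" value=\"%s\"/>",
                       names(pars), vapply(pars, .fmt, "")),
               "</listOfLocalParameters>", "</kineticLaw>", "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
  doc <- xml2::read_xml(paste(lines, collapse = ""))
  if (!is.null(path)) {
    writeLines(paste(lines, collapse = "\n"), path)
    return(invisible(doc))
  }
  doc
}

#' Import an SBML document written by [export_sbml()]
#'
#' Reconstructs compartments, species and the reaction table (using the
#' package annotation for law form, host compartment and gene regulation).
#' The result carries enough structure for [export_sbml()] to re-serialise
#' it byte-identically and for [sbml_reaction_rates()] to evaluate every
#' kinetic law.
#'
#' @param path File path or an `xml_document`.
#' @return A list of class `anlsim_sbml_model` with `compartments`,
#'   `species`, `reactions`, `variant`.
#' @export
import_sbml <- function(path) {
  doc <- if (inherits(path, "xml_document")) path else xml2::read_xml(path)
  ns <- c(s = .sbml_ns, a = .anlsim_ns)
  att <- function(node, a) xml2::xml_attr(node, a)

  comp_nodes <- xml2::xml_find_all(doc, ".//s:compartment", ns)
  compartments <- tibble::tibble(
    id = att(comp_nodes, "id"),
    description = att(comp_nodes, "name"),
    volume = as.numeric(att(comp_nodes, "size"))
  )
  sp_nodes <- xml2::xml_find_all(doc, ".//s:species", ns)
  keyparts <- strsplit(att(sp_nodes, "name"), "@", fixed = TRUE)
  species <- tibble::tibble(
    id = vapply(keyparts, `[`, "", 1),
    compartment = att(sp_nodes, "compartment"),
    initial = as.numeric(att(sp_nodes, "initialConcentration")),
    clamped = att(sp_nodes, "boundaryCondition") == "true"
  )
  key_of_id <- stats::setNames(att(sp_nodes, "name"), att(sp_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  parse_side <- function(node, xp) {
    refs <- xml2::xml_find_all(node, xp, ns)
    if (length(refs) == 0) {
      return(tibble::tibble(species = character(), compartment = character(),
                            stoich = numeric()))
    }
    keys <- strsplit(unname(key_of_id[att(refs, "species")]), "@", fixed = TRUE)
    st <- suppressWarnings(as.numeric(att(refs, "stoichiometry")))
    tibble::tibble(
      species = vapply(keys, `[`, "", 1),
      compartment = vapply(keys, `[`, "", 2),
      stoich = ifelse(is.na(st), 1, st)
    )
  }
  reactions <- tibble::tibble(
    number = integer(), name = character(), law = character(),
    host = character(), substrates = list(), products = list(),
    modifiers = list(), regulated_by = character(), params = list()
  )
  for (node in rx_nodes) {
    ann <- xml2::xml_find_first(node, ".//a:reaction", ns)
    num <- as.integer(att(ann, "number"))
    lp <- xml2::xml_find_all(node, ".//s:localParameter", ns)
    pars <- as.list(stats::setNames(as.numeric(att(lp, "value")), att(lp, "id")))
    reactions <- dplyr::bind_rows(reactions, tibble::tibble(
      number = num,
      name = sub(sprintf("^r%d_", num), "", att(node, "id")),
      law = att(ann, "law"), host = att(ann, "host"),
      substrates = list(parse_side(node, "./s:listOfReactants/s:speciesReference")),
      products = list(parse_side(node, "./s:listOfProducts/s:speciesReference")),
      modifiers = list(parse_side(node, "./s:listOfModifiers/s:modifierSpeciesReference")),
      regulated_by = att(ann, "regulatedBy"),
      params = list(pars)
    ))
  }
  variant <- sub("^anlsim_", "", att(xml2::xml_find_first(doc, ".//s:model", ns), "id"))
  structure(list(variant = variant, compartments = compartments,
                 species = species, reactions = reactions),
            class = "anlsim_sbml_model")
}

#' Evaluate every reaction rate of an (imported) model at a state point
#'
#' Independent evaluation route used by the SBML round-trip test: each
#' reaction's law is dispatched to the exported rate-law functions
#' ([passive_diffusion_flux()] and friends) at the supplied state, without
#' going through [assemble_odes()].
#'
#' @param model An `anlsim_model` or `anlsim_sbml_model`.
#' @param state Named state vector (`"species@compartment"` keys, mM).
#' @return Numeric vector of rates (mM/min, host-referenced), named by
#'   reaction number.
#' @export
sbml_reaction_rates <- function(model, state) {
  rx <- model$reactions
  out <- numeric(nrow(rx))
  for (i in seq_len(nrow(rx))) {
    r <- rx[i, ]
    p <- r$params[[1]]
    subs <- r$substrates[[1]]; prods <- r$products[[1]]; mods <- r$modifiers[[1]]
    conc <- function(s) {
      if (nrow(s) == 0) return(numeric(0))
      state[paste0(s$species, "@", s$compartment)]
    }
    cs <- conc(subs); cp <- conc(prods); cm <- conc(mods)
    out[i] <- switch(r$law,
      passive_diffusion = passive_diffusion_flux(p$gamma, p$sigma, cs[1], cp[1]),
      facilitated_transport = facilitated_transport_flux(p$v, p$km, cs[1]),
      michaelis_menten = michaelis_menten_rate(p$v_max, p$km, cs[1]),
      bimolecular_mm = saturating_product_rate(p$j_max, p$k, prod(cs)),
      mass_action = mass_action_rate(p$k, c(cs, cm)),
      uncompetitive_inhibition =
        uncompetitive_inhibition_rate(p$v_max, p$km, cs[1], p$ki, cm[1]))
  }
  stats::setNames(out, rx$number)
}

#' Structural checks on an SBML document
#'
#' Verifies that the document is namespaced SBML Level 3, that every
#' species' compartment is declared, and that every species reference in a
#' reaction resolves; failures are returned with element paths.
#'
#' @param doc An `xml_document` or file path.
#' @return Tibble of failures (empty when the document is consistent).
#' @export
validate_sbml <- function(doc) {
  if (!inherits(doc, "xml_document")) doc <- xml2::read_xml(doc)
  ns <- c(s = .sbml_ns)
  fails <- list()
  flag <- function(path, detail) {
    fails[[length(fails) + 1]] <<- tibble::tibble(path = path, detail = detail)
  }
  root <- xml2::xml_name(doc)
  if (root != "sbml") flag("/", "root element is not <sbml>")
  if (!identical(xml2::xml_attr(doc, "level"), "3")) flag("/sbml", "level != 3")
  comp_ids <- xml2::xml_attr(xml2::xml_find_all(doc, ".//s:compartment", ns), "id")
  sp <- xml2::xml_find_all(doc, ".//s:species", ns)
  sp_ids <- xml2::xml_attr(sp, "id")
  bad <- !xml2::xml_attr(sp, "compartment") %in% comp_ids
  for (b in sp_ids[bad]) flag(paste0("species[", b, "]"), "undeclared compartment")
  refs <- xml2::xml_find_all(doc, ".//s:speciesReference | .//s:modifierSpeciesReference", ns)
  bad <- !xml2::xml_attr(refs, "species") %in% sp_ids
  for (b in unique(xml2::xml_attr(refs, "species")[bad])) {
    flag(paste0("speciesReference[", b, "]"), "undeclared species")
  }
  if (length(fails) == 0) tibble::tibble(path = character(), detail = character())
  else dplyr::bind_rows(fails)
}
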