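#' @include accessors.R
NULL

#' Read an SBML model into a MetabolicNetwork
#'
#' Parses SBML Level 2 or Level 3 (with or without the fbc package) and
#' assembles the stoichiometric matrix column by column in document order.
#' Flux bounds are taken from fbc \code{lowerFluxBound}/\code{upperFluxBound}
#' parameter references when present, from legacy kineticLaw
#' \code{LOWER_BOUND}/\code{UPPER_BOUND} parameters otherwise, and default to
#' \code{[-u_default, u_default]} for reversible and \code{[0, u_default]} for
#' irreversible reactions when the document states none.
#'
#' @param path path to an SBML file.
#' @param u_default default bound magnitude used when the document gives no
#'   finite bound (moles over the transition interval).
#' @param boundary_rules character vector choosing how species are classified
#'   as outside the modelled system: \code{"attribute"} uses the SBML
#'   \code{boundaryCondition} flag, \code{"suffix"} additionally treats
#'   species ids ending in \code{"_b"} as boundary (a common convention in
#'   older genome-scale models). Both are applied by default.
#' @return a \linkS4class{MetabolicNetwork}.
#' @examples
#' f <- tempfile(fileext = ".xml")
#' writeSBML(makeToyNetwork("chain", 3), f)
#' net <- readSBML(f)
#' nReactions(net)
#' @export
readSBML <- function(path, u_default = 1000,
                     boundary_rules = c("attribute", "suffix")) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse failure in '", path, "': ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing"))
    stop("SBML parse failure: no <model> element in '", path, "'")

  sp_nodes <- xml2::xml_find_all(model, "./listOfSpecies/species")
  if (length(sp_nodes) == 0L)
    stop("SBML parse failure: no <species> in model")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  if (anyNA(sp_id) || any(!nzchar(sp_id)))
    stop("SBML format error: <species> element without id")
  sp_name <- xml2::xml_attr(sp_nodes, "name")
  sp_name[is.na(sp_name)] <- sp_id[is.na(sp_name)]
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  sp_comp[is.na(sp_comp)] <- ""
  boundary <- rep(FALSE, length(sp_id))
  if ("attribute" %in% boundary_rules)
    boundary <- boundary |
      (xml2::xml_attr(sp_nodes, "boundaryCondition") %in% c("true", "1"))
  if ("suffix" %in% boundary_rules)
    boundary <- boundary | grepl("_b$", sp_id)

  # global fbc parameters (id -> value), used by fbc bound references
  par_nodes <- xml2::xml_find_all(model, "./listOfParameters/parameter")
  par_val <- suppressWarnings(as.numeric(xml2::xml_attr(par_nodes, "value")))
  names(par_val) <- xml2::xml_attr(par_nodes, "id")

  rx_nodes <- xml2::xml_find_all(model, "./listOfReactions/reaction")
  if (length(rx_nodes) == 0L)
    stop("empty model: '", path, "' contains no reactions")

  n <- length(rx_nodes)
  rx_id <- xml2::xml_attr(rx_nodes, "id")
  if (anyNA(rx_id) || any(!nzchar(rx_id)))
    stop("SBML format error: <reaction> element without id")
  rx_name <- xml2::xml_attr(rx_nodes, "name")
  rx_name[is.na(rx_name)] <- rx_id[is.na(rx_name)]
  rev_attr <- xml2::xml_attr(rx_nodes, "reversible")
  # SBML L2 default for 'reversible' is true; L3 requires the attribute
  reversible <- ifelse(is.na(rev_attr), TRUE, rev_attr %in% c("true", "1"))

  sp_index <- stats::setNames(seq_along(sp_id), sp_id)
  tri_i <- integer(0); tri_j <- integer(0); tri_x <- numeric(0)
  lb <- numeric(n); ub <- numeric(n)

  read_side <- function(node, side) {
    refs <- xml2::xml_find_all(node, sprintf("./%s/speciesReference", side))
    if (length(refs) == 0L)
      return(stats::setNames(numeric(0), character(0)))
    ids <- xml2::xml_attr(refs, "species")
    st <- suppressWarnings(as.numeric(xml2::xml_attr(refs, "stoichiometry")))
    st[is.na(st)] <- 1
    if (any(st <= 0))
      stop("SBML format error: non-positive stoichiometry in reaction '",
           xml2::xml_attr(node, "id"), "'")
    tapply(st, ids, sum)  # merge duplicated references
  }

  attr_any_ns <- function(node, local) {
    at <- xml2::xml_attrs(node)
    hit <- grep(paste0("(^|:)", local, "$"), names(at))
    if (length(hit)) at[[hit[1L]]] else NA_character_
  }

  for (j in seq_len(n)) {
    node <- rx_nodes[[j]]
    subs <- read_side(node, "listOfReactants")
    prods <- read_side(node, "listOfProducts")
    both <- intersect(names(subs), names(prods))
    if (length(both))
      stop("SBML format error: reaction '", rx_id[j],
           "' has metabolites on both sides: ", paste(both, collapse = ", "))
    unknown <- setdiff(c(names(subs), names(prods)), sp_id)
    if (length(unknown))
      stop("SBML format error: reaction '", rx_id[j],
           "' references unknown species: ", paste(unknown, collapse = ", "))
    idx <- c(sp_index[names(subs)], sp_index[names(prods)])
    val <- c(-unname(subs), unname(prods))
    tri_i <- c(tri_i, unname(idx)); tri_j <- c(tri_j, rep(j, length(idx)))
    tri_x <- c(tri_x, val)

    # bounds: fbc references first, then legacy kineticLaw parameters
    lo <- hi <- NA_real_
    lref <- attr_any_ns(node, "lowerFluxBound")
    uref <- attr_any_ns(node, "upperFluxBound")
    if (!is.na(lref) && lref %in% names(par_val)) lo <- par_val[[lref]]
    if (!is.na(uref) && uref %in% names(par_val)) hi <- par_val[[uref]]
    if (is.na(lo) || is.na(hi)) {
      kl <- xml2::xml_find_all(node,
        "./kineticLaw/listOfParameters/parameter | ./kineticLaw/listOfLocalParameters/localParameter")
      if (length(kl)) {
        kid <- xml2::xml_attr(kl, "id")
        kval <- suppressWarnings(as.numeric(xml2::xml_attr(kl, "value")))
        if (is.na(lo) && "LOWER_BOUND" %in% kid)
          lo <- kval[match("LOWER_BOUND", kid)]
        if (is.na(hi) && "UPPER_BOUND" %in% kid)
          hi <- kval[match("UPPER_BOUND", kid)]
      }
    }
    if (is.na(lo) || !is.finite(lo))
      lo <- if (reversible[j]) -u_default else 0
    if (is.na(hi) || !is.finite(hi)) hi <- u_default
    lb[j] <- lo; ub[j] <- hi
  }

  S <- Matrix::sparseMatrix(i = tri_i, j = tri_j, x = tri_x,
                            dims = c(length(sp_id), n),
                            dimnames = list(sp_id, rx_id))
  new("MetabolicNetwork",
      metabolites = data.frame(id = sp_id, name = sp_name,
                               compartment = sp_comp, boundary = boundary,
                               stringsAsFactors = FALSE),
      reactions = data.frame(id = rx_id, name = rx_name,
                             reversible = reversible,
                             lower_bound = lb, upper_bound = ub,
                             stringsAsFactors = FALSE),
      stoich = S)
}

#' Write a network to SBML
#'
#' Serialises a \linkS4class{MetabolicNetwork} (or the base network of a
#' \linkS4class{SplitNetwork}) so toy and synthetic models can round-trip
#' through the SBML reader. Two dialects are supported: \code{"L3"} writes
#' Level 3 Version 1 with fbc-style bound parameters, \code{"L2"} writes
#' Level 2 Version 4 with legacy kineticLaw LOWER_BOUND/UPPER_BOUND
#' parameters.
#'
#' @param net a \linkS4class{MetabolicNetwork} or \linkS4class{SplitNetwork}.
#' @param path output file path.
#' @param dialect \code{"L3"} (default) or \code{"L2"}.
#' @return \code{path}, invisibly.
#' @export
writeSBML <- function(net, path, dialect = c("L3", "L2")) {
  dialect <- match.arg(dialect)
  if (is(net, "SplitNetwork")) net <- net@network
  stopifnot(is(net, "MetabolicNetwork"))
  met <- net@metabolites; rxn <- net@reactions
  S <- net@stoich

  if (dialect == "L3") {
    root <- xml2::xml_new_root("sbml",
      xmlns = "http://www.sbml.org/sbml/level3/version1/core",
      "xmlns:fbc" = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
      level = "3", version = "1", "fbc:required" = "false")
  } else {
    root <- xml2::xml_new_root("sbml",
      xmlns = "http://www.sbml.org/sbml/level2/version4",
      level = "2", version = "4")
  }
  model <- xml2::xml_add_child(root, "model", id = "model")
  comps <- unique(met$compartment)
  comps[!nzchar(comps)] <- "c"
  loc <- xml2::xml_add_child(model, "listOfCompartments")
  for (cmp in unique(comps))
    xml2::xml_add_child(loc, "compartment", id = cmp, constant = "true")
  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(met))) {
    cmp <- if (nzchar(met$compartment[i])) met$compartment[i] else "c"
    xml2::xml_add_child(los, "species",
      id = met$id[i], name = met$name[i], compartment = cmp,
      boundaryCondition = tolower(as.character(met$boundary[i])),
      hasOnlySubstanceUnits = "false", constant = "false")
  }
  if (dialect == "L3") {
    lop <- xml2::xml_add_child(model, "listOfParameters")
    bnd_id <- function(v) sprintf("b_%s", gsub("[^0-9A-Za-z]", "_", format(v, trim = TRUE)))
    vals <- unique(c(rxn$lower_bound, rxn$upper_bound))
    for (v in vals)
      xml2::xml_add_child(lop, "parameter", id = bnd_id(v),
        value = format(v, trim = TRUE), constant = "true")
  }
  lor <- xml2::xml_add_child(model, "listOfReactions")
  for (j in seq_len(nrow(rxn))) {
    col <- S[, j]
    subs <- which(col < 0); prods <- which(col > 0)
    rx <- xml2::xml_add_child(lor, "reaction",
      id = rxn$id[j], name = rxn$name[j],
      reversible = tolower(as.character(rxn$reversible[j])))
    if (dialect == "L3") {
      xml2::xml_set_attr(rx, "fast", "false")
      bnd_id <- function(v) sprintf("b_%s", gsub("[^0-9A-Za-z]", "_", format(v, trim = TRUE)))
      xml2::xml_set_attr(rx, "fbc:lowerFluxBound", bnd_id(rxn$lower_bound[j]))
      xml2::xml_set_attr(rx, "fbc:upperFluxBound", bnd_id(rxn$upper_bound[j]))
    }
    if (length(subs)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in subs)
        xml2::xml_add_child(lr, "speciesReference",
          species = met$id[i],
          stoichiometry = format(-col[i], trim = TRUE), constant = "true")
    }
    if (length(prods)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in prods)
        xml2::xml_add_child(lp, "speciesReference",
          species = met$id[i],
          stoichiometry = format(col[i], trim = TRUE), constant = "true")
    }
    if (dialect == "L2") {
      kl <- xml2::xml_add_child(rx, "kineticLaw")
      lopl <- xml2::xml_add_child(kl, "listOfParameters")
      xml2::xml_add_child(lopl, "parameter", id = "LOWER_BOUND",
        value = format(rxn$lower_bound[j], trim = TRUE))
      xml2::xml_add_child(lopl, "parameter", id = "UPPER_BOUND",
        value = format(rxn$upper_bound[j], trim = TRUE))
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}
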