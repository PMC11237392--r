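SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_ns <- c(s = SBML_CORE_NS, fbc = SBML_FBC_NS)

# SId-safe id for a gene product; the true gene id is kept in fbc:label.
gene_product_sid <- function(gene_id) {
  paste0("G_", gsub("[^A-Za-z0-9_]", "_", gene_id))
}

#' Read a model from SBML Level 3 with the fbc extension
#'
#' Parses the constraint-based subset of SBML L3V1 + fbc v2: species,
#' reactions with flux bounds given as parameters, gene products, nested
#' gene-product associations (translated to [gpr_node] trees) and the active
#' maximization objective. Other SBML levels/versions are rejected. Exchange
#' reactions are recognized by their single-metabolite stoichiometry; gene
#' origins are inferred from allele suffixes where present (see
#' [gene_origins()]).
#'
#' @param path path to an SBML file.
#' @return A `gem_model`.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed SBML: ", conditionMessage(e))
  })
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "sbml") {
    stop("malformed SBML: root element is <", xml2::xml_name(root), ">, expected <sbml>")
  }
  lvl <- xml2::xml_attr(root, "level"); ver <- xml2::xml_attr(root, "version")
  if (!identical(lvl, "3")) {
    stop("unsupported SBML level ", lvl, "; only SBML Level 3 Version 1 with fbc is supported")
  }
  nss <- unlist(xml2::xml_ns(doc))
  if (!(SBML_FBC_NS %in% nss)) {
    stop("SBML file lacks the fbc v2 namespace; cannot read flux bounds and GPRs")
  }
  mnode <- xml2::xml_find_first(doc, "/s:sbml/s:model", sbml_ns)
  if (is.na(xml2::xml_name(mnode))) stop("malformed SBML: no <model> element")
  model_id <- xml2::xml_attr(mnode, "id")

  sp <- xml2::xml_find_all(mnode, "./s:listOfSpecies/s:species", sbml_ns)
  metabolites <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = xml2::xml_attr(sp, "fbc:chemicalFormula", ns = sbml_ns),
    charge = suppressWarnings(as.numeric(xml2::xml_attr(sp, "fbc:charge", ns = sbml_ns))),
    stringsAsFactors = FALSE
  )

  pn <- xml2::xml_find_all(mnode, "./s:listOfParameters/s:parameter", sbml_ns)
  params <- stats::setNames(as.numeric(xml2::xml_attr(pn, "value")),
                            xml2::xml_attr(pn, "id"))

  gp <- xml2::xml_find_all(mnode, "./fbc:listOfGeneProducts/fbc:geneProduct", sbml_ns)
  gp_sid <- xml2::xml_attr(gp, "fbc:id", ns = sbml_ns)
  gp_label <- xml2::xml_attr(gp, "fbc:label", ns = sbml_ns)
  gene_ids <- ifelse(is.na(gp_label) | !nzchar(gp_label), gp_sid, gp_label)
  sid_to_gene <- stats::setNames(gene_ids, gp_sid)

  parse_assoc <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      sid <- xml2::xml_attr(node, "fbc:geneProduct", ns = sbml_ns)
      gid <- sid_to_gene[sid]
      if (is.na(gid)) {
        stop("GPR references undeclared gene product id: ", sid)
      }
      return(gpr_leaf(unname(gid)))
    }
    children <- lapply(xml2::xml_children(node), parse_assoc)
    if (length(children) == 1L) return(children[[1]])
    if (nm == "and") return(new_gpr_node("and", children = children))
    if (nm == "or") return(new_gpr_node("or", children = children))
    stop("malformed SBML: unexpected element <", nm, "> in gene product association")
  }

  rx <- xml2::xml_find_all(mnode, "./s:listOfReactions/s:reaction", sbml_ns)
  rids <- xml2::xml_attr(rx, "id")
  bound_of <- function(attr_val, rid, which) {
    if (is.na(attr_val)) {
      stop("reaction ", rid, " lacks an fbc:", which, "FluxBound parameter")
    }
    v <- params[attr_val]
    if (is.na(v)) stop("reaction ", rid, " references undeclared parameter: ", attr_val)
    unname(v)
  }
  stoich <- list()
  gprs <- list()
  lb <- numeric(length(rx)); ub <- numeric(length(rx))
  for (k in seq_along(rx)) {
    node <- rx[[k]]
    st <- numeric()
    for (ref in xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", sbml_ns)) {
      mid <- xml2::xml_attr(ref, "species")
      st[mid] <- (if (mid %in% names(st)) st[[mid]] else 0) -
        as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    for (ref in xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", sbml_ns)) {
      mid <- xml2::xml_attr(ref, "species")
      st[mid] <- (if (mid %in% names(st)) st[[mid]] else 0) +
        as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    stoich[[rids[k]]] <- st
    lb[k] <- bound_of(xml2::xml_attr(node, "fbc:lowerFluxBound", ns = sbml_ns), rids[k], "lower")
    ub[k] <- bound_of(xml2::xml_attr(node, "fbc:upperFluxBound", ns = sbml_ns), rids[k], "upper")
    assoc <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", sbml_ns)
    if (!is.na(xml2::xml_name(assoc))) {
      kids <- xml2::xml_children(assoc)
      if (length(kids) != 1L) stop("reaction ", rids[k],
        ": geneProductAssociation must hold exactly one association element")
      gprs[[rids[k]]] <- parse_assoc(kids[[1]])
    }
  }
  reactions <- data.frame(
    id = rids,
    name = ifelse(is.na(xml2::xml_attr(rx, "name")), rids, xml2::xml_attr(rx, "name")),
    lb = lb, ub = ub,
    sbo = xml2::xml_attr(rx, "sboTerm"),
    stringsAsFactors = FALSE
  )

  active <- xml2::xml_attr(
    xml2::xml_find_first(mnode, "./fbc:listOfObjectives", sbml_ns),
    "fbc:activeObjective", ns = sbml_ns)
  objective <- NA_character_
  if (!is.na(active)) {
    onode <- xml2::xml_find_first(mnode, sprintf(
      "./fbc:listOfObjectives/fbc:objective[@fbc:id='%s']/fbc:listOfFluxObjectives/fbc:fluxObjective",
      active), sbml_ns)
    objective <- xml2::xml_attr(onode, "fbc:reaction", ns = sbml_ns)
  }
  if (is.na(objective)) stop("SBML model declares no active flux objective")

  genes <- data.frame(id = gene_ids, name = gene_ids, origin = "template",
                      allele_partner = NA_character_, stringsAsFactors = FALSE)
  org <- gene_origins(structure(list(genes = genes), class = "gem_model"))
  genes$origin <- ifelse(is.na(org[genes$id]), "template", org[genes$id])

  new_model(id = if (is.na(model_id)) "model" else model_id,
            metabolites = metabolites, reactions = reactions,
            stoichiometry = stoich, gpr = gprs, genes = genes,
            objective = objective)
}

#' Write a model as SBML Level 3 with the fbc extension
#'
#' Emits SBML L3V1 + fbc v2: flux bounds as shared parameters, gene products
#' with the gene id in `fbc:label`, GPR trees as nested
#' `fbc:and`/`fbc:or`/`fbc:geneProductRef` elements (reactions without a
#' rule get no association element) and a single maximization objective.
#' `read_sbml(write_sbml(m, f))` reproduces `m` up to row ordering.
#'
#' @param model a `gem_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  root <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_CORE_NS, "xmlns:fbc" = SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false"
  )
  mnode <- xml2::xml_add_child(root, "model", id = model$id,
                               "fbc:strict" = "false")

  comps <- unique(model$metabolites$compartment)
  loc <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (cp in comps) {
    xml2::xml_add_child(loc, "compartment", id = cp, constant = "true")
  }

  los <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    node <- xml2::xml_add_child(los, "species", id = m$id, name = m$name,
      compartment = m$compartment, hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false")
    if (!is.na(m$formula)) xml2::xml_set_attr(node, "fbc:chemicalFormula", m$formula)
    if (!is.na(m$charge)) xml2::xml_set_attr(node, "fbc:charge",
                                             format(m$charge, scientific = FALSE))
  }

  fmt_num <- function(v) sprintf("%.17g", v)
  bounds <- sort(unique(c(model$reactions$lb, model$reactions$ub)))
  pid_of <- stats::setNames(sprintf("fb_%d", seq_along(bounds)), fmt_num(bounds))
  lop <- xml2::xml_add_child(mnode, "listOfParameters")
  for (bv in bounds) {
    xml2::xml_add_child(lop, "parameter", id = pid_of[[fmt_num(bv)]],
      value = fmt_num(bv), constant = "true")
  }

  write_assoc <- function(parent, node) {
    if (node$kind == "leaf") {
      xml2::xml_add_child(parent, "fbc:geneProductRef",
                          "fbc:geneProduct" = gene_product_sid(node$gene))
      return(invisible())
    }
    if (node$kind == "false") {
      stop("cannot serialize an unsatisfiable GPR; prune the model first")
    }
    el <- xml2::xml_add_child(parent, paste0("fbc:", node$kind))
    for (ch in node$children) write_assoc(el, ch)
  }

  lor <- xml2::xml_add_child(mnode, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    node <- xml2::xml_add_child(lor, "reaction", id = r$id, name = r$name,
      reversible = tolower(as.character(r$lb < 0)), fast = "false",
      "fbc:lowerFluxBound" = pid_of[[fmt_num(r$lb)]],
      "fbc:upperFluxBound" = pid_of[[fmt_num(r$ub)]])
    if (!is.na(r$sbo)) xml2::xml_set_attr(node, "sboTerm", r$sbo)
    st <- model$stoichiometry[[r$id]]
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      lref <- xml2::xml_add_child(node, "listOfReactants")
      for (mid in names(reac)) {
        xml2::xml_add_child(lref, "speciesReference", species = mid,
          stoichiometry = fmt_num(-reac[[mid]]), constant = "true")
      }
    }
    if (length(prod)) {
      lref <- xml2::xml_add_child(node, "listOfProducts")
      for (mid in names(prod)) {
        xml2::xml_add_child(lref, "speciesReference", species = mid,
          stoichiometry = fmt_num(prod[[mid]]), constant = "true")
      }
    }
    g <- model$gpr[[r$id]]
    if (!is.null(g)) {
      assoc <- xml2::xml_add_child(node, "fbc:geneProductAssociation")
      write_assoc(assoc, g)
    }
  }

  loo <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                             "fbc:activeObjective" = "obj")
  obj <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                             "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(obj, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lfo, "fbc:fluxObjective", "fbc:reaction" = model$objective,
                      "fbc:coefficient" = "1")

  logp <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
  for (i in seq_len(nrow(model$genes))) {
    g <- model$genes[i, ]
    xml2::xml_add_child(logp, "fbc:geneProduct",
                        "fbc:id" = gene_product_sid(g$id),
                        "fbc:label" = g$id, "fbc:name" = g$name)
  }

  xml2::write_xml(root, path)
  invisible(path)
}
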