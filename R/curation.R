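#' Apply manual curation actions to a model
#'
#' Manual curation is the audited edit step of a reconstruction: adding newly
#' evidenced reactions (e.g. a melibiase reaction giving the hybrid its
#' melibiose catabolism), re-integrating reactions removed during pruning but
#' supported by isoforms or organellar genes, and removing content. Each
#' action carries an `id`; applied ids are recorded on the model, so applying
#' the same action list twice equals applying it once.
#'
#' Supported kinds:
#' * `add_reaction` / `reintegrate_reaction` — payload: `equation` (tabular
#'   dialect syntax), optional `name`, `lb`, `ub`, `gpr` (rule string),
#'   `sbo`, `metabolites` (list of new metabolite defs: `id`, `name`,
#'   `compartment`, `formula`, `charge`) and `genes` (list of new gene defs:
#'   `id`, `name`, `origin`, `allele_partner`). Added reactions must pass
#'   [check_balance()] unless `balance_waiver: true` is set (exchanges are
#'   exempt by construction; unknown formulas make the check indeterminate,
#'   which is accepted).
#' * `add_gene` — payload: one gene def.
#' * `remove_reaction` — removes the target reaction.
#' * `remove_gene` — removes the gene and drops its leaf from every GPR
#'   (`or`: operand removed; `and`: branch unsatisfiable).
#'
#' Re-adding an id that already exists errors unless the action sets
#' `amend: true`, in which case the definition replaces the old one.
#'
#' @param model a `gem_model`.
#' @param actions list of action lists (fields `id`, `kind`, `target`,
#'   `payload`, optional `note`, `amend`); see [read_curation_actions()].
#' @return The curated model; provenance notes are kept in
#'   `attr(model, "provenance")` and applied ids in `model$curation_log`.
#' @export
apply_curation <- function(model, actions) {
  prov <- attr(model, "provenance") %||% character()
  for (act in actions) {
    if (is.null(act$id) || is.null(act$kind)) {
      stop("curation action needs 'id' and 'kind' fields")
    }
    if (act$id %in% model$curation_log) next
    model <- apply_one_action(model, act)
    if (!is.null(act$note) && !is.null(act$target)) {
      prov[act$target] <- act$note
    }
    model$curation_log <- c(model$curation_log, act$id)
  }
  validate_model(model)
  attr(model, "provenance") <- prov
  model
}

apply_one_action <- function(model, act) {
  kind <- act$kind
  target <- act$target
  payload <- act$payload
  amend <- isTRUE(act$amend)
  if (kind %in% c("add_reaction", "reintegrate_reaction")) {
    if (is.null(payload$equation)) stop("action ", act$id, ": payload needs 'equation'")
    if (target %in% model$reactions$id) {
      if (!amend) stop("reaction '", target, "' already exists; set amend: true to replace")
      model <- drop_reaction(model, target)
    }
    for (md in payload$metabolites) {
      if (!(md$id %in% model$metabolites$id)) {
        model$metabolites <- rbind(model$metabolites, data.frame(
          id = md$id, name = md$name %||% md$id,
          compartment = md$compartment %||% "c",
          formula = md$formula %||% NA_character_,
          charge = md$charge %||% NA_real_, stringsAsFactors = FALSE))
      }
    }
    for (gd in payload$genes) {
      if (!(gd$id %in% model$genes$id)) model <- add_gene_row(model, gd)
    }
    eq <- parse_equation(payload$equation)
    lb <- payload$lb %||% if (eq$reversible) -1000 else 0
    ub <- payload$ub %||% 1000
    new_row <- data.frame(id = target, name = payload$name %||% target,
                          lb = lb, ub = ub, sbo = payload$sbo %||% NA_character_,
                          stringsAsFactors = FALSE)
    model$reactions <- merge_rows(model$reactions, new_row)
    model$stoichiometry[[target]] <- eq$stoichiometry
    if (!is.null(payload$gpr) && nzchar(payload$gpr)) {
      model$gpr[[target]] <- parse_gpr(payload$gpr)
    }
    bal <- check_balance(model, target)
    if (bal$status == "imbalanced" && !isTRUE(payload$balance_waiver)) {
      stop("action ", act$id, ": added reaction '", target,
           "' is elementally imbalanced (", paste(names(bal$elements),
           bal$elements, sep = ":", collapse = ", "),
           "); set balance_waiver: true to accept")
    }
  } else if (kind == "add_gene") {
    if (target %in% model$genes$id) {
      if (!amend) stop("gene '", target, "' already exists; set amend: true to replace")
      model$genes <- model$genes[model$genes$id != target, ]
    }
    model <- add_gene_row(model, c(list(id = target), payload))
  } else if (kind == "remove_reaction") {
    if (target %in% model$reactions$id) model <- drop_reaction(model, target)
  } else if (kind == "remove_gene") {
    if (target %in% model$genes$id) {
      model$genes <- model$genes[model$genes$id != target, ]
      model$genes$allele_partner[!is.na(model$genes$allele_partner) &
        model$genes$allele_partner == target] <- NA_character_
      model$gpr <- lapply(model$gpr, drop_gene_from_gpr, gene = target)
      model$gpr <- model$gpr[!vapply(model$gpr, is.null, logical(1))]
    }
  } else {
    stop("unknown curation action kind: ", kind)
  }
  model
}

drop_reaction <- function(model, rid) {
  model$reactions <- model$reactions[model$reactions$id != rid, ]
  model$stoichiometry[[rid]] <- NULL
  model$gpr[[rid]] <- NULL
  model
}

add_gene_row <- function(model, gd) {
  model$genes <- merge_rows(model$genes,
    data.frame(id = gd$id, name = gd$name %||% gd$id,
               origin = gd$origin %||% "template",
               allele_partner = gd$allele_partner %||% NA_character_,
               stringsAsFactors = FALSE))
  model
}

drop_gene_from_gpr <- function(node, gene) {
  if (is.null(node)) return(NULL)
  if (node$kind == "leaf") {
    return(if (node$gene == gene) gpr_false() else node)
  }
  if (node$kind == "false") return(node)
  children <- lapply(node$children, drop_gene_from_gpr, gene = gene)
  dead <- vapply(children, function(ch) ch$kind == "false", logical(1))
  if (node$kind == "and") {
    if (any(dead)) return(gpr_false())
    return(new_gpr_node("and", children = children))
  }
  children <- children[!dead]
  if (length(children) == 0L) return(gpr_false())
  if (length(children) == 1L) return(children[[1]])
  new_gpr_node("or", children = children)
}

merge_rows <- function(df, row) {
  for (col in setdiff(names(df), names(row))) row[[col]] <- NA
  rbind(df, row[, names(df)])
}

#' Read curation actions from YAML or JSON
#'
#' The file holds a list of actions as documented in [apply_curation()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return List of action lists.
#' @export
read_curation_actions <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    return(yaml::read_yaml(path))
  }
  jsonlite::read_json(path, simplifyVector = FALSE)
}
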