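#' Constraint-based metabolic model container
#'
#' A `gem_model` holds the stoichiometric system behind flux balance analysis:
#' metabolites, reactions with flux bounds (mmol·gDCW^-1·h^-1), Boolean GPR
#' rules linking reactions to genes, and one objective reaction (typically
#' biomass). Exchange reactions — boundary reactions touching a single
#' metabolite — encode the growth medium through their bounds, with negative
#' flux meaning uptake and positive flux secretion.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `formula` (chemical formula string, `NA` if unknown), `charge` (integer,
#'   `NA` if unknown).
#' @param reactions data.frame with columns `id`, `name`, `lb`, `ub` and
#'   optionally `sbo`.
#' @param stoichiometry named list (by reaction id) of named numeric vectors:
#'   metabolite id -> signed coefficient, negative for consumed species.
#' @param gpr named list (by reaction id) of [gpr_node] trees or `NULL`.
#'   Reactions absent from the list carry no rule.
#' @param genes data.frame with columns `id`, `name`, `origin` (one of
#'   `"parentA"`, `"parentB"`, `"hybrid-specific"`, `"template"`) and
#'   `allele_partner` (id of the redundant ortholog, `NA` if none). May be
#'   `NULL`, in which case the gene table is derived from the GPR rules with
#'   origin `"template"`.
#' @param objective id of the objective reaction.
#' @return A validated object of class `gem_model`.
#' @export
new_model <- function(id, metabolites, reactions, stoichiometry, gpr = list(),
                      genes = NULL, objective) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(reactions$sbo)) reactions$sbo <- NA_character_
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$charge)) metabolites$charge <- NA_real_
  gpr <- gpr[!vapply(gpr, is.null, logical(1))]
  if (is.null(genes)) {
    gids <- unique(unlist(lapply(gpr, gpr_genes)))
    genes <- data.frame(
      id = gids %||% character(),
      name = gids %||% character(),
      origin = rep("template", length(gids)),
      allele_partner = rep(NA_character_, length(gids)),
      stringsAsFactors = FALSE
    )
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (is.null(genes$allele_partner)) genes$allele_partner <- NA_character_
  if (is.null(genes$origin)) genes$origin <- "template"
  if (is.null(genes$name)) genes$name <- genes$id
  model <- structure(
    list(
      id = id,
      metabolites = metabolites,
      reactions = reactions,
      stoichiometry = stoichiometry,
      gpr = gpr,
      genes = genes,
      objective = objective,
      curation_log = character()
    ),
    class = "gem_model"
  )
  validate_model(model)
  model
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Validate the internal consistency of a model
#'
#' Checks id uniqueness, bound ordering (`lb <= ub`), that every stoichiometry
#' entry references a declared metabolite, every GPR leaf a declared gene,
#' that allele partnerships are symmetric, and that the objective reaction
#' exists. Called by [new_model()]; exported so readers and editors can
#' re-check after manual surgery.
#'
#' @param model a `gem_model`.
#' @return `model`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "gem_model"))
  met <- model$metabolites; rxn <- model$reactions; gen <- model$genes
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(what, " table lacks column(s): ", paste(miss, collapse = ", "))
  }
  need(met, c("id", "name", "compartment"), "metabolite")
  need(rxn, c("id", "name", "lb", "ub"), "reaction")
  need(gen, c("id", "name", "origin"), "gene")
  if (anyDuplicated(met$id)) stop("duplicate metabolite ids: ",
    paste(unique(met$id[duplicated(met$id)]), collapse = ", "))
  if (anyDuplicated(rxn$id)) stop("duplicate reaction ids: ",
    paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", "))
  if (anyDuplicated(gen$id)) stop("duplicate gene ids: ",
    paste(unique(gen$id[duplicated(gen$id)]), collapse = ", "))
  bad <- rxn$id[rxn$lb > rxn$ub]
  if (length(bad)) stop("lb > ub for reaction(s): ", paste(bad, collapse = ", "))
  extra <- setdiff(names(model$stoichiometry), rxn$id)
  if (length(extra)) stop("stoichiometry for unknown reaction(s): ",
    paste(extra, collapse = ", "))
  missing_st <- setdiff(rxn$id, names(model$stoichiometry))
  if (length(missing_st)) stop("reaction(s) without stoichiometry: ",
    paste(missing_st, collapse = ", "))
  for (rid in rxn$id) {
    st <- model$stoichiometry[[rid]]
    if (!is.numeric(st) || is.null(names(st)) || any(!nzchar(names(st)))) {
      stop("stoichiometry of ", rid, " must be a named numeric vector")
    }
    dangling <- setdiff(names(st), met$id)
    if (length(dangling)) stop("reaction ", rid, " references undeclared metabolite(s): ",
      paste(dangling, collapse = ", "))
  }
  extra_gpr <- setdiff(names(model$gpr), rxn$id)
  if (length(extra_gpr)) stop("GPR for unknown reaction(s): ",
    paste(extra_gpr, collapse = ", "))
  gpr_gene_ids <- unique(unlist(lapply(model$gpr, gpr_genes)))
  undeclared <- setdiff(gpr_gene_ids, gen$id)
  if (length(undeclared)) stop("GPR rules reference undeclared gene(s): ",
    paste(undeclared, collapse = ", "))
  if (!is.null(gen$allele_partner)) {
    has <- !is.na(gen$allele_partner)
    partner_of <- stats::setNames(gen$allele_partner, gen$id)
    for (g in gen$id[has]) {
      p <- partner_of[[g]]
      if (!(p %in% gen$id) || is.na(partner_of[[p]]) || partner_of[[p]] != g) {
        stop("allele partnership of gene ", g, " is not symmetric")
      }
    }
  }
  if (length(model$objective) != 1L || !(model$objective %in% rxn$id)) {
    stop("objective reaction '", model$objective, "' is not in the model")
  }
  invisible(model)
}

#' @export
print.gem_model <- function(x, ...) {
  cat(sprintf("gem_model '%s': %d metabolites, %d reactions (%d exchanges), %d genes\n",
              x$id, nrow(x$metabolites), nrow(x$reactions),
              sum(is_exchange(x)), nrow(x$genes)))
  cat("objective:", x$objective, "\n")
  invisible(x)
}

#' Identify exchange reactions
#'
#' An exchange is a boundary reaction with exactly one non-zero stoichiometric
#' entry; its bounds encode medium composition (lb < 0 permits uptake).
#'
#' @param model a `gem_model`.
#' @return Named logical vector over reactions (in table order).
#' @export
is_exchange <- function(model) {
  v <- vapply(model$reactions$id, function(rid) {
    st <- model$stoichiometry[[rid]]
    sum(st != 0) == 1L
  }, logical(1))
  stats::setNames(v, model$reactions$id)
}

#' Which reactions are reversible
#'
#' Reversibility here is operational: a reaction is reversible iff its lower
#' bound admits negative flux.
#'
#' @param model a `gem_model`.
#' @return Named logical vector over reactions.
#' @export
is_reversible <- function(model) {
  stats::setNames(model$reactions$lb < 0, model$reactions$id)
}

## ---- chemical formulas and mass balance ------------------------------------

#' Parse a chemical formula into element counts
#'
#' Accepts flat Hill-style formulas such as `"C6H12O6"`; element symbols are
#' one capital letter optionally followed by a lowercase letter, counts
#' default to 1. Generic side-chain symbols (e.g. `R`, `X`) are treated as
#' ordinary elements.
#'
#' @param formula a formula string, or `NA`.
#' @return Named integer vector of element counts, or `NULL` for `NA`/empty.
#' @export
parse_formula <- function(formula) {
  if (length(formula) != 1L || is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse chemical formula: ", formula)
  }
  els <- sub("[0-9]*$", "", parts)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", parts), sub("^[A-Za-z]+", "", parts), "1"))
  tapply_sum <- tapply(cnt, els, sum)
  out <- as.integer(tapply_sum)
  names(out) <- names(tapply_sum)
  out
}

#' Elemental and charge balance of a reaction
#'
#' Computes, for each element, the net count produced minus consumed
#' (stoichiometric dot product over metabolite formulas), plus the net charge.
#' A reaction is balanced iff every net is zero. Exchange reactions are
#' one-sided by construction and reported as `"exempt"`; a participating
#' metabolite without a formula makes the status `"indeterminate"` rather
#' than an error.
#'
#' @param model a `gem_model`.
#' @param reaction_id id of the reaction to check.
#' @return A list with `status` (`"balanced"`, `"imbalanced"`, `"exempt"`,
#'   `"indeterminate"`), `elements` (named numeric vector of net counts,
#'   zeros dropped) and `charge` (net charge, `NA` if any charge unknown).
#' @export
#' @examples
#' # melibiose + H2O -> glucose + galactose is elementally balanced
check_balance <- function(model, reaction_id) {
  stopifnot(reaction_id %in% model$reactions$id)
  st <- model$stoichiometry[[reaction_id]]
  st <- st[st != 0]
  if (sum(st != 0) == 1L) {
    return(list(status = "exempt", elements = numeric(), charge = NA_real_))
  }
  met <- model$metabolites
  rownames(met) <- met$id
  net <- numeric()
  indeterminate <- FALSE
  for (mid in names(st)) {
    f <- parse_formula(met[mid, "formula"])
    if (is.null(f)) {
      indeterminate <- TRUE
      next
    }
    for (el in names(f)) {
      net[el] <- (if (el %in% names(net)) net[el] else 0) + st[[mid]] * f[[el]]
    }
  }
  charges <- met[names(st), "charge"]
  net_charge <- if (any(is.na(charges))) NA_real_ else sum(st * charges)
  if (indeterminate) {
    return(list(status = "indeterminate", elements = net, charge = net_charge))
  }
  nonzero <- net[abs(net) > 1e-9]
  charged <- !is.na(net_charge) && abs(net_charge) > 1e-9
  status <- if (length(nonzero) == 0L && !charged) "balanced" else "imbalanced"
  list(status = status, elements = nonzero, charge = net_charge)
}

## ---- medium ----------------------------------------------------------------

#' Apply a medium specification to a model
#'
#' A medium lists exchange reactions and their flux bounds
#' (mmol·gDCW^-1·h^-1); uptake is a negative lower bound (an uptake of 20
#' corresponds to `lb = -20`). Listed exchanges get the stated bounds; all
#' *unlisted* exchanges have uptake closed (`lb = 0`) while their secretion
#' direction is left as-is, so the medium fully determines what the cell may
#' consume.
#'
#' @param model a `gem_model`.
#' @param medium a data.frame with columns `exchange_id`, `lb`, `ub`, or a
#'   named list of `c(lb, ub)` pairs. See [read_medium()].
#' @return The constrained model.
#' @export
apply_medium <- function(model, medium) {
  medium <- as_medium(medium)
  ex <- is_exchange(model)
  unknown <- setdiff(medium$exchange_id, model$reactions$id)
  if (length(unknown)) stop("medium references unknown reaction(s): ",
    paste(unknown, collapse = ", "))
  not_ex <- medium$exchange_id[!ex[medium$exchange_id]]
  if (length(not_ex)) stop("medium references non-exchange reaction(s): ",
    paste(not_ex, collapse = ", "))
  if (any(medium$lb > medium$ub)) stop("medium has lb > ub")
  rid <- model$reactions$id
  close_ids <- rid[ex & !(rid %in% medium$exchange_id)]
  model$reactions$lb[match(close_ids, rid)] <-
    pmax(model$reactions$lb[match(close_ids, rid)], 0)
  idx <- match(medium$exchange_id, rid)
  model$reactions$lb[idx] <- medium$lb
  model$reactions$ub[idx] <- medium$ub
  validate_model(model)
  model
}

as_medium <- function(medium) {
  if (is.data.frame(medium)) {
    need <- setdiff(c("exchange_id", "lb", "ub"), names(medium))
    if (length(need)) stop("medium lacks column(s): ", paste(need, collapse = ", "))
    return(medium[, c("exchange_id", "lb", "ub")])
  }
  if (is.list(medium)) {
    if (length(medium) == 0L) {
      return(data.frame(exchange_id = character(), lb = numeric(), ub = numeric()))
    }
    return(data.frame(
      exchange_id = names(medium),
      lb = vapply(medium, function(x) x[[1]], numeric(1)),
      ub = vapply(medium, function(x) x[[2]], numeric(1)),
      stringsAsFactors = FALSE
    ))
  }
  stop("medium must be a data.frame or a named list of (lb, ub) pairs")
}

#' Read a medium specification from TSV or JSON
#'
#' TSV files need columns `exchange_id`, `lb`, `ub`; JSON files are an object
#' mapping exchange ids to `[lb, ub]` arrays.
#'
#' @param path file path ending in `.tsv`/`.txt` or `.json`.
#' @return A medium data.frame for [apply_medium()].
#' @export
read_medium <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(as_medium(lapply(x, function(v) c(v[[1]], v[[2]]))))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_medium(df)
}
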