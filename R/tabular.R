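#' Read a model from the tabular dialect
#'
#' A plain-TSV encoding of a constraint-based model:
#'
#' * `reactions.tsv` — columns `id`, `name`, `equation`, `lb`, `ub`, `gpr`,
#'   `sbo` (only `id` and `equation` are required). Equations use
#'   `"2 A + B -> C"` syntax; the arrow `->` marks an irreversible reaction,
#'   `<=>` a reversible one. Omitted bounds default to the conventional
#'   \eqn{[-1000, 1000]} for reversible and \eqn{[0, 1000]} for irreversible
#'   reactions.
#' * `metabolites.tsv` — columns `id`, `name`, `compartment`, `formula`,
#'   `charge` (only `id` required).
#' * `genes.tsv` (optional) — columns `id`, `name`, `origin`,
#'   `allele_partner`. When omitted, genes are collected from the GPR rules.
#'
#' @param reactions_tsv,metabolites_tsv paths to the two required tables.
#' @param genes_tsv optional path to the gene table.
#' @param id model id.
#' @param objective objective reaction id; defaults to the first reaction
#'   whose id or name contains "biomass" (case-insensitive), else errors.
#' @return A `gem_model`.
#' @export
read_tabular_model <- function(reactions_tsv, metabolites_tsv, genes_tsv = NULL,
                               id = "model", objective = NULL) {
  rxn <- utils::read.delim(reactions_tsv, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  met <- utils::read.delim(metabolites_tsv, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  for (col in c("id", "equation")) {
    if (!col %in% names(rxn)) stop("reactions table lacks required column: ", col)
  }
  if (!"id" %in% names(met)) stop("metabolites table lacks required column: id")
  if (is.null(met$name)) met$name <- met$id
  if (is.null(met$compartment)) met$compartment <- "c"
  if (is.null(rxn$name)) rxn$name <- rxn$id
  if (is.null(rxn$gpr)) rxn$gpr <- NA_character_
  if (is.null(rxn$sbo)) rxn$sbo <- NA_character_
  if (is.null(rxn$lb)) rxn$lb <- NA_real_
  if (is.null(rxn$ub)) rxn$ub <- NA_real_

  eq <- lapply(rxn$equation, parse_equation)
  reversible <- vapply(eq, `[[`, logical(1), "reversible")
  rxn$lb <- ifelse(is.na(rxn$lb), ifelse(reversible, -1000, 0), rxn$lb)
  rxn$ub <- ifelse(is.na(rxn$ub), 1000, rxn$ub)
  stoich <- stats::setNames(lapply(eq, `[[`, "stoichiometry"), rxn$id)
  gprs <- stats::setNames(lapply(rxn$gpr, function(g) {
    if (is.na(g)) NULL else parse_gpr(g)
  }), rxn$id)

  genes <- NULL
  if (!is.null(genes_tsv)) {
    genes <- utils::read.delim(genes_tsv, stringsAsFactors = FALSE,
                               na.strings = c("NA", ""))
    if (!"id" %in% names(genes)) stop("genes table lacks required column: id")
  }
  if (is.null(objective)) {
    hit <- grepl("biomass", rxn$id, ignore.case = TRUE) |
      grepl("biomass", rxn$name, ignore.case = TRUE)
    if (!any(hit)) stop("no objective given and no reaction matching 'biomass' found")
    objective <- rxn$id[which(hit)[1]]
  }
  new_model(
    id = id,
    metabolites = met[, intersect(c("id", "name", "compartment", "formula", "charge"),
                                  names(met))],
    reactions = rxn[, c("id", "name", "lb", "ub", "sbo")],
    stoichiometry = stoich,
    gpr = gprs,
    genes = genes,
    objective = objective
  )
}

#' Parse a reaction equation string
#'
#' `"2 A + B -> C"`: coefficients are optional (default 1), species are
#' whitespace-separated from coefficients, sides joined by `->` (irreversible)
#' or `<=>` (reversible). One side may be empty, as in exchange or drain
#' reactions (`"A ->"`).
#'
#' @param equation equation string.
#' @return List with `stoichiometry` (named numeric, negative = consumed) and
#'   `reversible` (logical).
#' @export
parse_equation <- function(equation) {
  stopifnot(is.character(equation), length(equation) == 1L, !is.na(equation))
  reversible <- grepl("<=>", equation, fixed = TRUE)
  arrow <- if (reversible) "<=>" else "->"
  if (!grepl(arrow, equation, fixed = TRUE)) {
    stop("equation lacks an arrow ('->' or '<=>'): ", equation)
  }
  sides <- strsplit(equation, arrow, fixed = TRUE)[[1]]
  if (length(sides) > 2L) stop("equation has more than one arrow: ", equation)
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric())
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric()
    for (term in terms) {
      if (!nzchar(term)) stop("empty term in equation: ", equation)
      bits <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(bits) == 2L && grepl("^[0-9.]+$", bits[1])) {
        coef <- as.numeric(bits[1]); sp <- bits[2]
      } else if (length(bits) == 1L) {
        coef <- 1; sp <- bits[1]
      } else {
        stop("cannot parse equation term '", term, "' in: ", equation)
      }
      out[sp] <- (if (sp %in% names(out)) out[[sp]] else 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (sp in names(rhs)) {
    st[sp] <- (if (sp %in% names(st)) st[[sp]] else 0) + rhs[[sp]]
  }
  list(stoichiometry = st, reversible = reversible)
}

format_equation <- function(st, reversible) {
  fmt_side <- function(x) {
    if (length(x) == 0L) return("")
    paste(ifelse(abs(x) == 1, names(x), paste(abs(x), names(x))), collapse = " + ")
  }
  lhs <- st[st < 0]; rhs <- st[st > 0]
  paste(fmt_side(lhs), if (reversible) "<=>" else "->", fmt_side(rhs))
}

#' Write a model in the tabular dialect
#'
#' @param model a `gem_model`.
#' @param dir output directory; `reactions.tsv`, `metabolites.tsv` and
#'   `genes.tsv` are created inside it.
#' @return `dir`, invisibly.
#' @export
write_tabular_model <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rev <- is_reversible(model)
  rxn <- model$reactions
  rxn$equation <- vapply(rxn$id, function(rid) {
    format_equation(model$stoichiometry[[rid]], rev[[rid]])
  }, "")
  rxn$gpr <- vapply(rxn$id, function(rid) format_gpr(model$gpr[[rid]]), "")
  utils::write.table(rxn[, c("id", "name", "equation", "lb", "ub", "gpr", "sbo")],
                     file.path(dir, "reactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(model$metabolites, file.path(dir, "metabolites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(model$genes, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
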