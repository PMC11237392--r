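#' Build a template-to-hybrid gene mapping from ortholog tables
#'
#' Consumes ortholog records — hybrid gene, template gene, parental
#' sub-genome, percent identity and evidence level (`gene` for
#' nucleotide-level calls, `protein` for protein-level calls) — and resolves
#' them into one call per (template gene, parent): records at or below the
#' identity threshold are discarded; protein-level records can rescue
#' template genes that no gene-level record reached; and when the gene-level
#' and protein-level annotation of the same hybrid gene disagree (different
#' isoforms attributed at the two levels), the disagreement is logged and the
#' protein-level call wins.
#'
#' @param template a template `gem_model`.
#' @param orthologs data.frame with columns `hybrid_gene_id`,
#'   `template_gene_id`, `parent` (`"parentA"`/`"parentB"`),
#'   `percent_identity` (0-100), `evidence` (`"gene"`/`"protein"`). See
#'   [read_ortholog_table()].
#' @param identity_threshold minimum percent identity, strict (default 70:
#'   a record at exactly 70 is excluded).
#' @return Object of class `hybrid_mapping`: `entries` (resolved calls, one
#'   row per template gene x parent), `unmapped` (template genes with no
#'   surviving call), `conflicts` (hybrid genes with discordant gene/protein
#'   annotation), `template_genes`, `identity_threshold`.
#' @export
build_mapping <- function(template, orthologs, identity_threshold = 70) {
  orthologs <- as.data.frame(orthologs, stringsAsFactors = FALSE)
  need <- setdiff(c("hybrid_gene_id", "template_gene_id", "parent",
                    "percent_identity", "evidence"), names(orthologs))
  if (length(need)) stop("ortholog table lacks column(s): ", paste(need, collapse = ", "))
  if (!all(orthologs$parent %in% c("parentA", "parentB"))) {
    stop("parent must be 'parentA' or 'parentB'")
  }
  if (!all(orthologs$evidence %in% c("gene", "protein"))) {
    stop("evidence must be 'gene' or 'protein'")
  }
  if (any(orthologs$percent_identity < 0 | orthologs$percent_identity > 100)) {
    stop("percent_identity must lie in [0, 100]")
  }
  template_genes <- template$genes$id
  unknown <- setdiff(orthologs$template_gene_id, template_genes)
  if (length(unknown)) stop("ortholog table references template gene(s) not in model: ",
    paste(unknown, collapse = ", "))

  kept <- orthologs[orthologs$percent_identity > identity_threshold, , drop = FALSE]

  # one-to-one within each (parent, evidence) stratum
  for (p in unique(kept$parent)) for (ev in unique(kept$evidence)) {
    s <- kept[kept$parent == p & kept$evidence == ev, ]
    dup_t <- unique(s$template_gene_id[duplicated(s$template_gene_id)])
    dup_h <- unique(s$hybrid_gene_id[duplicated(s$hybrid_gene_id)])
    if (length(dup_t) || length(dup_h)) {
      stop("ortholog calls are not one-to-one in stratum (", p, ", ", ev,
           "); offending ids: ", paste(c(dup_t, dup_h), collapse = ", "))
    }
  }

  # gene- vs protein-level disagreement for the same hybrid gene
  conflicts <- data.frame(hybrid_gene_id = character(),
                          gene_level_call = character(),
                          protein_level_call = character(),
                          stringsAsFactors = FALSE)
  g_lvl <- kept[kept$evidence == "gene", ]
  p_lvl <- kept[kept$evidence == "protein", ]
  common <- intersect(g_lvl$hybrid_gene_id, p_lvl$hybrid_gene_id)
  for (h in common) {
    tg <- g_lvl$template_gene_id[g_lvl$hybrid_gene_id == h]
    tp <- p_lvl$template_gene_id[p_lvl$hybrid_gene_id == h]
    if (!identical(sort(tg), sort(tp))) {
      conflicts <- rbind(conflicts, data.frame(
        hybrid_gene_id = h, gene_level_call = paste(tg, collapse = ";"),
        protein_level_call = paste(tp, collapse = ";"), stringsAsFactors = FALSE))
      # protein call wins: discard this hybrid gene's gene-level records
      kept <- kept[!(kept$evidence == "gene" & kept$hybrid_gene_id == h), ]
    }
  }

  # resolve one call per (template gene, parent), protein evidence preferred
  entries <- kept[order(kept$template_gene_id, kept$parent,
                        kept$evidence != "protein"), ]
  key <- paste(entries$template_gene_id, entries$parent)
  entries <- entries[!duplicated(key), c("template_gene_id", "hybrid_gene_id",
                                         "parent", "evidence", "percent_identity")]
  rownames(entries) <- NULL
  unmapped <- setdiff(template_genes, entries$template_gene_id)
  structure(
    list(entries = entries, unmapped = unmapped, conflicts = conflicts,
         template_genes = template_genes,
         identity_threshold = identity_threshold),
    class = "hybrid_mapping"
  )
}

#' @export
print.hybrid_mapping <- function(x, ...) {
  v <- venn_summary(x)
  cat(sprintf("hybrid_mapping over %d template genes: %d both, %d parentA-only, %d parentB-only, %d unmapped; %d gene/protein conflicts\n",
              length(x$template_genes), v[["both"]], v[["parentA_only"]],
              v[["parentB_only"]], v[["unmapped"]], nrow(x$conflicts)))
  invisible(x)
}

#' Parental-coverage summary of a mapping
#'
#' Counts template genes with both parental alleles, one parent only, or no
#' hybrid ortholog at all. The four categories are disjoint and sum to the
#' template gene total.
#'
#' @param mapping a `hybrid_mapping`.
#' @return Named integer vector `both`, `parentA_only`, `parentB_only`,
#'   `unmapped`.
#' @export
venn_summary <- function(mapping) {
  stopifnot(inherits(mapping, "hybrid_mapping"))
  tab <- table(factor(mapping$entries$parent, levels = c("parentA", "parentB")),
               factor(mapping$entries$template_gene_id,
                      levels = setdiff(mapping$template_genes, mapping$unmapped)))
  hasA <- tab["parentA", ] > 0
  hasB <- tab["parentB", ] > 0
  c(both = sum(hasA & hasB),
    parentA_only = sum(hasA & !hasB),
    parentB_only = sum(!hasA & hasB),
    unmapped = length(mapping$unmapped))
}

#' Rewrite template GPR rules with hybrid alleles
#'
#' Replaces every template gene leaf by its hybrid allele(s): a gene with
#' both parental orthologs becomes an `or` of the two allele leaves (either
#' parent's product can catalyze — functional redundancy), a single-parent
#' gene becomes one leaf, and an unmapped gene is dropped from its Boolean
#' context (an `or` loses the operand; an `and` containing it becomes
#' unsatisfiable, mirroring the removal of protein complexes with a missing
#' subunit). Allele identifiers are the template gene's common name plus a
#' parent suffix. Stoichiometry and bounds are untouched; use [prune_model()]
#' afterwards to drop unsupported reactions and orphan genes.
#'
#' @param template a template `gem_model`.
#' @param mapping a `hybrid_mapping` built against `template`.
#' @param suffixes named character vector mapping `parentA`/`parentB` to the
#'   allele name suffixes (default `"_Scer"` / `"_Seub"`).
#' @param hybrid_id id for the resulting model.
#' @return A `gem_model` whose genes are hybrid alleles; reactions that lost
#'   all support carry an unsatisfiable GPR until pruned.
#' @export
rewrite_gprs <- function(template, mapping,
                         suffixes = c(parentA = "_Scer", parentB = "_Seub"),
                         hybrid_id = paste0(template$id, "_hybrid")) {
  stopifnot(inherits(mapping, "hybrid_mapping"))
  stopifnot(all(c("parentA", "parentB") %in% names(suffixes)))
  gen <- template$genes
  base_name <- stats::setNames(ifelse(is.na(gen$name) | !nzchar(gen$name),
                                      gen$id, gen$name), gen$id)
  entries <- mapping$entries

  allele_id <- paste0(base_name[entries$template_gene_id],
                      suffixes[entries$parent])
  if (anyDuplicated(allele_id)) {
    stop("allele id collision after suffixing: ",
         paste(unique(allele_id[duplicated(allele_id)]), collapse = ", "))
  }
  entries$allele_id <- allele_id

  alleles_of <- split(entries$allele_id, entries$template_gene_id)
  substitute_leaf <- function(gid) {
    al <- alleles_of[[gid]]
    if (is.null(al)) return(gpr_false())
    if (length(al) == 1L) return(gpr_leaf(al))
    do.call(gpr_or, lapply(sort(al), gpr_leaf))
  }
  rewrite <- function(node) {
    if (is.null(node)) return(NULL)
    if (node$kind == "leaf") return(substitute_leaf(node$gene))
    if (node$kind == "false") return(node)
    children <- lapply(node$children, rewrite)
    dead <- vapply(children, function(ch) ch$kind == "false", logical(1))
    if (node$kind == "and") {
      if (any(dead)) return(gpr_false())
      if (length(children) == 1L) return(children[[1]])
      return(new_gpr_node("and", children = children))
    }
    children <- children[!dead]
    if (length(children) == 0L) return(gpr_false())
    if (length(children) == 1L) return(children[[1]])
    new_gpr_node("or", children = children)
  }

  model <- template
  model$id <- hybrid_id
  model$gpr <- lapply(template$gpr, rewrite)

  by_tmpl <- split(entries, entries$template_gene_id)
  partner <- rep(NA_character_, nrow(entries))
  names(partner) <- entries$allele_id
  for (e in by_tmpl) {
    if (nrow(e) == 2L) {
      partner[e$allele_id[1]] <- e$allele_id[2]
      partner[e$allele_id[2]] <- e$allele_id[1]
    }
  }
  model$genes <- data.frame(
    id = entries$allele_id,
    name = entries$allele_id,
    origin = entries$parent,
    allele_partner = unname(partner[entries$allele_id]),
    template_gene_id = entries$template_gene_id,
    hybrid_gene_id = entries$hybrid_gene_id,
    stringsAsFactors = FALSE
  )
  validate_model(model)
  model
}

#' Prune unsupported reactions and orphan genes
#'
#' Removes, in order: (1) reactions whose GPR is unsatisfiable even with
#' every remaining gene present (all catalytic support lost during the hybrid
#' rewrite); then (2) genes that appear in no remaining GPR. The ordering
#' means genes orphaned by reaction removal are dropped too. Reactions with
#' no GPR (exchanges, spontaneous) are never pruned.
#'
#' @param model a `gem_model`.
#' @return List with `model` (pruned) and `report` (data.frame `entity_id`,
#'   `kind`, `reason`).
#' @export
prune_model <- function(model) {
  report <- data.frame(entity_id = character(), kind = character(),
                       reason = character(), stringsAsFactors = FALSE)
  dead_rxns <- names(model$gpr)[!vapply(model$gpr, evaluate_gpr, logical(1),
                                        absent = character())]
  if (length(dead_rxns)) {
    report <- rbind(report, data.frame(
      entity_id = dead_rxns, kind = "reaction",
      reason = "GPR unsatisfiable: no supporting gene content",
      stringsAsFactors = FALSE))
    model$reactions <- model$reactions[!(model$reactions$id %in% dead_rxns), ]
    model$stoichiometry <- model$stoichiometry[model$reactions$id]
    model$gpr <- model$gpr[intersect(names(model$gpr), model$reactions$id)]
  }
  used <- unique(unlist(lapply(model$gpr, gpr_genes)))
  orphans <- setdiff(model$genes$id, used)
  if (length(orphans)) {
    report <- rbind(report, data.frame(
      entity_id = orphans, kind = "gene",
      reason = "not associated to any reaction", stringsAsFactors = FALSE))
    model$genes <- model$genes[!(model$genes$id %in% orphans), ]
    # sever allele partnerships pointing at removed genes
    bad <- !is.na(model$genes$allele_partner) &
      !(model$genes$allele_partner %in% model$genes$id)
    model$genes$allele_partner[bad] <- NA_character_
  }
  validate_model(model)
  list(model = model, report = report)
}

#' Read an ortholog table TSV
#'
#' Expects columns `hybrid_gene_id`, `template_gene_id`, `parent`,
#' `percent_identity`, `evidence`. Output of ortholog-detection pipelines can
#' be adapted by renaming columns via `col_map`.
#'
#' @param path TSV path.
#' @param col_map optional named character vector mapping this package's
#'   column names to the file's (e.g.
#'   `c(hybrid_gene_id = "query", template_gene_id = "target")`).
#' @return data.frame suitable for [build_mapping()].
#' @export
read_ortholog_table <- function(path, col_map = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      names(df)[names(df) == col_map[[std]]] <- std
    }
  }
  df
}
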