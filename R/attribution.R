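#' Attribute a reaction's expression support to parental sub-genomes
#'
#' In a hybrid, a reaction carried by redundant parental alleles can be
#' driven by either sub-genome; expression data reveal which parent actually
#' supports it under a given condition. The share of each parent is computed
#' recursively over the GPR tree:
#'
#' * a leaf contributes its parent of origin, weighted by its expression;
#' * an `or` group of alternatives is the expression-weighted average of its
#'   children — for a flat `or` over alleles this is
#'   \eqn{\sum TPM(\text{parent's leaves}) / \sum TPM(\text{all leaves})};
#' * an `and` complex is the unweighted mean of its member groups' shares
#'   (each subunit slot counts once, however strongly expressed).
#'
#' The call is `inconclusive` when the total expression over all leaves does
#' not exceed `threshold` — too little signal to apportion.
#'
#' @param gpr a [gpr_node].
#' @param tpm named numeric vector of expression levels.
#' @param origin named character vector mapping each leaf gene to
#'   `"parentA"`, `"parentB"` or `"hybrid-specific"`; see [gene_origins()].
#'   A leaf without an entry is an error. Hybrid-specific genes take part in
#'   neither parent's share and are excluded from the weighting.
#' @param threshold minimum total leaf expression for a conclusive call
#'   (default 10, the expression-gating threshold).
#' @param condition optional condition label carried into the result.
#' @param reaction_id optional reaction id carried into the result.
#' @return One-row data.frame: `reaction_id`, `condition`, `prop_parentA`,
#'   `prop_parentB` (summing to 1 when conclusive, `NA` otherwise), `status`
#'   (`"conclusive"`/`"inconclusive"`).
#' @export
#' @examples
#' attribute_reaction(parse_gpr("G_Scer or G_Seub"), c(G_Scer = 20, G_Seub = 80),
#'                    c(G_Scer = "parentA", G_Seub = "parentB"))
attribute_reaction <- function(gpr, tpm, origin, threshold = 10,
                               condition = NA_character_,
                               reaction_id = NA_character_) {
  stopifnot(is_gpr_node(gpr))
  leaves <- gpr_genes(gpr)
  no_origin <- setdiff(leaves, names(origin))
  if (length(no_origin)) {
    stop("no parental origin for gene(s): ", paste(no_origin, collapse = ", "))
  }
  lv <- function(g) {
    x <- unname(tpm[g])
    if (length(x) == 0L || is.na(x)) 0 else x
  }
  # share(node) returns c(propA, propB, weight); weight is the node's
  # parental expression mass (leaf TPM; or: sum; and: min), used to weight
  # 'or' averaging. Hybrid-specific leaves carry zero parental weight.
  share <- function(node) {
    if (node$kind == "leaf") {
      o <- origin[[node$gene]]
      w <- lv(node$gene)
      if (o == "parentA") return(c(w, 0, w))
      if (o == "parentB") return(c(0, w, w))
      return(c(0, 0, 0))
    }
    if (node$kind == "false") return(c(0, 0, 0))
    ch <- lapply(node$children, share)
    if (node$kind == "or") {
      a <- sum(vapply(ch, `[`, numeric(1), 1))
      b <- sum(vapply(ch, `[`, numeric(1), 2))
      w <- sum(vapply(ch, `[`, numeric(1), 3))
      return(c(a, b, w))
    }
    # and: unweighted mean of the children's proportions, scaled back to a
    # weight of min(child weights) so nested groups stay comparable
    props <- t(vapply(ch, function(x) {
      if (x[3] > 0) x[1:2] / x[3] else c(NA_real_, NA_real_)
    }, numeric(2)))
    defined <- !is.na(props[, 1])
    w <- min(vapply(ch, `[`, numeric(1), 3))
    if (!any(defined)) return(c(0, 0, 0))
    p <- colMeans(props[defined, , drop = FALSE])
    c(p[1] * max(w, 1e-300), p[2] * max(w, 1e-300), max(w, 1e-300))
  }
  total <- sum(vapply(leaves, lv, numeric(1)))
  res <- share(gpr)
  conclusive <- total > threshold && res[3] > 0
  data.frame(
    reaction_id = reaction_id, condition = condition,
    prop_parentA = if (conclusive) res[1] / res[3] else NA_real_,
    prop_parentB = if (conclusive) res[2] / res[3] else NA_real_,
    status = if (conclusive) "conclusive" else "inconclusive",
    stringsAsFactors = FALSE
  )
}

#' Resolve parental origins for a model's genes
#'
#' Uses the model's gene table where it records an origin, falling back to
#' the allele name suffix (`_Scer` -> parentA, `_Seub` -> parentB, `_Spast`
#' -> hybrid-specific, matching the suffix convention of [rewrite_gprs()]).
#'
#' @param model a `gem_model`.
#' @param suffixes named character vector mapping origins to suffixes.
#' @return Named character vector gene id -> origin; genes that resolve to
#'   `"template"` and match no suffix are returned as `NA`.
#' @export
gene_origins <- function(model, suffixes = c(parentA = "_Scer",
                                             parentB = "_Seub",
                                             `hybrid-specific` = "_Spast")) {
  org <- stats::setNames(model$genes$origin, model$genes$id)
  for (g in names(org)) {
    if (is.na(org[[g]]) || org[[g]] == "template") {
      hit <- NA_character_
      for (o in names(suffixes)) {
        if (endsWith(g, suffixes[[o]])) { hit <- o; break }
      }
      org[[g]] <- hit
    }
  }
  org
}

#' Attribute every reaction across expression conditions
#'
#' Runs [attribute_reaction()] for each GPR-bearing reaction under each
#' condition's expression profile. Reactions whose GPR references genes with
#' no resolvable origin raise an error (silent exclusion would bias the
#' summary); conditions missing expression for a reaction's genes simply
#' drive it towards `inconclusive`.
#'
#' @param model a `gem_model` with parental gene origins (see
#'   [gene_origins()]).
#' @param profiles named list: condition label -> `expression_profile` or
#'   named TPM vector.
#' @param threshold conclusiveness threshold, as in [attribute_reaction()].
#' @return data.frame with one row per (reaction, condition), columns as in
#'   [attribute_reaction()].
#' @export
attribute_model <- function(model, profiles, threshold = 10) {
  stopifnot(is.list(profiles), length(profiles) >= 1L,
            !is.null(names(profiles)))
  origin <- gene_origins(model)
  used <- unique(unlist(lapply(model$gpr, gpr_genes)))
  unresolved <- used[is.na(origin[used])]
  if (length(unresolved)) {
    stop("cannot resolve parental origin for gene(s): ",
         paste(unresolved, collapse = ", "))
  }
  rows <- list()
  for (cond in names(profiles)) {
    tpm <- tpm_vector(profiles[[cond]])
    for (rid in names(model$gpr)) {
      rows[[length(rows) + 1L]] <- attribute_reaction(
        model$gpr[[rid]], tpm, origin, threshold = threshold,
        condition = cond, reaction_id = rid)
    }
  }
  do.call(rbind, rows)
}

#' Detect a parental-usage shift across ordered conditions
#'
#' Classifies a reaction's allele usage as `shifted` when the parent-A share
#' differs by at least `delta` between any two conclusive conditions (e.g.
#' growth temperatures), `stable` otherwise, and `indeterminate` when fewer
#' than two conditions are conclusive.
#'
#' @param shares data.frame of [attribute_model()] rows for one reaction
#'   (columns `prop_parentA`, `status`).
#' @param delta minimum share difference to call a shift (default 0.10).
#' @return `"stable"`, `"shifted"` or `"indeterminate"`.
#' @export
#' @examples
#' # 0.50 -> 0.40 -> 0.30 across temperatures: shifted at delta 0.10
detect_shift <- function(shares, delta = 0.10) {
  stopifnot(delta > 0)
  p <- shares$prop_parentA[shares$status == "conclusive"]
  if (length(p) < 2L) return("indeterminate")
  if (max(p) - min(p) >= delta) "shifted" else "stable"
}

#' Export attribution results as a Table-style report
#'
#' Rounds parental shares to 5% granularity for a human-readable table while
#' the input keeps full precision.
#'
#' @param shares data.frame from [attribute_model()].
#' @param path optional TSV output path.
#' @param reaction_ids optional filter (e.g. one pathway's reactions).
#' @return The (filtered, rounded) data.frame, invisibly if written.
#' @export
attribution_report <- function(shares, path = NULL, reaction_ids = NULL) {
  if (!is.null(reaction_ids)) {
    shares <- shares[shares$reaction_id %in% reaction_ids, ]
  }
  out <- shares
  rounded <- round(out$prop_parentA * 20) / 20
  out$prop_parentA <- ifelse(out$status == "conclusive", rounded, NA)
  out$prop_parentB <- ifelse(out$status == "conclusive", 1 - rounded, NA)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
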