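#' TPM-normalize raw RNA-seq counts
#'
#' Transcripts-per-million normalization corrects raw read counts for gene
#' length and sequencing depth: reads per kilobase
#' \eqn{RPK_g = count_g / length_g(kb)}, the per-million scaling factor is
#' \eqn{\sum_g RPK_g / 10^6}, and \eqn{TPM_g = RPK_g / factor}. Every library
#' therefore sums to exactly \eqn{10^6}, making genes comparable within and
#' across libraries.
#'
#' @param counts named numeric vector of non-negative raw counts (names are
#'   gene ids).
#' @param lengths_kb named numeric vector of gene lengths in kilobases
#'   covering every gene in `counts` (use `lengths_bp / 1000` for
#'   base pairs).
#' @param library_id optional library label.
#' @return data.frame of class `expression_profile` with columns `gene_id`,
#'   `raw_count`, `length_kb`, `rpk`, `tpm`; attribute `library_id`.
#' @export
#' @examples
#' tpm_normalize(c(g1 = 100, g2 = 300), c(g1 = 1, g2 = 3))  # both 500000 TPM
tpm_normalize <- function(counts, lengths_kb, library_id = NA_character_) {
  if (length(counts) == 0L) stop("empty library: no counts supplied")
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be a named vector of gene ids")
  }
  if (any(counts < 0)) stop("raw counts must be non-negative")
  missing_len <- setdiff(names(counts), names(lengths_kb))
  if (length(missing_len)) stop("no length for gene(s): ",
    paste(missing_len, collapse = ", "))
  len <- lengths_kb[names(counts)]
  if (any(!is.finite(len) | len <= 0)) stop("gene lengths must be positive")
  rpk <- counts / len
  scaling <- sum(rpk) / 1e6
  if (scaling == 0) stop("library has zero total signal; cannot normalize")
  out <- data.frame(gene_id = names(counts), raw_count = as.numeric(counts),
                    length_kb = as.numeric(len), rpk = as.numeric(rpk),
                    tpm = as.numeric(rpk / scaling), stringsAsFactors = FALSE)
  attr(out, "library_id") <- library_id
  class(out) <- c("expression_profile", class(out))
  out
}

#' Extract a named TPM vector from an expression profile
#'
#' @param profile an `expression_profile` (from [tpm_normalize()]) or already
#'   a named numeric vector, returned as-is.
#' @return Named numeric vector of TPM values.
#' @export
tpm_vector <- function(profile) {
  if (is.numeric(profile)) return(profile)
  stopifnot(is.data.frame(profile), all(c("gene_id", "tpm") %in% names(profile)))
  stats::setNames(profile$tpm, profile$gene_id)
}

#' Constrain reaction bounds from transcriptome data
#'
#' Maps expression onto flux capacity: for each reaction with a GPR whose
#' leaf genes are *all* expressed above `threshold_abundance`, the rule is
#' aggregated over the expression values (`or` = sum of alternative
#' catalysts, `and` = minimum over complex subunits, applied recursively; see
#' [aggregate_gpr()]) and the result E caps the bounds — irreversible
#' reactions get `ub = min(E, ub)`, reversible ones `(max(-E, lb),
#' min(E, ub))`. Reactions with any leaf at or below the threshold, or
#' without a GPR, are left untouched, so bounds are only ever tightened. TPM
#' magnitudes are used directly as flux-bound magnitudes
#' (mmol·gDCW^-1·h^-1 equivalents), a deliberately heuristic unit convention
#' documented in the package vignette.
#'
#' @param model a `gem_model`.
#' @param expression an `expression_profile` or named TPM vector. Genes
#'   absent from it count as unexpressed (level 0), which keeps the reaction
#'   unconstrained but flags it.
#' @param threshold_abundance expression level a gene must strictly exceed to
#'   count as expressed (default 10, above typical RNA-seq noise).
#' @param max_bound cap on any expression-derived bound magnitude
#'   (default 1000, the conventional unconstrained flux bound).
#' @param gating `"all"` (default): constrain only when every leaf gene is
#'   expressed above the threshold; `"any"`: one expressed gene suffices (a
#'   satisfied `or` branch can justify the constraint).
#' @return List: `model` (constrained), `n_constrained` (number of reactions
#'   whose bounds changed), `constrained_ids`, `incomplete_ids` (reactions
#'   whose GPR has genes missing from the expression data).
#' @export
map_transcriptome_data <- function(model, expression, threshold_abundance = 10,
                                   max_bound = 1000, gating = c("all", "any")) {
  gating <- match.arg(gating)
  stopifnot(threshold_abundance > 0, max_bound > 0)
  tpm <- tpm_vector(expression)
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM values must be non-negative")
  constrained <- character()
  incomplete <- character()
  rev <- is_reversible(model)
  for (rid in names(model$gpr)) {
    g <- model$gpr[[rid]]
    leaves <- gpr_genes(g)
    if (length(leaves) == 0L) next
    miss <- setdiff(leaves, names(tpm))
    if (length(miss)) incomplete <- c(incomplete, rid)
    levels <- ifelse(leaves %in% names(tpm), tpm[leaves], 0)
    expressed <- levels > threshold_abundance
    if (if (gating == "all") !all(expressed) else !any(expressed)) next
    E <- min(aggregate_gpr(g, tpm), max_bound)
    i <- match(rid, model$reactions$id)
    old_lb <- model$reactions$lb[i]; old_ub <- model$reactions$ub[i]
    new_ub <- min(E, old_ub)
    new_lb <- if (rev[[rid]]) max(-E, old_lb) else old_lb
    if (new_lb != old_lb || new_ub != old_ub) {
      model$reactions$lb[i] <- new_lb
      model$reactions$ub[i] <- new_ub
      constrained <- c(constrained, rid)
    }
  }
  list(model = model, n_constrained = length(constrained),
       constrained_ids = constrained, incomplete_ids = unique(incomplete))
}

#' Count reactions whose bounds differ between two models
#'
#' @param model_before,model_after two `gem_model`s over the same reaction
#'   set (e.g. before and after [map_transcriptome_data()]).
#' @return Integer count of reactions with changed `lb` or `ub`.
#' @export
count_constrained <- function(model_before, model_after) {
  if (!setequal(model_before$reactions$id, model_after$reactions$id)) {
    stop("models do not share the same reaction set")
  }
  idx <- match(model_before$reactions$id, model_after$reactions$id)
  sum(model_before$reactions$lb != model_after$reactions$lb[idx] |
      model_before$reactions$ub != model_after$reactions$ub[idx])
}

#' Read an expression table TSV
#'
#' Accepts either raw data — columns `gene_id`, `raw_count` and `length_bp`
#' (or `length_kb`) — which is TPM-normalized, or a precomputed `tpm` column
#' used verbatim.
#'
#' @param path TSV path.
#' @param library_id optional library label.
#' @return An `expression_profile` (raw input) or named TPM vector
#'   (precomputed input).
#' @export
read_expression <- function(path, library_id = NA_character_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) stop("expression table lacks column: gene_id")
  if ("tpm" %in% names(df)) {
    return(stats::setNames(df$tpm, df$gene_id))
  }
  if (!"raw_count" %in% names(df)) {
    stop("expression table needs either a 'tpm' or a 'raw_count' column")
  }
  len_kb <- if ("length_kb" %in% names(df)) df$length_kb
            else if ("length_bp" %in% names(df)) df$length_bp / 1000
            else stop("expression table needs 'length_kb' or 'length_bp'")
  tpm_normalize(stats::setNames(df$raw_count, df$gene_id),
                stats::setNames(len_kb, df$gene_id), library_id = library_id)
}
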