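#' Assemble the flux balance LP of a model
#'
#' Builds the stoichiometric matrix \eqn{S} (metabolites x reactions, column
#' `j` holding the signed coefficients of reaction `j`), the objective
#' indicator vector and the flux bound vectors — the linear program
#' \eqn{\max c^T v,\ S v = 0,\ v_l \le v \le v_u} whose optimum FBA reports.
#'
#' @param model a `gem_model`.
#' @return List of class `lp_problem`: `S`, `obj`, `lb`, `ub`,
#'   `reaction_ids`, `metabolite_ids`.
#' @export
build_lp <- function(model) {
  mids <- model$metabolites$id
  rids <- model$reactions$id
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (rid in rids) {
    st <- model$stoichiometry[[rid]]
    S[names(st), rid] <- st
  }
  obj <- as.numeric(rids == model$objective)
  structure(
    list(S = S, obj = obj, lb = model$reactions$lb, ub = model$reactions$ub,
         reaction_ids = rids, metabolite_ids = mids),
    class = "lp_problem"
  )
}

#' Flux balance analysis
#'
#' Maximizes the objective reaction's flux under steady-state mass balance
#' (\eqn{S v = 0}) and the model's flux bounds. The optimum (e.g. biomass
#' flux) is unique; the flux vector returned is one optimal vertex and may be
#' non-unique when alternate optima exist.
#'
#' @param model a `gem_model`.
#' @return List of class `fba_result`: `status`, `objective`, `fluxes`
#'   (named over reactions) and `residual` (\eqn{\|S v\|_\infty}).
#'   Infeasible/unbounded statuses are propagated, never reported as zero
#'   growth.
#' @export
run_fba <- function(model) {
  lp <- build_lp(model)
  sol <- solve_lp(lp$obj, lp$S, rep(0, nrow(lp$S)), lp$lb, lp$ub,
                  maximize = TRUE)
  res <- list(status = sol$status, objective = sol$objective, fluxes = NULL,
              residual = NA_real_)
  if (sol$status == "optimal") {
    res$fluxes <- stats::setNames(sol$x, lp$reaction_ids)
    res$residual <- max(abs(lp$S %*% sol$x))
  }
  class(res) <- "fba_result"
  res
}

#' @export
print.fba_result <- function(x, ...) {
  cat(sprintf("FBA %s; objective = %s\n", x$status,
              format(x$objective, digits = 6)))
  invisible(x)
}

#' Flux variability analysis
#'
#' For each reaction of interest, minimizes and maximizes its flux while
#' holding the original objective at at least a fraction `gamma` of the FBA
#' optimum \eqn{Z_0} (`gamma = 1` explores alternate optima; `gamma < 1`
#' admits suboptimal network states). Two LPs per reaction.
#'
#' @param model a `gem_model`.
#' @param reactions reaction ids to scan (default: all).
#' @param gamma fraction of the optimum to retain, in `[0, 1]`.
#' @return data.frame with columns `reaction_id`, `min`, `max`, `status`,
#'   plus attributes `Z0` and `gamma`.
#' @export
run_fva <- function(model, reactions = NULL, gamma = 1) {
  stopifnot(gamma >= 0, gamma <= 1)
  lp <- build_lp(model)
  fba <- run_fba(model)
  if (fba$status != "optimal") {
    stop("FVA requires an optimal FBA solution; status was ", fba$status)
  }
  Z0 <- fba$objective
  if (is.null(reactions)) reactions <- lp$reaction_ids
  unknown <- setdiff(reactions, lp$reaction_ids)
  if (length(unknown)) stop("unknown reaction(s): ", paste(unknown, collapse = ", "))

  # Append the objective-retention row  w'v - s = gamma * Z0  with slack
  # s >= 0, i.e. the inequality w'v >= gamma * Z0.
  m <- nrow(lp$S); n <- ncol(lp$S)
  A <- rbind(cbind(lp$S, 0), c(lp$obj, -1))
  b <- c(rep(0, m), gamma * Z0)
  lb <- c(lp$lb, 0)
  ub <- c(lp$ub, Inf)

  out <- data.frame(reaction_id = reactions, min = NA_real_, max = NA_real_,
                    status = "optimal", stringsAsFactors = FALSE)
  for (k in seq_along(reactions)) {
    j <- match(reactions[k], lp$reaction_ids)
    e <- numeric(n + 1); e[j] <- 1
    lo <- solve_lp(e, A, b, lb, ub, maximize = FALSE)
    hi <- solve_lp(e, A, b, lb, ub, maximize = TRUE)
    if (lo$status == "optimal" && hi$status == "optimal") {
      out$min[k] <- lo$objective
      out$max[k] <- hi$objective
    } else {
      out$status[k] <- if (lo$status != "optimal") lo$status else hi$status
    }
  }
  attr(out, "Z0") <- Z0
  attr(out, "gamma") <- gamma
  out
}

#' Simulate gene knockouts
#'
#' Re-evaluates every GPR rule with the given genes absent; reactions whose
#' rule is no longer satisfied lose all catalytic support and have their flux
#' bounds closed to `(0, 0)`. Reactions without a rule (exchanges,
#' spontaneous reactions) are untouched. In an allele-redundant hybrid,
#' deleting a single parental allele of an `or` pair leaves the reaction
#' open — the redundancy the hybrid GPR rewrite encodes.
#'
#' @param model a `gem_model`.
#' @param genes character vector of gene ids to delete.
#' @return The knockout model.
#' @export
knockout <- function(model, genes) {
  unknown <- setdiff(genes, model$genes$id)
  if (length(unknown)) stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  if (length(genes) == 0L) return(model)
  for (rid in names(model$gpr)) {
    if (!evaluate_gpr(model$gpr[[rid]], absent = genes)) {
      i <- match(rid, model$reactions$id)
      model$reactions$lb[i] <- 0
      model$reactions$ub[i] <- 0
    }
  }
  model
}

#' Gene or reaction essentiality scan
#'
#' Computes wild-type growth by FBA, then deletes each gene (or closes each
#' reaction) singly and calls the entity essential when the knockout optimum
#' drops below `threshold_fraction` of wild type. Deterministic given model,
#' medium and threshold. Gene deletions that close no reaction are skipped
#' (growth equals wild type by construction).
#'
#' @param model a `gem_model`.
#' @param medium optional medium (see [apply_medium()]) applied before the
#'   scan.
#' @param mode `"gene"` or `"reaction"`.
#' @param threshold_fraction essential iff knockout growth is strictly below
#'   this fraction of wild-type growth (default 0.01).
#' @return data.frame of class `essentiality_report` with columns `id`,
#'   `growth`, `essential`; attributes `wild_type`, `mode`,
#'   `threshold_fraction`.
#' @export
essentiality_scan <- function(model, medium = NULL,
                              mode = c("gene", "reaction"),
                              threshold_fraction = 0.01) {
  mode <- match.arg(mode)
  if (!is.null(medium)) model <- apply_medium(model, medium)
  wt <- run_fba(model)
  if (wt$status != "optimal" || wt$objective <= 1e-9) {
    stop("wild-type growth is zero or infeasible; the medium cannot support growth")
  }
  ids <- if (mode == "gene") model$genes$id else model$reactions$id
  growth <- numeric(length(ids))
  for (k in seq_along(ids)) {
    ko <- if (mode == "gene") knockout(model, ids[k]) else {
      mm <- model
      i <- match(ids[k], mm$reactions$id)
      mm$reactions$lb[i] <- 0
      mm$reactions$ub[i] <- 0
      mm
    }
    if (identical(ko$reactions$lb, model$reactions$lb) &&
        identical(ko$reactions$ub, model$reactions$ub)) {
      growth[k] <- wt$objective
      next
    }
    sol <- run_fba(ko)
    growth[k] <- if (sol$status == "optimal") sol$objective else 0
  }
  out <- data.frame(id = ids, growth = growth,
                    essential = growth < threshold_fraction * wt$objective,
                    stringsAsFactors = FALSE)
  attr(out, "wild_type") <- wt$objective
  attr(out, "mode") <- mode
  attr(out, "threshold_fraction") <- threshold_fraction
  class(out) <- c("essentiality_report", class(out))
  out
}

#' Census of GPR rule structure
#'
#' Partitions the reactions into six disjoint categories: supported by a
#' single gene; by isoforms only (pure `or`); by one protein complex only
#' (pure `and`); by a mixture of `and` and `or`; no gene association
#' (non-exchange); and exchange reactions without gene association.
#'
#' @param model a `gem_model`.
#' @return Named integer vector `single_gene`, `or_only`, `and_only`,
#'   `mixed`, `no_gene`, `no_gene_exchange`; sums to the reaction count.
#' @export
gpr_census <- function(model) {
  ex <- is_exchange(model)
  counts <- c(single_gene = 0L, or_only = 0L, and_only = 0L, mixed = 0L,
              no_gene = 0L, no_gene_exchange = 0L)
  ops_of <- function(node) {
    if (node$kind %in% c("leaf", "false")) return(character())
    unique(c(node$kind, unlist(lapply(node$children, ops_of))))
  }
  for (rid in model$reactions$id) {
    g <- model$gpr[[rid]]
    cat_ <- if (is.null(g) || g$kind == "false") {
      if (ex[[rid]]) "no_gene_exchange" else "no_gene"
    } else {
      ops <- ops_of(g)
      if (length(ops) == 0L) "single_gene"
      else if (setequal(ops, "or")) "or_only"
      else if (setequal(ops, "and")) "and_only"
      else "mixed"
    }
    counts[cat_] <- counts[cat_] + 1L
  }
  counts
}
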