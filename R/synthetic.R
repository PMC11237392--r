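with_preserved_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a toy template metabolic model
#'
#' Builds a small, connected network whose FBA optimum is known analytically:
#' one substrate exchange, a transport step, `n_parallel_paths` parallel
#' conversion paths whose first steps are capacity-capped at
#' `uptake_per_path`, converging on a biomass metabolite drained by the
#' objective reaction. The optimum therefore equals
#' `uptake_per_path * n_parallel_paths`. GPR rules span all census
#' categories: the transport step is a two-subunit complex (`and`), internal
#' steps are single genes or isozyme pairs (`or`, a seeded fraction), the
#' last internal step (when at least two exist) mixes `and` and `or`, the
#' exchanges and the biomass drain carry no rule, and — when a path is long
#' enough — one spontaneous gene-less internal step is included.
#'
#' @param n_internal_reactions internal (path) reactions, at least
#'   `n_parallel_paths` and at least 1.
#' @param n_parallel_paths parallel routes from substrate to biomass.
#' @param fraction_redundant_genes fraction of single-gene steps upgraded to
#'   isozyme (`or`) pairs, in `[0, 1]`.
#' @param seed integer seed; the same spec and seed give an identical model.
#' @param uptake_per_path flux capacity of each path (default 10).
#' @return A `gem_model` that grows on its default medium.
#' @export
make_template <- function(n_internal_reactions = 6, n_parallel_paths = 2,
                          fraction_redundant_genes = 0.5, seed = 1,
                          uptake_per_path = 10) {
  if (n_internal_reactions < 1) stop("infeasible spec: need at least one internal reaction")
  if (n_parallel_paths < 1) stop("infeasible spec: need at least one path")
  if (n_internal_reactions < n_parallel_paths) {
    stop("infeasible spec: need at least one internal reaction per path")
  }
  stopifnot(fraction_redundant_genes >= 0, fraction_redundant_genes <= 1)
  with_preserved_rng(seed, {
    mets <- data.frame(id = c("A_e", "A_c", "biomass_c"),
                       name = c("substrate (extracellular)", "substrate", "biomass"),
                       compartment = c("e", "c", "c"),
                       formula = c("C6H12O6", "C6H12O6", NA),
                       charge = c(0, 0, NA), stringsAsFactors = FALSE)
    rxns <- data.frame(id = character(), name = character(), lb = numeric(),
                       ub = numeric(), sbo = character(), stringsAsFactors = FALSE)
    stoich <- list(); gprs <- list()
    add_rxn <- function(id, st, lb, ub, gpr_str = NA) {
      rxns <<- rbind(rxns, data.frame(id = id, name = id, lb = lb, ub = ub,
                                      sbo = NA_character_, stringsAsFactors = FALSE))
      stoich[[id]] <<- st
      if (!is.na(gpr_str)) gprs[[id]] <<- parse_gpr(gpr_str)
    }
    total_uptake <- uptake_per_path * n_parallel_paths
    add_rxn("EX_A", c(A_e = -1), lb = -total_uptake, ub = 1000)
    add_rxn("TRANS_A", c(A_e = -1, A_c = 1), lb = 0, ub = 1000,
            gpr_str = "TC1 and TC2")

    # distribute internal reactions over paths (each path >= 1 step)
    per_path <- rep(n_internal_reactions %/% n_parallel_paths, n_parallel_paths)
    extra <- n_internal_reactions %% n_parallel_paths
    if (extra > 0) per_path[seq_len(extra)] <- per_path[seq_len(extra)] + 1L
    idx <- 0L
    spont_idx <- if (max(per_path) >= 3) which.max(per_path) else 0L
    for (p in seq_len(n_parallel_paths)) {
      k <- per_path[p]
      for (s in seq_len(k)) {
        idx <- idx + 1L
        from <- if (s == 1L) "A_c" else sprintf("M_p%d_%d", p, s - 1L)
        to <- if (s == k) "biomass_c" else sprintf("M_p%d_%d", p, s)
        if (!(from %in% mets$id)) {
          mets <- rbind(mets, data.frame(id = from, name = from, compartment = "c",
                                         formula = NA, charge = NA))
        }
        if (!(to %in% mets$id)) {
          mets <- rbind(mets, data.frame(id = to, name = to, compartment = "c",
                                         formula = NA, charge = NA))
        }
        gpr_str <- if (p == spont_idx && s == 2L) {
          NA  # spontaneous, gene-less internal step
        } else if (idx == n_internal_reactions && n_internal_reactions >= 2) {
          sprintf("(X%da or X%db) and X%dc", idx, idx, idx)  # mixed rule
        } else if (stats::runif(1) < fraction_redundant_genes) {
          sprintf("G%da or G%db", idx, idx)
        } else {
          sprintf("G%d", idx)
        }
        add_rxn(sprintf("R_p%d_s%d", p, s), stats::setNames(c(-1, 1), c(from, to)),
                lb = 0, ub = if (s == 1L) uptake_per_path else 1000,
                gpr_str = gpr_str)
      }
    }
    add_rxn("BIOMASS", c(biomass_c = -1), lb = 0, ub = 1000)
    new_model(id = sprintf("toy_s%d", seed), metabolites = mets,
              reactions = rxns, stoichiometry = stoich, gpr = gprs,
              objective = "BIOMASS")
  })
}

#' Generate a synthetic ortholog table for a template model
#'
#' Assigns each template gene a parental-coverage category by a seeded draw —
#' both parents, parent A only, parent B only, or unmapped — and emits
#' ortholog records accordingly. Mapped records draw identities strictly
#' above the threshold; unmapped genes emit a decoy record below it, so
#' threshold filtering is exercised.
#'
#' @param template a `gem_model`.
#' @param fraction_both,fraction_Aonly,fraction_Bonly category probabilities;
#'   their sum must not exceed 1, the remainder is the unmapped fraction.
#' @param seed integer seed.
#' @param identity_threshold threshold the identities are drawn around
#'   (default 70).
#' @return data.frame of ortholog records for [build_mapping()], with the
#'   per-gene category assignment in `attr(, "categories")`.
#' @export
make_ortholog_tables <- function(template, fraction_both = 0.6,
                                 fraction_Aonly = 0.1, fraction_Bonly = 0.3,
                                 seed = 1, identity_threshold = 70) {
  fr <- c(fraction_both, fraction_Aonly, fraction_Bonly)
  if (any(fr < 0)) stop("fractions must be non-negative")
  if (sum(fr) > 1 + 1e-12) stop("fractions sum to more than 1")
  with_preserved_rng(seed, {
    genes <- template$genes$id
    cats <- sample(c("both", "Aonly", "Bonly", "unmapped"), length(genes),
                   replace = TRUE, prob = c(fr, max(0, 1 - sum(fr))))
    names(cats) <- genes
    rows <- list()
    hi <- function(n) stats::runif(n, identity_threshold + 0.5, 100)
    lo <- function(n) stats::runif(n, 30, identity_threshold - 0.5)
    for (g in genes) {
      rec <- function(parent, ident) data.frame(
        hybrid_gene_id = paste0("H_", g, "_", substr(parent, 7, 7)),
        template_gene_id = g, parent = parent, percent_identity = ident,
        evidence = "gene", stringsAsFactors = FALSE)
      rows[[g]] <- switch(cats[[g]],
        both = rbind(rec("parentA", hi(1)), rec("parentB", hi(1))),
        Aonly = rec("parentA", hi(1)),
        Bonly = rec("parentB", hi(1)),
        unmapped = rec("parentB", lo(1))
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "categories") <- cats
    out
  })
}

#' Generate synthetic expression profiles for a hybrid model
#'
#' Emulates condition-wise RNA-seq of a hybrid: each allele pair shares a
#' base expression level of which the parent-B allele receives fraction
#' `parentB_bias` and the parent-A allele the rest; single-allele genes keep
#' the full level. Optional multiplicative log-normal noise (`noise_cv`) and
#' per-condition, per-gene log-normal perturbations (`condition_sd`) are
#' applied before normalizing each library to TPM (sum \eqn{10^6}).
#'
#' @param model a hybrid `gem_model` whose genes carry origins and allele
#'   partnerships ([rewrite_gprs()] output).
#' @param parentB_bias fraction of each pair's expression on the parent-B
#'   allele, in `[0, 1]`.
#' @param conditions character vector of condition labels.
#' @param condition_sd named numeric (per condition) or single sd of the
#'   per-gene log-normal condition effect (default 0: conditions identical).
#' @param noise_cv coefficient of variation of multiplicative noise
#'   (default 0: deterministic).
#' @param seed integer seed.
#' @return Named list: condition -> named TPM vector over the model's genes.
#' @export
make_expression <- function(model, parentB_bias = 0.5,
                            conditions = c("13C", "22C", "30C"),
                            condition_sd = 0, noise_cv = 0, seed = 1) {
  if (parentB_bias < 0 || parentB_bias > 1) {
    stop("parentB_bias must lie in [0, 1]")
  }
  genes <- model$genes
  if (nrow(genes) == 0L) stop("model has no genes")
  if (length(condition_sd) == 1L && is.null(names(condition_sd))) {
    condition_sd <- stats::setNames(rep(condition_sd, length(conditions)), conditions)
  }
  with_preserved_rng(seed, {
    # one base level per allele family (pair or singleton)
    fam <- ifelse(is.na(genes$allele_partner), genes$id,
                  pmin(genes$id, genes$allele_partner))
    fam_levels <- stats::setNames(
      stats::rlnorm(length(unique(fam)), meanlog = log(100), sdlog = 1),
      unique(fam))
    base <- numeric(nrow(genes))
    for (i in seq_len(nrow(genes))) {
      tot <- fam_levels[[fam[i]]]
      base[i] <- if (is.na(genes$allele_partner[i])) tot
      else if (genes$origin[i] == "parentB") parentB_bias * tot
      else if (genes$origin[i] == "parentA") (1 - parentB_bias) * tot
      else tot
    }
    names(base) <- genes$id
    sdlog_noise <- sqrt(log(1 + noise_cv^2))
    out <- list()
    for (cond in conditions) {
      x <- base
      sdl <- if (cond %in% names(condition_sd)) condition_sd[[cond]] else 0
      if (sdl > 0) x <- x * stats::rlnorm(length(x), 0, sdl)
      if (noise_cv > 0) x <- x * stats::rlnorm(length(x), 0, sdlog_noise)
      out[[cond]] <- x / sum(x) * 1e6
    }
    out
  })
}
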