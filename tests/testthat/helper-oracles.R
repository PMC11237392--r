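# Independent oracles used across the suite. Each deliberately takes a
# different route than the implementation it checks.

# ---- reference LP solver: scipy.optimize.linprog (HiGHS) via python --------

lp_oracle_script <- function() {
  path <- file.path(tempdir(), "lp_oracle.py")
  if (!file.exists(path)) {
    writeLines(c(
      "import json, sys",
      "import numpy as np",
      "from scipy.optimize import linprog",
      "probs = json.load(open(sys.argv[1]))",
      "out = []",
      "for p in probs:",
      "    A = np.array(p['A'], dtype=float).reshape(p['m'], p['n'])",
      "    bounds = [(lo, None if hi >= 1e29 else hi) for lo, hi in zip(p['lb'], p['ub'])]",
      "    r = linprog(-np.array(p['c']), A_eq=A, b_eq=p['b'], bounds=bounds, method='highs')",
      "    status = {0: 'optimal', 2: 'infeasible', 3: 'unbounded'}.get(r.status, 'other')",
      "    out.append({'status': status, 'obj': -r.fun if r.status == 0 else None})",
      "json.dump(out, open(sys.argv[2], 'w'))"
    ), path)
  }
  path
}

# problems: list of lists with c, A (matrix), b, lb, ub; solved as
# maximizations. Returns list of list(status, obj). One python process for
# the whole batch.
reference_lp_batch <- function(problems) {
  payload <- lapply(problems, function(p) {
    A <- as.matrix(p$A)
    list(c = p$c, A = as.vector(t(A)), b = p$b, lb = p$lb,
         ub = ifelse(is.finite(p$ub), p$ub, 1e30),
         m = nrow(A), n = ncol(A))
  })
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA)
  status <- system2("python", c(lp_oracle_script(), fin, fout))
  if (status != 0) stop("reference LP solver failed")
  jsonlite::read_json(fout, simplifyVector = FALSE)
}

# ---- Boolean oracle: hand the rule string to the R parser ------------------

# Evaluates a GPR string by rewriting it into an R logical expression and
# letting R's own parser/evaluator handle precedence and parentheses.
boolean_oracle <- function(rule, present) {
  expr <- gsub("\\bor\\b", "||", gsub("\\band\\b", "&&", rule, ignore.case = TRUE),
               ignore.case = TRUE)
  genes <- gpr_genes(parse_gpr(rule))
  env <- new.env()
  for (g in genes) assign(g, g %in% present, envir = env)
  eval(parse(text = expr), envir = env)
}

# ---- aggregation oracle: shunting-yard to postfix, stack evaluation --------

# Independent of the recursive tree walker: tokenizes the rule string,
# converts to postfix (and > or), then evaluates with sum/min on a stack.
aggregate_oracle <- function(rule, expr) {
  toks <- regmatches(rule, gregexpr("\\(|\\)|[^()[:space:]]+", rule))[[1]]
  prec <- c(and = 2, or = 1)
  outq <- character(); ops <- character()
  for (tk in toks) {
    lt <- tolower(tk)
    if (lt %in% c("and", "or")) {
      while (length(ops) && ops[length(ops)] %in% c("and", "or") &&
             prec[[ops[length(ops)]]] >= prec[[lt]]) {
        outq <- c(outq, ops[length(ops)]); ops <- ops[-length(ops)]
      }
      ops <- c(ops, lt)
    } else if (tk == "(") {
      ops <- c(ops, tk)
    } else if (tk == ")") {
      while (ops[length(ops)] != "(") {
        outq <- c(outq, ops[length(ops)]); ops <- ops[-length(ops)]
      }
      ops <- ops[-length(ops)]
    } else {
      outq <- c(outq, tk)
    }
  }
  outq <- c(outq, rev(ops))
  stack <- numeric()
  for (tk in outq) {
    if (tk == "or" || tk == "and") {
      b <- stack[length(stack)]; a <- stack[length(stack) - 1]
      stack <- stack[seq_len(length(stack) - 2)]
      stack <- c(stack, if (tk == "or") a + b else min(a, b))
    } else {
      v <- expr[tk]
      stack <- c(stack, if (is.na(v)) 0 else unname(v))
    }
  }
  stack
}

# ---- random GPR trees ------------------------------------------------------

random_gpr <- function(max_depth = 4, genes = paste0("g", 1:12), p_leaf = 0.4) {
  build <- function(depth) {
    if (depth >= max_depth || runif(1) < p_leaf) {
      return(gpr_leaf(sample(genes, 1)))
    }
    kind <- sample(c("and", "or"), 1)
    k <- sample(2:3, 1)
    new_gpr_node(kind, children = lapply(seq_len(k), function(i) build(depth + 1)))
  }
  build(0)
}
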