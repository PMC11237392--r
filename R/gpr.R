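#' Gene-protein-reaction (GPR) rule trees
#'
#' A GPR rule is a Boolean expression over gene identifiers stating which gene
#' products can catalyze a reaction: isoforms combine with `or` (any one
#' suffices), complex subunits with `and` (all required). `hybridgem`
#' represents a rule as a tree of nodes of class `gpr_node`, each of kind
#' `"leaf"` (a single gene), `"and"` or `"or"` (two or more children), or the
#' degenerate kind `"false"`, used to mark a branch made unsatisfiable by gene
#' loss during hybrid reconstruction.
#'
#' @param gene a single gene identifier (character).
#' @param ... child nodes (`gpr_node` objects), at least two for `gpr_and()` /
#'   `gpr_or()`.
#' @return A `gpr_node` object.
#' @examples
#' gpr_or(gpr_leaf("PGI1_Scer"), gpr_leaf("PGI1_Seub"))
#' @name gpr_node
NULL

new_gpr_node <- function(kind, gene = NULL, children = NULL) {
  node <- list(kind = kind)
  if (kind == "leaf") {
    stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene))
    node$gene <- gene
  } else if (kind %in% c("and", "or")) {
    stopifnot(is.list(children), length(children) >= 2L)
    node$children <- children
  } else if (kind != "false") {
    stop("unknown GPR node kind: ", kind)
  }
  class(node) <- "gpr_node"
  node
}

#' @rdname gpr_node
#' @export
gpr_leaf <- function(gene) new_gpr_node("leaf", gene = gene)

#' @rdname gpr_node
#' @export
gpr_and <- function(...) new_gpr_node("and", children = list(...))

#' @rdname gpr_node
#' @export
gpr_or <- function(...) new_gpr_node("or", children = list(...))

#' @rdname gpr_node
#' @export
gpr_false <- function() new_gpr_node("false")

#' @export
print.gpr_node <- function(x, ...) {
  cat("<gpr> ", format_gpr(x), "\n", sep = "")
  invisible(x)
}

is_gpr_node <- function(x) inherits(x, "gpr_node")

## ---- parsing ---------------------------------------------------------------

gpr_tokenize <- function(rule) {
  # Tokens: '(' ')' and bare identifiers; 'and'/'or' keywords are
  # case-insensitive, identifiers are case-sensitive.
  pos <- gregexpr("\\(|\\)|[^()[:space:]]+", rule)[[1]]
  if (pos[1] == -1L) {
    return(data.frame(text = character(), pos = integer()))
  }
  len <- attr(pos, "match.length")
  data.frame(
    text = substring(rule, pos, pos + len - 1L),
    pos = as.integer(pos),
    stringsAsFactors = FALSE
  )
}

#' Parse a GPR rule string
#'
#' Parses the Boolean grammar used both in the tabular dialect's `gpr` column
#' and when flattening SBML-fbc gene associations: identifiers, keywords
#' `and` / `or` (case-insensitive), and parentheses. `and` binds tighter than
#' `or`, so `a or b and c` is `a or (b and c)`; parenthesized structure is
#' preserved as written.
#'
#' @param rule a GPR string, e.g. `"(PFK1_Scer or PFK1_Seub) and PFK2_Scer"`.
#'   An empty or all-whitespace string returns `NULL` (no gene association).
#' @return A [gpr_node] tree, or `NULL` for an empty rule.
#' @export
#' @examples
#' parse_gpr("PGI1_Scer or PGI1_Seub")
#' parse_gpr("(PFK1_Scer or PFK1_Seub) and (PFK2_Scer or PFK2_Seub)")
parse_gpr <- function(rule) {
  stopifnot(is.character(rule), length(rule) == 1L)
  if (is.na(rule) || !nzchar(trimws(rule))) {
    return(NULL)
  }
  toks <- gpr_tokenize(rule)
  i <- 1L
  n <- nrow(toks)

  peek <- function() if (i <= n) toks$text[i] else NA_character_
  pos_here <- function() if (i <= n) toks$pos[i] else nchar(rule) + 1L
  fail <- function(msg) {
    stop(sprintf("GPR parse error at position %d: %s (rule: %s)",
                 pos_here(), msg, rule), call. = FALSE)
  }
  is_kw <- function(tok, kw) !is.na(tok) && tolower(tok) == kw

  parse_factor <- function() {
    tok <- peek()
    if (is.na(tok)) fail("unexpected end of rule, expected a gene or '('")
    if (tok == "(") {
      i <<- i + 1L
      node <- parse_or()
      if (!identical(peek(), ")")) fail("unbalanced parentheses, expected ')'")
      i <<- i + 1L
      return(node)
    }
    if (tok == ")") fail("unexpected ')'")
    if (is_kw(tok, "and") || is_kw(tok, "or")) fail(sprintf("empty operand before '%s'", tok))
    i <<- i + 1L
    gpr_leaf(tok)
  }

  parse_and <- function() {
    children <- list(parse_factor())
    while (is_kw(peek(), "and")) {
      i <<- i + 1L
      children <- c(children, list(parse_factor()))
    }
    if (length(children) == 1L) children[[1]] else new_gpr_node("and", children = children)
  }

  parse_or <- function() {
    children <- list(parse_and())
    while (is_kw(peek(), "or")) {
      i <<- i + 1L
      children <- c(children, list(parse_and()))
    }
    if (length(children) == 1L) children[[1]] else new_gpr_node("or", children = children)
  }

  node <- parse_or()
  if (i <= n) fail(sprintf("unexpected token '%s'", peek()))
  node
}

#' Render a GPR tree as a rule string
#'
#' Inverse of [parse_gpr()]: `parse_gpr(format_gpr(x))` is structurally
#' identical to `x`. Nested nodes of equal or lower precedence are
#' parenthesized so the tree shape survives the round trip.
#'
#' @param node a [gpr_node], or `NULL` (renders as `""`).
#' @return A character string.
#' @export
format_gpr <- function(node) {
  if (is.null(node)) return("")
  stopifnot(is_gpr_node(node))
  render <- function(nd, parent_kind) {
    if (nd$kind == "leaf") return(nd$gene)
    if (nd$kind == "false") return("__UNSATISFIABLE__")
    sep <- if (nd$kind == "and") " and " else " or "
    body <- paste(vapply(nd$children, render, "", parent_kind = nd$kind),
                  collapse = sep)
    # Parenthesize when this node would not re-parse as a single operand of
    # its parent: 'or' under 'and', and same-kind nesting (n-ary flattening).
    needs_paren <- !is.na(parent_kind) &&
      (parent_kind == nd$kind || (parent_kind == "and" && nd$kind == "or"))
    if (needs_paren) paste0("(", body, ")") else body
  }
  render(node, NA_character_)
}

## ---- evaluation ------------------------------------------------------------

#' Evaluate a GPR rule under gene knockouts
#'
#' A leaf is satisfied iff its gene is not in `absent`; `and` nodes require all
#' children, `or` nodes any child. This is the Boolean machinery behind
#' knockout simulation: a reaction whose rule evaluates `FALSE` has lost all
#' catalytic support. In an allele-redundant hybrid, deleting one parental
#' allele of an `or` pair leaves the rule satisfied.
#'
#' @param node a [gpr_node]; `NULL` (no rule) evaluates `TRUE` (spontaneous or
#'   unannotated reactions are never switched off by gene removal).
#' @param absent character vector of knocked-out / missing gene ids.
#' @return `TRUE` or `FALSE`.
#' @export
evaluate_gpr <- function(node, absent = character()) {
  if (is.null(node)) return(TRUE)
  stopifnot(is_gpr_node(node))
  switch(node$kind,
    leaf = !(node$gene %in% absent),
    and = all(vapply(node$children, evaluate_gpr, logical(1), absent = absent)),
    or = any(vapply(node$children, evaluate_gpr, logical(1), absent = absent)),
    false = FALSE
  )
}

#' Aggregate gene expression over a GPR rule
#'
#' Converts per-gene expression levels into one reaction-level capacity by
#' recursion over the rule tree: a leaf contributes its own level, an `or`
#' node the sum of its children (alternative catalysts add capacity), and an
#' `and` node the minimum of its children (a complex is limited by its
#' scarcest subunit). Genes missing from `expr` count as 0.
#'
#' @param node a [gpr_node].
#' @param expr named numeric vector of non-negative expression levels
#'   (e.g. TPM), names are gene ids.
#' @return A single non-negative number.
#' @export
#' @examples
#' aggregate_gpr(parse_gpr("a or b"), c(a = 5, b = 7))   # 12
#' aggregate_gpr(parse_gpr("a and b"), c(a = 5, b = 7))  # 5
aggregate_gpr <- function(node, expr) {
  stopifnot(is_gpr_node(node), is.numeric(expr))
  if (any(expr < 0, na.rm = TRUE)) {
    stop("expression levels must be non-negative")
  }
  switch(node$kind,
    leaf = {
      lv <- unname(expr[node$gene])
      if (length(lv) == 0L || is.na(lv)) 0 else lv
    },
    or = sum(vapply(node$children, aggregate_gpr, numeric(1), expr = expr)),
    and = min(vapply(node$children, aggregate_gpr, numeric(1), expr = expr)),
    false = 0
  )
}

#' Genes referenced by a GPR rule
#'
#' @param node a [gpr_node] or `NULL`.
#' @return Character vector of unique gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(node) {
  if (is.null(node)) return(character())
  stopifnot(is_gpr_node(node))
  switch(node$kind,
    leaf = node$gene,
    false = character(),
    unique(unlist(lapply(node$children, gpr_genes)))
  )
}

#' Structural equality of two GPR trees
#'
#' @param a,b [gpr_node] objects or `NULL`.
#' @return `TRUE` iff the trees have identical shape, operators and leaves.
#' @export
gpr_identical <- function(a, b) {
  if (is.null(a) || is.null(b)) return(is.null(a) && is.null(b))
  if (a$kind != b$kind) return(FALSE)
  if (a$kind == "leaf") return(a$gene == b$gene)
  if (a$kind == "false") return(TRUE)
  if (length(a$children) != length(b$children)) return(FALSE)
  all(mapply(gpr_identical, a$children, b$children))
}
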