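#' @useDynLib angionet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn .data
NULL

# ---------------------------------------------------------------------------
# Boolean expression AST
#
# Expressions are plain lists: list(op = "var", name = <chr>),
# list(op = "const", value = 0L/1L), list(op = "not", x = <expr>),
# list(op = "and"/"or", args = <list of expr>).  AND/OR are n-ary with
# children kept in source order; no simplification happens at parse time so
# rules stay textually traceable to the model file.
# ---------------------------------------------------------------------------

bx_var <- function(name) list(op = "var", name = name)
bx_const <- function(value) list(op = "const", value = as.integer(value))
bx_not <- function(x) list(op = "not", x = x)
bx_and <- function(...) list(op = "and", args = list(...))
bx_or <- function(...) list(op = "or", args = list(...))

#' Tokenize a Boolean rule expression
#' @noRd
tokenize_expr <- function(text, line = NA) {
  m <- gregexpr("[A-Za-z_][A-Za-z0-9_.]*|[01()!&|]|\\S", text)[[1]]
  if (m[1] == -1) return(character())
  toks <- regmatches(text, list(m))[[1]]
  bad <- setdiff(toks, c("(", ")", "!", "&", "|", "0", "1"))
  bad <- bad[!grepl("^[A-Za-z_][A-Za-z0-9_.]*$", bad)]
  if (length(bad) > 0) {
    abort(sprintf("syntax error%s: unexpected token '%s'",
                  if (is.na(line)) "" else paste0(" on line ", line), bad[1]))
  }
  toks
}

#' Parse a Boolean expression in BoolNet dialect
#'
#' Operator precedence is NOT > AND > OR; parentheses group as usual.
#'
#' @param text Expression text, e.g. `"!B & (C | A)"`.
#' @return An expression AST (a nested list).
#' @examples
#' parse_expression("!B & (C | A)")
#' @export
parse_expression <- function(text) {
  toks <- tokenize_expr(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() {
    t <- toks[pos]; pos <<- pos + 1L; t
  }
  p_or <- function() {
    args <- list(p_and())
    while (identical(peek(), "|")) {
      advance()
      args[[length(args) + 1L]] <- p_and()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  p_and <- function() {
    args <- list(p_not())
    while (identical(peek(), "&")) {
      advance()
      args[[length(args) + 1L]] <- p_not()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  p_not <- function() {
    if (identical(peek(), "!")) {
      advance()
      bx_not(p_not())
    } else p_atom()
  }
  p_atom <- function() {
    t <- advance()
    if (is.na(t)) abort("syntax error: unexpected end of expression")
    if (t == "(") {
      e <- p_or()
      if (!identical(advance(), ")")) abort("syntax error: expected ')'")
      return(e)
    }
    if (t %in% c("0", "1")) return(bx_const(t))
    if (grepl("^[A-Za-z_]", t)) return(bx_var(t))
    abort(sprintf("syntax error: unexpected token '%s'", t))
  }
  e <- p_or()
  if (pos <= length(toks)) {
    abort(sprintf("syntax error: trailing input '%s'", toks[pos]))
  }
  e
}

#' Deparse an expression AST back to BoolNet-dialect text
#'
#' Output is precedence-safe: parentheses are inserted wherever a weaker
#' operator nests under a stronger one, so `parse_expression()` of the result
#' recovers the same tree.
#'
#' @param expr An expression AST.
#' @return A character scalar.
#' @export
deparse_expression <- function(expr) {
  prec <- c(or = 1L, and = 2L, not = 3L, var = 4L, const = 4L)
  dep <- function(e, parent_prec) {
    p <- prec[[e$op]]
    txt <- switch(e$op,
      var = e$name,
      const = as.character(e$value),
      not = paste0("!", dep(e$x, prec[["not"]])),
      and = paste(vapply(e$args, dep, "", prec[["and"]]), collapse = " & "),
      or = paste(vapply(e$args, dep, "", prec[["or"]]), collapse = " | "))
    if (p < parent_prec) paste0("(", txt, ")") else txt
  }
  dep(expr, 0L)
}

#' Variables referenced by an expression
#' @param expr An expression AST.
#' @return Character vector of node names (unique, in first-use order).
#' @export
expression_support <- function(expr) {
  out <- character()
  walk <- function(e) {
    switch(e$op,
      var = out[[length(out) + 1L]] <<- e$name,
      const = NULL,
      not = walk(e$x),
      { for (a in e$args) walk(a) })
  }
  walk(expr)
  unique(out)
}

# ---------------------------------------------------------------------------
# BooleanNetwork class
# ---------------------------------------------------------------------------

#' Construct a synchronous Boolean network
#'
#' A network is an ordered list of nodes with one update rule per node; the
#' node order defines the bit order used everywhere (state serialization,
#' canonical attractor forms, environment codes).  Nodes listed in `inputs`
#' represent the extracellular micro-environment and must have identity
#' self-loop rules (`A, A`), which hold them constant along any trajectory.
#'
#' @param rules Named list of expression ASTs (or rule strings), one per node,
#'   in node order.
#' @param inputs Character vector of input node names (possibly empty).
#' @param strict If `TRUE` (default) an input whose rule is not the identity
#'   self-loop is an error; if `FALSE` it is demoted to a warning.
#' @return An object of class `boolean_network`.
#' @examples
#' net <- boolean_network(list(A = "!B", B = "A"))
#' @export
boolean_network <- function(rules, inputs = character(), strict = TRUE) {
  nodes <- names(rules)
  if (is.null(nodes) || any(nodes == "")) abort("rules must be a fully named list")
  if (anyDuplicated(nodes)) {
    abort(sprintf("duplicate target node: %s", nodes[duplicated(nodes)][1]))
  }
  if (any(grepl("\\s", nodes))) abort("node names must not contain whitespace")
  rules <- lapply(rules, function(r) {
    if (is.character(r)) parse_expression(r) else r
  })
  for (nm in nodes) {
    undeclared <- setdiff(expression_support(rules[[nm]]), nodes)
    if (length(undeclared) > 0) {
      abort(sprintf("rule for '%s' references undeclared node '%s'",
                    nm, undeclared[1]))
    }
  }
  missing_inputs <- setdiff(inputs, nodes)
  if (length(missing_inputs) > 0) {
    abort(sprintf("declared input '%s' is not a node", missing_inputs[1]))
  }
  for (nm in inputs) {
    r <- rules[[nm]]
    ok <- identical(r$op, "var") && identical(r$name, nm)
    if (!ok) {
      msg <- sprintf("input node '%s' does not have an identity self-loop rule", nm)
      if (strict) abort(msg) else warn(msg)
    }
  }
  structure(
    list(nodes = nodes, rules = rules, inputs = as.character(inputs)),
    class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Synchronous Boolean network: %d nodes, %d inputs\n",
              length(x$nodes), length(x$inputs)))
  if (length(x$inputs) > 0) {
    cat("inputs:", paste(x$inputs, collapse = ", "), "\n")
  }
  shown <- utils::head(x$nodes, 10)
  for (nm in shown) {
    cat(sprintf("  %s <- %s\n", nm, deparse_expression(x$rules[[nm]])))
  }
  if (length(x$nodes) > 10) cat(sprintf("  ... and %d more rules\n", length(x$nodes) - 10))
  invisible(x)
}

#' Tidy a Boolean network into a rule table
#'
#' @param x A `boolean_network`.
#' @param ... Unused.
#' @return A tibble with columns `node`, `rule`, `is_input`, `in_degree`.
#' @importFrom generics tidy
#' @export
tidy.boolean_network <- function(x, ...) {
  tibble(
    node = x$nodes,
    rule = vapply(x$rules, deparse_expression, ""),
    is_input = x$nodes %in% x$inputs,
    in_degree = vapply(x$rules, function(r) length(expression_support(r)), 0L))
}

#' Number of nodes in a network
#' @param net A `boolean_network`.
#' @return Integer.
#' @export
n_nodes <- function(net) length(net$nodes)

# ---------------------------------------------------------------------------
# BoolNet-dialect text I/O
# ---------------------------------------------------------------------------

#' Read a Boolean network from BoolNet-dialect text
#'
#' The format is the plain-text dialect used by the BoolNet R package: a
#' header line `targets, factors`, then one `NAME, EXPRESSION` line per node.
#' Expressions use `!` (NOT), `&` (AND), `|` (OR), parentheses and the
#' literals `0`/`1`.  Lines starting with `#` are comments.
#'
#' @param file Path to a model file, or a character vector of lines via
#'   `text =`.
#' @param text Optional character scalar/vector with the document content.
#' @param inputs Character vector of input (micro-environment) node names.
#' @param strict Passed to [boolean_network()]: whether a non-self-loop input
#'   rule is an error (default) or a warning.
#' @return A `boolean_network`.
#' @examples
#' net <- read_network(text = "targets, factors\nA, !B\nB, A")
#' @export
read_network <- function(file = NULL, text = NULL, inputs = character(),
                         strict = TRUE) {
  if (is.null(text)) {
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) abort("empty document")
  if (!grepl("^\\s*targets\\s*,\\s*factors\\s*$", lines[1], ignore.case = TRUE)) {
    abort("missing 'targets, factors' header line")
  }
  lines <- lines[-1]; lineno <- lineno[-1]
  rules <- list()
  for (k in seq_along(lines)) {
    parts <- regmatches(lines[k], regexpr(",", lines[k]), invert = TRUE)[[1]]
    if (length(parts) != 2) {
      abort(sprintf("syntax error on line %d: expected 'NAME, EXPRESSION'", lineno[k]))
    }
    nm <- trimws(parts[1])
    if (!grepl("^[A-Za-z_][A-Za-z0-9_.]*$", nm)) {
      abort(sprintf("syntax error on line %d: invalid node name '%s'", lineno[k], nm))
    }
    if (nm %in% names(rules)) {
      abort(sprintf("duplicate target '%s' on line %d", nm, lineno[k]))
    }
    expr <- tryCatch(parse_expression(parts[2]), error = function(e) {
      abort(sprintf("syntax error on line %d: %s", lineno[k], conditionMessage(e)))
    })
    rules[[nm]] <- expr
  }
  boolean_network(rules, inputs = inputs, strict = strict)
}

#' Write a Boolean network as BoolNet-dialect text
#'
#' Emits a header plus one precedence-safe rule line per node in node order;
#' `read_network(write_network(net))` recovers a structurally identical
#' network, and write-parse-write is idempotent.
#'
#' @param net A `boolean_network`.
#' @param file Optional path; if `NULL` the document is returned as a
#'   character vector of lines.
#' @return The document lines, invisibly when written to a file.
#' @export
write_network <- function(net, file = NULL) {
  lines <- c("targets, factors",
             vapply(net$nodes, function(nm) {
               paste0(nm, ", ", deparse_expression(net$rules[[nm]]))
             }, "", USE.NAMES = FALSE))
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

# ---------------------------------------------------------------------------
# bytecode compilation for the C++ engine
# ---------------------------------------------------------------------------

#' Compile network rules to engine bytecode
#'
#' Postfix token stream per node: `>= 10` pushes node `token - 10`, `0`/`1`
#' push constants, `-1` NOT, `-2` AND, `-3` OR (binary).
#' @noRd
compile_program <- function(net) {
  cached <- attr(net, "program")
  if (!is.null(cached)) return(cached)
  index <- stats::setNames(seq_along(net$nodes) - 1L, net$nodes)
  emit <- function(e) {
    switch(e$op,
      var = index[[e$name]] + 10L,
      const = e$value,
      not = c(emit(e$x), -1L),
      and = {
        out <- emit(e$args[[1L]])
        for (a in e$args[-1L]) out <- c(out, emit(a), -2L)
        out
      },
      or = {
        out <- emit(e$args[[1L]])
        for (a in e$args[-1L]) out <- c(out, emit(a), -3L)
        out
      })
  }
  lapply(net$rules, function(r) as.integer(emit(r)))
}

#' Attach the compiled bytecode to a network (internal cache)
#' @noRd
with_program <- function(net) {
  if (is.null(attr(net, "program"))) {
    attr(net, "program") <- compile_program(net)
  }
  net
}
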