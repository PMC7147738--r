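# ---------------------------------------------------------------------------
# Expression DSL for user-defined equation systems.
#
# Grammar (EBNF):
#   expr     := cmp
#   cmp      := add { ("<" | ">" | "<=" | ">=" | "==" | "!=") add }
#   add      := mul { ("+" | "-") mul }
#   mul      := unary { ("*" | "/") unary }
#   unary    := "-" unary | power
#   power    := primary [ "^" unary ]            (right associative)
#   primary  := number | name | name "(" expr {"," expr} ")" | "(" expr ")"
#
# Functions: exp log sqrt min max abs sin cos tanh pow step ifelse.
# Comparisons evaluate to 0/1 and gate conditionals, e.g.
#   "mu * (N > 0.5)"  or  "ifelse(temp > 10, r1, r2)".
# ---------------------------------------------------------------------------

DSL_FUNCTIONS <- c(exp = 1L, log = 1L, sqrt = 1L, abs = 1L, sin = 1L,
                   cos = 1L, tanh = 1L, step = 1L,
                   min = 2L, max = 2L, pow = 2L, ifelse = 3L)

dsl_tokenize <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value, pos) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value,
                                           pos = pos)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[ \t\n]$", ch)) { i <- i + 1L; next }
    rest <- substr(text, i, n)
    if (grepl("^[0-9.]", ch)) {
      m <- regmatches(rest, regexpr("^[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?", rest))
      if (length(m) == 0L || m == "") {
        stop(sprintf("syntax error in \"%s\" at position %d: bad number",
                     text, i))
      }
      push("num", as.numeric(m), i)
      i <- i + nchar(m)
    } else if (grepl("^[A-Za-z_]", ch)) {
      m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
      push("name", m, i)
      i <- i + nchar(m)
    } else if (nchar(rest) >= 2 &&
               substr(rest, 1, 2) %in% c("<=", ">=", "==", "!=")) {
      push("cmp", substr(rest, 1, 2), i)
      i <- i + 2L
    } else if (ch %in% c("<", ">")) {
      push("cmp", ch, i)
      i <- i + 1L
    } else if (ch %in% c("+", "-", "*", "/", "^", "(", ")", ",")) {
      push(ch, ch, i)
      i <- i + 1L
    } else {
      stop(sprintf("syntax error in \"%s\" at position %d: unexpected '%s'",
                   text, i, ch))
    }
  }
  tokens
}

#' Parse one DSL expression into an abstract syntax tree
#'
#' @param text the expression string.
#' @return AST: nested lists with node types \code{num}, \code{var},
#'   \code{bin}, \code{neg}, \code{call}.
#' @export
dsl_parse <- function(text) {
  toks <- dsl_tokenize(text)
  k <- 1L
  peek <- function() if (k <= length(toks)) toks[[k]] else NULL
  take <- function() { t <- toks[[k]]; k <<- k + 1L; t }
  expect <- function(type) {
    t <- peek()
    if (is.null(t) || t$type != type) {
      stop(sprintf("syntax error in \"%s\" at position %d: expected '%s'",
                   text, if (is.null(t)) nchar(text) + 1L else t$pos, type))
    }
    take()
  }
  parse_primary <- function() {
    t <- peek()
    if (is.null(t)) {
      stop(sprintf("syntax error in \"%s\": unexpected end of expression",
                   text))
    }
    if (t$type == "num") { take(); return(list(op = "num", value = t$value)) }
    if (t$type == "name") {
      take()
      nxt <- peek()
      if (!is.null(nxt) && nxt$type == "(") {
        take()
        args <- list(parse_expr())
        while (!is.null(peek()) && peek()$type == ",") {
          take()
          args[[length(args) + 1L]] <- parse_expr()
        }
        expect(")")
        return(list(op = "call", fn = t$value, args = args, pos = t$pos))
      }
      return(list(op = "var", name = t$value, pos = t$pos))
    }
    if (t$type == "(") {
      take()
      e <- parse_expr()
      expect(")")
      return(e)
    }
    stop(sprintf("syntax error in \"%s\" at position %d: unexpected '%s'",
                 text, t$pos, t$value))
  }
  parse_power <- function() {
    base <- parse_primary()
    t <- peek()
    if (!is.null(t) && t$type == "^") {
      take()
      return(list(op = "bin", sym = "^", lhs = base, rhs = parse_unary()))
    }
    base
  }
  parse_unary <- function() {
    t <- peek()
    if (!is.null(t) && t$type == "-") {
      take()
      return(list(op = "neg", arg = parse_unary()))
    }
    if (!is.null(t) && t$type == "+") { take(); return(parse_unary()) }
    parse_power()
  }
  parse_mul <- function() {
    lhs <- parse_unary()
    repeat {
      t <- peek()
      if (is.null(t) || !(t$type %in% c("*", "/"))) return(lhs)
      take()
      lhs <- list(op = "bin", sym = t$value, lhs = lhs, rhs = parse_unary())
    }
  }
  parse_add <- function() {
    lhs <- parse_mul()
    repeat {
      t <- peek()
      if (is.null(t) || !(t$type %in% c("+", "-"))) return(lhs)
      take()
      lhs <- list(op = "bin", sym = t$value, lhs = lhs, rhs = parse_mul())
    }
  }
  parse_expr <- function() {
    lhs <- parse_add()
    repeat {
      t <- peek()
      if (is.null(t) || t$type != "cmp") return(lhs)
      take()
      lhs <- list(op = "bin", sym = t$value, lhs = lhs, rhs = parse_add())
    }
  }
  ast <- parse_expr()
  t <- peek()
  if (!is.null(t)) {
    stop(sprintf("syntax error in \"%s\" at position %d: unexpected '%s'",
                 text, t$pos, t$value))
  }
  ast
}

# Names referenced by an AST (excluding function names).
dsl_names <- function(ast) {
  switch(ast$op,
    num  = character(0),
    var  = ast$name,
    neg  = dsl_names(ast$arg),
    bin  = c(dsl_names(ast$lhs), dsl_names(ast$rhs)),
    call = unlist(lapply(ast$args, dsl_names))
  )
}

dsl_validate <- function(ast, declared, expr_text = "") {
  walk <- function(a) {
    if (a$op == "call") {
      if (!(a$fn %in% names(DSL_FUNCTIONS))) {
        stop(sprintf("unknown function '%s' in \"%s\"", a$fn, expr_text))
      }
      if (length(a$args) != DSL_FUNCTIONS[[a$fn]]) {
        stop(sprintf("function '%s' takes %d argument(s) in \"%s\"",
                     a$fn, DSL_FUNCTIONS[[a$fn]], expr_text))
      }
      lapply(a$args, walk)
    } else if (a$op == "var") {
      if (!(a$name %in% declared)) {
        stop(sprintf("undeclared symbol '%s' in \"%s\"", a$name, expr_text))
      }
    } else if (a$op == "bin") {
      walk(a$lhs); walk(a$rhs)
    } else if (a$op == "neg") {
      walk(a$arg)
    }
    invisible(NULL)
  }
  walk(ast)
  invisible(TRUE)
}

# Compile an AST to an R expression; evaluated in an environment holding the
# fields.  min/max map to the elementwise pmin/pmax; step(x) = 1 when x >= 0.
dsl_to_lang <- function(ast) {
  switch(ast$op,
    num = ast$value,
    var = as.name(ast$name),
    neg = call("-", dsl_to_lang(ast$arg)),
    bin = {
      sym <- switch(ast$sym, "^" = "^", "==" = "==", "!=" = "!=", ast$sym)
      if (ast$sym %in% c("<", ">", "<=", ">=", "==", "!=")) {
        call("*", call(sym, dsl_to_lang(ast$lhs), dsl_to_lang(ast$rhs)), 1)
      } else {
        call(sym, dsl_to_lang(ast$lhs), dsl_to_lang(ast$rhs))
      }
    },
    call = {
      fn <- switch(ast$fn, min = "pmin", max = "pmax", ast$fn)
      args <- lapply(ast$args, dsl_to_lang)
      if (ast$fn == "pow") {
        call("^", args[[1]], args[[2]])
      } else if (ast$fn == "step") {
        call("*", call(">=", args[[1]], 0), 1)
      } else {
        as.call(c(as.name(fn), args))
      }
    }
  )
}

#' Compile a DSL expression to an R evaluator
#'
#' @param text expression string.
#' @param declared character vector of names the expression may reference.
#' @return function(env) evaluating the expression elementwise in \code{env}
#'   (an environment or named list of fields).
#' @export
dsl_compile <- function(text, declared) {
  ast <- dsl_parse(text)
  dsl_validate(ast, declared, text)
  lang <- dsl_to_lang(ast)
  function(env) {
    if (is.list(env)) env <- list2env(env, parent = baseenv())
    eval(lang, env)
  }
}
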