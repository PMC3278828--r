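# Rule language for evolved chlorophyll-a predictors.
#
# A rule set is a single IF/THEN/ELSE rule: a boolean-rooted condition tree
# over comparisons (>=, >, <, <=) combined with AND/OR, and two
# arithmetic-rooted branch expressions built from +, -, *, protected /,
# ln|.| and (optionally) exp over variables and numeric constants.
# Expression nodes are plain lists tagged by `kind`:
#   list(kind = "const", value = <double>)
#   list(kind = "var",   name  = <canonical variable>)
#   list(kind = "op",    op    = <operator>, args = list(<nodes>))

ARITH_BINARY <- c("+", "-", "*", "/")
ARITH_UNARY  <- c("lnabs", "exp")
BOOL_BINARY  <- c("AND", "OR")
COMPARISONS  <- c(">=", "<=", ">", "<")

DIV_SENTINEL <- 1e6
LN_SENTINEL  <- -1e6

expr_const <- function(value) list(kind = "const", value = as.numeric(value))
expr_var   <- function(name) list(kind = "var", name = name)
expr_op    <- function(op, ...) list(kind = "op", op = op, args = list(...))

node_type <- function(node) {
  if (node$kind %in% c("const", "var")) return("arith")
  if (node$op %in% c(BOOL_BINARY, COMPARISONS)) "bool" else "arith"
}

#' Build a single-rule set
#'
#' @param condition Boolean-rooted expression node.
#' @param then_expr,else_expr Arithmetic-rooted expression nodes giving the
#'   chlorophyll-a prediction (ug/l) on each branch.
#' @return A `rule_set` object.
#' @export
rule_set <- function(condition, then_expr, else_expr) {
  rs <- structure(list(condition = condition, then_expr = then_expr,
                       else_expr = else_expr), class = "rule_set")
  validate_rule(rs)
  rs
}

#' @export
print.rule_set <- function(x, ...) {
  cat(format_rule(x), "\n")
  invisible(x)
}

# Checks arity and boolean/arithmetic typing of a whole rule set; used by
# tests on every genetic offspring.
validate_rule <- function(ruleset) {
  check <- function(node, want) {
    if (!is.list(node) || is.null(node$kind)) stop("malformed node")
    t <- node_type(node)
    if (t != want) stop("type error: expected ", want, " node, found ", t)
    if (node$kind == "op") {
      arity <- if (node$op %in% ARITH_UNARY) 1L else 2L
      if (length(node$args) != arity) {
        stop("operator '", node$op, "' expects ", arity, " argument(s)")
      }
      child_want <- if (node$op %in% BOOL_BINARY) "bool" else "arith"
      for (a in node$args) check(a, child_want)
    } else if (node$kind == "var") {
      if (!node$name %in% limno_variables()) {
        stop("unknown variable '", node$name, "'")
      }
    }
    invisible(TRUE)
  }
  check(ruleset$condition, "bool")
  check(ruleset$then_expr, "arith")
  check(ruleset$else_expr, "arith")
  invisible(TRUE)
}

rule_variables <- function(ruleset) {
  acc <- character(0)
  walk <- function(node) {
    if (node$kind == "var") acc <<- c(acc, node$name)
    if (node$kind == "op") for (a in node$args) walk(a)
  }
  walk(ruleset$condition); walk(ruleset$then_expr); walk(ruleset$else_expr)
  unique(acc)
}

# ---- evaluation -----------------------------------------------------------

# Evaluate an arithmetic node over an environment of equal-length numeric
# vectors (a data frame works). Division by ~0 yields a signed 1e6 sentinel
# and ln(0) yields -1e6 so evolved programs never crash on singular inputs.
eval_arith <- function(node, env) {
  switch(node$kind,
    const = rep(node$value, nrow(env)),
    var = {
      v <- env[[node$name]]
      if (is.null(v)) stop("variable '", node$name, "' missing from input")
      v
    },
    op = {
      if (node$op %in% ARITH_UNARY) {
        x <- eval_arith(node$args[[1]], env)
        if (node$op == "lnabs") {
          ax <- abs(x)
          ifelse(ax < 1e-300, LN_SENTINEL, log(ax))
        } else {
          pmin(exp(pmin(x, 700)), 1e300)
        }
      } else {
        a <- eval_arith(node$args[[1]], env)
        b <- eval_arith(node$args[[2]], env)
        switch(node$op,
          "+" = a + b,
          "-" = a - b,
          "*" = a * b,
          "/" = ifelse(abs(b) < 1e-12,
                       DIV_SENTINEL * ifelse(a < 0, -1, 1), a / b))
      }
    })
}

eval_bool <- function(node, env) {
  if (node$op %in% BOOL_BINARY) {
    a <- eval_bool(node$args[[1]], env)
    b <- eval_bool(node$args[[2]], env)
    if (node$op == "AND") a & b else a | b
  } else {
    a <- eval_arith(node$args[[1]], env)
    b <- eval_arith(node$args[[2]], env)
    switch(node$op, ">=" = a >= b, "<=" = a <= b, ">" = a > b, "<" = a < b)
  }
}

#' Evaluate a rule set on samples
#'
#' Pure, deterministic interpreter for the rule language: the condition is
#' evaluated with standard boolean semantics and the matching branch
#' expression gives the chlorophyll-a prediction. Division by zero is
#' protected (signed 1e6 sentinel) and `ln` takes the absolute value of its
#' argument, with `ln(0)` mapped to -1e6.
#'
#' @param ruleset A [rule_set()] (e.g. from [parse_rule()]).
#' @param samples Data frame (or [limno_series()]) carrying every variable
#'   the rule references.
#' @return Numeric vector of predictions, one per row (ug/l).
#' @export
eval_rule <- function(ruleset, samples) {
  samples <- as.data.frame(samples)
  need <- setdiff(rule_variables(ruleset), names(samples))
  if (length(need) > 0) {
    stop("rule references missing variable(s): ", paste(need, collapse = ", "))
  }
  cond <- eval_bool(ruleset$condition, samples)
  ifelse(cond,
         eval_arith(ruleset$then_expr, samples),
         eval_arith(ruleset$else_expr, samples))
}

# ---- formatting -----------------------------------------------------------

format_expr <- function(node) {
  switch(node$kind,
    const = as.character(node$value),
    var = node$name,
    op = {
      if (node$op == "lnabs") {
        paste0("ln(|", format_expr(node$args[[1]]), "|)")
      } else if (node$op == "exp") {
        paste0("exp(", format_expr(node$args[[1]]), ")")
      } else {
        paste0("(", format_expr(node$args[[1]]), node$op,
               format_expr(node$args[[2]]), ")")
      }
    })
}

#' Serialize a rule set to its textual grammar
#'
#' Produces `IF(cond)THEN chlorophyll-a=(expr) ELSE chlorophyll-a=(expr)`
#' with full parenthesization; [parse_rule()] round-trips the output to an
#' equivalent tree.
#'
#' @param ruleset A [rule_set()].
#' @return A single string.
#' @export
format_rule <- function(ruleset) {
  # top-level parts are always parenthesized so names cannot fuse with the
  # IF/THEN/ELSE keywords when whitespace is stripped
  wrap <- function(s) if (startsWith(s, "(")) s else paste0("(", s, ")")
  paste0("IF ", wrap(format_expr(ruleset$condition)),
         " THEN chlorophyll-a=", wrap(format_expr(ruleset$then_expr)),
         " ELSE chlorophyll-a=", wrap(format_expr(ruleset$else_expr)))
}

# ---- parsing --------------------------------------------------------------

# Tokenizer: multi-character operators first; `|` delimits the absolute
# value inside ln(|x|).
tokenize_rule <- function(text) {
  s <- gsub("[[:space:]]+", "", text)
  tokens <- list()
  i <- 1L
  n <- nchar(s)
  push <- function(type, value, at) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value,
                                           at = at)
  }
  while (i <= n) {
    rest <- substring(s, i)
    two <- substring(s, i, i + 1L)
    ch <- substring(s, i, i)
    if (grepl("^(?i)IF", rest, perl = TRUE) &&
        !grepl("^[A-Za-z0-9_]", substring(s, i + 2L))) {
      push("kw", "IF", i); i <- i + 2L
    } else if (grepl("^(?i)THEN", rest, perl = TRUE)) {
      push("kw", "THEN", i); i <- i + 4L
    } else if (grepl("^(?i)ELSE", rest, perl = TRUE)) {
      push("kw", "ELSE", i); i <- i + 4L
    } else if (grepl("^(?i)AND", rest, perl = TRUE)) {
      push("op", "AND", i); i <- i + 3L
    } else if (grepl("^(?i)OR", rest, perl = TRUE)) {
      push("op", "OR", i); i <- i + 2L
    } else if (grepl("^(?i)ln\\(\\|", rest, perl = TRUE)) {
      push("lnabs", "ln(|", i); i <- i + 4L
    } else if (grepl("^(?i)exp\\(", rest, perl = TRUE)) {
      push("expfn", "exp(", i); i <- i + 4L
    } else if (two %in% c(">=", "<=")) {
      push("op", two, i); i <- i + 2L
    } else if (ch %in% c(">", "<", "+", "*", "/", "(", ")", "=", "|")) {
      push(if (ch %in% c("(", ")", "=", "|")) ch else "op", ch, i)
      i <- i + 1L
    } else if (ch == "-") {
      push("op", "-", i); i <- i + 1L
    } else if (grepl("^[0-9.]", ch)) {
      m <- regmatches(rest, regexpr("^[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?",
                                    rest))
      push("num", m, i); i <- i + nchar(m)
    } else if (grepl("^[A-Za-z_]", ch)) {
      m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
      push("name", m, i); i <- i + nchar(m)
    } else {
      stop("syntax error at offset ", i, ": unexpected character '", ch, "'")
    }
  }
  tokens
}

# Hyphenated spellings are collapsed before tokenizing so the hyphen can
# act as a subtraction operator everywhere else.
normalize_rule_text <- function(text) {
  text <- gsub("chlorophyll-a", "chla", text, ignore.case = TRUE)
  text <- gsub("NH3-N", "NH3N", text, fixed = TRUE)
  gsub("NO3-N", "NO3N", text, fixed = TRUE)
}

# Variable-name spellings accepted on input, mapped to canonical names.
RULE_NAME_ALIASES <- c(
  WaterTemp = "WaterTemp", WT = "WaterTemp", Temp = "WaterTemp",
  pH = "pH", PH = "pH",
  DO = "DO",
  Secchi = "Secchi", SD = "Secchi",
  Turbidity = "Turbidity",
  Conductivity = "Conductivity",
  NH3N = "NH3N", "NH3-N" = "NH3N",
  NO3N = "NO3N", "NO3-N" = "NO3N",
  COD = "COD", TSS = "TSS")

#' Parse a rule from its textual grammar
#'
#' Accepts whitespace-insensitive text of the form
#' `IF(cond)THEN chlorophyll-a=(expr) ELSE chlorophyll-a=(expr)` with
#' operators `>=`, `>`, `<`, `<=`, `AND`, `OR`, `+`, `-`, `*`, `/` and
#' `ln(|...|)`. Comparison binds looser than arithmetic; `AND`/`OR`
#' combinations of comparisons must be parenthesized (as in evolved rules,
#' which are always fully parenthesized).
#'
#' @param text Rule text.
#' @return A [rule_set()].
#' @export
parse_rule <- function(text) {
  tokens <- tokenize_rule(normalize_rule_text(text))
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() {
    tk <- peek()
    if (is.null(tk)) stop("syntax error: unexpected end of rule")
    pos <<- pos + 1L
    tk
  }
  expect <- function(type, value = NULL) {
    tk <- advance()
    if (tk$type != type || (!is.null(value) && tk$value != value)) {
      stop("syntax error at offset ", tk$at, ": expected ",
           if (is.null(value)) type else paste0("'", value, "'"),
           ", found '", tk$value, "'")
    }
    tk
  }

  parse_primary <- function() {
    tk <- peek()
    if (is.null(tk)) stop("syntax error: unexpected end of rule")
    if (tk$type == "num") {
      advance(); return(expr_const(as.numeric(tk$value)))
    }
    if (tk$type == "op" && tk$value == "-") {
      advance()
      nxt <- peek()
      if (!is.null(nxt) && nxt$type == "num") {
        advance()
        return(expr_const(-as.numeric(nxt$value)))
      }
      return(expr_op("-", expr_const(0), parse_primary()))
    }
    if (tk$type == "name") {
      advance()
      canon <- unname(RULE_NAME_ALIASES[tk$value])
      if (is.na(canon)) {
        stop("unknown variable '", tk$value, "' at offset ", tk$at)
      }
      return(expr_var(canon))
    }
    if (tk$type == "lnabs") {
      advance()
      inner <- parse_arith()
      expect("|"); expect(")")
      return(expr_op("lnabs", inner))
    }
    if (tk$type == "expfn") {
      advance()
      inner <- parse_arith()
      expect(")")
      return(expr_op("exp", inner))
    }
    if (tk$type == "(") {
      advance()
      inner <- parse_arith()
      expect(")")
      return(inner)
    }
    stop("syntax error at offset ", tk$at, ": unexpected '", tk$value, "'")
  }

  parse_term <- function() {
    node <- parse_primary()
    repeat {
      tk <- peek()
      if (!is.null(tk) && tk$type == "op" && tk$value %in% c("*", "/")) {
        advance()
        node <- expr_op(tk$value, node, parse_primary())
      } else return(node)
    }
  }

  parse_arith <- function() {
    node <- parse_term()
    repeat {
      tk <- peek()
      if (!is.null(tk) && tk$type == "op" && tk$value %in% c("+", "-")) {
        advance()
        node <- expr_op(tk$value, node, parse_term())
      } else return(node)
    }
  }

  # cond := boolterm (AND|OR boolterm)*    (left-associative, equal prec.)
  # boolterm := "(" cond ")"  if it re-parses as boolean, else comparison
  parse_comparison_or_group <- function() {
    tk <- peek()
    if (!is.null(tk) && tk$type == "(") {
      # lookahead: try boolean group first, fall back to arithmetic lhs
      save <- pos
      advance()
      node <- tryCatch(parse_bool(), error = function(e) NULL)
      if (!is.null(node)) {
        nxt <- peek()
        if (!is.null(nxt) && nxt$type == ")") {
          advance()
          return(node)
        }
      }
      pos <<- save
    }
    lhs <- parse_arith()
    tk <- advance()
    if (tk$type != "op" || !tk$value %in% COMPARISONS) {
      stop("syntax error at offset ", tk$at,
           ": expected comparison operator, found '", tk$value, "'")
    }
    rhs <- parse_arith()
    expr_op(tk$value, lhs, rhs)
  }

  parse_bool <- function() {
    node <- parse_comparison_or_group()
    repeat {
      tk <- peek()
      if (!is.null(tk) && tk$type == "op" && tk$value %in% BOOL_BINARY) {
        advance()
        node <- expr_op(tk$value, node, parse_comparison_or_group())
      } else return(node)
    }
  }

  expect("kw", "IF")
  cond <- parse_bool()
  expect("kw", "THEN")
  expect("name"); expect("=")
  then_expr <- parse_arith()
  expect("kw", "ELSE")
  expect("name"); expect("=")
  else_expr <- parse_arith()
  if (!is.null(peek())) {
    stop("syntax error at offset ", peek()$at, ": trailing input")
  }
  rule_set(cond, then_expr, else_expr)
}
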