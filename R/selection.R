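# Atom-selection mini-grammar.
#
# Grammar (case-insensitive keywords):
#   expr    := term (OR term)*
#   term    := factor (AND factor)*
#   factor  := NOT factor | '(' expr ')' | primary
#   primary := chain <id>[,<id>...]
#            | resid <n> | resid <a>-<b> | resid <n>,<n>,...
#            | resname <name>[,...] | name <name>[,...] | element <sym>[,...]
#            | all | none
#
# Resolution against a Topology is deterministic and returns a sorted,
# duplicate-free integer index vector (1-based rows of top$atoms).

sel_tokenize <- function(expression) {
  chars <- strsplit(expression, "")[[1]]
  tokens <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("\\s", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch, pos = i)
      i <- i + 1L
      next
    }
    j <- i
    while (j <= n && !grepl("[\\s()]", chars[j], perl = TRUE)) j <- j + 1L
    word <- paste(chars[i:(j - 1L)], collapse = "")
    tokens[[length(tokens) + 1L]] <- list(type = "word", value = word, pos = i)
    i <- j
  }
  tokens
}

sel_parse <- function(expression) {
  tokens <- sel_tokenize(expression)
  pos <- 1L

  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() { tk <- tokens[[pos]]; pos <<- pos + 1L; tk }
  fail <- function(msg, tk = peek()) {
    where <- if (is.null(tk)) nchar(expression) + 1L else tk$pos
    stop(sprintf("selection parse error at position %d: %s", where, msg))
  }
  is_kw <- function(tk, kw) {
    !is.null(tk) && tk$type == "word" && tolower(tk$value) == kw
  }

  parse_expr <- function() {
    node <- parse_term()
    while (is_kw(peek(), "or")) {
      advance()
      node <- list(op = "or", lhs = node, rhs = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (is_kw(peek(), "and")) {
      advance()
      node <- list(op = "and", lhs = node, rhs = parse_factor())
    }
    node
  }
  parse_factor <- function() {
    tk <- peek()
    if (is.null(tk)) fail("unexpected end of expression")
    if (is_kw(tk, "not")) {
      advance()
      return(list(op = "not", arg = parse_factor()))
    }
    if (tk$type == "(") {
      advance()
      node <- parse_expr()
      if (is.null(peek()) || peek()$type != ")") fail("expected ')'")
      advance()
      return(node)
    }
    parse_primary()
  }
  parse_primary <- function() {
    tk <- peek()
    if (is.null(tk) || tk$type != "word") fail("expected a selection keyword")
    kw <- tolower(tk$value)
    advance()
    if (kw %in% c("all", "none")) return(list(op = kw))
    if (!kw %in% c("chain", "resid", "resname", "name", "element")) {
      fail(sprintf("unknown keyword '%s'", tk$value), tk)
    }
    vtk <- peek()
    if (is.null(vtk) || vtk$type != "word") fail(sprintf("'%s' needs a value", kw), tk)
    advance()
    list(op = kw, value = vtk$value)
  }

  node <- parse_expr()
  if (!is.null(peek())) fail("trailing input")
  node
}

sel_parse_resid <- function(value) {
  parts <- strsplit(value, ",", fixed = TRUE)[[1]]
  out <- integer(0)
  for (p in parts) {
    if (grepl("^[0-9]+[-:][0-9]+$", p)) {
      a <- as.integer(sub("^([0-9]+)[-:]([0-9]+)$", "\\1", p))
      b <- as.integer(sub("^([0-9]+)[-:]([0-9]+)$", "\\2", p))
      out <- c(out, seq(a, b))
    } else if (grepl("^-?[0-9]+$", p)) {
      out <- c(out, as.integer(p))
    } else {
      stop(sprintf("selection parse error: bad residue range '%s'", p))
    }
  }
  out
}

sel_eval <- function(node, atoms) {
  switch(node$op,
    all = rep(TRUE, nrow(atoms)),
    none = rep(FALSE, nrow(atoms)),
    and = sel_eval(node$lhs, atoms) & sel_eval(node$rhs, atoms),
    or = sel_eval(node$lhs, atoms) | sel_eval(node$rhs, atoms),
    not = !sel_eval(node$arg, atoms),
    chain = atoms$chain %in% strsplit(node$value, ",", fixed = TRUE)[[1]],
    resid = atoms$resid %in% sel_parse_resid(node$value),
    resname = toupper(atoms$resname) %in%
      toupper(strsplit(node$value, ",", fixed = TRUE)[[1]]),
    name = toupper(atoms$name) %in%
      toupper(strsplit(node$value, ",", fixed = TRUE)[[1]]),
    element = toupper(atoms$element) %in%
      toupper(strsplit(node$value, ",", fixed = TRUE)[[1]]),
    stop("internal: unknown selection node")
  )
}

#' Create a selection
#'
#' @param expression selection expression, e.g.
#'   `"chain C and name CA"`, `"resid 85-96 and not element H"`.
#' @return An object of class `Selection` (parsed, reusable).
#' @export
selection <- function(expression) {
  structure(
    list(expression = expression, ast = sel_parse(expression)),
    class = "Selection"
  )
}

#' @export
print.Selection <- function(x, ...) {
  cat("Selection:", x$expression, "\n")
  invisible(x)
}

#' Resolve a selection against a topology
#'
#' @param top a [topology()].
#' @param sel a [selection()] or a character expression.
#' @return Sorted integer vector of atom indices (rows of `top$atoms`);
#'   may be empty.
#' @export
resolve_selection <- function(top, sel) {
  if (is.character(sel)) sel <- selection(sel)
  if (!inherits(sel, "Selection")) stop("`sel` must be a Selection or character")
  sort(which(sel_eval(sel$ast, top$atoms)))
}
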