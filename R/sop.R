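#' Parse a sum-of-products Boolean expression
#'
#' Parses an ASCII sum-of-products (SOP) formula over the variables
#' `A`..`H` into an `sop_expr` object. The grammar is: OR is `+` or `|`,
#' AND is `*` or `&`, NOT is a `!` or `~` prefix, product terms may be
#' parenthesised, whitespace is ignored, and the degenerate constant
#' expressions `"0"` and `"1"` are accepted. This is the plain-text form
#' of the typeset formulas used for colloid-derived logic gates (e.g. the
#' two-input XOR `"(A * !B) + (B * !A)"`).
#'
#' @param text A single expression string.
#' @param arity Optional neighbourhood arity, one of 2, 4 or 8. When
#'   omitted, the smallest of 2/4/8 covering all variables present is
#'   inferred. Some catalogued functions omit variables of their family
#'   (e.g. `A + B + D` in a four-input family), so catalogue entries carry
#'   an explicit arity.
#'
#' @return An object of class `sop_expr`: a list with `terms` (a list of
#'   named logical vectors, names are variables, `TRUE` marks a negated
#'   literal), `constant` (`NA` for ordinary expressions, otherwise 0 or
#'   1) and `arity`.
#'
#' @examples
#' parse_sop("(A * !B) + (B * !A)")   # XOR, arity 2
#' parse_sop("A + B + D", arity = 4)
#' parse_sop("0")                     # constant false
#' @export
parse_sop <- function(text, arity = NULL) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  toks <- sop_tokenize(text)
  if (length(toks$type) == 0L)
    stop("parse error: empty expression", call. = FALSE)

  # degenerate constant expression
  if (toks$type[1] %in% c("CONST0", "CONST1")) {
    if (length(toks$type) > 1L)
      stop(sprintf("parse error: constant must stand alone (position %d)",
                   toks$pos[2]), call. = FALSE)
    value <- if (toks$type[1] == "CONST1") 1L else 0L
    return(new_sop_expr(list(), constant = value,
                        arity = resolve_arity(character(0), arity)))
  }

  terms <- list()
  i <- 1L
  n <- length(toks$type)
  repeat {
    parsed <- parse_term(toks, i)
    terms[[length(terms) + 1L]] <- parsed$term
    i <- parsed$i
    if (i > n) break
    if (toks$type[i] != "OR")
      stop(sprintf("parse error: expected '+' at position %d, got '%s'",
                   toks$pos[i], toks$text[i]), call. = FALSE)
    i <- i + 1L
    if (i > n)
      stop("parse error: expression ends with '+'", call. = FALSE)
  }

  vars <- sort(unique(unlist(lapply(terms, names))))
  new_sop_expr(terms, constant = NA_integer_,
               arity = resolve_arity(vars, arity))
}

sop_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  type <- character(0); tok_text <- character(0); pos <- integer(0)
  for (j in seq_along(chars)) {
    ch <- chars[j]
    if (grepl("^\\s$", ch)) next
    t <- if (ch %in% LETTERS[1:8]) "VAR"
    else if (ch %in% c("+", "|")) "OR"
    else if (ch %in% c("*", "&")) "AND"
    else if (ch %in% c("!", "~")) "NOT"
    else if (ch == "(") "LPAREN"
    else if (ch == ")") "RPAREN"
    else if (ch == "0") "CONST0"
    else if (ch == "1") "CONST1"
    else if (ch %in% LETTERS)
      stop(sprintf("arity error: variable '%s' beyond H (position %d)", ch, j),
           call. = FALSE)
    else stop(sprintf("parse error: unknown symbol '%s' at position %d", ch, j),
              call. = FALSE)
    type <- c(type, t); tok_text <- c(tok_text, ch); pos <- c(pos, j)
  }
  list(type = type, text = tok_text, pos = pos)
}

# one product term, optionally parenthesised; returns term + next index
parse_term <- function(toks, i) {
  n <- length(toks$type)
  wrapped <- toks$type[i] == "LPAREN"
  if (wrapped) i <- i + 1L
  lits_var <- character(0); lits_neg <- logical(0)
  repeat {
    neg <- FALSE
    while (i <= n && toks$type[i] == "NOT") { neg <- !neg; i <- i + 1L }
    if (i > n || toks$type[i] != "VAR")
      stop(sprintf("parse error: expected variable at position %d",
                   if (i <= n) toks$pos[i] else nchar(paste(toks$text, collapse = "")) + 1L),
           call. = FALSE)
    v <- toks$text[i]; i <- i + 1L
    hit <- which(lits_var == v)
    if (length(hit)) {
      if (lits_neg[hit] != neg)
        stop(sprintf("contradiction error: term contains both %s and !%s", v, v),
             call. = FALSE)
      # duplicate literal of equal polarity: collapse silently
    } else {
      lits_var <- c(lits_var, v); lits_neg <- c(lits_neg, neg)
    }
    if (i <= n && toks$type[i] == "AND") { i <- i + 1L; next }
    break
  }
  if (wrapped) {
    if (i > n || toks$type[i] != "RPAREN")
      stop(sprintf("parse error: unbalanced '(' (expected ')' near position %d)",
                   if (i <= length(toks$pos)) toks$pos[i] else toks$pos[length(toks$pos)]),
           call. = FALSE)
    i <- i + 1L
  }
  term <- stats::setNames(lits_neg, lits_var)
  list(term = term, i = i)
}

resolve_arity <- function(vars, arity) {
  need <- if (length(vars)) max(match(vars, LETTERS[1:8])) else 0L
  if (is.null(arity)) {
    k <- c(2L, 4L, 8L)[which(c(2L, 4L, 8L) >= max(need, 1L))[1]]
    return(k)
  }
  arity <- as.integer(arity)
  if (!arity %in% c(2L, 4L, 8L))
    stop("arity error: arity must be one of 2, 4, 8", call. = FALSE)
  if (need > arity)
    stop(sprintf("arity error: expression uses %s but arity is %d",
                 LETTERS[need], arity), call. = FALSE)
  arity
}

new_sop_expr <- function(terms, constant, arity) {
  structure(list(terms = terms, constant = constant, arity = arity),
            class = "sop_expr")
}

#' @export
format.sop_expr <- function(x, ...) {
  if (!is.na(x$constant)) return(as.character(x$constant))
  fmt_term <- function(term) {
    lits <- paste0(ifelse(term, "!", ""), names(term))
    body <- paste(lits, collapse = " * ")
    if (length(lits) > 1L) paste0("(", body, ")") else body
  }
  paste(vapply(x$terms, fmt_term, character(1)), collapse = " + ")
}

#' @export
print.sop_expr <- function(x, ...) {
  cat("<sop_expr> arity", x$arity, "\n ", format(x), "\n")
  invisible(x)
}

#' Evaluate a sum-of-products expression at one assignment
#'
#' Standard SOP semantics: the result is 1 iff at least one product term
#' has all its literals satisfied; constant expressions return their value.
#'
#' @param expr An [parse_sop()] expression.
#' @param assignment Named vector (logical or 0/1) covering every variable
#'   the expression uses; an uncovered variable is an error.
#' @return Integer 0 or 1.
#' @examples
#' xor2 <- parse_sop("(A * !B) + (B * !A)")
#' sop_evaluate(xor2, c(A = 1, B = 0))
#' @export
sop_evaluate <- function(expr, assignment) {
  stopifnot(inherits(expr, "sop_expr"))
  if (!is.na(expr$constant)) return(expr$constant)
  vals <- as.integer(assignment) != 0L
  names(vals) <- names(assignment)
  used <- unique(unlist(lapply(expr$terms, names)))
  missing <- setdiff(used, names(vals))
  if (length(missing))
    stop("assignment does not cover variable(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (term in expr$terms) {
    lit <- vals[names(term)] != term   # TRUE where literal satisfied
    if (all(lit)) return(1L)
  }
  0L
}

#' Compile an expression into a rule lookup table
#'
#' Enumerates all `2^k` assignments of the first `k` variables (`k` the
#' expression's arity) and records the expression's value for each. The
#' indexing convention is fixed: variable `A` is the most significant bit,
#' so index `i` (0-based) encodes the assignment whose binary digits, read
#' from the high bit down, are the values of A, B, C, ...
#'
#' @param expr An [parse_sop()] expression.
#' @return An object of class `rule_table`: list with `arity` and
#'   `outputs`, an integer 0/1 vector of length `2^arity`.
#' @examples
#' truth_table(parse_sop("(A * !B) + (B * !A)"))$outputs  # 0 1 1 0
#' @export
truth_table <- function(expr) {
  stopifnot(inherits(expr, "sop_expr"))
  k <- expr$arity
  n <- 2L^k
  if (!is.na(expr$constant)) {
    return(new_rule_table(rep(expr$constant, n), k))
  }
  idx <- 0:(n - 1L)
  # bits[, j] is the value of the j-th variable (A first = MSB)
  bits <- vapply(seq_len(k), function(j) {
    bitwAnd(idx, bitwShiftL(1L, k - j)) > 0L
  }, logical(n))
  out <- rep(FALSE, n)
  vars <- LETTERS[1:8]
  for (term in expr$terms) {
    sat <- rep(TRUE, n)
    for (v in names(term)) {
      col <- bits[, match(v, vars)]
      sat <- sat & (if (term[[v]]) !col else col)
    }
    out <- out | sat
  }
  new_rule_table(as.integer(out), k)
}

new_rule_table <- function(outputs, arity) {
  outputs <- as.integer(outputs)
  stopifnot(length(outputs) == 2L^arity, all(outputs %in% c(0L, 1L)))
  structure(list(arity = as.integer(arity), outputs = outputs),
            class = "rule_table")
}

#' @export
print.rule_table <- function(x, ...) {
  cat("<rule_table> arity", x$arity, "-", length(x$outputs), "entries\n")
  if (length(x$outputs) <= 16L)
    cat(" outputs:", paste(x$outputs, collapse = " "), "\n")
  else
    cat(" ", sum(x$outputs), "of", length(x$outputs), "entries are 1\n")
  invisible(x)
}

#' Canonical form of an expression
#'
#' Sorts the literals of each term by variable, removes duplicate terms,
#' and sorts the terms lexicographically, giving a unique representative
#' of each SOP formula up to commutativity. Idempotent; used for
#' catalogue deduplication and round-trip tests. No Boolean minimisation
#' is attempted.
#'
#' @param expr An [parse_sop()] expression.
#' @return An `sop_expr` in canonical order.
#' @export
canonical_form <- function(expr) {
  stopifnot(inherits(expr, "sop_expr"))
  if (!is.na(expr$constant)) return(expr)
  terms <- lapply(expr$terms, function(term) term[order(names(term))])
  keys <- vapply(terms, function(term)
    paste0(ifelse(term, "!", ""), names(term), collapse = "*"), character(1))
  keep <- !duplicated(keys)
  terms <- terms[keep][order(keys[keep], method = "radix")]
  new_sop_expr(terms, constant = NA_integer_, arity = expr$arity)
}
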