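## Boolean set-operation expressions over supporting-caller sets.
## Grammar (precedence NOT > AND > OR; binary NOT is set difference):
##   expr    := and_expr ( OR and_expr )*
##   and_expr:= unary ( (AND | NOT) unary )*
##   unary   := NOT unary | primary
##   primary := '(' expr ')' | min_support '(' k ')' | max_support '(' k ')'
##            | caller identifier

#' Parse a set-operation expression
#'
#' Parses strings like `"(manta AND svaba) NOT (lumpy OR delly)"` or
#' `"min_support(2)"` into an expression tree. `AND`/`OR`/`NOT` are
#' case-insensitive keywords; `NOT` used between two terms is set
#' difference (`A NOT B` keeps records supported by A and not by B), and
#' unary `NOT` is complement. `min_support(k)` / `max_support(k)` are
#' support-count predicates.
#'
#' @param text expression string.
#' @return a `SetExpression` tree (nested lists with an `op` field).
#' @examples
#' expr <- parseSetExpression("(manta AND svaba) NOT (lumpy OR delly)")
#' deparseSetExpression(expr)
#' @export
parseSetExpression <- function(text) {
  toks <- .tokenizeExpr(text)
  st <- new.env()
  st$toks <- toks
  st$k <- 1L
  e <- .parseOr(st, text)
  if (st$k <= nrow(st$toks))
    .stopValidation("syntax error at offset %d of '%s': unexpected '%s'",
                    st$toks$offset[st$k], text, st$toks$value[st$k])
  structure(e, class = "SetExpression")
}

.tokenizeExpr <- function(text) {
  pat <- "\\(|\\)|[A-Za-z0-9_.:-]+"
  m <- gregexpr(pat, text)[[1L]]
  if (m[1L] == -1L) .stopValidation("empty set expression")
  vals <- regmatches(text, gregexpr(pat, text))[[1L]]
  ## anything between tokens must be whitespace
  covered <- rep(FALSE, nchar(text))
  for (i in seq_along(vals))
    covered[seq(m[i], m[i] + attr(m, "match.length")[i] - 1L)] <- TRUE
  resid <- strsplit(text, "")[[1L]][!covered]
  if (any(!grepl("^\\s$", resid)))
    .stopValidation("syntax error in '%s': unexpected character '%s'",
                    text, resid[!grepl("^\\s$", resid)][1L])
  data.frame(value = vals, offset = as.integer(m), stringsAsFactors = FALSE)
}

.peek <- function(st) if (st$k <= nrow(st$toks)) st$toks$value[st$k] else NA_character_
.advance <- function(st) { v <- .peek(st); st$k <- st$k + 1L; v }
.isKw <- function(tok, kw) !is.na(tok) && toupper(tok) == kw

.parseOr <- function(st, text) {
  e <- .parseAnd(st, text)
  while (.isKw(.peek(st), "OR")) {
    .advance(st)
    e <- list(op = "OR", lhs = e, rhs = .parseAnd(st, text))
  }
  e
}

.parseAnd <- function(st, text) {
  e <- .parseUnary(st, text)
  repeat {
    tok <- .peek(st)
    if (.isKw(tok, "AND")) {
      .advance(st)
      e <- list(op = "AND", lhs = e, rhs = .parseUnary(st, text))
    } else if (.isKw(tok, "NOT")) {
      .advance(st)
      e <- list(op = "AND", lhs = e,
                rhs = list(op = "NOT", arg = .parseUnary(st, text)))
    } else break
  }
  e
}

.parseUnary <- function(st, text) {
  if (.isKw(.peek(st), "NOT")) {
    .advance(st)
    return(list(op = "NOT", arg = .parseUnary(st, text)))
  }
  .parsePrimary(st, text)
}

.parsePrimary <- function(st, text) {
  tok <- .peek(st)
  off <- if (st$k <= nrow(st$toks)) st$toks$offset[st$k] else nchar(text) + 1L
  if (is.na(tok))
    .stopValidation("syntax error at offset %d of '%s': unexpected end of expression",
                    off, text)
  if (tok == "(") {
    .advance(st)
    e <- .parseOr(st, text)
    if (!identical(.peek(st), ")"))
      .stopValidation("syntax error at offset %d of '%s': expected ')'",
                      if (st$k <= nrow(st$toks)) st$toks$offset[st$k] else nchar(text) + 1L,
                      text)
    .advance(st)
    return(e)
  }
  if (tok == ")")
    .stopValidation("syntax error at offset %d of '%s': unexpected ')'", off, text)
  if (tolower(tok) %in% c("min_support", "max_support")) {
    .advance(st)
    if (!identical(.peek(st), "("))
      .stopValidation("syntax error at offset %d of '%s': expected '(' after %s",
                      off, text, tok)
    .advance(st)
    karg <- .advance(st)
    if (is.na(karg) || !grepl("^[0-9]+$", karg))
      .stopValidation("syntax error in '%s': %s requires an integer argument",
                      text, tok)
    if (!identical(.advance(st), ")"))
      .stopValidation("syntax error in '%s': expected ')' after %s(%s",
                      text, tok, karg)
    return(list(op = tolower(tok), k = as.integer(karg)))
  }
  if (toupper(tok) %in% c("AND", "OR"))
    .stopValidation("syntax error at offset %d of '%s': unexpected '%s'",
                    off, text, tok)
  .advance(st)
  list(op = "caller", name = tok)
}

#' Canonical text form of a set expression
#' @param expr a `SetExpression` from [parseSetExpression()].
#' @return character scalar; reparsing it yields an equivalent tree.
#' @export
deparseSetExpression <- function(expr) {
  switch(expr$op,
    caller = expr$name,
    min_support = sprintf("min_support(%d)", expr$k),
    max_support = sprintf("max_support(%d)", expr$k),
    NOT = sprintf("NOT (%s)", deparseSetExpression(expr$arg)),
    AND = sprintf("(%s AND %s)", deparseSetExpression(expr$lhs),
                  deparseSetExpression(expr$rhs)),
    OR = sprintf("(%s OR %s)", deparseSetExpression(expr$lhs),
                 deparseSetExpression(expr$rhs)))
}

## callers referenced by an expression tree
.exprCallers <- function(expr) {
  switch(expr$op,
    caller = expr$name,
    min_support = , max_support = character(),
    NOT = .exprCallers(expr$arg),
    c(.exprCallers(expr$lhs), .exprCallers(expr$rhs)))
}

#' Evaluate a set expression against one support set
#' @param expr a `SetExpression`.
#' @param support character vector of supporting callers.
#' @return logical.
#' @export
evalSetExpression <- function(expr, support) {
  switch(expr$op,
    caller = expr$name %in% support,
    min_support = length(support) >= expr$k,
    max_support = length(support) <= expr$k,
    NOT = !evalSetExpression(expr$arg, support),
    AND = evalSetExpression(expr$lhs, support) &&
          evalSetExpression(expr$rhs, support),
    OR = evalSetExpression(expr$lhs, support) ||
         evalSetExpression(expr$rhs, support))
}

#' Filter a merged callset by a set operation
#'
#' Retains exactly the consensus records whose supporting-caller set
#' satisfies the expression. Union is `min_support(1)`; intersection is
#' `min_support(n)` with `n` the total caller count.
#'
#' @param merged a [MergedSVSet-class].
#' @param expr a `SetExpression` or expression string; alternatively use
#'   `mode` for the common operations.
#' @param mode one of `"union"`, `"intersection"`, `"min_support"`,
#'   `"max_support"`, `"caller"` (ignored when `expr` is given).
#' @param k support threshold for the support modes.
#' @param caller caller name for `mode = "caller"`.
#' @return the filtered [MergedSVSet-class].
#' @export
applySetOperation <- function(merged, expr = NULL,
                              mode = c("union", "intersection",
                                       "min_support", "max_support", "caller"),
                              k = NULL, caller = NULL) {
  stopifnot(is(merged, "MergedSVSet"))
  if (is.null(expr)) {
    mode <- match.arg(mode)
    expr <- switch(mode,
      union = list(op = "min_support", k = 1L),
      intersection = list(op = "min_support",
                          k = max(1L, length(merged@callers))),
      min_support = list(op = "min_support", k = as.integer(k)),
      max_support = list(op = "max_support", k = as.integer(k)),
      caller = list(op = "caller", name = caller))
    expr <- structure(expr, class = "SetExpression")
  }
  if (is.character(expr)) expr <- parseSetExpression(expr)
  unknown <- setdiff(.exprCallers(expr), merged@callers)
  if (length(unknown))
    .stopValidation("unknown caller identifier(s) in expression: %s",
                    paste(unknown, collapse = ", "))
  keep <- vapply(svSupport(merged), function(s) evalSetExpression(expr, s),
                 logical(1L))
  new("MergedSVSet",
      SVCallSet(records = merged@records[keep, , drop = FALSE],
                sampleNames = merged@sampleNames,
                metadata = c(merged@metadata,
                             list(set_operation = deparseSetExpression(expr)))),
      members = merged@members[keep], callers = merged@callers)
}
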