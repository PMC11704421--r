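#' Gene-protein-reaction (GPR) boolean expressions
#'
#' A GPR rule links genes to a reaction as a boolean expression: OR encodes
#' isoenzymes (any listed gene suffices), AND encodes protein complexes (all
#' subunits required). Expressions are stored as trees with node kinds
#' `"gene"`, `"and"`, `"or"`, and the distinguished `"empty"` expression for
#' reactions that are not gene-controlled.
#'
#' @details
#' The concrete grammar is infix `and` / `or` (case-insensitive) with
#' parentheses; `and` binds tighter than `or`. Gene identifiers are any
#' whitespace-free token other than the operator words and parentheses.
#' N-ary chains of the same operator are flattened, so round-tripping through
#' [gpr_render()] is identity up to associativity.
#'
#' @param text GPR string; empty or all-whitespace text yields the empty
#'   expression.
#' @return `parse_gpr()` returns an object of class `gpr`.
#' @examples
#' e <- parse_gpr("YJL130C or (YJR109C and YOR303W)")
#' gpr_render(e)
#' eval_gpr(e, deleted = "YJL130C")
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L || is.na(text) || !nzchar(trimws(text))) {
    return(gpr_empty())
  }
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  expr <- gpr_parse_or(st, text)
  if (st$pos <= length(st$toks)) {
    stop(sprintf("GPR parse error in %s: unexpected token '%s' at position %d",
                 sQuote(text), st$toks[[st$pos]]$value, st$toks[[st$pos]]$at),
         call. = FALSE)
  }
  expr
}

gpr_empty <- function() structure(list(kind = "empty"), class = "gpr")
gpr_gene  <- function(id) structure(list(kind = "gene", gene = id), class = "gpr")
gpr_node  <- function(op, args) {
  # flatten nested same-op nodes so associativity never matters
  flat <- list()
  for (a in args) {
    if (a$kind == op) flat <- c(flat, a$args) else flat <- c(flat, list(a))
  }
  structure(list(kind = op, args = flat), class = "gpr")
}

gpr_tokenize <- function(text) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, value = ch, at = i)
      i <- i + 1L
      next
    }
    m <- regmatches(substr(text, i, n), regexpr("^[^()[:space:]]+", substr(text, i, n)))
    word <- m[[1]]
    type <- switch(tolower(word), "and" = "and", "or" = "or", "gene")
    toks[[length(toks) + 1L]] <- list(type = type, value = word, at = i)
    i <- i + nchar(word)
  }
  toks
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL

gpr_parse_or <- function(st, text) {
  args <- list(gpr_parse_and(st, text))
  while (!is.null(tk <- gpr_peek(st)) && tk$type == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st, text)))
  }
  if (length(args) == 1L) args[[1]] else gpr_node("or", args)
}

gpr_parse_and <- function(st, text) {
  args <- list(gpr_parse_atom(st, text))
  while (!is.null(tk <- gpr_peek(st)) && tk$type == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st, text)))
  }
  if (length(args) == 1L) args[[1]] else gpr_node("and", args)
}

gpr_parse_atom <- function(st, text) {
  tk <- gpr_peek(st)
  if (is.null(tk)) {
    stop(sprintf("GPR parse error in %s: dangling operator at end of input",
                 sQuote(text)), call. = FALSE)
  }
  if (tk$type == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st, text)
    cl <- gpr_peek(st)
    if (is.null(cl) || cl$type != ")") {
      stop(sprintf("GPR parse error in %s: unbalanced parenthesis opened at position %d",
                   sQuote(text), tk$at), call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk$type == "gene") {
    st$pos <- st$pos + 1L
    return(gpr_gene(tk$value))
  }
  stop(sprintf("GPR parse error in %s: unexpected '%s' at position %d",
               sQuote(text), tk$value, tk$at), call. = FALSE)
}

#' Render a GPR expression back to its string form
#'
#' Sub-expressions under a different operator are always parenthesized, so the
#' emitted string is unambiguous regardless of operator precedence.
#'
#' @param expr a `gpr` object.
#' @return A single string; the empty expression renders as `""`.
#' @export
gpr_render <- function(expr) {
  stopifnot(inherits(expr, "gpr"))
  switch(expr$kind,
    empty = "",
    gene = expr$gene,
    and = paste(vapply(expr$args, gpr_render_child, "", parent = "and"),
                collapse = " and "),
    or = paste(vapply(expr$args, gpr_render_child, "", parent = "or"),
               collapse = " or ")
  )
}

gpr_render_child <- function(x, parent) {
  s <- gpr_render(x)
  if (x$kind %in% c("and", "or") && x$kind != parent) paste0("(", s, ")") else s
}

#' Evaluate a GPR expression under a gene deletion
#'
#' Deleted genes are false, all other genes true; the empty expression is
#' true (the reaction is not gene-controlled and survives any knockout).
#'
#' @param expr a `gpr` object.
#' @param deleted character vector of deleted gene ids.
#' @return `TRUE` if the reaction retains its gene support, else `FALSE`.
#' @export
eval_gpr <- function(expr, deleted = character()) {
  stopifnot(inherits(expr, "gpr"))
  switch(expr$kind,
    empty = TRUE,
    gene = !(expr$gene %in% deleted),
    and = all(vapply(expr$args, eval_gpr, logical(1), deleted = deleted)),
    or = any(vapply(expr$args, eval_gpr, logical(1), deleted = deleted))
  )
}

#' Genes named by a GPR expression
#'
#' @param expr a `gpr` object.
#' @return Character vector of distinct gene ids, in first-appearance order.
#' @export
gpr_genes <- function(expr) {
  stopifnot(inherits(expr, "gpr"))
  switch(expr$kind,
    empty = character(),
    gene = expr$gene,
    unique(unlist(lapply(expr$args, gpr_genes)))
  )
}

#' @export
print.gpr <- function(x, ...) {
  s <- gpr_render(x)
  cat("<gpr> ", if (nzchar(s)) s else "(empty)", "\n", sep = "")
  invisible(x)
}

#' @export
format.gpr <- function(x, ...) gpr_render(x)
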