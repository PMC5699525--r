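# Gene-protein-reaction (GPR) boolean expressions.
#
# A GPR is a tree over gene-id leaves: leaves are character scalars, inner
# nodes are list(op = "and"|"or", args = list(...)). NULL is the empty
# association (spontaneous reaction).

#' Parse a gene association string
#'
#' Parses the `and`/`or`/parentheses grammar used by GENE_ASSOCIATION notes
#' and by flattened fbc associations, case-insensitively. Gene identifiers
#' are any token other than `and`/`or`/parentheses.
#'
#' @param text association string; `""`, `NA` or whitespace give the empty
#'   expression (`NULL`).
#' @return A GPR expression tree, or `NULL` when empty.
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' gpr_genes(parse_gpr("g1 and g2"))
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- regmatches(text, gregexpr("\\(|\\)|[^()\\s]+", text, perl = TRUE))[[1]]
  pos <- 1L

  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  is_kw <- function(t, kw) !is.na(t) && tolower(t) == kw

  parse_expr <- function() {
    node <- parse_term()
    args <- list(node)
    while (is_kw(peek(), "or")) {
      advance()
      args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    node <- parse_factor()
    args <- list(node)
    while (is_kw(peek(), "and")) {
      advance()
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("GPR syntax error: unexpected end of expression at position ",
                       pos, " in \"", text, "\"")
    if (t == "(") {
      advance()
      node <- parse_expr()
      if (!identical(peek(), ")")) {
        stop("GPR syntax error: unbalanced parentheses at token ", pos,
             " in \"", text, "\"")
      }
      advance()
      return(node)
    }
    if (t == ")" || is_kw(t, "and") || is_kw(t, "or")) {
      stop("GPR syntax error: unexpected \"", t, "\" at token ", pos,
           " in \"", text, "\"")
    }
    advance()
  }

  tree <- parse_expr()
  if (pos <= length(toks)) {
    stop("GPR syntax error: unexpected \"", toks[pos], "\" at token ", pos,
         " in \"", text, "\"")
  }
  tree
}

#' Flatten a GPR expression to its gene set
#'
#' @param gpr a GPR tree from [parse_gpr()] (or `NULL`).
#' @return Sorted, duplicate-free character vector of gene ids (empty for the
#'   empty expression).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character())
  if (is.character(gpr)) return(gpr)
  sort(unique(unlist(lapply(gpr$args, gpr_genes))))
}

#' Render a GPR expression as text
#'
#' The printed form re-parses to a tree with the same flattened gene set.
#'
#' @param gpr a GPR tree (or `NULL`).
#' @return A string; `""` for the empty expression.
#' @export
gpr_string <- function(gpr) {
  if (is.null(gpr)) return("")
  if (is.character(gpr)) return(gpr)
  parts <- vapply(gpr$args, function(a) {
    s <- gpr_string(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", gpr$op, " "))
}
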