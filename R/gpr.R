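# Gene-protein-reaction (GPR) boolean rules.
#
# Rules are boolean expressions over gene identifiers with AND/OR and
# parentheses, e.g. "(b0114 and b0115) or b0116".  AND binds tighter than
# OR; keywords are case-insensitive.  Parsed form is a nested list:
#   leaf:  list(op = "gene", gene = "b0114")
#   node:  list(op = "and"|"or", args = list(...))

#' Parse a GPR rule string
#'
#' @param rule character scalar; `""` or `NA` yields `NULL` (no rule).
#' @return parsed rule tree, or `NULL`.
#' @export
#' @examples
#' parse_gpr("(b0114 and b0115) or b0116")
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0L || is.na(rule) ||
      !nzchar(trimws(rule))) return(NULL)
  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks))
    stop("malformed GPR rule near '", st$toks[st$pos], "': ", rule)
  tree
}

gpr_tokenize <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.na(tk)) stop("malformed GPR rule: unexpected end of expression")
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")")
      stop("malformed GPR rule: unbalanced parenthesis")
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tolower(tk) %in% c("and", "or", ")"))
    stop("malformed GPR rule: unexpected token '", tk, "'")
  st$pos <- st$pos + 1L
  list(op = "gene", gene = tk)
}

#' Genes referenced by a GPR rule
#' @param tree parsed rule (or `NULL`).
#' @return character vector of unique gene identifiers.
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (tree$op == "gene") return(tree$gene)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

#' Serialize a parsed GPR rule back to a string
#' @param tree parsed rule (or `NULL`).
#' @return character scalar (`""` for `NULL`).
#' @export
gpr_to_string <- function(tree) {
  if (is.null(tree)) return("")
  if (tree$op == "gene") return(tree$gene)
  parts <- vapply(tree$args, function(a) {
    s <- gpr_to_string(a)
    if (a$op != "gene") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}

#' Protein complexes implied by a GPR rule
#'
#' Converts the rule to disjunctive normal form; each conjunct is one
#' protein (an enzyme or enzyme complex).  A complex is identified by its
#' sorted member genes joined with `"&"`; a single-gene protein keeps the
#' gene identifier.  Isozymes ("a or b") therefore yield two proteins.
#'
#' @param tree parsed rule (or `NULL`).
#' @return character vector of protein identifiers.
#' @export
gpr_proteins <- function(tree) {
  if (is.null(tree)) return(character(0))
  conj <- gpr_dnf(tree)
  unique(vapply(conj, function(g) paste(sort(unique(g)), collapse = "&"),
                character(1)))
}

# DNF as a list of character vectors (gene sets of each conjunct)
gpr_dnf <- function(tree) {
  if (tree$op == "gene") return(list(tree$gene))
  parts <- lapply(tree$args, gpr_dnf)
  if (tree$op == "or") return(do.call(c, parts))
  # and: cartesian product of conjuncts
  out <- list(character(0))
  for (p in parts) {
    out <- unlist(lapply(out, function(a) lapply(p, function(b) c(a, b))),
                  recursive = FALSE)
  }
  out
}
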