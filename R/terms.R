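# Term grammar: tag(entity). The tag names the functional form of a biological
# entity (its mRNA, protein, an activity, ...); the entity name is opaque.

.TAG_TO_FUNCTION <- c(
  r       = "rna-abundance",
  p       = "protein-abundance",
  pp      = "phosphoprotein",
  taof    = "transcriptional-activity",
  kaof    = "kinase-activity",
  gtpof   = "gtp-bound-activity",
  complex = "complex",
  fam     = "protein-family",
  bp      = "biological-process",
  chem    = "chemical"
)

.FUNCTION_TO_TAG <- stats::setNames(names(.TAG_TO_FUNCTION), .TAG_TO_FUNCTION)

#' Functional vocabulary of biological terms
#'
#' The closed set of functional categories a term may take: mRNA abundance,
#' protein abundance, phosphoprotein, transcriptional / kinase / GTP-bound
#' activity, complex, protein family, biological process, or chemical.
#'
#' @return Named character vector mapping term-grammar tags to function names.
#' @export
#' @examples
#' term_functions()
term_functions <- function() .TAG_TO_FUNCTION

#' Construct a biological term
#'
#' A term is a functionalized biological entity, e.g. the transcriptional
#' activity of Nfe2l2 is written `taof(Nfe2l2)`. Two terms are equal iff their
#' function and entity are equal; the function tag is case-insensitive, the
#' entity name is case-sensitive.
#'
#' @param fun Function category (one of `term_functions()`), or a grammar tag
#'   such as `"taof"` (case-insensitive).
#' @param entity Non-empty entity name.
#' @return An object of class `bio_term` with fields `fun` and `entity`.
#' @seealso [parse_term()]
#' @export
#' @examples
#' bio_term("transcriptional-activity", "Nfe2l2")
bio_term <- function(fun, entity) {
  stopifnot(is.character(fun), length(fun) == 1L,
            is.character(entity), length(entity) == 1L)
  fun <- tolower(fun)
  if (fun %in% names(.TAG_TO_FUNCTION)) fun <- .TAG_TO_FUNCTION[[fun]]
  if (!fun %in% .TAG_TO_FUNCTION)
    stop("unknown term function: '", fun, "'", call. = FALSE)
  if (!nzchar(entity))
    stop("term entity must be a non-empty string", call. = FALSE)
  structure(list(fun = fun, entity = entity), class = "bio_term")
}

#' Parse a term string
#'
#' Parses the `tag(entity)` grammar, e.g. `"taof(Nfe2l2)"` is the
#' transcriptional activity of Nfe2l2 and `"r(Cyp1a1)"` the mRNA abundance of
#' Cyp1a1. Entity names may contain spaces and internal parentheses
#' (`"taof(AP-1 complex)"`); the tag is case-insensitive.
#'
#' @param text A single term string.
#' @return A [bio_term()].
#' @export
#' @examples
#' parse_term("taof(Nfe2l2)")
#' parse_term("gtpof(Kras)")
parse_term <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  m <- regmatches(txt, regexec("^([A-Za-z]+)\\((.*)\\)$", txt))[[1]]
  if (length(m) != 3L)
    stop("malformed term: '", text, "' (expected tag(entity))", call. = FALSE)
  tag <- tolower(m[2]); entity <- m[3]
  # entity-internal parentheses must balance
  depth <- cumsum((strsplit(entity, "")[[1]] == "(") -
                    (strsplit(entity, "")[[1]] == ")"))
  if (length(depth) && (any(depth < 0) || depth[length(depth)] != 0))
    stop("malformed term: '", text, "' (unbalanced parentheses)", call. = FALSE)
  if (!nzchar(entity))
    stop("malformed term: '", text, "' (empty entity)", call. = FALSE)
  if (!tag %in% names(.TAG_TO_FUNCTION))
    stop("unknown term tag '", tag, "' in '", text, "'", call. = FALSE)
  bio_term(.TAG_TO_FUNCTION[[tag]], entity)
}

#' @export
as.character.bio_term <- function(x, ...) {
  paste0(.FUNCTION_TO_TAG[[x$fun]], "(", x$entity, ")")
}

#' @export
format.bio_term <- function(x, ...) as.character(x)

#' @export
print.bio_term <- function(x, ...) {
  cat("<bio_term> ", as.character(x), "  [", x$fun, "]\n", sep = "")
  invisible(x)
}

#' @export
`==.bio_term` <- function(e1, e2) {
  inherits(e1, "bio_term") && inherits(e2, "bio_term") &&
    identical(e1$fun, e2$fun) && identical(e1$entity, e2$entity)
}

# Vectorized canonicalization of term strings; returns canonical strings and
# stops with the offending text on error. Used by the TSV parser.
canonicalize_terms <- function(x) {
  vapply(x, function(t) as.character(parse_term(t)), character(1),
         USE.NAMES = FALSE)
}

# Vectorized accessors on canonical term strings
term_function_of <- function(x) {
  tag <- tolower(sub("\\(.*$", "", x))
  unname(.TAG_TO_FUNCTION[tag])
}

term_entity_of <- function(x) {
  sub("\\)$", "", sub("^[A-Za-z]+\\(", "", x))
}
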