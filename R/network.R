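# Signed causal network model: nodes are biological terms, edges are signed,
# evidence-annotated cause-effect assertions. Non-causal edges link different
# functional forms of one entity (e.g. r(X) and p(X)) and are excluded from
# all inference.

.SPECIES <- c("human", "mouse", "rat", "unspecified")

split_semi <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

join_semi <- function(x) paste(x, collapse = ";")

edge_key <- function(edges) {
  paste(edges$source, edges$target, edges$sign, edges$causal, sep = "\r")
}

#' Construct a causal network model
#'
#' Builds a network from an edge table. Edge identity is
#' (source, target, sign, causal): duplicate assertions are merged and their
#' PMID evidence lists unioned. Every edge endpoint becomes a node; additional
#' (isolated) nodes may be declared through `nodes`. Edges with identical
#' endpoints but opposite signs are both retained — context-dependent biology
#' allows it, and such pairs later yield ambiguous signature entries.
#'
#' @param edges Data frame with columns `source`, `target` (term strings in the
#'   `tag(entity)` grammar), `sign` (+1 or -1), and optionally `causal`
#'   (logical, default `TRUE`), `species` (`"human"`, `"mouse"`, `"rat"` or
#'   `"unspecified"`), `tissue` (free-text label), `pmids` (semicolon-joined
#'   PubMed ids, may be empty).
#' @param nodes Optional data frame with columns `term` and `blocks`
#'   (semicolon-joined building-block labels). Endpoint nodes are added
#'   automatically; blocks are a node attribute, not a partition (a node may
#'   belong to several blocks).
#' @param name Model name.
#' @return An object of class `causal_network` with elements `name`, `nodes`
#'   (data frame: `term`, `fun`, `entity`, `blocks`) and `edges`.
#' @export
#' @examples
#' net <- causal_network(data.frame(
#'   source = "taof(Nfe2l2)", target = "r(Nqo1)", sign = 1))
#' net
causal_network <- function(edges = NULL, nodes = NULL, name = "network") {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(source = character(0), target = character(0),
                        sign = integer(0), causal = logical(0),
                        species = character(0), tissue = character(0),
                        pmids = character(0), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("source", "target", "sign") %in% names(edges)))
      stop("edges must have columns source, target, sign", call. = FALSE)
    if (is.null(edges$causal)) edges$causal <- TRUE
    if (is.null(edges$species)) edges$species <- "unspecified"
    if (is.null(edges$tissue)) edges$tissue <- ""
    if (is.null(edges$pmids)) edges$pmids <- ""
    edges$source <- canonicalize_terms(edges$source)
    edges$target <- canonicalize_terms(edges$target)
    edges$sign <- as.integer(edges$sign)
    edges$causal <- as.logical(edges$causal)
    edges$tissue[is.na(edges$tissue)] <- ""
    edges$pmids[is.na(edges$pmids)] <- ""
    if (!all(edges$sign %in% c(1L, -1L)))
      stop("edge sign must be +1 or -1", call. = FALSE)
    if (any(!edges$causal & edges$sign != 1L))
      stop("non-causal edges must carry sign +1", call. = FALSE)
    if (!all(edges$species %in% .SPECIES))
      stop("edge species must be one of: ", paste(.SPECIES, collapse = ", "),
           call. = FALSE)
    edges <- merge_duplicate_edges(edges)
    edges <- edges[, c("source", "target", "sign", "causal", "species",
                       "tissue", "pmids")]
  }

  node_terms <- unique(c(edges$source, edges$target))
  blocks <- stats::setNames(rep("", length(node_terms)), node_terms)
  if (!is.null(nodes) && nrow(nodes) > 0L) {
    nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
    nodes$term <- canonicalize_terms(nodes$term)
    if (is.null(nodes$blocks)) nodes$blocks <- ""
    nodes$blocks[is.na(nodes$blocks)] <- ""
    for (i in seq_len(nrow(nodes))) {
      t <- nodes$term[i]
      cur <- if (t %in% names(blocks)) split_semi(blocks[[t]]) else character(0)
      blocks[t] <- join_semi(sort(unique(c(cur, split_semi(nodes$blocks[i])))))
    }
    node_terms <- names(blocks)
  }
  nd <- data.frame(term = node_terms,
                   fun = term_function_of(node_terms),
                   entity = term_entity_of(node_terms),
                   blocks = unname(blocks[node_terms]),
                   stringsAsFactors = FALSE)
  nd <- nd[order(nd$term), , drop = FALSE]
  rownames(nd) <- NULL
  edges <- edges[order(edge_key(edges)), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(name = name, nodes = nd, edges = edges),
            class = "causal_network")
}

merge_duplicate_edges <- function(edges) {
  key <- edge_key(edges)
  if (!anyDuplicated(key)) return(edges)
  first <- !duplicated(key)
  pm <- tapply(edges$pmids, key, function(p)
    join_semi(unique(unlist(lapply(p, split_semi)))))
  out <- edges[first, , drop = FALSE]
  out$pmids <- unname(pm[key[first]])
  out
}

#' @export
print.causal_network <- function(x, ...) {
  st <- network_statistics(x)
  cat("<causal_network> ", x$name, ": ", st$n_nodes, " nodes, ",
      st$n_edges, " edges (", st$n_causal, " causal)\n", sep = "")
  invisible(x)
}

#' Parse a network from canonical edge-TSV
#'
#' Reads the canonical tab-separated network dialect: a header row followed by
#' one edge per line with columns `source`, `relation`, `target`,
#' `causal_flag`, `species`, `tissue`, `pmids`, `blocks`. The relation word is
#' `increases` or `decreases` (sign +1 / -1); rows with relation `node` declare
#' an isolated node (term in `source`, `target` empty). Block labels are
#' semicolon-joined; a bare label applies to both endpoints, and
#' `source:`/`target:`-qualified labels to one endpoint.
#'
#' @param path Path to a TSV file (or a connection readable by
#'   [utils::read.delim()]).
#' @param name Model name; defaults to the file name.
#' @return A [causal_network()].
#' @export
parse_network_tsv <- function(path, name = NULL) {
  if (is.null(name))
    name <- if (is.character(path)) basename(path) else "network"
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           check.names = FALSE, na.strings = NULL)
  req <- c("source", "relation", "target", "causal_flag", "species",
           "tissue", "pmids", "blocks")
  if (!all(req %in% names(tab)))
    stop("network TSV must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) == 0L) return(causal_network(name = name))

  line_no <- seq_len(nrow(tab)) + 1L  # header is line 1
  is_node <- tab$relation == "node"
  bad <- !(tab$relation %in% c("increases", "decreases", "node"))
  if (any(bad))
    stop("unknown relation word '", tab$relation[which(bad)[1]],
         "' at line ", line_no[which(bad)[1]], call. = FALSE)

  parse_at <- function(txt, ln) {
    tryCatch(as.character(parse_term(txt)),
             error = function(e) stop(conditionMessage(e), " at line ", ln,
                                      call. = FALSE))
  }

  src_blocks <- list(); tgt_blocks <- list()
  split_blocks <- function(b) {
    labs <- split_semi(b)
    s <- sub("^source:", "", labs[startsWith(labs, "source:")])
    t <- sub("^target:", "", labs[startsWith(labs, "target:")])
    both <- labs[!startsWith(labs, "source:") & !startsWith(labs, "target:")]
    list(src = c(s, both), tgt = c(t, both))
  }

  edge_rows <- which(!is_node)
  edges <- NULL
  if (length(edge_rows)) {
    edges <- data.frame(
      source = vapply(edge_rows, function(i) parse_at(tab$source[i], line_no[i]),
                      character(1)),
      target = vapply(edge_rows, function(i) parse_at(tab$target[i], line_no[i]),
                      character(1)),
      sign = ifelse(tab$relation[edge_rows] == "increases", 1L, -1L),
      causal = tab$causal_flag[edge_rows] != "non-causal",
      species = ifelse(tab$species[edge_rows] %in% .SPECIES,
                       tab$species[edge_rows], "unspecified"),
      tissue = tab$tissue[edge_rows],
      pmids = tab$pmids[edge_rows],
      stringsAsFactors = FALSE)
  }

  node_tab <- list()
  add_blocks <- function(term, labs) {
    if (!length(labs)) labs <- character(0)
    node_tab[[term]] <<- unique(c(node_tab[[term]], labs))
  }
  for (i in seq_len(nrow(tab))) {
    bl <- split_blocks(tab$blocks[i])
    if (is_node[i]) {
      add_blocks(parse_at(tab$source[i], line_no[i]), c(bl$src, bl$tgt))
    } else {
      add_blocks(parse_at(tab$source[i], line_no[i]), bl$src)
      add_blocks(parse_at(tab$target[i], line_no[i]), bl$tgt)
    }
  }
  nodes <- data.frame(term = names(node_tab),
                      blocks = vapply(node_tab, function(b)
                        join_semi(sort(unique(b))), character(1)),
                      stringsAsFactors = FALSE)
  causal_network(edges, nodes, name = name)
}

#' Summary statistics of a network model
#'
#' Counts distinct nodes (overall and per functional category), edges, causal
#' edges (overall and per species), and unique PMIDs across causal-edge
#' evidence. Counts are of distinct elements under term and edge identity, so
#' they are invariant under reordering and duplicate re-assertion.
#'
#' @param model A [causal_network()].
#' @return A list with elements `n_nodes`, `nodes_by_function` (named integer
#'   vector over the full functional vocabulary), `n_edges`, `n_causal`,
#'   `causal_by_species`, `n_unique_pmids`.
#' @export
network_statistics <- function(model) {
  stopifnot(inherits(model, "causal_network"))
  funs <- unname(.TAG_TO_FUNCTION)
  by_fun <- stats::setNames(integer(length(funs)), funs)
  tb <- table(model$nodes$fun)
  by_fun[names(tb)] <- as.integer(tb)
  ce <- model$edges[model$edges$causal, , drop = FALSE]
  by_sp <- stats::setNames(integer(length(.SPECIES)), .SPECIES)
  tbs <- table(ce$species)
  by_sp[names(tbs)] <- as.integer(tbs)
  pmids <- unique(unlist(lapply(ce$pmids, split_semi)))
  list(n_nodes = nrow(model$nodes),
       nodes_by_function = by_fun,
       n_edges = nrow(model$edges),
       n_causal = nrow(ce),
       causal_by_species = by_sp,
       n_unique_pmids = length(pmids))
}

#' Tissue-context composition of causal edges
#'
#' Maps each causal edge's tissue label to a category and reports the fraction
#' of causal edges per category. Labels not covered by the map fall into
#' `"other"`. Fractions sum to 1; categories are returned in alphabetical
#' order for determinism.
#'
#' @param model A [causal_network()].
#' @param category_map Named character vector, tissue label -> category.
#' @return Named numeric vector of fractions (empty if no causal edges).
#' @export
tissue_context_summary <- function(model, category_map = character(0)) {
  stopifnot(inherits(model, "causal_network"))
  ce <- model$edges[model$edges$causal, , drop = FALSE]
  if (nrow(ce) == 0L) return(stats::setNames(numeric(0), character(0)))
  cat <- ifelse(ce$tissue %in% names(category_map),
                unname(category_map[ce$tissue]), "other")
  tb <- table(cat)
  frac <- as.numeric(tb) / nrow(ce)
  stats::setNames(frac, names(tb))[order(names(tb))]
}

#' Merge two network models
#'
#' Unions the node sets, merges edges under the
#' (source, target, sign, causal) identity with evidence-list union, and
#' unions building-block labels per node. Merging a model with an empty model,
#' or with itself, returns an equal model.
#'
#' @param a,b [causal_network()] objects.
#' @param name Name for the merged model.
#' @return A [causal_network()].
#' @export
merge_models <- function(a, b, name = paste(a$name, b$name, sep = "+")) {
  stopifnot(inherits(a, "causal_network"), inherits(b, "causal_network"))
  edges <- rbind(a$edges, b$edges)
  nodes <- rbind(a$nodes[, c("term", "blocks")], b$nodes[, c("term", "blocks")])
  causal_network(edges, nodes, name = name)
}

#' Export a network model
#'
#' Writes a model in one of three dialects: the canonical edge-TSV (lossless;
#' `parse_network_tsv()` of the output reproduces an equal model), SIF
#' (source / relation word / target, viewable in Cytoscape and similar tools),
#' or GraphML (via igraph, with sign/causal/species/tissue edge attributes and
#' function/blocks node attributes).
#'
#' @param model A [causal_network()].
#' @param path Output file path.
#' @param dialect One of `"edge-TSV"`, `"SIF"`, `"GraphML"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(model, path, dialect = c("edge-TSV", "SIF", "GraphML")) {
  stopifnot(inherits(model, "causal_network"))
  dialect <- match.arg(dialect)
  switch(dialect,
         "edge-TSV" = write_edge_tsv(model, path),
         "SIF" = write_sif(model, path),
         "GraphML" = write_graphml(model, path))
  invisible(path)
}

write_edge_tsv <- function(model, path) {
  e <- model$edges
  blocks_of <- stats::setNames(model$nodes$blocks, model$nodes$term)
  qual <- function(term, prefix) {
    b <- split_semi(blocks_of[[term]])
    if (!length(b)) character(0) else paste0(prefix, b)
  }
  rows <- data.frame(
    source = e$source,
    relation = ifelse(e$sign == 1L, "increases", "decreases"),
    target = e$target,
    causal_flag = ifelse(e$causal, "causal", "non-causal"),
    species = e$species, tissue = e$tissue, pmids = e$pmids,
    blocks = vapply(seq_len(nrow(e)), function(i)
      join_semi(c(qual(e$source[i], "source:"), qual(e$target[i], "target:"))),
      character(1)),
    stringsAsFactors = FALSE)
  isolated <- setdiff(model$nodes$term, c(e$source, e$target))
  if (length(isolated)) {
    rows <- rbind(rows, data.frame(
      source = isolated, relation = "node", target = "",
      causal_flag = "non-causal", species = "unspecified", tissue = "",
      pmids = "",
      blocks = vapply(isolated, function(t) join_semi(qual(t, "source:")),
                      character(1), USE.NAMES = FALSE),
      stringsAsFactors = FALSE))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

write_sif <- function(model, path) {
  e <- model$edges
  rel <- ifelse(!e$causal, "noncausal",
                ifelse(e$sign == 1L, "increases", "decreases"))
  writeLines(paste(e$source, rel, e$target, sep = "\t"), path)
}

write_graphml <- function(model, path) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = model$edges$source, to = model$edges$target,
                   sign = model$edges$sign, causal = model$edges$causal,
                   species = model$edges$species, tissue = model$edges$tissue,
                   pmids = model$edges$pmids, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = model$nodes$term, fun = model$nodes$fun,
                          blocks = model$nodes$blocks,
                          stringsAsFactors = FALSE))
  igraph::write_graph(g, path, format = "graphml")
}

#' Test two network models for equality
#'
#' Equality under the model's identity rules: same node set with identical
#' block labels, and the same edge set (with identical evidence) under the
#' (source, target, sign, causal) edge identity. The model name is ignored.
#'
#' @param a,b [causal_network()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
network_equal <- function(a, b) {
  norm_pm <- function(p) vapply(p, function(x)
    join_semi(sort(split_semi(x))), character(1), USE.NAMES = FALSE)
  ea <- a$edges; eb <- b$edges
  ea$pmids <- norm_pm(ea$pmids); eb$pmids <- norm_pm(eb$pmids)
  isTRUE(all.equal(a$nodes, b$nodes, check.attributes = FALSE)) &&
    isTRUE(all.equal(ea, eb, check.attributes = FALSE))
}
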