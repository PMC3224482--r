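# Downstream analytics: how much of a state-change set the significant
# hypotheses explain, overlap between comparisons, and clustering of
# prediction patterns across a genotype-perturbation test design.

hyp_table <- function(significant) {
  s <- if (inherits(significant, "rcr")) significant_hypotheses(significant)
       else as.data.frame(significant, stringsAsFactors = FALSE)
  if (!nrow(s)) return(data.frame(term = character(0), direction = character(0),
                                  stringsAsFactors = FALSE))
  stopifnot(all(c("term", "direction") %in% names(s)))
  unique(s[, c("term", "direction")])
}

explained_genes <- function(scs, hyps, kam, require_sign_match) {
  if (!nrow(hyps) || !nrow(scs$changes))
    return(list(explained = character(0), per_hyp = integer(0)))
  d <- sc_directions(scs)
  e <- kam$edges
  e <- e[e$causal & term_function_of(e$target) == "rna-abundance", ,
         drop = FALSE]
  e$gene <- term_entity_of(e$target)
  e <- e[e$gene != term_entity_of(e$source), , drop = FALSE]
  expl <- character(0)
  per <- stats::setNames(integer(nrow(hyps)),
                         paste(hyps$term, hyps$direction))
  for (i in seq_len(nrow(hyps))) {
    dir_i <- if (hyps$direction[i] == "increase") 1L else -1L
    ei <- e[e$source == hyps$term[i] & e$gene %in% names(d), , drop = FALSE]
    if (!nrow(ei)) next
    ok <- if (require_sign_match) ei$sign * dir_i == d[ei$gene] else TRUE
    g <- unique(ei$gene[ok])
    per[i] <- length(g)
    expl <- union(expl, g)
  }
  list(explained = sort(expl), per_hyp = per)
}

#' State-change coverage by significant hypotheses
#'
#' A state change for gene `g` is "explained" when at least one significant
#' hypothesis (term plus predicted direction) has a causal edge to the mRNA
#' of `g` whose implied direction (edge sign times hypothesis direction)
#' matches the observed change direction. With
#' `require_sign_match = FALSE` any causal edge to the mRNA counts, which is
#' the permissive, direction-blind variant.
#'
#' @param scs A [state_change_set()].
#' @param significant An [rcr()] fit (its significant rows are used) or a data
#'   frame with columns `term` and `direction`.
#' @param kam The [causal_network()] the hypotheses came from.
#' @param require_sign_match Require direction consistency (default `TRUE`).
#' @return Object of class `coverage_report`: `label`, `explained` (gene set),
#'   `total_sc`, `fraction`, and `per_hypothesis` explained counts.
#' @export
coverage <- function(scs, significant, kam, require_sign_match = TRUE) {
  stopifnot(inherits(scs, "state_change_set"),
            inherits(kam, "causal_network"))
  hyps <- hyp_table(significant)
  res <- explained_genes(scs, hyps, kam, require_sign_match)
  total <- nrow(scs$changes)
  structure(list(label = scs$label, explained = res$explained,
                 total_sc = total,
                 fraction = if (total) length(res$explained) / total else 0,
                 per_hypothesis = res$per_hyp),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("<coverage_report> ", x$label, ": ", length(x$explained), "/",
      x$total_sc, " state changes explained (",
      sprintf("%.0f%%", 100 * x$fraction), ")\n", sep = "")
  invisible(x)
}

#' Coverage restricted to a node subset
#'
#' Same explanation rule as [coverage()], but only hypotheses whose term lies
#' in `node_subset` may explain (e.g. coverage attributable to a single
#' master regulator and its partner). With the subset equal to all
#' significant terms this equals [coverage()].
#'
#' @param scs A [state_change_set()].
#' @param node_subset Character vector of term strings; each must be a node
#'   of `kam`.
#' @param significant Significant hypotheses, as in [coverage()].
#' @param kam The [causal_network()].
#' @param require_sign_match Require direction consistency (default `TRUE`).
#' @return A `coverage_report`.
#' @export
coverage_by_nodes <- function(scs, node_subset, significant, kam,
                              require_sign_match = TRUE) {
  node_subset <- canonicalize_terms(node_subset)
  missing <- setdiff(node_subset, kam$nodes$term)
  if (length(missing))
    stop("node not in network: ", paste(missing, collapse = ", "),
         call. = FALSE)
  hyps <- hyp_table(significant)
  hyps <- hyps[hyps$term %in% node_subset, , drop = FALSE]
  res <- explained_genes(scs, hyps, kam, require_sign_match)
  total <- nrow(scs$changes)
  structure(list(label = scs$label, explained = res$explained,
                 total_sc = total,
                 fraction = if (total) length(res$explained) / total else 0,
                 per_hypothesis = res$per_hyp),
            class = "coverage_report")
}

#' Pairwise overlap between state-change sets
#'
#' For every pair of sets, reports the intersection by gene and by
#' gene-plus-direction, and the corresponding fractions relative to each set
#' (the denominators of overlap fractions differ between sets of unequal
#' size, so both are reported).
#'
#' @param sets List of two or more [state_change_set()] objects.
#' @return Data frame, one row per unordered pair, with columns `set_a`,
#'   `set_b`, `n_a`, `n_b`, `gene_overlap`, `gene_dir_overlap`, `frac_of_a`,
#'   `frac_of_b`, `frac_dir_of_a`, `frac_dir_of_b`.
#' @export
overlap_statistics <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2,
            all(vapply(sets, inherits, logical(1), "state_change_set")))
  labs <- vapply(sets, function(s) s$label, character(1))
  pairs <- utils::combn(length(sets), 2)
  rows <- apply(pairs, 2, function(ij) {
    a <- sets[[ij[1]]]; b <- sets[[ij[2]]]
    ga <- a$changes$gene; gb <- b$changes$gene
    keyed <- function(s) paste(s$changes$gene, s$changes$direction)
    og <- length(intersect(ga, gb))
    od <- length(intersect(keyed(a), keyed(b)))
    data.frame(set_a = a$label, set_b = b$label,
               n_a = length(ga), n_b = length(gb),
               gene_overlap = og, gene_dir_overlap = od,
               frac_of_a = if (length(ga)) og / length(ga) else 0,
               frac_of_b = if (length(gb)) og / length(gb) else 0,
               frac_dir_of_a = if (length(ga)) od / length(ga) else 0,
               frac_dir_of_b = if (length(gb)) od / length(gb) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Prediction patterns across comparisons
#'
#' Collects, for every hypothesis term appearing in any fit, its significant
#' call in each comparison: +1 significant increase, -1 significant decrease,
#' 0 not significant. When a term is significant in both directions of one
#' comparison the direction with the smaller concordance p wins (ties toward
#' increase).
#'
#' @param fits Named list of [rcr()] fits, in comparison order.
#' @return Integer matrix, terms x comparisons.
#' @export
prediction_patterns <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "rcr")))
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$sc_label, character(1))
  terms <- sort(unique(unlist(lapply(fits, function(f) f$scores$term))))
  pat <- matrix(0L, nrow = length(terms), ncol = length(fits),
                dimnames = list(terms, names(fits)))
  for (j in seq_along(fits)) {
    s <- best_direction(fits[[j]])
    s <- s[s$significant, , drop = FALSE]
    if (nrow(s))
      pat[s$term, j] <- ifelse(s$direction == "increase", 1L, -1L)
  }
  pat
}

#' Cluster prediction patterns across the three-comparison test design
#'
#' Classifies each term's call vector over the three ordered comparisons
#' (c1 = exposed vs sham in the reference genotype, c2 = exposed vs sham in
#' the perturbed genotype, c3 = perturbed vs reference under exposure) into
#' the lettered pattern clusters, applying the rules in order with first
#' match winning:
#' \describe{
#'   \item{A}{c1 = ±1, c2 = 0, c3 = -c1: signal fully dependent on the
#'     perturbed factor.}
#'   \item{B}{c1 = c2 = ±1, c3 = -c1: same direction in both genotypes but
#'     differential in the direct comparison — partial dependence.}
#'   \item{C}{c1 = c2 = ±1, c3 = 0: factor-independent response.}
#'   \item{D}{c1 = ±1, c2 = 0, c3 = 0: called in the reference genotype only.}
#'   \item{E}{c1 = 0, c2 = ±1, c3 = 0: called in the perturbed genotype only.}
#' }
#' Anything else is `unclustered`.
#'
#' @param patterns Matrix or data frame with exactly 3 columns of calls in
#'   \{-1, 0, +1\} (rownames are terms), as from [prediction_patterns()].
#' @return Data frame with columns `term` and `cluster`.
#' @export
assign_clusters <- function(patterns) {
  pat <- as.matrix(patterns)
  if (ncol(pat) != 3L)
    stop("patterns must have exactly 3 comparisons (columns)", call. = FALSE)
  if (!all(pat %in% c(-1L, 0L, 1L)))
    stop("pattern entries must be -1, 0 or +1", call. = FALSE)
  cl <- apply(pat, 1, function(p) {
    c1 <- p[1]; c2 <- p[2]; c3 <- p[3]
    if (c1 != 0 && c2 == 0 && c3 == -c1) "A"
    else if (c1 != 0 && c2 == c1 && c3 == -c1) "B"
    else if (c1 != 0 && c2 == c1 && c3 == 0) "C"
    else if (c1 != 0 && c2 == 0 && c3 == 0) "D"
    else if (c1 == 0 && c2 != 0 && c3 == 0) "E"
    else "unclustered"
  })
  data.frame(term = if (!is.null(rownames(pat))) rownames(pat)
             else as.character(seq_len(nrow(pat))),
             cluster = unname(cl), stringsAsFactors = FALSE)
}
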