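# Reverse causal reasoning: score every eligible network node, in both
# activity directions, as a candidate upstream cause of an observed
# state-change set. Richness is a hypergeometric upper tail on the overlap
# between a node's measured downstream transcripts and the state changes;
# concordance is a binomial upper tail on the number of direction-consistent
# overlaps under a coin-flip null.

#' RCR configuration
#'
#' @param min_downstream_measured Eligibility: a node must have at least this
#'   many measured downstream transcripts to be scored (default 4).
#' @param min_correct Significance: at least this many direction-consistent
#'   overlaps required (default 4).
#' @param richness_cutoff,concordance_cutoff Significance p-value cutoffs
#'   (default 0.1 each; strict `<`).
#' @param binomial_success_prob Null success probability of the concordance
#'   test (default 0.5, a direction coin flip).
#' @param population_mode `"all-measured-genes"` (default): the hypergeometric
#'   universe is every measured gene; `"all-network-downstream-measured"`:
#'   only measured genes downstream of at least one network node.
#' @return Object of class `rcr_config`.
#' @export
rcr_config <- function(min_downstream_measured = 4L, min_correct = 4L,
                       richness_cutoff = 0.1, concordance_cutoff = 0.1,
                       binomial_success_prob = 0.5,
                       population_mode = c("all-measured-genes",
                                           "all-network-downstream-measured")) {
  stopifnot(min_downstream_measured >= 1, min_correct >= 1,
            richness_cutoff > 0, richness_cutoff <= 1,
            concordance_cutoff > 0, concordance_cutoff <= 1,
            binomial_success_prob > 0, binomial_success_prob < 1)
  structure(list(min_downstream_measured = as.integer(min_downstream_measured),
                 min_correct = as.integer(min_correct),
                 richness_cutoff = richness_cutoff,
                 concordance_cutoff = concordance_cutoff,
                 binomial_success_prob = binomial_success_prob,
                 population_mode = match.arg(population_mode)),
            class = "rcr_config")
}

#' Build downstream signatures
#'
#' For each network node, collects the causal edges whose target is an
#' mRNA-abundance term and whose gene is measured, recording the sign the
#' transcript takes when the node's activity increases. A gene reached by
#' both a positive and a negative edge is stored with sign 0 (ambiguous). A
#' node's own mRNA is excluded from its signature — a hypothesis cannot
#' explain itself. Only nodes with at least `min_downstream_measured`
#' measured targets are returned (they are the prediction-capable nodes).
#'
#' @param kam A [causal_network()] used as the knowledge assembly model.
#' @param measured_genes Character vector of measured gene symbols.
#' @param config An [rcr_config()].
#' @return Named list of signatures; each element has `term` and `targets`
#'   (named vector gene -> sign in \{-1, 0, +1\}).
#' @export
build_signatures <- function(kam, measured_genes, config = rcr_config()) {
  stopifnot(inherits(kam, "causal_network"))
  e <- kam$edges
  e <- e[e$causal & term_function_of(e$target) == "rna-abundance", ,
         drop = FALSE]
  if (nrow(e) == 0L) return(list())
  e$gene <- term_entity_of(e$target)
  e <- e[e$gene %in% measured_genes, , drop = FALSE]
  e <- e[e$gene != term_entity_of(e$source), , drop = FALSE]  # no self-loops
  if (nrow(e) == 0L) return(list())

  sigs <- lapply(split(e, e$source), function(es) {
    sgn <- tapply(es$sign, es$gene, function(s) {
      u <- unique(s)
      if (length(u) == 1L) u else 0L
    })
    list(term = es$source[1],
         targets = stats::setNames(as.integer(sgn), names(sgn)))
  })
  sigs <- sigs[vapply(sigs, function(s)
    length(s$targets) >= config$min_downstream_measured, logical(1))]
  sigs[order(names(sigs))]
}

#' Richness: hypergeometric enrichment of a signature in the state changes
#'
#' Upper-tail probability that, drawing the node's `n` measured downstream
#' genes from a population of `N` measured genes of which `K` are state
#' changes, at least `k` of the draws are state changes. Returns exactly 1
#' when `k = 0`.
#'
#' @param N Population size (measured genes).
#' @param K State changes in the population.
#' @param n Measured downstream targets of the hypothesis.
#' @param k Observed overlap between targets and state changes.
#' @return The upper-tail probability `P(X >= k)`, in `(0, 1]`.
#' @export
#' @examples
#' score_richness(10, 5, 5, 5)  # 1/252
score_richness <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(n, K))
    stop("inconsistent counts: need 0 <= k <= min(n, K) <= N and n <= N",
         call. = FALSE)
  if (k == 0) return(1)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Concordance: binomial test of direction consistency
#'
#' Upper-tail probability of observing at least `c` direction-consistent
#' overlaps out of `c + contra` directional trials under a null success
#' probability (a direction coin flip by default). Ambiguous overlaps carry
#' no directional information and are excluded from the trial count. Returns
#' exactly 1 when `c = 0`.
#'
#' @param c Direction-consistent overlaps.
#' @param contra Direction-contradicting overlaps.
#' @param success_prob Null success probability in `(0, 1)`.
#' @return The upper-tail probability `P(X >= c)`, in `(0, 1]`.
#' @export
#' @examples
#' score_concordance(4, 0)  # 0.5^4 = 0.0625
score_concordance <- function(c, contra, success_prob = 0.5) {
  if (c < 0 || contra < 0) stop("counts must be non-negative", call. = FALSE)
  if (success_prob <= 0 || success_prob >= 1)
    stop("success_prob must lie in (0, 1)", call. = FALSE)
  if (c == 0) return(1)
  stats::pbinom(c - 1, size = c + contra, prob = success_prob,
                lower.tail = FALSE)
}

#' Score one hypothesis in both directions
#'
#' Overlaps the signature's targets with the state changes and scores the
#' hypothesis "node activity increased" and "node activity decreased". For
#' the increase direction a target with implied sign `s` and observed change
#' direction `d` (+1 increased, -1 decreased) is consistent iff `s * d = +1`;
#' the decrease direction mirrors this, so sign-flipping every state change
#' swaps the two directions' scores exactly. Richness depends only on the
#' undirected overlap and is identical for both directions.
#'
#' @param sig One signature from [build_signatures()].
#' @param scs A [state_change_set()]; signature genes must be measured.
#' @param config An [rcr_config()].
#' @param N,K Population size and state-change count; default to the
#'   state-change set's population.
#' @return Data frame of two rows (directions `increase` and `decrease`) with
#'   columns `term`, `direction`, `N`, `K`, `n`, `k`, `c`, `contra`,
#'   `ambiguous`, `richness_p`, `concordance_p`, `significant`.
#' @export
evaluate_hypothesis <- function(sig, scs, config = rcr_config(),
                                N = length(scs$population),
                                K = nrow(scs$changes)) {
  stopifnot(inherits(scs, "state_change_set"))
  if (!all(names(sig$targets) %in% scs$population))
    stop("signature targets must be measured (in the SC population)",
         call. = FALSE)
  d <- sc_directions(scs)
  ov <- intersect(names(sig$targets), names(d))
  s <- sig$targets[ov]; dd <- d[ov]
  k <- length(ov)
  amb <- sum(s == 0L)
  c_inc <- sum(s * dd == 1L)
  contra_inc <- sum(s * dd == -1L)
  rich <- score_richness(N, K, length(sig$targets), k)
  p <- config$binomial_success_prob
  row <- function(direction, cc, ct) {
    conc <- score_concordance(cc, ct, p)
    data.frame(term = sig$term, direction = direction, N = N, K = K,
               n = length(sig$targets), k = k, c = cc, contra = ct,
               ambiguous = amb, richness_p = rich, concordance_p = conc,
               significant = rich < config$richness_cutoff &
                 conc < config$concordance_cutoff & cc >= config$min_correct,
               stringsAsFactors = FALSE)
  }
  rbind(row("increase", c_inc, contra_inc),
        row("decrease", contra_inc, c_inc))
}

#' Reverse causal reasoning
#'
#' The central fit: interrogates a causal network with an observed
#' state-change set, builds the downstream signature of every
#' prediction-capable node, and scores each node in both activity directions
#' by richness (hypergeometric) and concordance (binomial). A hypothesis is
#' significant when both p-values fall below their cutoffs and the
#' direction-consistent overlap reaches `min_correct`. No multiple-testing
#' correction is applied across hypotheses by default (significance is
#' statistical, not corrected); set `bh_correct = TRUE` to adjust both
#' p-value families by Benjamini-Hochberg before the cutoffs are applied.
#'
#' @param kam A [causal_network()].
#' @param scs A [state_change_set()].
#' @param config An [rcr_config()].
#' @param bh_correct Adjust hypothesis p-values by BH before thresholding
#'   (default `FALSE`).
#' @return An object of class `rcr`: the score table (`$scores`, one row per
#'   signature per direction, sorted ascending by concordance p, then
#'   richness p, then term) plus the configuration and run metadata. Use
#'   [significant_hypotheses()], [best_direction()], `summary()`, `plot()` and
#'   `as.data.frame()` to inspect it.
#' @export
#' @examples
#' net <- causal_network(data.frame(
#'   source = "taof(TF1)",
#'   target = c("r(G1)", "r(G2)", "r(G3)", "r(G4)"),
#'   sign = 1))
#' scs <- state_change_set("toy", paste0("G", 1:40),
#'   data.frame(gene = paste0("G", 1:4), direction = "increased"))
#' fit <- rcr(net, scs)
#' fit
rcr <- function(kam, scs, config = rcr_config(), bh_correct = FALSE) {
  stopifnot(inherits(kam, "causal_network"), inherits(scs, "state_change_set"))
  sigs <- build_signatures(kam, scs$population, config)
  if (config$population_mode == "all-network-downstream-measured") {
    e <- kam$edges
    e <- e[e$causal & term_function_of(e$target) == "rna-abundance", ,
           drop = FALSE]
    pop <- intersect(scs$population, term_entity_of(e$target))
  } else {
    pop <- scs$population
  }
  N <- length(pop)
  K <- sum(scs$changes$gene %in% pop)
  scs_pop <- state_change_set(scs$label, pop,
                              scs$changes[scs$changes$gene %in% pop, ,
                                          drop = FALSE])
  rows <- lapply(sigs, evaluate_hypothesis, scs = scs_pop, config = config,
                 N = N, K = K)
  scores <- if (length(rows)) do.call(rbind, rows) else
    evaluate_hypothesis(list(term = "x", targets = stats::setNames(
      integer(0), character(0))), scs_pop, config, N = max(N, 1), K = 0)[0, ]
  if (nrow(scores) && bh_correct) {
    scores$richness_p <- bh_adjust(scores$richness_p)
    scores$concordance_p <- bh_adjust(scores$concordance_p)
    scores$significant <- scores$richness_p < config$richness_cutoff &
      scores$concordance_p < config$concordance_cutoff &
      scores$c >= config$min_correct
  }
  scores <- scores[order(scores$concordance_p, scores$richness_p, scores$term,
                         scores$direction != "increase"), , drop = FALSE]
  rownames(scores) <- NULL
  structure(list(scores = scores, config = config,
                 n_signatures = length(sigs), N = N, K = K,
                 network_name = kam$name, sc_label = scs$label),
            class = "rcr")
}

#' Significant hypotheses of an RCR fit
#'
#' @param x An [rcr()] object.
#' @return The significant rows of the score table.
#' @export
significant_hypotheses <- function(x) {
  stopifnot(inherits(x, "rcr"))
  x$scores[x$scores$significant, , drop = FALSE]
}

#' Best-direction view of an RCR fit
#'
#' Keeps, per hypothesis term, the direction with the smaller concordance
#' p-value (ties broken toward increase, deterministically).
#'
#' @param x An [rcr()] object.
#' @return One row per term.
#' @export
best_direction <- function(x) {
  stopifnot(inherits(x, "rcr"))
  s <- x$scores
  s <- s[order(s$term, s$concordance_p, s$direction != "increase"), ,
         drop = FALSE]
  s <- s[!duplicated(s$term), , drop = FALSE]
  s <- s[order(s$concordance_p, s$richness_p, s$term), , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' @export
print.rcr <- function(x, n = 6L, ...) {
  cat("Reverse causal reasoning: '", x$sc_label, "' on network '",
      x$network_name, "'\n", sep = "")
  cat("  population N = ", x$N, ", state changes K = ", x$K,
      ", prediction-capable nodes = ", x$n_signatures, "\n", sep = "")
  sig <- significant_hypotheses(x)
  cat("  significant hypotheses: ", nrow(sig), "\n", sep = "")
  if (nrow(sig)) {
    cat("\nTop hypotheses:\n")
    print(utils::head(sig[, c("term", "direction", "n", "k", "c", "contra",
                              "richness_p", "concordance_p")], n),
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
summary.rcr <- function(object, ...) {
  sig <- significant_hypotheses(object)
  out <- list(sc_label = object$sc_label, network = object$network_name,
              N = object$N, K = object$K,
              n_signatures = object$n_signatures,
              n_scored = nrow(object$scores),
              n_significant = nrow(sig),
              n_significant_terms = length(unique(sig$term)),
              by_direction = table(sig$direction))
  class(out) <- "summary.rcr"
  out
}

#' @export
print.summary.rcr <- function(x, ...) {
  cat("RCR summary for '", x$sc_label, "' (network '", x$network, "')\n",
      "  N = ", x$N, ", K = ", x$K, ", signatures = ", x$n_signatures,
      ", scored rows = ", x$n_scored, "\n",
      "  significant: ", x$n_significant, " (", x$n_significant_terms,
      " distinct terms)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.rcr <- function(x, ...) x$scores

#' @export
plot.rcr <- function(x, ...) {
  s <- x$scores
  if (!nrow(s)) {
    graphics::plot.new(); graphics::title("no scored hypotheses")
    return(invisible(x))
  }
  rx <- -log10(pmax(s$richness_p, 1e-300))
  cy <- -log10(pmax(s$concordance_p, 1e-300))
  graphics::plot(rx, cy, pch = ifelse(s$significant, 19, 1),
                 col = ifelse(s$significant, "firebrick", "grey50"),
                 xlab = expression(-log[10] ~ "richness p"),
                 ylab = expression(-log[10] ~ "concordance p"),
                 main = paste("RCR:", x$sc_label), ...)
  graphics::abline(v = -log10(x$config$richness_cutoff),
                   h = -log10(x$config$concordance_cutoff),
                   lty = 2, col = "grey70")
  invisible(x)
}

#' Write / read a hypothesis score table as TSV
#'
#' @param x An [rcr()] object or its score data frame.
#' @param path Output path.
#' @return `path` (write) or a data frame (read).
#' @export
write_hypotheses <- function(x, path) {
  s <- if (inherits(x, "rcr")) x$scores else x
  utils::write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypotheses
#' @export
read_hypotheses <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
}
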