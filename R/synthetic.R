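# Synthetic experiments with planted active regulators: a bipartite
# regulator -> transcript causal network, a state-change realization with
# tunable direction agreement and background rate, and a two-group expression
# matrix realizing those changes, so the whole inference stack can be
# benchmarked without external data.

# deterministic sub-seed per simulation stage, derived from the single
# user-facing seed; kept below 2^31
stage_seed <- function(seed, stage) {
  as.integer((abs(as.numeric(seed)) * 131 + stage) %% 2147483629)
}

#' Specification of a synthetic RCR experiment
#'
#' The defaults are the package's reference benchmark conditions: 50
#' regulators over 2000 transcripts with mean out-degree 8, 5 active
#' regulators, perfect direction agreement (`concordance_prob = 1`), no
#' background state changes, 5 samples per group, a 2-unit log2 effect and
#' 0.1 log2 noise.
#'
#' @param n_regulators Number of regulator nodes.
#' @param n_genes Number of transcript nodes.
#' @param mean_degree Mean targets per regulator (out-degrees are Poisson
#'   with this mean, floored at 1).
#' @param positive_sign_prob Probability that a regulator -> transcript edge
#'   is positive.
#' @param n_active Number of active regulators when `active` is `NULL`.
#' @param active Optional explicit active set: data frame with columns
#'   `term` (regulator term string) and `direction` (`"increase"` /
#'   `"decrease"`). When `NULL`, the active set is drawn deterministically
#'   from regulators with at least 4 targets (alternating directions), the
#'   eligibility condition under which exact recovery is guaranteed.
#' @param concordance_prob q: probability a target of an active regulator
#'   becomes a state change in the implied direction.
#' @param background_sc_rate b: probability a non-target gene becomes a state
#'   change (uniform direction).
#' @param flip_prob Share of the non-concordant mass (1 - q) in which the
#'   target changes in the opposite direction instead of not changing.
#' @param samples_per_group Samples per group in the expression realization
#'   (>= 2).
#' @param effect_size Log2 shift applied to planted state-change genes.
#' @param noise_sd Log2-scale Gaussian noise standard deviation.
#' @param allow_shared_targets If `FALSE` (default) regulator target sets are
#'   sampled disjointly, which makes planted-regulator recovery exactly
#'   identifiable; `TRUE` samples each regulator's targets independently.
#' @param seed Single integer seed; all stages derive their streams from it.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_regulators = 50L, n_genes = 2000L,
                           mean_degree = 8, positive_sign_prob = 0.5,
                           n_active = 5L, active = NULL,
                           concordance_prob = 1, background_sc_rate = 0,
                           flip_prob = 0.5, samples_per_group = 5L,
                           effect_size = 2, noise_sd = 0.1,
                           allow_shared_targets = FALSE, seed = 1L) {
  stopifnot(n_regulators >= 1, n_genes >= 1, mean_degree > 0,
            positive_sign_prob >= 0, positive_sign_prob <= 1,
            concordance_prob >= 0, concordance_prob <= 1,
            background_sc_rate >= 0, background_sc_rate < 1,
            flip_prob >= 0, flip_prob <= 1,
            samples_per_group >= 2, noise_sd > 0)
  structure(list(n_regulators = as.integer(n_regulators),
                 n_genes = as.integer(n_genes), mean_degree = mean_degree,
                 positive_sign_prob = positive_sign_prob,
                 n_active = as.integer(n_active), active = active,
                 concordance_prob = concordance_prob,
                 background_sc_rate = background_sc_rate,
                 flip_prob = flip_prob,
                 samples_per_group = as.integer(samples_per_group),
                 effect_size = effect_size, noise_sd = noise_sd,
                 allow_shared_targets = isTRUE(allow_shared_targets),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

reg_term <- function(i) sprintf("taof(REG%03d)", i)
gene_name <- function(i) sprintf("G%05d", i)

#' Generate a synthetic regulator network
#'
#' Builds a bipartite causal graph from regulator activity terms to
#' transcript abundance terms. Out-degrees are Poisson(`mean_degree`) floored
#' at 1; edge signs are i.i.d. positive with probability
#' `positive_sign_prob`. By default target sets are disjoint across
#' regulators. Deterministic given the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A [causal_network()] whose nodes also include every transcript.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(stage_seed(spec$seed, 1L))
  deg <- pmax(1L, stats::rpois(spec$n_regulators, spec$mean_degree))
  if (max(deg) > spec$n_genes)
    stop("n_genes smaller than the largest out-degree", call. = FALSE)
  if (!spec$allow_shared_targets && sum(deg) > spec$n_genes)
    stop("disjoint target sampling needs n_genes >= total out-degree; ",
         "raise n_genes or set allow_shared_targets = TRUE", call. = FALSE)
  genes <- gene_name(seq_len(spec$n_genes))
  if (spec$allow_shared_targets) {
    tgt <- lapply(deg, function(d) sample(genes, d))
  } else {
    perm <- sample(genes)
    ends <- cumsum(deg)
    tgt <- lapply(seq_along(deg), function(i)
      perm[(ends[i] - deg[i] + 1):ends[i]])
  }
  edges <- data.frame(
    source = rep(reg_term(seq_len(spec$n_regulators)), deg),
    target = paste0("r(", unlist(tgt), ")"),
    sign = ifelse(stats::rbinom(sum(deg), 1, spec$positive_sign_prob) == 1,
                  1L, -1L),
    causal = TRUE, species = "unspecified", tissue = "synthetic",
    pmids = "", stringsAsFactors = FALSE)
  causal_network(edges,
                 nodes = data.frame(term = paste0("r(", genes, ")"),
                                    blocks = "", stringsAsFactors = FALSE),
                 name = sprintf("synthetic-%d", spec$seed))
}

# out-degree (measured rna targets) per regulator term
regulator_degrees <- function(net) {
  e <- net$edges[net$edges$causal &
                   term_function_of(net$edges$target) == "rna-abundance", ,
                 drop = FALSE]
  tab <- table(e$source)
  stats::setNames(as.integer(tab), names(tab))
}

resolve_active <- function(net, spec) {
  if (!is.null(spec$active)) {
    act <- as.data.frame(spec$active, stringsAsFactors = FALSE)
    stopifnot(all(c("term", "direction") %in% names(act)))
    act$term <- canonicalize_terms(act$term)
    if (!all(act$term %in% net$nodes$term))
      stop("active regulator not in network: ",
           paste(setdiff(act$term, net$nodes$term), collapse = ", "),
           call. = FALSE)
    return(act)
  }
  deg <- regulator_degrees(net)
  eligible <- names(deg)[deg >= 4L]
  eligible <- eligible[order(eligible)]
  if (length(eligible) < spec$n_active)
    stop("fewer than n_active regulators with >= 4 targets", call. = FALSE)
  terms <- eligible[seq_len(spec$n_active)]
  data.frame(term = terms,
             direction = rep(c("increase", "decrease"),
                             length.out = length(terms)),
             stringsAsFactors = FALSE)
}

#' Simulate state changes from planted active regulators
#'
#' Each measured target of an active regulator becomes a state change in its
#' implied direction (edge sign times activity direction) with probability
#' `q = concordance_prob`, in the opposite direction with probability
#' `(1 - q) * flip_prob`, and is otherwise unchanged. Genes implied in
#' conflicting directions by several active regulators change with
#' probability `q` in a uniformly random direction. Every non-target gene
#' becomes a state change with probability `background_sc_rate`, direction
#' uniform. The population is every transcript in the network.
#'
#' @param net A [causal_network()] from [generate_network()] (any network
#'   with transcript targets works).
#' @param spec A [synthetic_spec()].
#' @return List with `sc` (a [state_change_set()]) and `truth` (data frame
#'   `term`, `direction` of the active regulators).
#' @export
simulate_state_changes <- function(net, spec) {
  stopifnot(inherits(net, "causal_network"), inherits(spec, "synthetic_spec"))
  truth <- resolve_active(net, spec)
  set.seed(stage_seed(spec$seed, 2L))
  genes <- sort(term_entity_of(
    net$nodes$term[net$nodes$fun == "rna-abundance"]))

  e <- net$edges[net$edges$causal &
                   term_function_of(net$edges$target) == "rna-abundance", ,
                 drop = FALSE]
  e$gene <- term_entity_of(e$target)
  dir_of <- stats::setNames(ifelse(truth$direction == "increase", 1L, -1L),
                            truth$term)
  ea <- e[e$source %in% truth$term, , drop = FALSE]
  implied <- tapply(ea$sign * dir_of[ea$source], ea$gene, function(s) {
    u <- unique(s)
    if (length(u) == 1L) u else 0L
  })
  targets <- names(implied)

  sc_gene <- character(0); sc_dir <- integer(0)
  q <- spec$concordance_prob
  for (g in targets) {
    u <- stats::runif(1)
    s <- implied[[g]]
    if (s == 0L) {
      if (u < q) {
        sc_gene <- c(sc_gene, g)
        sc_dir <- c(sc_dir, sample(c(1L, -1L), 1))
      }
    } else if (u < q) {
      sc_gene <- c(sc_gene, g); sc_dir <- c(sc_dir, s)
    } else if (u < q + (1 - q) * spec$flip_prob) {
      sc_gene <- c(sc_gene, g); sc_dir <- c(sc_dir, -s)
    }
  }
  bg <- setdiff(genes, targets)
  if (length(bg) && spec$background_sc_rate > 0) {
    hit <- stats::runif(length(bg)) < spec$background_sc_rate
    if (any(hit)) {
      sc_gene <- c(sc_gene, bg[hit])
      sc_dir <- c(sc_dir, sample(c(1L, -1L), sum(hit), replace = TRUE))
    }
  }
  changes <- if (length(sc_gene))
    data.frame(gene = sc_gene,
               direction = ifelse(sc_dir == 1L, "increased", "decreased"),
               stringsAsFactors = FALSE) else NULL
  list(sc = state_change_set(sprintf("synthetic-%d", spec$seed), genes,
                             changes),
       truth = truth)
}

#' Realize planted state changes as a two-group expression matrix
#'
#' Control samples are gene-specific log2 baselines (uniform on 6..12) plus
#' Gaussian noise; treatment samples additionally shift planted state-change
#' genes by `effect_size` in the planted direction. One probe per gene; the
#' matrix is exported on the linear scale.
#'
#' @param sim Output of [simulate_state_changes()] (or any list with an `sc`
#'   element).
#' @param spec A [synthetic_spec()].
#' @return List with `expr` ([expression_matrix()]), `design`
#'   ([comparison_design()]) and `map` (probe-to-gene data frame).
#' @export
simulate_expression <- function(sim, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  scs <- sim$sc
  set.seed(stage_seed(spec$seed, 3L))
  genes <- scs$population
  ng <- length(genes); k <- spec$samples_per_group
  baseline <- stats::runif(ng, 6, 12)
  shift <- stats::setNames(numeric(ng), genes)
  if (nrow(scs$changes))
    shift[scs$changes$gene] <- ifelse(scs$changes$direction == "increased",
                                      1, -1) * spec$effect_size
  samples <- c(paste0("ctrl", seq_len(k)), paste0("trt", seq_len(k)))
  m <- matrix(stats::rnorm(ng * 2 * k, 0, spec$noise_sd), ng, 2 * k,
              dimnames = list(paste0("probe_", genes), samples))
  m <- m + baseline
  m[, (k + 1):(2 * k)] <- m[, (k + 1):(2 * k)] + shift
  list(expr = expression_matrix(2^m, log2 = FALSE),
       design = comparison_design(scs$label,
                                  treatment = paste0("trt", seq_len(k)),
                                  control = paste0("ctrl", seq_len(k))),
       map = data.frame(probe_id = paste0("probe_", genes), gene = genes,
                        stringsAsFactors = FALSE))
}

#' Generate a complete synthetic experiment
#'
#' Network, planted state changes, and expression realization in one call,
#' fully determined by the spec and its seed.
#'
#' @param spec A [synthetic_spec()].
#' @return Object of class `synthetic_experiment` with elements `network`,
#'   `truth`, `planted_sc`, `expr`, `design`, `map`, `spec`.
#' @export
simulate_rcr_experiment <- function(spec = synthetic_spec()) {
  net <- generate_network(spec)
  sim <- simulate_state_changes(net, spec)
  ex <- simulate_expression(sim, spec)
  structure(list(network = net, truth = sim$truth, planted_sc = sim$sc,
                 expr = ex$expr, design = ex$design, map = ex$map,
                 spec = spec),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("<synthetic_experiment> seed ", x$spec$seed, ": ",
      x$spec$n_regulators, " regulators, ", x$spec$n_genes, " genes, ",
      nrow(x$truth), " active, ", nrow(x$planted_sc$changes),
      " planted state changes\n", sep = "")
  invisible(x)
}

#' Recovery metrics against the planted truth
#'
#' Compares the significant hypotheses of an RCR fit (best direction per
#' term) with the planted active regulators. Precision is the fraction of
#' significant terms that are truly active, recall the fraction of active
#' regulators found significant, and direction accuracy the fraction of true
#' positives called in the planted direction. With no significant hypotheses
#' at all, precision is reported as 1 by convention (no false claims were
#' made) with `no_calls = TRUE`.
#'
#' @param fit An [rcr()] object (or a score data frame with `term`,
#'   `direction`, `significant`, `concordance_p` columns).
#' @param truth Data frame with columns `term` and `direction`.
#' @return List with `precision`, `recall`, `direction_accuracy`,
#'   `n_significant`, `no_calls`.
#' @export
recovery_metrics <- function(fit, truth) {
  s <- if (inherits(fit, "rcr")) best_direction(fit) else {
    s0 <- fit[order(fit$term, fit$concordance_p,
                    fit$direction != "increase"), , drop = FALSE]
    s0[!duplicated(s0$term), , drop = FALSE]
  }
  s <- s[s$significant, , drop = FALSE]
  truth <- as.data.frame(truth, stringsAsFactors = FALSE)
  tp <- intersect(s$term, truth$term)
  no_calls <- nrow(s) == 0L
  precision <- if (no_calls) 1 else length(tp) / nrow(s)
  recall <- if (nrow(truth)) length(tp) / nrow(truth) else 1
  dir_acc <- if (length(tp)) {
    pred <- stats::setNames(s$direction, s$term)[tp]
    want <- stats::setNames(truth$direction, truth$term)[tp]
    mean(pred == want)
  } else NA_real_
  list(precision = precision, recall = recall,
       direction_accuracy = dir_acc, n_significant = nrow(s),
       no_calls = no_calls)
}

#' Synthetic stand-in for the published cellular-stress network summary
#'
#' Deterministically constructs a synthetic network whose summary statistics
#' equal the published totals of the cellular stress network model this
#' package's data model is patterned on: 730 nodes (84 mRNAs, 235 proteins,
#' 43 phosphoproteins, 180 activities, 57 complexes, 18 protein families, 48
#' biological processes, 65 chemicals), 1280 edges of which 778 are causal
#' (545 human-, 175 mouse-, 58 rat-derived), 428 unique PMIDs across the
#' causal evidence, and roughly two thirds of causal edges in lung or
#' cardiovascular tissue contexts. The original supplementary network file
#' is not redistributed here; this object is synthetic — its wiring is
#' arbitrary and only its summary statistics are meaningful. It exercises
#' the parser, exporters and statistics at realistic scale.
#'
#' @return A [causal_network()].
#' @export
synthetic_stress_network <- function() {
  counts <- c("rna-abundance" = 84, "protein-abundance" = 235,
              "phosphoprotein" = 43, "transcriptional-activity" = 100,
              "kinase-activity" = 50, "gtp-bound-activity" = 30,
              "complex" = 57, "protein-family" = 18,
              "biological-process" = 48, "chemical" = 65)  # activities: 180
  tags <- .FUNCTION_TO_TAG[rep(names(counts), counts)]
  terms <- paste0(tags, "(N", sprintf("%03d", seq_len(sum(counts))), ")")
  n <- length(terms)  # 730

  # distinct ordered pairs: a full ring plus a stride-2 partial ring
  s1 <- seq_len(n); t1 <- s1 %% n + 1L
  s2 <- seq_len(1280L - n); t2 <- (s2 + 1L) %% n + 1L
  src <- terms[c(s1, s2)]; tgt <- terms[c(t1, t2)]

  n_causal <- 778L
  causal <- seq_along(src) <= n_causal
  species <- rep("unspecified", length(src))
  species[seq_len(545)] <- "human"
  species[546:720] <- "mouse"
  species[721:778] <- "rat"
  tissue <- rep("", length(src))
  lung_cv <- rep(c("lung epithelium", "coronary artery endothelium"),
                 length.out = 519)
  tissue[seq_len(519)] <- lung_cv
  tissue[520:778] <- rep(c("liver", "kidney", "macrophage"),
                         length.out = 778 - 519)
  pmids <- rep("", length(src))
  pmids[seq_len(n_causal)] <-
    as.character(10000000 + (seq_len(n_causal) - 1) %% 428)
  sign <- rep(1L, length(src))
  sign[seq_len(n_causal)] <- rep(c(1L, -1L), length.out = n_causal)

  blocks <- rep(c("oxidative", "ER", "hypoxic", "osmotic", "xenobiotic",
                  "shear"), length.out = n)
  causal_network(
    data.frame(source = src, target = tgt, sign = sign, causal = causal,
               species = species, tissue = tissue, pmids = pmids,
               stringsAsFactors = FALSE),
    nodes = data.frame(term = terms, blocks = blocks, stringsAsFactors = FALSE),
    name = "synthetic-cellular-stress-network")
}
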