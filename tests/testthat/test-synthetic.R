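test_that("network generation is deterministic and respects the spec", {
  spec <- synthetic_spec(n_regulators = 1, n_genes = 50, mean_degree = 5,
                         seed = 4)
  net <- generate_network(spec)
  st <- network_statistics(net)
  # transcripts are declared nodes even when untargeted
  expect_equal(st$n_nodes, 51)
  expect_true(all(net$edges$causal))
  expect_equal(nrow(net$edges),
               unname(regulator_degree <- sum(net$edges$source == "taof(REG001)")))

  expect_true(network_equal(net, generate_network(spec)))
  expect_false(network_equal(net, generate_network(
    synthetic_spec(n_regulators = 1, n_genes = 50, mean_degree = 5,
                   seed = 5))))

  # all-positive signs under positive_sign_prob = 1
  allpos <- generate_network(synthetic_spec(n_regulators = 5, n_genes = 100,
                                            positive_sign_prob = 1, seed = 1))
  expect_true(all(allpos$edges$sign == 1L))

  # disjoint target sets by default
  spec2 <- synthetic_spec(seed = 9)
  net2 <- generate_network(spec2)
  expect_false(anyDuplicated(net2$edges$target) > 0)

  expect_error(generate_network(synthetic_spec(n_regulators = 10,
                                               n_genes = 5, seed = 1)),
               "n_genes")
})

test_that("state-change simulation follows the planted-regulator model", {
  spec <- synthetic_spec(seed = 2)
  net <- generate_network(spec)
  sim <- simulate_state_changes(net, spec)  # q = 1, b = 0
  expect_equal(length(sim$sc$population), 2000)

  # q=1, b=0: the SC set is exactly the active targets with implied signs
  e <- net$edges
  truth_dir <- setNames(ifelse(sim$truth$direction == "increase", 1L, -1L),
                        sim$truth$term)
  ea <- e[e$source %in% sim$truth$term, ]
  want <- setNames(ea$sign * truth_dir[ea$source],
                   sub("\\)$", "", sub("^r\\(", "", ea$target)))
  got <- setNames(ifelse(sim$sc$changes$direction == "increased", 1L, -1L),
                  sim$sc$changes$gene)
  expect_setequal(names(got), names(want))
  expect_equal(got[sort(names(got))], want[sort(names(want))])

  # q=0 with no flip noise: exactly empty
  spec0 <- synthetic_spec(concordance_prob = 0, flip_prob = 0, seed = 2)
  sim0 <- simulate_state_changes(generate_network(spec0), spec0)
  expect_equal(nrow(sim0$sc$changes), 0)

  # determinism
  sim2 <- simulate_state_changes(net, spec)
  expect_equal(sim$sc$changes, sim2$sc$changes)
})

test_that("planted SC counts track binomial expectations across seeds", {
  hits <- vapply(1:20, function(s) {
    spec <- synthetic_spec(n_regulators = 10, n_genes = 1000, mean_degree = 8,
                           n_active = 3, concordance_prob = 0.8,
                           flip_prob = 0.5, background_sc_rate = 0.01,
                           seed = s)
    net <- generate_network(spec)
    sim <- simulate_state_changes(net, spec)
    n_t <- sum(net$edges$source %in% sim$truth$term)
    # targets change w.p. q + (1-q)*flip = 0.9; background w.p. 0.01
    c(obs = nrow(sim$sc$changes), exp = 0.9 * n_t + 0.01 * (1000 - n_t),
      var = n_t * 0.9 * 0.1 + (1000 - n_t) * 0.01 * 0.99)
  }, numeric(3))
  # each seed within 4 sd, and the mean deviation small
  z <- (hits["obs", ] - hits["exp", ]) / sqrt(hits["var", ])
  expect_true(all(abs(z) < 4))
  expect_lt(abs(mean(z)), 1)
})

test_that("expression realization encodes the planted changes", {
  spec <- synthetic_spec(n_regulators = 5, n_genes = 200, n_active = 2,
                         seed = 6)
  ex <- simulate_rcr_experiment(spec)
  expect_equal(dim(ex$expr), c(200, 10))
  expect_false(isTRUE(attr(ex$expr, "log2")))
  expect_true(all(ex$expr > 0))

  # determinism
  ex2 <- simulate_rcr_experiment(spec)
  expect_equal(unclass(ex$expr), unclass(ex2$expr))

  # with a zero effect the pipeline recovers ~no SCs at standard thresholds
  spec_null <- synthetic_spec(n_regulators = 5, n_genes = 200, n_active = 2,
                              effect_size = 0, seed = 6)
  exn <- simulate_rcr_experiment(spec_null)
  scs <- state_changes(exn$expr, exn$design, exn$map)
  expect_lte(nrow(scs$changes), 2)
})

test_that("the state-change pipeline recovers planted changes", {
  spec <- synthetic_spec(n_regulators = 20, n_genes = 500, n_active = 3,
                         effect_size = 2, noise_sd = 0.1,
                         samples_per_group = 5, seed = 8)
  ex <- simulate_rcr_experiment(spec)
  scs <- state_changes(ex$expr, ex$design, ex$map)
  planted <- ex$planted_sc$changes
  hit <- merge(planted, scs$changes, by = "gene")
  recovered <- sum(hit$direction.x == hit$direction.y) / nrow(planted)
  # quantile normalization compresses effects at the extremes of the
  # intensity range, so at this small scale a planted gene sitting at the
  # distribution floor can occasionally be shrunk below the fold-change
  # cutoff; recovery stays high
  expect_gte(recovered, 0.9)
})

test_that("rcr recovers planted regulators exactly under ideal conditions", {
  for (s in c(3, 14)) {
    spec <- synthetic_spec(seed = s)  # q = 1, b = 0 defaults
    net <- generate_network(spec)
    sim <- simulate_state_changes(net, spec)
    fit <- rcr(net, sim$sc)
    m <- recovery_metrics(fit, sim$truth)
    expect_equal(m$precision, 1)
    expect_equal(m$recall, 1)
    expect_equal(m$direction_accuracy, 1)
  }
})

test_that("inactive regulators with no shared targets are never significant", {
  spec <- synthetic_spec(seed = 5)  # disjoint targets, b = 0
  net <- generate_network(spec)
  sim <- simulate_state_changes(net, spec)
  fit <- rcr(net, sim$sc)
  inactive <- setdiff(unique(fit$scores$term), sim$truth$term)
  rows <- fit$scores[fit$scores$term %in% inactive, ]
  expect_true(all(rows$k == 0))
  expect_true(all(rows$richness_p == 1))
  expect_false(any(rows$significant))
})

test_that("recovery metrics follow the stated conventions", {
  mk_fit <- function(term, direction, significant) {
    data.frame(term = term, direction = direction,
               significant = significant, concordance_p = 0.01,
               stringsAsFactors = FALSE)
  }
  truth <- data.frame(term = c("taof(A)", "taof(B)"),
                      direction = c("increase", "decrease"))
  # perfect recovery
  m <- recovery_metrics(mk_fit(c("taof(A)", "taof(B)"),
                               c("increase", "decrease"), TRUE), truth)
  expect_equal(unlist(m[1:3]), c(precision = 1, recall = 1,
                                 direction_accuracy = 1))
  # no calls at all: recall 0, precision 1 by convention, flagged
  m0 <- recovery_metrics(mk_fit("taof(A)", "increase", FALSE), truth)
  expect_equal(m0$recall, 0)
  expect_equal(m0$precision, 1)
  expect_true(m0$no_calls)
  # one of two found plus one false positive
  m1 <- recovery_metrics(mk_fit(c("taof(A)", "taof(Z)"),
                               c("increase", "increase"), TRUE), truth)
  expect_equal(m1$precision, 0.5)
  expect_equal(m1$recall, 0.5)
  expect_equal(m1$direction_accuracy, 1)
})

test_that("the synthetic stress fixture reproduces the reference totals", {
  net <- synthetic_stress_network()
  st <- network_statistics(net)
  expect_equal(st$n_nodes, 730)
  expect_equal(st$n_edges, 1280)
  expect_equal(st$n_causal, 778)
  expect_equal(st$n_unique_pmids, 428)
  expect_equal(unname(st$causal_by_species[c("human", "mouse", "rat")]),
               c(545L, 175L, 58L))
  by_fun <- st$nodes_by_function
  expect_equal(unname(by_fun["rna-abundance"]), 84L)
  expect_equal(unname(by_fun["protein-abundance"]), 235L)
  expect_equal(unname(by_fun["phosphoprotein"]), 43L)
  expect_equal(unname(sum(by_fun[c("transcriptional-activity",
                                   "kinase-activity",
                                   "gtp-bound-activity")])), 180L)
  expect_equal(unname(by_fun["complex"]), 57L)
  expect_equal(unname(by_fun["protein-family"]), 18L)
  expect_equal(unname(by_fun["biological-process"]), 48L)
  expect_equal(unname(by_fun["chemical"]), 65L)
})
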