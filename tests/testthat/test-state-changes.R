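make_matrix <- function(values, log2 = FALSE, probes = NULL, samples = NULL) {
  if (is.null(probes)) probes <- paste0("p", seq_len(nrow(values)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
  dimnames(values) <- list(probes, samples)
  expression_matrix(values, log2 = log2)
}

test_that("quantile normalization equals the sorted-column-means oracle", {
  m <- make_matrix(matrix(c(1, 5, 3, 7), 2))
  qn <- quantile_normalize(m)
  # sorted columns are (1,5) and (3,7); row means of sorted = (2,6)
  expect_equal(unname(sort(qn[, 1])), c(2, 6))
  expect_equal(unname(sort(qn[, 2])), c(2, 6))

  # columns that are permutations of each other are unchanged up to row order
  set.seed(42)
  v <- rnorm(20)
  m2 <- make_matrix(cbind(v, sample(v), sample(v)), log2 = TRUE)
  qn2 <- quantile_normalize(m2)
  for (j in 1:3) expect_equal(sort(qn2[, j]), sort(m2[, j]),
                              ignore_attr = TRUE)

  # idempotence
  m3 <- make_matrix(matrix(runif(60, 1, 100), 10))
  expect_equal(unclass(quantile_normalize(quantile_normalize(m3))),
               unclass(quantile_normalize(m3)), tolerance = 1e-12)
})

test_that("differential test matches a pooled-variance t-test oracle", {
  set.seed(7)
  vals <- matrix(2^rnorm(5 * 6, 8, 1), 5, 6)
  m <- make_matrix(vals)
  des <- comparison_design("t vs c", paste0("s", 1:3), paste0("s", 4:6))
  res <- differential_test(m, des)
  lg <- log2(vals)
  for (i in 1:5) {
    tt <- t.test(lg[i, 1:3], lg[i, 4:6], var.equal = TRUE)
    expect_equal(res$raw_p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(res$log2_fc[i], mean(lg[i, 1:3]) - mean(lg[i, 4:6]),
                 tolerance = 1e-12)
  }
  expect_equal(res$mean_intensity, rowMeans(vals), ignore_attr = TRUE)
})

test_that("differential test handles degenerate inputs sensibly", {
  # identical group means with nonzero variance: fc 0, p near 1
  v <- matrix(c(1, 3, 2, 4, 2, 4, 1, 3), 2, 4) * 100
  m <- make_matrix(v)
  des <- comparison_design("x", c("s1", "s2"), c("s3", "s4"))
  res <- differential_test(m, des)
  expect_equal(res$log2_fc, c(0, 0))
  expect_true(all(res$raw_p > 0.99))

  # exact doubling with tiny noise: log2 fc ~ 1
  set.seed(1)
  base <- 2^(8 + matrix(rnorm(8, 0, 0.01), 2, 4))
  m2 <- make_matrix(cbind(base * 2, base))
  des2 <- comparison_design("x", paste0("s", 1:4), paste0("s", 5:8))
  expect_equal(differential_test(m2, des2)$log2_fc, c(1, 1), tolerance = 0.05)

  # zero variance everywhere is an error asking for replicates
  m3 <- make_matrix(matrix(5, 3, 4))
  expect_error(differential_test(m3, des),
               "zero within-group variance.*replicates")
})

test_that("BH adjustment obeys the step-up formula", {
  expect_equal(bh_adjust(0.03), 0.03)
  # step-up oracle: min over j >= i of m * p(j) / j
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_adjust(p), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(3)
  pr <- runif(50)
  m <- length(pr)
  o <- order(pr)
  oracle <- numeric(m)
  oracle[o] <- rev(cummin(rev(m * pr[o] / seq_len(m))))
  expect_equal(bh_adjust(pr), pmin(oracle, 1))
  expect_true(all(bh_adjust(pr) >= pr))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

toy_results <- function() {
  data.frame(probe_id = c("a1", "a2", "b1", "b2", "c1", "d1"),
             log2_fc = c(log2(1.5), 0.1, log2(1.5), -log2(1.5),
                         -log2(2), 1),
             mean_intensity = c(300, 300, 300, 300, 100, 300),
             adjusted_p = c(0.04, 0.5, 0.01, 0.02, 0.001, 0.001),
             raw_p = NA_real_, stringsAsFactors = FALSE)
}

toy_map <- function() {
  data.frame(probe_id = c("a1", "a2", "b1", "b2", "c1", "d1", "e9"),
             gene = c("A", "A", "B", "B", "C", "D", "E"),
             stringsAsFactors = FALSE)
}

test_that("state-change calling applies the filter chain and gene rules", {
  scs <- call_state_changes(toy_results(), toy_map())
  # A: one passing up probe + one non-significant -> increased (at-least-one)
  expect_equal(scs$changes$direction[scs$changes$gene == "A"], "increased")
  # B: passing probes in both directions -> dropped, logged as conflicting
  expect_false("B" %in% scs$changes$gene)
  expect_equal(attr(scs, "conflicting"), "B")
  # C: passes without the intensity filter
  expect_equal(scs$changes$direction[scs$changes$gene == "C"], "decreased")
  # D: fold change exactly 2 passes the 1.3 default but is excluded at a
  # cutoff of exactly 2 (strict inequality on "greater than")
  expect_true("D" %in% scs$changes$gene)
  at_boundary <- call_state_changes(toy_results(), toy_map(), fc = 2)
  expect_false("D" %in% at_boundary$changes$gene)
  # population: every mapped measured gene, independent of thresholds
  expect_setequal(scs$population, c("A", "B", "C", "D"))
  strict <- call_state_changes(toy_results(), toy_map(), adj_p = 1e-6)
  expect_setequal(strict$population, scs$population)

  # intensity filter drops the low-abundance probe when enabled
  filt <- call_state_changes(toy_results(), toy_map(), min_intensity = 250)
  expect_false("C" %in% filt$changes$gene)
  expect_true("A" %in% filt$changes$gene)

  # fold change reported on linear scale as max(ratio, 1/ratio)
  expect_equal(scs$changes$fold_change[scs$changes$gene == "C"], 2)
})

test_that("raising any threshold never increases the state-change count", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 40
    vals <- matrix(2^rnorm(n * 6, 8, 1), n, 6)
    m <- make_matrix(vals)
    des <- comparison_design("x", paste0("s", 1:3), paste0("s", 4:6))
    map <- data.frame(probe_id = paste0("p", 1:n),
                      gene = paste0("g", rep(1:(n / 2), each = 2)))
    res <- differential_test(m, des)
    res$adjusted_p <- bh_adjust(res$raw_p)
    base <- nrow(call_state_changes(res, map, adj_p = 0.5, fc = 1.1)$changes)
    tighter_p <- nrow(call_state_changes(res, map, adj_p = 0.2,
                                         fc = 1.1)$changes)
    tighter_fc <- nrow(call_state_changes(res, map, adj_p = 0.5,
                                          fc = 1.6)$changes)
    with_int <- nrow(call_state_changes(res, map, adj_p = 0.5, fc = 1.1,
                                        min_intensity = 2^8)$changes)
    expect_lte(tighter_p, base)
    expect_lte(tighter_fc, base)
    expect_lte(with_int, base)
  }
})

test_that("tabular readers and writers round-trip", {
  d <- tempfile(); dir.create(d)
  ef <- file.path(d, "expr.tsv"); df <- file.path(d, "design.tsv")
  mf <- file.path(d, "map.tsv"); sf <- file.path(d, "sc.tsv")
  pf <- file.path(d, "pop.txt")

  vals <- matrix(c(10, 20, 30, 40, 50, 60), 2, 3,
                 dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
  write.table(data.frame(probe = rownames(vals), vals, check.names = FALSE),
              ef, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(unclass(read_expression_tsv(ef)), vals, ignore_attr = TRUE)

  writeLines(c("sample_id\tgroup", "s1\tCS", "s2\tCS", "s3\tsham",
               "s4\tsham"), df)
  des <- read_design_tsv(df, "CS", "sham")
  expect_equal(des$treatment, c("s1", "s2"))
  expect_equal(des$control, c("s3", "s4"))

  writeLines(c("probe_id\tgene_symbol", "p1\tA", "p2\tB"), mf)
  mp <- read_probe_map_tsv(mf)
  expect_equal(mp$gene_symbol, c("A", "B"))

  scs <- toy_scs(c("G1", "G2"), c(1, -1))
  write_state_changes(scs, sf, pf)
  back <- read_state_changes(sf, pf, label = "toy-cmp")
  expect_equal(back$changes$gene, scs$changes$gene)
  expect_equal(back$changes$direction, scs$changes$direction)
  expect_setequal(back$population, scs$population)
})
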