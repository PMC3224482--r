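# Two-group expression comparison -> directional State Changes.
# Filter chain: quantile normalization, per-probe pooled-variance test,
# Benjamini-Hochberg adjustment, then adjusted p / fold-change / (optional)
# intensity thresholds, collapsed to gene level by the at-least-one-probe rule.

#' Construct an expression matrix
#'
#' A probes-by-samples intensity matrix with an explicit scale flag. Linear
#' scale values must be finite and non-negative; probe and sample identifiers
#' must be unique.
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param log2 Logical; `TRUE` if `values` are already log2-transformed.
#' @return The matrix with attribute `log2` and class `expr_matrix`.
#' @export
expression_matrix <- function(values, log2 = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs probe rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("duplicate probe or sample ids", call. = FALSE)
  if (!all(is.finite(values)))
    stop("expression values must be finite", call. = FALSE)
  if (!log2 && any(values < 0))
    stop("linear-scale expression values must be non-negative", call. = FALSE)
  structure(values, log2 = isTRUE(log2), class = c("expr_matrix", "matrix"))
}

is_log2 <- function(x) isTRUE(attr(x, "log2"))

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto a common distribution: after
#' normalization each column's sorted values equal the row-wise means of the
#' column-sorted input, with ties resolved by averaging.
#'
#' @param matrix An [expression_matrix()] (or plain numeric matrix).
#' @return Normalized matrix of the same shape and scale flag.
#' @export
#' @examples
#' m <- expression_matrix(matrix(c(1, 5, 3, 7), 2,
#'   dimnames = list(c("p1", "p2"), c("s1", "s2"))))
#' quantile_normalize(m)  # both columns become (2, 6)
quantile_normalize <- function(matrix) {
  if (!all(is.finite(matrix))) stop("non-finite expression values", call. = FALSE)
  out <- limma::normalizeQuantiles(unclass(matrix), ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  structure(out, log2 = is_log2(matrix), class = c("expr_matrix", "matrix"))
}

#' Define a two-group comparison
#'
#' @param label Comparison label (e.g. `"WT 1d CS vs sham"`).
#' @param treatment,control Disjoint sample-id sets, each of size >= 2.
#' @return Object of class `comparison_design`.
#' @export
comparison_design <- function(label, treatment, control) {
  treatment <- as.character(treatment); control <- as.character(control)
  if (length(treatment) < 2L || length(control) < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  if (length(intersect(treatment, control)))
    stop("treatment and control sample sets must be disjoint", call. = FALSE)
  structure(list(label = label, treatment = treatment, control = control),
            class = "comparison_design")
}

# log2 view of a matrix; zeros in linear input are offset by +1 so the
# transform is defined (documented convention for count-like zero intensities)
as_log2 <- function(matrix) {
  if (is_log2(matrix)) return(unclass(matrix))
  v <- unclass(matrix)
  if (any(v == 0)) v <- v + 1
  log2(v)
}

#' Per-probe two-group differential test
#'
#' For each probe computes the log2 fold change (mean log2 treatment minus
#' mean log2 control), the average linear-scale intensity over the samples of
#' the two groups, and a raw p-value from an equal-variance two-sample t
#' statistic. Probes with zero pooled variance get p = 1 when the group means
#' agree and p = 0 otherwise; if every probe has zero within-group variance
#' the input carries no replication noise and an error asks for replicates or
#' jitter.
#'
#' @param matrix An [expression_matrix()]; log2-transformed internally when
#'   flagged linear.
#' @param design A [comparison_design()] whose sample ids are all columns of
#'   `matrix`.
#' @return Data frame with columns `probe_id`, `log2_fc`, `mean_intensity`,
#'   `raw_p`.
#' @export
differential_test <- function(matrix, design) {
  stopifnot(inherits(design, "comparison_design"))
  ids <- c(design$treatment, design$control)
  if (!all(ids %in% colnames(matrix)))
    stop("design sample ids missing from matrix: ",
         paste(setdiff(ids, colnames(matrix)), collapse = ", "), call. = FALSE)
  lg <- as_log2(matrix)
  xt <- lg[, design$treatment, drop = FALSE]
  xc <- lg[, design$control, drop = FALSE]
  n1 <- ncol(xt); n0 <- ncol(xc)
  m1 <- rowMeans(xt); m0 <- rowMeans(xc)
  ss1 <- rowSums((xt - m1)^2); ss0 <- rowSums((xc - m0)^2)
  sp2 <- (ss1 + ss0) / (n1 + n0 - 2)
  if (all(sp2 == 0))
    stop("zero within-group variance for every probe; ",
         "add replicates or jitter the data", call. = FALSE)
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  lfc <- m1 - m0
  tt <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  p <- 2 * stats::pt(-abs(tt), df = n1 + n0 - 2)
  lin <- if (is_log2(matrix)) 2^lg else unclass(matrix)
  data.frame(probe_id = rownames(matrix),
             log2_fc = unname(lfc),
             mean_intensity = unname(rowMeans(lin[, ids, drop = FALSE])),
             raw_p = unname(p),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment of raw p-values.
#'
#' @param raw_p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, each in `[0, 1]` and elementwise no smaller than
#'   the input.
#' @export
bh_adjust <- function(raw_p) {
  if (any(!is.finite(raw_p)) || any(raw_p < 0 | raw_p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(raw_p, method = "BH")
}

#' Construct a state-change set
#'
#' The directional significant gene expression changes of one comparison plus
#' the measured-gene population. At most one change per gene; change genes are
#' a subset of the population.
#'
#' @param label Comparison label.
#' @param population Character vector of measured gene symbols.
#' @param changes Data frame with columns `gene`, `direction` (`"increased"`
#'   or `"decreased"`), `fold_change` (linear ratio >= 1, may be `NA` for
#'   simulated sets) and `adjusted_p` (may be `NA`).
#' @return Object of class `state_change_set`.
#' @export
state_change_set <- function(label, population, changes = NULL) {
  population <- unique(as.character(population))
  if (is.null(changes) || nrow(changes) == 0L) {
    changes <- data.frame(gene = character(0), direction = character(0),
                          fold_change = numeric(0), adjusted_p = numeric(0),
                          stringsAsFactors = FALSE)
  } else {
    changes <- as.data.frame(changes, stringsAsFactors = FALSE)
    if (is.null(changes$fold_change)) changes$fold_change <- NA_real_
    if (is.null(changes$adjusted_p)) changes$adjusted_p <- NA_real_
    if (anyDuplicated(changes$gene))
      stop("at most one state change per gene", call. = FALSE)
    if (!all(changes$direction %in% c("increased", "decreased")))
      stop("direction must be 'increased' or 'decreased'", call. = FALSE)
    if (!all(changes$gene %in% population))
      stop("state-change genes must belong to the measured population",
           call. = FALSE)
    changes <- changes[order(changes$gene),
                       c("gene", "direction", "fold_change", "adjusted_p")]
    rownames(changes) <- NULL
  }
  structure(list(label = label, population = population, changes = changes),
            class = "state_change_set")
}

#' @export
print.state_change_set <- function(x, ...) {
  cat("<state_change_set> ", x$label, ": ", nrow(x$changes),
      " state changes over ", length(x$population), " measured genes\n",
      sep = "")
  up <- sum(x$changes$direction == "increased")
  cat("  increased: ", up, "   decreased: ", nrow(x$changes) - up, "\n",
      sep = "")
  invisible(x)
}

# named +1/-1 vector of SC directions
sc_directions <- function(scs) {
  stats::setNames(ifelse(scs$changes$direction == "increased", 1L, -1L),
                  scs$changes$gene)
}

#' Call state changes from per-probe results
#'
#' Applies the significance filter chain at probe level — adjusted p below the
#' cutoff, linear absolute fold change strictly greater than the cutoff, and
#' (when enabled) mean intensity above the abundance floor — then collapses to
#' genes: a gene changed if at least one of its probes passed, taking the
#' direction of its passing probes. Genes whose probes pass in both directions
#' carry no defensible direction and are dropped from the change list (they
#' stay in the population; see the `conflicting` attribute of the result).
#' Probes without a gene mapping are dropped; the population is every mapped
#' gene with at least one measured probe, independent of the thresholds.
#'
#' @param results Data frame from [differential_test()], plus a column
#'   `adjusted_p` (see [bh_adjust()]); if absent it is computed from `raw_p`.
#' @param map Data frame with columns `probe_id`, `gene` (many probes per gene
#'   allowed).
#' @param label Comparison label for the returned set.
#' @param adj_p Adjusted-p cutoff (strict `<`), default 0.05.
#' @param fc Linear fold-change cutoff (strict `>`), default 1.3.
#' @param min_intensity Abundance floor (strict `>`) on mean linear intensity,
#'   or `NULL` (default) to disable; the documented conventional floor is 250.
#' @return A [state_change_set()]; per-gene fold change and adjusted p are
#'   taken from the gene's best passing probe (smallest adjusted p, ties by
#'   larger fold change, then probe id).
#' @export
call_state_changes <- function(results, map, label = "comparison",
                               adj_p = 0.05, fc = 1.3, min_intensity = NULL) {
  stopifnot(adj_p > 0, fc > 1)
  if (is.null(results$adjusted_p)) results$adjusted_p <- bh_adjust(results$raw_p)
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (is.null(map$gene) && !is.null(map$gene_symbol)) map$gene <- map$gene_symbol
  map <- map[nzchar(map$probe_id) & !is.na(map$gene) & nzchar(map$gene), ]
  r <- merge(results, map[, c("probe_id", "gene")], by = "probe_id")
  population <- sort(unique(r$gene))

  lin_fc <- 2^abs(r$log2_fc)
  pass <- r$adjusted_p < adj_p & lin_fc > fc
  if (!is.null(min_intensity)) pass <- pass & r$mean_intensity > min_intensity
  pr <- r[pass, , drop = FALSE]

  changes <- NULL; conflicting <- character(0)
  if (nrow(pr)) {
    pr$direction <- ifelse(pr$log2_fc > 0, "increased", "decreased")
    dirs <- tapply(pr$direction, pr$gene, function(d) length(unique(d)))
    conflicting <- names(dirs)[dirs > 1]
    pr <- pr[!pr$gene %in% conflicting, , drop = FALSE]
    if (nrow(pr)) {
      pr <- pr[order(pr$gene, pr$adjusted_p, -abs(pr$log2_fc), pr$probe_id), ]
      best <- pr[!duplicated(pr$gene), , drop = FALSE]
      changes <- data.frame(gene = best$gene, direction = best$direction,
                            fold_change = 2^abs(best$log2_fc),
                            adjusted_p = best$adjusted_p,
                            stringsAsFactors = FALSE)
    }
  }
  out <- state_change_set(label, population, changes)
  attr(out, "conflicting") <- conflicting
  out
}

#' Run the full state-change pipeline
#'
#' Quantile normalization, per-probe two-group test, Benjamini-Hochberg
#' adjustment, and gene-level state-change calling in one step. The defaults
#' are the conventional microarray thresholds: adjusted p < 0.05, linear
#' |fold change| > 1.3, abundance filter disabled (set `min_intensity = 250`
#' to enable the conventional floor).
#'
#' @param matrix An [expression_matrix()].
#' @param design A [comparison_design()].
#' @param map Probe-to-gene map (columns `probe_id`, `gene`).
#' @param adj_p,fc,min_intensity Thresholds; see [call_state_changes()].
#' @param quantile Apply quantile normalization first (default `TRUE`).
#' @return A [state_change_set()] with the per-probe result table in attribute
#'   `probe_results`.
#' @export
state_changes <- function(matrix, design, map, adj_p = 0.05, fc = 1.3,
                          min_intensity = NULL, quantile = TRUE) {
  if (quantile) matrix <- quantile_normalize(matrix)
  res <- differential_test(matrix, design)
  res$adjusted_p <- bh_adjust(res$raw_p)
  out <- call_state_changes(res, map, label = design$label, adj_p = adj_p,
                            fc = fc, min_intensity = min_intensity)
  attr(out, "probe_results") <- res
  out
}

#' Read / write helpers for the tabular interchange formats
#'
#' `read_expression_tsv` reads a probes-by-samples TSV (first column probe
#' ids, header row sample ids); `read_design_tsv` reads a two-column
#' `sample_id` / `group` file and builds a [comparison_design()];
#' `read_probe_map_tsv` reads a `probe_id` / `gene_symbol` table;
#' `write_state_changes` / `read_state_changes` round-trip a
#' [state_change_set()] as TSV (columns gene, direction, fold_change,
#' adjusted_p, with the population in a companion `.population` column file
#' when `population_path` is given).
#'
#' @param path File path.
#' @param log2 Scale flag for the expression values.
#' @name io_tsv
NULL

#' @rdname io_tsv
#' @export
read_expression_tsv <- function(path, log2 = FALSE) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, row.names = 1)
  expression_matrix(as.matrix(tab), log2 = log2)
}

#' @rdname io_tsv
#' @param label,treatment_group,control_group Comparison label and the group
#'   names taken as treatment and control.
#' @export
read_design_tsv <- function(path, treatment_group, control_group,
                            label = paste(treatment_group, "vs", control_group)) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character")
  comparison_design(label,
                    treatment = tab$sample_id[tab$group == treatment_group],
                    control = tab$sample_id[tab$group == control_group])
}

#' @rdname io_tsv
#' @export
read_probe_map_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character")
}

#' @rdname io_tsv
#' @param scs A [state_change_set()].
#' @param population_path Optional path for the measured-gene population (one
#'   gene per line).
#' @export
write_state_changes <- function(scs, path, population_path = NULL) {
  utils::write.table(scs$changes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(population_path))
    writeLines(scs$population, population_path)
  invisible(path)
}

#' @rdname io_tsv
#' @export
read_state_changes <- function(path, population_path = NULL,
                               label = basename(path)) {
  ch <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  pop <- if (!is.null(population_path)) readLines(population_path) else ch$gene
  state_change_set(label, unique(c(pop, ch$gene)), ch)
}
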