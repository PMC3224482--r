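# Small in-code fixtures shared across test files.

# a two-regulator toy network: TF1 up-regulates G1..G4, down-regulates G5;
# TF2 reaches G6..G9; one non-causal edge links r(G1) to p(G1)
toy_network <- function() {
  causal_network(data.frame(
    source = c(rep("taof(TF1)", 5), rep("kaof(TF2)", 4), "r(G1)"),
    target = c("r(G1)", "r(G2)", "r(G3)", "r(G4)", "r(G5)",
               "r(G6)", "r(G7)", "r(G8)", "r(G9)", "p(G1)"),
    sign = c(1, 1, 1, 1, -1, 1, 1, -1, -1, 1),
    causal = c(rep(TRUE, 9), FALSE),
    species = c(rep("human", 5), rep("mouse", 4), "unspecified"),
    tissue = c(rep("lung", 5), rep("heart", 4), ""),
    pmids = c("11", "11;12", "12", "13", "", "21", "21", "22", "22", ""),
    stringsAsFactors = FALSE), name = "toy")
}

toy_population <- function() paste0("G", 1:40)

toy_scs <- function(genes, dirs, population = toy_population(),
                    label = "toy-cmp") {
  state_change_set(label, population,
                   data.frame(gene = genes,
                              direction = ifelse(dirs > 0, "increased",
                                                 "decreased"),
                              stringsAsFactors = FALSE))
}

# exhaustive richness oracle: fraction of all C(N, K) placements of the K
# state changes among N genes whose overlap with a fixed n-target set is >= k
richness_enum_oracle <- function(N, K, n, k) {
  placements <- utils::combn(N, K)
  mean(apply(placements, 2, function(p) sum(p <= n)) >= k)
}

# explicit binomial tail oracle
concordance_tail_oracle <- function(c, contra, p = 0.5) {
  t <- c + contra
  if (c == 0) return(1)
  sum(vapply(c:t, function(i) choose(t, i) * p^i * (1 - p)^(t - i), 0))
}
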