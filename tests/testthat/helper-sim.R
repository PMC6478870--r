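# Shared fixtures: small synthetic studies cached per test session.

tiny_config <- function(seed = 1, ...) {
  sim_config(n_cell_lines = 10, n_tissues = 3, n_ions = 60,
             n_true_metabolites = 30, n_genes = 120, n_trs = 15,
             n_kinases = 8, targets_per_tr = 6, lines_per_batch = 5,
             n_reactions = 40, n_tissue_ions = 10, n_planted_trs = 3,
             n_drugs = 12, seed = seed, ...)
}

.sim_cache <- new.env(parent = emptyenv())

cached_study <- function(key, config) {
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_study(config)
  .sim_cache[[key]]
}

tiny_study <- function() cached_study("tiny1", tiny_config(seed = 1))

# independent all-pairs shortest-path oracle (Floyd-Warshall on the
# bipartite adjacency, distances counted in traversed edges)
fw_reaction_distance <- function(graph, sources, metabolite) {
  nodes <- c(paste0("m:", graph$metabolites), paste0("r:", graph$reactions))
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (k in seq_len(nrow(graph$edges))) {
    i <- paste0("m:", graph$edges$metabolite[k])
    j <- paste0("r:", graph$edges$reaction[k])
    D[i, j] <- D[j, i] <- 1
  }
  for (k in nodes) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  best <- min(D[paste0("r:", sources), paste0("m:", metabolite)])
  if (!is.finite(best)) return(NA_integer_)
  # edge count from a reaction to a metabolite is odd: 2d - 1 reactions -> d
  as.integer((best + 1) / 2)
}

random_reaction_table <- function(n_met = 12, n_rxn = 14, seed = 1) {
  set.seed(seed)
  mets <- sprintf("m%02d", seq_len(n_met))
  data.frame(
    reaction_id = sprintf("r%02d", seq_len(n_rxn)),
    gene_ids = sprintf("g%02d", sample(6, n_rxn, replace = TRUE)),
    substrates = vapply(seq_len(n_rxn), function(i)
      paste(sample(mets, sample(1:2, 1)), collapse = ";"), ""),
    products = vapply(seq_len(n_rxn), function(i)
      paste(sample(mets, sample(1:2, 1)), collapse = ";"), ""),
    stringsAsFactors = FALSE)
}

# all 5! = 120 permutations of 1:5, for exhaustive permutation oracles
gtools_permutations_5 <- function() {
  perm_rec <- function(v) {
    if (length(v) == 1) return(matrix(v, 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], perm_rec(v[-i]))))
  }
  perm_rec(1:5)
}

# full-size default study (54 lines), shared by tests needing the
# designed statistical power
default_study <- function() cached_study("default41", sim_config(seed = 41))

# exhaustive hypergeometric enumeration oracle over all C(N, n) draws
enum_hyper <- function(N, K, n, k) {
  draws <- combn(N, n)
  members <- seq_len(K)
  mean(apply(draws, 2, function(d) sum(d %in% members)) >= k)
}
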