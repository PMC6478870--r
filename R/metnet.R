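# Bipartite stoichiometric network distances: reaction-count shortest
# paths between enzymes (or TR enzyme-target sets) and metabolites, with
# degree-preserving randomized nulls.

#' Build a bipartite metabolite/reaction graph
#'
#' Metabolite and reaction nodes joined by undirected participation edges
#' (substrate or product; direction is ignored for distances), plus an
#' enzyme(gene) to reaction mapping. Gene-reaction rules are a flat list
#' (`;`-separated gene ids per reaction).
#'
#' @param reactions data.frame with columns `reaction_id`, `gene_ids`,
#'   `substrates`, `products` (`;`-separated metabolite ids).
#' @param max_degree optional currency-metabolite exclusion: metabolites
#'   participating in more than `max_degree` reactions are dropped from
#'   the graph.
#' @return object of class `metabolic_graph`.
#' @export
metabolic_graph <- function(reactions, max_degree = Inf) {
  split_ids <- function(x) strsplit(as.character(x), ";", fixed = TRUE)
  subs <- split_ids(reactions$substrates)
  prods <- split_ids(reactions$products)
  rxns <- as.character(reactions$reaction_id)
  edges <- unique(do.call(rbind, lapply(seq_along(rxns), function(i) {
    m <- unique(c(subs[[i]], prods[[i]]))
    m <- m[nzchar(m)]
    if (length(m) == 0) return(NULL)
    data.frame(metabolite = m, reaction = rxns[i], stringsAsFactors = FALSE)
  })))
  if (is.finite(max_degree)) {
    deg <- table(edges$metabolite)
    hubs <- names(deg)[deg > max_degree]
    edges <- edges[!edges$metabolite %in% hubs, , drop = FALSE]
  }
  mets <- sort(unique(edges$metabolite))
  genes <- split_ids(reactions$gene_ids)
  g2r <- do.call(rbind, lapply(seq_along(rxns), function(i) {
    g <- genes[[i]][nzchar(genes[[i]])]
    if (length(g) == 0) return(NULL)
    data.frame(gene = g, reaction = rxns[i], stringsAsFactors = FALSE)
  }))
  structure(list(metabolites = mets, reactions = rxns, edges = edges,
                 gene_map = g2r), class = "metabolic_graph")
}

graph_index <- function(graph) {
  list(met_id = match(graph$edges$metabolite, graph$metabolites) - 1L,
       rxn_id = match(graph$edges$reaction, graph$reactions) - 1L,
       n_met = length(graph$metabolites),
       n_rxn = length(graph$reactions))
}

reaction_sources <- function(graph, genes) {
  rx <- unique(graph$gene_map$reaction[graph$gene_map$gene %in% genes])
  match(rx, graph$reactions) - 1L
}

#' Enzyme-to-metabolite network distance
#'
#' Breadth-first search from the enzyme's reaction nodes; the distance to a
#' metabolite is the number of reaction nodes on the shortest alternating
#' path, so metabolites of the enzyme's own reactions have distance 1.
#' Unreachable metabolites get NA.
#'
#' @param graph a [metabolic_graph()].
#' @param enzyme gene id (must map to at least one reaction).
#' @param metabolites metabolite ids to query (default all).
#' @return named integer vector of distances.
#' @export
enzyme_metabolite_distance <- function(graph, enzyme,
                                       metabolites = graph$metabolites) {
  src <- reaction_sources(graph, enzyme)
  if (length(src) == 0)
    stop("enzyme_metabolite_distance: enzyme '", enzyme,
         "' maps to no reaction")
  unknown <- setdiff(metabolites, graph$metabolites)
  if (length(unknown))
    stop("enzyme_metabolite_distance: unknown metabolite(s) ",
         paste(unknown, collapse = ", "))
  gi <- graph_index(graph)
  d <- bfs_distance_cpp(gi$met_id, gi$rxn_id, gi$n_met, gi$n_rxn,
                        list(src))[1, ]
  names(d) <- graph$metabolites
  d[metabolites]
}

#' TR-to-metabolite distance via its enzyme targets
#'
#' Minimum over the TR's enzyme targets of the enzyme-metabolite distance
#' (equivalently, a multi-source BFS from the union of their reactions).
#'
#' @param graph a [metabolic_graph()].
#' @param targets the TR's enzyme (gene) target set.
#' @param metabolites metabolite ids to query (default all).
#' @return named integer vector of distances (NA if unreachable or no
#'   target maps to a reaction).
#' @export
tr_metabolite_distance <- function(graph, targets,
                                   metabolites = graph$metabolites) {
  if (length(targets) == 0)
    stop("tr_metabolite_distance: empty target set")
  src <- reaction_sources(graph, targets)
  gi <- graph_index(graph)
  if (length(src) == 0)
    return(stats::setNames(rep(NA_integer_, length(metabolites)),
                           metabolites))
  d <- bfs_distance_cpp(gi$met_id, gi$rxn_id, gi$n_met, gi$n_rxn,
                        list(src))[1, ]
  names(d) <- graph$metabolites
  d[metabolites]
}

#' All TR x metabolite distances
#'
#' @param graph a [metabolic_graph()].
#' @param target_sets named list: per TR, its enzyme target genes.
#' @return TRs x metabolites integer matrix (NA where unreachable).
#' @export
tr_distance_matrix <- function(graph, target_sets) {
  gi <- graph_index(graph)
  src <- lapply(target_sets, function(g) reaction_sources(graph, g))
  D <- bfs_distance_cpp(gi$met_id, gi$rxn_id, gi$n_met, gi$n_rxn, src)
  dimnames(D) <- list(names(target_sets), graph$metabolites)
  D
}

#' Degree-preserving randomization of a metabolic graph
#'
#' Double-edge swaps on the bipartite edge list preserve the degree
#' sequences of both node classes exactly; swaps that would duplicate an
#' existing edge are skipped.
#'
#' @param graph a [metabolic_graph()].
#' @param swap_mult attempted swaps as a multiple of the edge count.
#' @param seed optional integer seed.
#' @return a randomized `metabolic_graph` (same gene mapping).
#' @export
randomize_graph <- function(graph, swap_mult = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gi <- graph_index(graph)
  sw <- swap_edges_cpp(gi$met_id, gi$rxn_id,
                       as.integer(swap_mult * length(gi$met_id)))
  out <- graph
  out$edges <- data.frame(
    metabolite = graph$metabolites[sw$met_id + 1L],
    reaction = graph$reactions[sw$rxn_id + 1L], stringsAsFactors = FALSE)
  out
}

#' Distance versus association-strength curve with randomized null
#'
#' For each absolute-correlation threshold `t`, the mean TR-metabolite
#' network distance over all pairs with `|R| >= t` (cumulative sweep, or
#' per-bin with `mode = "binned"`). The null band repeats the computation
#' on `n_random` degree-preserving randomized graphs; the per-threshold
#' permutation p is the fraction of null means at or below the observed
#' mean (proximity), with Storey q-values appended.
#'
#' @param assoc an `assoc_matrix` (or plain TR x metabolite R matrix).
#' @param graph a [metabolic_graph()].
#' @param target_sets named list of enzyme targets per TR (rows of the
#'   association matrix).
#' @param thresholds ascending absolute-correlation thresholds in \[0, 1\].
#' @param n_random number of randomized graphs.
#' @param swap_mult swap attempts per edge for each randomization.
#' @param mode cumulative sweep (default) or binned thresholds.
#' @param seed integer seed.
#' @return data.frame: threshold, n_pairs, mean_distance, null_mean,
#'   null_sd, p, q.
#' @export
distance_correlation_curve <- function(assoc, graph, target_sets,
                                       thresholds = seq(0, 0.6, by = 0.1),
                                       n_random = 10000, swap_mult = 10,
                                       mode = c("cumulative", "binned"),
                                       seed = 1L) {
  mode <- match.arg(mode)
  if (is.unsorted(thresholds) || any(thresholds < 0 | thresholds > 1))
    stop("distance_correlation_curve: thresholds must ascend within [0,1]")
  R <- if (inherits(assoc, "assoc_matrix")) assoc$R else assoc
  target_sets <- target_sets[rownames(R)]
  D <- tr_distance_matrix(graph, target_sets)
  mets <- intersect(colnames(R), colnames(D))
  R <- R[, mets, drop = FALSE]
  D <- D[, mets, drop = FALSE]
  absR <- abs(R)
  n_met <- ncol(D)
  sel_idx <- lapply(seq_along(thresholds), function(i) {
    keep <- if (mode == "cumulative") absR >= thresholds[i] else
      absR >= thresholds[i] &
        (i == length(thresholds) | absR < c(thresholds, Inf)[i + 1])
    w <- which(t(keep)) - 1L  # row-major over metabolites within TR rows
    w
  })
  tD <- t(D)
  obs <- vapply(seq_along(thresholds), function(i) {
    d <- tD[sel_idx[[i]] + 1L]
    n <- sum(!is.na(d))
    c(n, if (n > 0) mean(d, na.rm = TRUE) else NA_real_)
  }, numeric(2))
  gi <- graph_index(graph)
  met_pos <- match(mets, graph$metabolites) - 1L
  # map selected (TR, met) pairs to flattened indices q * n_met_all + m
  pair_sets <- lapply(sel_idx, function(w) {
    q <- w %/% n_met
    m <- met_pos[(w %% n_met) + 1L]
    as.integer(q * gi$n_met + m)
  })
  set.seed(seed)
  null_means <- null_distance_curve_cpp(
    gi$met_id, gi$rxn_id, gi$n_met, gi$n_rxn,
    lapply(target_sets, function(g) reaction_sources(graph, g)),
    pair_sets, as.integer(n_random), as.integer(swap_mult))
  p <- vapply(seq_along(thresholds), function(i) {
    nm <- null_means[, i]
    nm <- nm[!is.na(nm)]
    if (length(nm) == 0 || !is.finite(obs[2, i])) return(NA_real_)
    mean(nm <= obs[2, i])
  }, numeric(1))
  out <- data.frame(
    threshold = thresholds, n_pairs = obs[1, ],
    mean_distance = obs[2, ],
    null_mean = colMeans(null_means, na.rm = TRUE),
    null_sd = apply(null_means, 2, stats::sd, na.rm = TRUE),
    p = p)
  out <- out[out$n_pairs > 0, , drop = FALSE]
  out$q <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$q[ok] <- storey_q(out$p[ok])
  rownames(out) <- NULL
  out
}
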