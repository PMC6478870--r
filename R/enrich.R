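# Pathway enrichment: set-based (hypergeometric), rank-based (iterative
# hypergeometric with permutation calibration) and Storey q-values.

#' Storey q-values
#'
#' Estimates the proportion of true nulls pi0 on a lambda grid
#' (`pi0(lambda) = mean(p > lambda) / (1 - lambda)`), smooths it with a
#' cubic spline and evaluates at the largest lambda; q-values are the
#' monotone-adjusted `pi0 * m * p_(i) / i`. With fewer than `min_tests`
#' p-values the pi0 estimate is unreliable and Benjamini-Hochberg is used
#' instead, with a warning.
#'
#' @param p p-values in \[0, 1\].
#' @param lambda grid for the pi0 smoother.
#' @param min_tests minimum tests before falling back to BH.
#' @return q-values (same order as `p`), with attribute `pi0`.
#' @export
storey_q <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                     min_tests = 10) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("storey_q: p-values must lie in [0, 1]")
  ok <- !is.na(p)
  m <- sum(ok)
  if (m < min_tests) {
    warning("storey_q: fewer than ", min_tests,
            " p-values; falling back to Benjamini-Hochberg")
    q <- rep(NA_real_, length(p))
    q[ok] <- stats::p.adjust(p[ok], method = "BH")
    attr(q, "pi0") <- 1
    return(q)
  }
  pi0_l <- vapply(lambda, function(l) mean(p[ok] > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  pi0 <- min(1, max(pi0, 1 / m))
  o <- order(p[ok])
  pm <- p[ok][o]
  qv <- pi0 * m * pm / seq_len(m)
  qv <- rev(cummin(rev(qv)))
  qv <- pmin(qv, 1)
  q <- rep(NA_real_, length(p))
  q[ok][o] <- qv
  attr(q, "pi0") <- pi0
  q
}

#' Hypergeometric over-representation of pathways in a selection
#'
#' Upper-tail hypergeometric p per pathway for the overlap between the
#' selected ids and the pathway members, within the stated universe;
#' Storey q-values appended.
#'
#' @param selected selected ids (subset of the universe).
#' @param sets named list of pathway member vectors.
#' @param universe background ids; defaults to the union of the sets and
#'   the selection.
#' @return data.frame: pathway, k (overlap), K (set size), n (selection
#'   size), N (universe), p, q.
#' @export
hypergeom_enrichment <- function(selected, sets, universe = NULL) {
  if (is.null(universe)) universe <- union(unlist(sets), selected)
  if (length(universe) == 0) stop("hypergeom_enrichment: empty universe")
  if (!all(selected %in% universe))
    stop("hypergeom_enrichment: selection outside the universe")
  selected <- unique(selected)
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  N <- length(universe); n <- length(selected)
  out <- data.frame(
    pathway = names(sets),
    k = vapply(sets, function(s) length(intersect(s, selected)), 0L),
    K = lengths(sets), n = n, N = N, stringsAsFactors = FALSE)
  out$p <- stats::phyper(out$k - 1, out$K, N - out$K, n,
                         lower.tail = FALSE)
  out$q <- as.numeric(storey_q(out$p))
  rownames(out) <- NULL
  out
}

#' Directional pathway enrichment of a correlation signature
#'
#' Runs [hypergeom_enrichment()] separately on the positively and
#' negatively scoring ids at an absolute cutoff.
#'
#' @param scores named signed scores (e.g. correlation coefficients).
#' @param sets named list of pathway member vectors.
#' @param cutoff absolute score defining the selections.
#' @return data.frame as [hypergeom_enrichment()] plus a `direction`
#'   column.
#' @export
directional_enrichment <- function(scores, sets, cutoff = 0.5) {
  universe <- names(scores)
  up <- hypergeom_enrichment(names(scores)[scores >= cutoff & !is.na(scores)],
                             sets, universe)
  dn <- hypergeom_enrichment(names(scores)[scores <= -cutoff & !is.na(scores)],
                             sets, universe)
  up$direction <- "positive"
  dn$direction <- "negative"
  rbind(up, dn)
}

min_prefix_hyper <- function(member_ranks, K, N) {
  r <- sort(member_ranks)
  min(stats::phyper(seq_along(r) - 1, K, N - K, r, lower.tail = FALSE))
}

#' Iterative hypergeometric rank enrichment
#'
#' Tests whether a pathway's members concentrate toward the top of a
#' ranked list: for each prefix ending at a member's rank, the upper-tail
#' hypergeometric p is computed, and the pathway score is the minimum over
#' prefixes. Because the minimum is selection-biased, significance is
#' calibrated against `n_perm` random permutations of the ranking (the
#' fraction of null minima at or below the observed one); Storey q-values
#' appended. Null minima are shared between pathways of equal size.
#'
#' @param ranked ids ordered from most to least extreme (a permutation of
#'   the universe; break ties beforehand).
#' @param sets named list of pathway member vectors.
#' @param n_perm permutations for calibration.
#' @param seed integer seed.
#' @return data.frame: pathway, K, raw_min_p, p, q.
#' @export
iterative_rank_enrichment <- function(ranked, sets, n_perm = 1000,
                                      seed = 1L) {
  N <- length(ranked)
  if (anyDuplicated(ranked))
    stop("iterative_rank_enrichment: ranked list contains duplicates")
  sets <- lapply(sets, function(s) intersect(unique(s), ranked))
  keep <- lengths(sets) > 0
  sets <- sets[keep]
  if (length(sets) == 0)
    return(data.frame(pathway = character(0), K = integer(0),
                      raw_min_p = numeric(0), p = numeric(0),
                      q = numeric(0)))
  pos <- stats::setNames(seq_len(N), ranked)
  raw <- vapply(sets, function(s)
    min_prefix_hyper(pos[s], length(s), N), numeric(1))
  set.seed(seed)
  sizes <- sort(unique(lengths(sets)))
  null_min <- lapply(sizes, function(K)
    vapply(seq_len(n_perm), function(b)
      min_prefix_hyper(sample(N, K), K, N), numeric(1)))
  names(null_min) <- as.character(sizes)
  p <- vapply(seq_along(sets), function(i) {
    mean(null_min[[as.character(length(sets[[i]]))]] <= raw[i])
  }, numeric(1))
  out <- data.frame(pathway = names(sets), K = lengths(sets),
                    raw_min_p = raw, p = p, stringsAsFactors = FALSE)
  out$q <- as.numeric(storey_q(out$p))
  rownames(out) <- NULL
  out
}
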