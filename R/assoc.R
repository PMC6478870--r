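# TR-metabolite association networks: Spearman correlation matrices with
# bootstrap FDR control, the augmented TR-gene network, and tissue
# signature statistics.

#' Spearman correlation matrix with p-values
#'
#' Pairwise Spearman correlations between the rows of `X` and the rows of
#' `Y` over shared columns, with two-sided p-values from the t
#' approximation `t = r * sqrt((n-2)/(1-r^2))`. Constant rows give NA
#' (pair flagged undefined).
#'
#' @param X,Y variables x samples matrices with matching column order.
#' @return list with `R`, `p` (rows of X by rows of Y), `n_obs`.
#' @export
spearman_matrix <- function(X, Y) {
  stopifnot(ncol(X) == ncol(Y))
  n <- ncol(X)
  R <- suppressWarnings(stats::cor(t(X), t(Y), method = "spearman"))
  tt <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  p[!is.na(R) & abs(R) >= 1] <- 0
  list(R = R, p = p, n_obs = n)
}

#' Correlate TR activities with metabolite abundances
#'
#' Spearman R and two-sided p for every (TR, metabolite) pair over the
#' cell lines shared between the activity matrix and the Z-scored
#' metabolome. Missing metabolite values reflect abundances near
#' background and are treated as zero.
#'
#' @param activity an `activity_matrix` (or plain TRs x lines matrix).
#' @param z a [zscore_abundance()] result (or plain ions x lines matrix).
#' @param min_lines minimum shared cell lines.
#' @return object of class `assoc_matrix`: list with `R`, `p`
#'   (TRs x metabolites), `n_obs`, `cell_lines`.
#' @export
tr_metabolite_correlation <- function(activity, z, min_lines = 5) {
  act <- if (inherits(activity, "activity_matrix")) activity$activity
         else activity
  zm <- if (is.list(z) && !is.null(z$z)) z$z else z
  shared <- intersect(colnames(act), colnames(zm))
  if (length(shared) < min_lines)
    stop("tr_metabolite_correlation: fewer than ", min_lines,
         " shared cell lines")
  act <- act[, shared, drop = FALSE]
  zm <- zm[, shared, drop = FALSE]
  zm[is.na(zm)] <- 0
  sm <- spearman_matrix(act, zm)
  structure(list(R = sm$R, p = sm$p, n_obs = sm$n_obs,
                 cell_lines = shared), class = "assoc_matrix")
}

#' Bootstrap FDR threshold on association strength
#'
#' The metabolome's cell-line labels are resampled with replacement
#' `n_resamples` times (breaking the pairing with TR activities); all
#' pairwise absolute Spearman correlations are pooled into a null, and the
#' threshold is the smallest pooled value exceeding the `1 - fdr` fraction
#' of the null (the paper's 99.9% confidence rule at the 0.1% FDR
#' default).
#'
#' @inheritParams tr_metabolite_correlation
#' @param n_resamples bootstrap resamples (>= 2).
#' @param fdr nominal false-discovery level among network links.
#' @param seed integer seed.
#' @return list of class `fdr_threshold`: `threshold`, `fdr`,
#'   `n_resamples`.
#' @export
bootstrap_fdr_threshold <- function(activity, z, n_resamples = 100,
                                    fdr = 0.001, seed = 1L) {
  if (n_resamples < 2)
    stop("bootstrap_fdr_threshold: n_resamples must be >= 2")
  act <- if (inherits(activity, "activity_matrix")) activity$activity
         else activity
  zm <- if (is.list(z) && !is.null(z$z)) z$z else z
  shared <- intersect(colnames(act), colnames(zm))
  act <- act[, shared, drop = FALSE]
  zm <- zm[, shared, drop = FALSE]
  zm[is.na(zm)] <- 0
  set.seed(seed)
  ta <- t(act)
  pool <- vector("list", n_resamples)
  for (b in seq_len(n_resamples)) {
    idx <- sample(length(shared), replace = TRUE)
    Rb <- suppressWarnings(
      stats::cor(ta, t(zm[, idx, drop = FALSE]), method = "spearman"))
    pool[[b]] <- abs(as.vector(Rb))
  }
  pool <- sort(unlist(pool), na.last = NA)
  m <- length(pool)
  threshold <- if (fdr >= 1) 0 else {
    j <- floor((1 - fdr) * m)
    pool[min(j + 1L, m)]
  }
  structure(list(threshold = threshold, fdr = fdr,
                 n_resamples = n_resamples), class = "fdr_threshold")
}

#' Augmented TR-gene network from an expression compendium
#'
#' Edges (TR, enzyme) for enzymes whose transcript levels correlate with a
#' TR's activity profile with absolute Spearman correlation above
#' `r_threshold` across the compendium samples.
#'
#' @param activity TRs x samples activity matrix.
#' @param expression genes x samples matrix on the same compendium.
#' @param enzyme_genes gene ids considered enzymes.
#' @param r_threshold absolute correlation cutoff.
#' @return data.frame with `tr`, `enzyme`, `R`.
#' @export
augmented_network <- function(activity, expression, enzyme_genes,
                              r_threshold = 0.5) {
  act <- if (inherits(activity, "activity_matrix")) activity$activity
         else activity
  shared <- intersect(colnames(act), colnames(expression))
  enz <- intersect(enzyme_genes, rownames(expression))
  R <- suppressWarnings(stats::cor(
    t(act[, shared, drop = FALSE]),
    t(expression[enz, shared, drop = FALSE]), method = "spearman"))
  hit <- which(abs(R) > r_threshold, arr.ind = TRUE)
  out <- data.frame(tr = rownames(R)[hit[, 1]],
                    enzyme = colnames(R)[hit[, 2]],
                    R = R[hit], stringsAsFactors = FALSE)
  out[order(out$tr, out$enzyme), , drop = FALSE]
}

#' Tissue-dependence of metabolite abundances by one-way ANOVA
#'
#' One-way ANOVA of each metabolite's Z-scored abundance on the tissue of
#' origin, with Storey q-values.
#'
#' @param z ions x lines matrix (or [zscore_abundance()] result).
#' @param tissue named tissue labels covering the columns of `z`.
#' @return data.frame: metabolite, F, p, q, flagged (degenerate groups).
#' @export
tissue_anova <- function(z, tissue) {
  zm <- if (is.list(z) && !is.null(z$z)) z$z else z
  g <- factor(tissue[colnames(zm)])
  if (nlevels(g) < 2) stop("tissue_anova: need >= 2 tissues")
  res <- t(vapply(seq_len(nrow(zm)), function(i) {
    y <- zm[i, ]
    ok <- !is.na(y)
    gi <- droplevels(g[ok])
    if (nlevels(gi) < 2 || any(table(gi) < 2))
      return(c(NA_real_, NA_real_))
    ft <- tryCatch(
      stats::oneway.test(y[ok] ~ gi, var.equal = TRUE),
      error = function(e) NULL)
    if (is.null(ft)) c(NA_real_, NA_real_)
    else c(unname(ft$statistic), ft$p.value)
  }, numeric(2)))
  out <- data.frame(metabolite = rownames(zm), F = res[, 1], p = res[, 2],
                    stringsAsFactors = FALSE)
  out$flagged <- is.na(out$p)
  out$q <- NA_real_
  ok <- !out$flagged
  if (any(ok)) out$q[ok] <- storey_q(out$p[ok])
  rownames(out) <- NULL
  out
}

#' Tissue-signature ROC analysis of molecular profiles
#'
#' Scores every unordered pair of cell lines by the Spearman (or Pearson)
#' similarity of their profiles; pairs from the same tissue are the
#' positive class. The AUC is computed by the Mann-Whitney rank formula
#' and quantifies how much more similar same-tissue lines are.
#'
#' @param profiles features x lines matrix.
#' @param tissue named tissue labels covering the columns.
#' @param method similarity correlation method.
#' @return list with `auc`, `n_pos`, `n_neg`, `scores`, `same_tissue`.
#' @export
tissue_similarity_roc <- function(profiles, tissue,
                                  method = c("spearman", "pearson")) {
  method <- match.arg(method)
  tiss <- tissue[colnames(profiles)]
  if (length(unique(tiss)) < 2)
    stop("tissue_similarity_roc: need >= 2 tissues")
  S <- suppressWarnings(stats::cor(profiles, method = method,
                                   use = "pairwise.complete.obs"))
  ut <- upper.tri(S)
  scores <- S[ut]
  same <- outer(tiss, tiss, "==")[ut]
  n_pos <- sum(same); n_neg <- sum(!same)
  if (n_pos == 0 || n_neg == 0)
    stop("tissue_similarity_roc: need both same- and different-tissue pairs")
  r <- rank(scores)
  auc <- (sum(r[same]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(auc = auc, n_pos = n_pos, n_neg = n_neg, scores = scores,
       same_tissue = same)
}
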