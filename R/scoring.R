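# Dot-product scoring of TRs: glycolytic-flux association, in-vivo TR
# inference from patient fold-changes, knockdown ranking and drug-TR
# regression.

#' Correlate metabolite abundances with glycolytic flux
#'
#' Per metabolite, the mean of the Spearman correlation with glucose
#' uptake and with lactate secretion across shared cell lines.
#'
#' @param z ions x lines matrix (or [zscore_abundance()] result).
#' @param flux data.frame with columns `cell_line`, `glucose_uptake`,
#'   `lactate_secretion`.
#' @param min_lines minimum shared cell lines.
#' @return named per-metabolite score vector.
#' @export
metabolite_flux_correlation <- function(z, flux, min_lines = 5) {
  zm <- if (is.list(z) && !is.null(z$z)) z$z else z
  shared <- intersect(colnames(zm), flux$cell_line)
  if (length(shared) < min_lines)
    stop("metabolite_flux_correlation: fewer than ", min_lines,
         " shared lines")
  fx <- flux[match(shared, flux$cell_line), ]
  if (stats::sd(fx$glucose_uptake) == 0 ||
      stats::sd(fx$lactate_secretion) == 0)
    stop("metabolite_flux_correlation: constant flux vector")
  zm <- zm[, shared, drop = FALSE]
  zm[is.na(zm)] <- 0
  r_up <- suppressWarnings(
    stats::cor(t(zm), fx$glucose_uptake, method = "spearman"))
  r_sec <- suppressWarnings(
    stats::cor(t(zm), fx$lactate_secretion, method = "spearman"))
  stats::setNames((r_up + r_sec)[, 1] / 2, rownames(zm))
}

#' Score TRs against a metabolite-flux correlation vector
#'
#' `score_TR = sum_m R[TR, m] * f[m] / sum_m |R[TR, m]|`: the dot product
#' of the TR-metabolite and metabolite-flux correlation vectors,
#' normalized by the absolute sum of TR-metabolite correlations.
#' Undefined pairs contribute 0; all-zero rows give NA.
#'
#' @param assoc an `assoc_matrix` (or plain TR x metabolite R matrix).
#' @param flux_corr named per-metabolite scores from
#'   [metabolite_flux_correlation()].
#' @return named per-TR score vector.
#' @export
tr_flux_score <- function(assoc, flux_corr) {
  R <- if (inherits(assoc, "assoc_matrix")) assoc$R else assoc
  mets <- intersect(colnames(R), names(flux_corr))
  R <- R[, mets, drop = FALSE]
  f <- flux_corr[mets]
  R[is.na(R)] <- 0
  f[is.na(f)] <- 0
  denom <- rowSums(abs(R))
  score <- as.vector(R %*% f) / denom
  score[denom == 0] <- NA_real_
  stats::setNames(score, rownames(R))
}

#' Pathway-level aggregation of TR scores with a permutation test
#'
#' Mean score over the TRs mapped to each pathway, compared with means of
#' equal-size random TR sets (one-sided: enrichment of high scores);
#' Storey q-values appended.
#'
#' @param scores named per-TR scores.
#' @param pathway_trs named list: per pathway, its member TRs.
#' @param n_perm random sets per pathway size.
#' @param seed integer seed.
#' @return data.frame: pathway, n_trs, mean_score, p, q.
#' @export
pathway_tr_score <- function(scores, pathway_trs, n_perm = 1000,
                             seed = 1L) {
  scores <- scores[!is.na(scores)]
  pathway_trs <- lapply(pathway_trs, function(t)
    intersect(t, names(scores)))
  keep <- lengths(pathway_trs) > 0
  if (!any(keep))
    stop("pathway_tr_score: no pathway with mapped, scored TRs")
  pathway_trs <- pathway_trs[keep]
  obs <- vapply(pathway_trs, function(t) mean(scores[t]), numeric(1))
  set.seed(seed)
  sizes <- sort(unique(lengths(pathway_trs)))
  nulls <- lapply(sizes, function(K)
    vapply(seq_len(n_perm), function(b)
      mean(sample(scores, K)), numeric(1)))
  names(nulls) <- as.character(sizes)
  p <- vapply(seq_along(pathway_trs), function(i)
    mean(nulls[[as.character(length(pathway_trs[[i]]))]] >= obs[i]),
    numeric(1))
  out <- data.frame(pathway = names(pathway_trs),
                    n_trs = lengths(pathway_trs),
                    mean_score = obs, p = p, stringsAsFactors = FALSE)
  out$q <- as.numeric(storey_q(out$p))
  rownames(out) <- NULL
  out
}

#' TR-metabolite correlation signature vectors
#'
#' Per-TR vector with entries `R * (-log10 p)`; undefined pairs are 0.
#'
#' @param assoc an `assoc_matrix`.
#' @param p_floor p-values below this are clamped before the log (exact
#'   zeros would give infinite weights).
#' @return TRs x metabolites matrix.
#' @export
ctr_vectors <- function(assoc, p_floor = 1e-300) {
  C <- assoc$R * (-log10(pmax(assoc$p, p_floor)))
  C[is.na(C)] <- 0
  C
}

#' Infer TR involvement from in vivo metabolite fold-changes
#'
#' Per patient, `S_TR = C_TR . FC / ||C_TR||_1` over the overlapping
#' metabolites (after excluding metabolites with more than `max_missing`
#' missing values across patients; remaining missing fold-changes count as
#' zero). Significance by a one-sided permutation test shuffling the
#' metabolite order (`p = fraction of shuffled scores >= observed`, no
#' pseudocount), Storey q-values per patient, and per-TR medians across
#' patients.
#'
#' @param ctr TRs x metabolites signature matrix from [ctr_vectors()].
#' @param fc metabolites x patients log2 fold-change matrix (NAs missing).
#' @param n_perm permutations.
#' @param max_missing per-metabolite missing-value tolerance.
#' @param seed integer seed.
#' @param chunk permutations evaluated per matrix product.
#' @return list with `S`, `p`, `q` (TRs x patients), `median_S`,
#'   `median_q` (per TR), `metabolites` (overlap used).
#' @export
invivo_tr_score <- function(ctr, fc, n_perm = 10000, max_missing = 10,
                            seed = 1L, chunk = 50L) {
  keep <- rowSums(is.na(fc)) <= max_missing
  fc <- fc[keep, , drop = FALSE]
  mets <- intersect(colnames(ctr), rownames(fc))
  if (length(mets) < 2)
    stop("invivo_tr_score: fewer than 2 overlapping metabolites")
  C <- ctr[, mets, drop = FALSE]
  FC <- fc[mets, , drop = FALSE]
  FC[is.na(FC)] <- 0
  l1 <- rowSums(abs(C))
  l1[l1 == 0] <- NA_real_
  S <- (C %*% FC) / l1
  set.seed(seed)
  cnt <- matrix(0, nrow(S), ncol(S))
  m <- length(mets)
  done <- 0L
  while (done < n_perm) {
    nb <- min(chunk, n_perm - done)
    perm <- unlist(lapply(seq_len(nb), function(b) sample.int(m)))
    FCb <- FC[perm, , drop = FALSE]
    dim(FCb) <- c(m, nb * ncol(FC))
    Sb <- (C %*% FCb) / l1
    dim(Sb) <- c(nrow(S), ncol(FC), nb)
    cnt <- cnt + rowSums(Sb >= as.vector(S), dims = 2)
    done <- done + nb
  }
  p <- cnt / n_perm
  dimnames(p) <- dimnames(S)
  if (nrow(p) < 10)
    warning("invivo_tr_score: fewer than 10 TRs; per-patient q-values ",
            "use the Benjamini-Hochberg fallback")
  q <- p
  for (j in seq_len(ncol(p)))
    q[, j] <- suppressWarnings(as.numeric(storey_q(p[, j])))
  list(S = S, p = p, q = q,
       median_S = apply(S, 1, stats::median),
       median_q = apply(q, 1, stats::median),
       metabolites = mets)
}

#' Rank TRs against knockdown metabolite fold-changes
#'
#' Per siRNA concentration, the L1-normalized dot-product score of each
#' TR's signature with the metabolite fold-changes; combined per-metabolite
#' significance is the product of p-values across concentrations; TRs are
#' ranked by the absolute median score over concentrations.
#'
#' @param ctr TRs x metabolites signature matrix.
#' @param fc_by_conc metabolites x concentrations fold-change matrix.
#' @param p_by_conc matching per-concentration p-value matrix (optional).
#' @return list with `scores` (TRs x concentrations), `median_score`,
#'   `ranking` (data.frame, strongest first), `combined_p` (per
#'   metabolite, if p-values supplied).
#' @export
knockdown_rank <- function(ctr, fc_by_conc, p_by_conc = NULL) {
  if (ncol(fc_by_conc) < 2)
    stop("knockdown_rank: need >= 2 siRNA concentrations")
  mets <- intersect(colnames(ctr), rownames(fc_by_conc))
  C <- ctr[, mets, drop = FALSE]
  FC <- fc_by_conc[mets, , drop = FALSE]
  FC[is.na(FC)] <- 0
  l1 <- rowSums(abs(C))
  l1[l1 == 0] <- NA_real_
  scores <- (C %*% FC) / l1
  med <- apply(scores, 1, stats::median)
  ranking <- data.frame(tr = rownames(C), median_score = med,
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-abs(ranking$median_score)), ]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  combined <- NULL
  if (!is.null(p_by_conc)) {
    pp <- p_by_conc[mets, , drop = FALSE]
    combined <- stats::setNames(apply(pp, 1, prod), mets)
  }
  list(scores = scores, median_score = med, ranking = ranking,
       combined_p = combined)
}

#' Regress drug sensitivity on TR activity with tissue covariates
#'
#' Per (TR, drug) pair: least squares of (log-scale) sensitivity on the
#' TR's activity plus tissue indicators (no further intercept), with a
#' two-sided t-test on the activity coefficient lambda; significance at
#' the Bonferroni threshold `alpha / (n_TR * n_drug)`. Tissues with fewer
#' than 2 lines are pooled into "other".
#'
#' @param panel drugs x lines sensitivity matrix.
#' @param activity an `activity_matrix` or TRs x lines matrix.
#' @param tissue named tissue labels.
#' @param alpha family-wise error rate.
#' @return list with `results` (data.frame: tr, drug, lambda, se, p,
#'   significant), `beta` (TRs x drugs x tissues array), `threshold`.
#' @export
drug_tr_regression <- function(panel, activity, tissue, alpha = 0.05) {
  act <- if (inherits(activity, "activity_matrix")) activity$activity
         else activity
  shared <- intersect(colnames(panel), colnames(act))
  tiss <- as.character(tissue[shared])
  small <- names(table(tiss))[table(tiss) < 2]
  if (length(small)) {
    warning("drug_tr_regression: pooling tissue(s) with < 2 lines into ",
            "'other': ", paste(small, collapse = ", "))
    tiss[tiss %in% small] <- "other"
  }
  tf <- factor(tiss)
  Tm <- stats::model.matrix(~ 0 + tf)
  colnames(Tm) <- levels(tf)
  Y <- t(panel[, shared, drop = FALSE])
  n <- length(shared)
  trs <- rownames(act)
  drugs <- rownames(panel)
  threshold <- alpha / (length(trs) * length(drugs))
  res <- vector("list", length(trs))
  beta <- array(NA_real_, c(length(trs), length(drugs), nlevels(tf)),
                dimnames = list(trs, drugs, levels(tf)))
  for (i in seq_along(trs)) {
    X <- cbind(activity = act[trs[i], shared], Tm)
    xtx_inv <- solve(crossprod(X))
    coefs <- xtx_inv %*% crossprod(X, Y)
    resid <- Y - X %*% coefs
    df <- n - ncol(X)
    sigma2 <- colSums(resid^2) / df
    se <- sqrt(xtx_inv[1, 1] * sigma2)
    lambda <- coefs[1, ]
    p <- 2 * stats::pt(-abs(lambda / se), df)
    beta[i, , ] <- t(coefs[-1, , drop = FALSE])
    res[[i]] <- data.frame(tr = trs[i], drug = drugs, lambda = lambda,
                           se = se, p = p, stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res)
  results$significant <- results$p <= threshold
  rownames(results) <- NULL
  list(results = results, beta = beta, threshold = threshold)
}

#' Cluster-by-mechanism enrichment of significant drug-TR associations
#'
#' For every (TR cluster, drug mechanism-of-action) cell, hypergeometric
#' over-representation of significant (TR, drug) pairs among the cell's
#' pairs, against all tested pairs; significance at the Bonferroni
#' threshold `alpha / (n_clusters * n_moa)`.
#'
#' @param results the `results` data.frame from [drug_tr_regression()].
#' @param clusters named cluster label per TR.
#' @param moa named mechanism label per drug.
#' @param alpha family-wise error rate.
#' @return list with `p` (clusters x MoA matrix), `significant` (logical
#'   matrix), `threshold`.
#' @export
moa_cluster_enrichment <- function(results, clusters, moa, alpha = 0.05) {
  cl <- clusters[results$tr]
  mo <- moa[results$drug]
  ok <- !is.na(cl) & !is.na(mo)
  cl <- cl[ok]; mo <- mo[ok]
  sig <- results$significant[ok]
  N <- length(sig); n <- sum(sig)
  cls <- sort(unique(cl)); mos <- sort(unique(mo))
  p <- matrix(NA_real_, length(cls), length(mos),
              dimnames = list(cls, mos))
  for (a in cls) for (b in mos) {
    inside <- cl == a & mo == b
    K <- sum(inside)
    k <- sum(inside & sig)
    p[a, b] <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }
  threshold <- alpha / (length(cls) * length(mos))
  list(p = p, significant = p <= threshold, threshold = threshold)
}
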