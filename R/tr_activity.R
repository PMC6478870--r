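# TR activity inference: topology-constrained decomposition of expression
# into loadings and activities, with subnetwork bootstrapping and a growth
# pseudo-TR absorbing the pleiotropic proliferation signal.

GROWTH_TR <- ".growth"

#' Build a signed support matrix for NCA
#'
#' Encodes the topology constraint on the loading matrix: 0 absent, 1
#' loading constrained nonnegative (activation), -1 nonpositive
#' (repression), 2 unconstrained (unknown mode). When `growth` is TRUE an
#' extra pseudo-TR column, connected to every gene without sign
#' constraint, is appended.
#'
#' @param network data.frame with columns `tr`, `target`, `mode`
#'   (Activation / Repression / Unknown).
#' @param trs TR ids (columns); defaults to all TRs in the network.
#' @param genes gene ids (rows); defaults to the TRs' targets.
#' @param growth append the dense growth pseudo-TR column.
#' @param sign_constraints honour edge signs; otherwise all edges are
#'   unconstrained.
#' @return integer genes x TRs matrix (see codes above).
#' @export
build_support <- function(network, trs = NULL, genes = NULL, growth = TRUE,
                          sign_constraints = TRUE) {
  if (is.null(trs)) trs <- unique(network$tr)
  net <- network[network$tr %in% trs, , drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(net$target))
  net <- net[net$target %in% genes, , drop = FALSE]
  code <- if (!sign_constraints) rep(2L, nrow(net)) else
    ifelse(net$mode == "Activation", 1L,
           ifelse(net$mode == "Repression", -1L, 2L))
  cols <- if (growth) c(trs, GROWTH_TR) else trs
  sup <- matrix(0L, length(genes), length(cols),
                dimnames = list(genes, cols))
  sup[cbind(net$target, net$tr)] <- code
  if (growth) sup[, GROWTH_TR] <- 2L
  sup
}

#' Sample a bootstrap subnetwork around a focal TR
#'
#' The focal TR plus `k` further TRs drawn uniformly without replacement,
#' plus the growth pseudo-TR (k + 2 columns in total); genes are the union
#' of the real TRs' targets.
#'
#' @param network regulatory edge data.frame (`tr`, `target`, `mode`).
#' @param focal focal TR id.
#' @param k number of additional TRs (48 gives subnetworks of 50 real TRs).
#' @param seed optional integer seed for reproducible draws.
#' @inheritParams build_support
#' @return list with `trs`, `genes`, `support`.
#' @export
sample_subnetwork <- function(network, focal, k = 48, seed = NULL,
                              growth = TRUE, sign_constraints = TRUE) {
  pool <- unique(network$tr)
  if (!focal %in% pool) stop("sample_subnetwork: unknown focal TR")
  if (k >= length(pool))
    stop("sample_subnetwork: k must be smaller than the number of TRs")
  if (!is.null(seed)) set.seed(seed)
  others <- if (k > 0) sample(setdiff(pool, focal), k) else character(0)
  trs <- c(focal, others)
  sup <- build_support(network, trs, growth = growth,
                       sign_constraints = sign_constraints)
  list(trs = trs, genes = rownames(sup), support = sup)
}

#' Network component analysis by constrained alternating least squares
#'
#' Minimizes `||E - A %*% P||^2` with the loading matrix `A` restricted to
#' the signed support. Both half-steps are guarded so the objective is
#' non-increasing; convergence is declared when the relative objective
#' change drops below `tol`. Activity rows of TRs whose loadings carry no
#' sign constraint are oriented so that their loading-weighted mean target
#' correlation is positive (sign-constrained rows are already pinned).
#'
#' @param expression genes x samples matrix; rows must cover the support's
#'   genes.
#' @param support integer genes x TRs matrix from [build_support()].
#' @param tol relative objective-change tolerance.
#' @param max_iter iteration cap; non-convergence returns the best iterate
#'   with a warning.
#' @return list with `A` (loadings), `P` (activities, TRs x samples),
#'   `objective` (trace), `converged`.
#' @export
run_nca <- function(expression, support, tol = 1e-6, max_iter = 100) {
  missing_genes <- setdiff(rownames(support), rownames(expression))
  if (length(missing_genes))
    stop("run_nca: expression lacks ", length(missing_genes),
         " support genes")
  if (ncol(expression) < 2) stop("run_nca: need >= 2 samples")
  E <- expression[rownames(support), , drop = FALSE]
  fit <- nca_als_cpp(E, support, tol, as.integer(max_iter))
  if (!fit$converged)
    warning("run_nca: not converged in ", max_iter,
            " iterations; returning best iterate")
  A <- fit$A; P <- fit$P
  dimnames(A) <- dimnames(support)
  dimnames(P) <- list(colnames(support), colnames(E))
  # Gauge fix: the growth column's support is free on every gene, so the
  # fit is invariant to P[t, ] <- P[t, ] - c * P[growth, ] with the growth
  # loading column absorbing c * A[, t]. Resolve the indeterminacy by
  # projecting each real TR's activity orthogonal to the growth
  # pseudo-activity.
  if (GROWTH_TR %in% rownames(P)) {
    pg <- P[GROWTH_TR, ]
    ss <- sum(pg^2)
    if (ss > 0) {
      for (t in setdiff(rownames(P), GROWTH_TR)) {
        cc <- sum(P[t, ] * pg) / ss
        if (cc != 0) {
          P[t, ] <- P[t, ] - cc * pg
          A[, GROWTH_TR] <- A[, GROWTH_TR] + cc * A[, t]
        }
      }
    }
  }
  # orient sign-free TR rows
  for (t in seq_len(ncol(A))) {
    if (any(support[, t] %in% c(1L, -1L))) next
    nz <- which(A[, t] != 0)
    if (length(nz) == 0 || stats::sd(P[t, ]) == 0) next
    cc <- suppressWarnings(
      vapply(nz, function(g) stats::cor(E[g, ], P[t, ]), numeric(1)))
    s <- sum(A[nz, t] * cc, na.rm = TRUE)
    if (is.finite(s) && s < 0) {
      A[, t] <- -A[, t]
      P[t, ] <- -P[t, ]
    }
  }
  list(A = A, P = P, objective = fit$objective, converged = fit$converged)
}

#' Bootstrap TR activities over random subnetworks
#'
#' For every TR, `subnetworks_per_tr` subnetworks are seeded (each adding
#' `k` randomly drawn further TRs and the growth pseudo-TR); each
#' subnetwork is decomposed by [run_nca()], and a TR's activity estimates
#' are collected from every subnetwork containing it. Per subnetwork each
#' TR row is normalized by its maximum absolute value (or pooled and
#' normalized per TR globally with `normalize = "global"`); the reported
#' activity is the per-(TR, line) median over estimates, rescaled so each
#' TR's maximum absolute activity is 1, with the matching SD and estimate
#' counts. Growth pseudo-TR estimates are discarded.
#'
#' @param expression genes x cell-lines matrix.
#' @param network regulatory edge data.frame.
#' @param subnetworks_per_tr subnetworks seeded per TR.
#' @param k additional TRs per subnetwork.
#' @param seed integer seed governing all draws.
#' @param include_growth include the growth pseudo-TR column.
#' @param sign_constraints honour edge signs in the support.
#' @param normalize estimate normalization scheme.
#' @param tol,max_iter passed to [run_nca()].
#' @return object of class `activity_matrix`: list with `activity`,
#'   `spread` (TRs x lines), `n_estimates`, `missing_trs` (TRs with no
#'   expressed targets).
#' @export
bootstrap_activities <- function(expression, network,
                                 subnetworks_per_tr = 10, k = 48,
                                 seed = 1L, include_growth = TRUE,
                                 sign_constraints = TRUE,
                                 normalize = c("per_subnetwork", "global"),
                                 tol = 1e-6, max_iter = 100) {
  normalize <- match.arg(normalize)
  all_trs <- sort(unique(network$tr))
  network <- network[network$target %in% rownames(expression), ,
                     drop = FALSE]
  trs <- sort(unique(network$tr))
  missing_trs <- setdiff(all_trs, trs)
  if (length(missing_trs))
    warning("bootstrap_activities: no expressed targets for TR(s) ",
            paste(missing_trs, collapse = ", "))
  set.seed(seed)
  est <- stats::setNames(vector("list", length(trs)), trs)
  for (focal in trs) {
    for (b in seq_len(subnetworks_per_tr)) {
      sn <- sample_subnetwork(network, focal, k = min(k, length(trs) - 1L),
                              growth = include_growth,
                              sign_constraints = sign_constraints)
      fit <- suppressWarnings(
        run_nca(expression, sn$support, tol = tol, max_iter = max_iter))
      P <- fit$P[sn$trs, , drop = FALSE]
      if (normalize == "per_subnetwork") {
        mx <- apply(abs(P), 1, max)
        mx[mx == 0] <- 1
        P <- P / mx
      }
      for (t in sn$trs)
        est[[t]] <- c(est[[t]], list(P[t, ]))
    }
  }
  lines <- colnames(expression)
  activity <- spread <- matrix(NA_real_, length(trs), length(lines),
                               dimnames = list(trs, lines))
  n_estimates <- stats::setNames(integer(length(trs)), trs)
  for (t in trs) {
    M <- do.call(rbind, est[[t]])
    if (normalize == "global") {
      mx <- max(abs(M))
      if (mx > 0) M <- M / mx
    }
    activity[t, ] <- apply(M, 2, stats::median)
    spread[t, ] <- apply(M, 2, stats::sd)
    n_estimates[t] <- nrow(M)
    mx <- max(abs(activity[t, ]))
    if (mx > 0) {
      spread[t, ] <- spread[t, ] / mx
      activity[t, ] <- activity[t, ] / mx
    }
  }
  structure(list(activity = activity, spread = spread,
                 n_estimates = n_estimates, missing_trs = missing_trs),
            class = "activity_matrix")
}

#' Expected number of subnetworks containing a fixed TR
#'
#' Under the bootstrap scheme each of `n_trs` TRs seeds `per_tr`
#' subnetworks, each adding `k` TRs drawn uniformly without replacement
#' from the remaining `n_trs - 1`. A fixed TR appears in its own `per_tr`
#' subnetworks plus each other TR's with probability `k / (n_trs - 1)`:
#' the expectation is `per_tr * (1 + k)`, independent of `n_trs`.
#'
#' @param n_trs number of TRs.
#' @param per_tr subnetworks seeded per TR.
#' @param k additional TRs drawn per subnetwork.
#' @return expected subnetwork count (488 + 2 = 490 at the defaults).
#' @export
expected_subnetwork_coverage <- function(n_trs = 728, per_tr = 10, k = 48) {
  if (k >= n_trs) stop("k must be below n_trs")
  per_tr + (n_trs - 1) * per_tr * k / (n_trs - 1)
}

#' Collapse probe-level expression to gene level by the median
#'
#' @param expression probes x samples matrix.
#' @param probe_map data.frame with columns `probe`, `gene`.
#' @return genes x samples matrix.
#' @export
collapse_probes <- function(expression, probe_map) {
  probe_map <- probe_map[probe_map$probe %in% rownames(expression), ,
                         drop = FALSE]
  idx <- split(probe_map$probe, probe_map$gene)
  out <- t(vapply(idx, function(p)
    apply(expression[p, , drop = FALSE], 2, stats::median),
    numeric(ncol(expression))))
  colnames(out) <- colnames(expression)
  out
}
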