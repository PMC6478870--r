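# Ensemble nonlinear effector models: saturable metabolite/kinase
# modulation of TR activity on top of TR protein abundance, scanned over
# all candidate modulator combinations with a resampling FDR.

#' Enumerate candidate effector model specifications
#'
#' Per TR: each metabolite in activating and inhibiting mode, each kinase
#' in both modes, and every metabolite x kinase pair in all four mode
#' combinations (`2M + 2K + 4MK` models per TR), in deterministic order.
#'
#' @param trs,metabolites,kinases candidate id vectors (metabolites and/or
#'   kinases may be empty).
#' @return data.frame: tr, metabolite, met_mode, kinase, kin_mode,
#'   form_id.
#' @export
enumerate_effector_models <- function(trs, metabolites, kinases) {
  modes <- c("activating", "inhibiting")
  per_tr <- list()
  if (length(metabolites))
    per_tr$met <- expand.grid(metabolite = metabolites, met_mode = modes,
                              kinase = NA_character_,
                              kin_mode = NA_character_,
                              stringsAsFactors = FALSE)
  if (length(kinases))
    per_tr$kin <- expand.grid(metabolite = NA_character_,
                              met_mode = NA_character_,
                              kinase = kinases, kin_mode = modes,
                              stringsAsFactors = FALSE)
  if (length(metabolites) && length(kinases))
    per_tr$both <- expand.grid(metabolite = metabolites, met_mode = modes,
                               kinase = kinases, kin_mode = modes,
                               stringsAsFactors = FALSE)
  if (length(per_tr) == 0)
    return(data.frame(tr = character(0), metabolite = character(0),
                      met_mode = character(0), kinase = character(0),
                      kin_mode = character(0), form_id = character(0)))
  base <- do.call(rbind, per_tr)
  out <- do.call(rbind, lapply(trs, function(t)
    cbind(data.frame(tr = t, stringsAsFactors = FALSE), base)))
  out$form_id <- paste0(
    ifelse(is.na(out$met_mode), "", substr(out$met_mode, 1, 3)),
    ifelse(is.na(out$met_mode) | is.na(out$kin_mode), "", "*"),
    ifelse(is.na(out$kin_mode), "", substr(out$kin_mode, 1, 3)))
  rownames(out) <- NULL
  out
}

# profile RSS of activity ~ a + b * protein * f(met;Km) * f(kin;Kk):
# for fixed K's the (a, b) pair is solved linearly
effector_rss <- function(logK, activity, protein, met, kin, met_mode,
                         kin_mode) {
  logK <- pmin(pmax(logK, -20), 20)
  x <- protein
  i <- 1L
  if (!is.null(met)) {
    x <- x * effector_f(met, exp(logK[i]), met_mode)
    i <- i + 1L
  }
  if (!is.null(kin)) x <- x * effector_f(kin, exp(logK[i]), kin_mode)
  X <- cbind(1, x)
  fit <- stats::lm.fit(X, activity)
  sum(fit$residuals^2)
}

#' Fit one nonlinear effector model of TR activity
#'
#' Nonlinear least squares of
#' `activity = a + b * protein * f(met; K_m, mode) * f(kin; K_k, mode)`
#' with saturable activation `x/(K+x)` or inhibition `K/(K+x)`, `K > 0`.
#' Modulator profiles are rescaled to unit median before fitting. The
#' half-saturation constants are profiled (the linear pair `a, b` is
#' solved exactly at each candidate K) and optimized from `n_starts`
#' seeded multi-starts. The baseline model is `a + b * protein`; the
#' improvement `dmse = mse_baseline - mse` is reported without clipping —
#' a negative value flags an optimizer failure on this nested family.
#'
#' @param activity per-line TR activity vector.
#' @param protein per-line TR protein abundance (positive).
#' @param met,kin optional per-line modulator abundances (positive).
#' @param met_mode,kin_mode "activating" or "inhibiting".
#' @param n_starts multi-start count.
#' @return list: params (a, b, K_met, K_kin), mse, mse_baseline, dmse, ok.
#' @export
fit_effector_model <- function(activity, protein, met = NULL, kin = NULL,
                               met_mode = NULL, kin_mode = NULL,
                               n_starts = 3) {
  if (is.null(met) && is.null(kin))
    stop("fit_effector_model: at least one modulator is required")
  n <- length(activity)
  if (n < 8) stop("fit_effector_model: need >= 8 shared cell lines")
  protein <- protein / stats::median(protein)
  if (!is.null(met)) met <- met / stats::median(met)
  if (!is.null(kin)) kin <- kin / stats::median(kin)
  base_fit <- stats::lm.fit(cbind(1, protein), activity)
  mse_base <- mean(base_fit$residuals^2)
  n_par <- (!is.null(met)) + (!is.null(kin))
  starts <- log(c(0.25, 1, 4))[seq_len(max(n_starts, 1))]
  best <- NULL
  for (s in starts) {
    res <- tryCatch({
      if (n_par == 1) {
        o <- stats::optim(rep(s, 1), effector_rss, activity = activity,
                          protein = protein, met = met, kin = kin,
                          met_mode = met_mode, kin_mode = kin_mode,
                          method = "Brent", lower = -20, upper = 20)
      } else {
        o <- stats::optim(rep(s, 2), effector_rss, activity = activity,
                          protein = protein, met = met, kin = kin,
                          met_mode = met_mode, kin_mode = kin_mode,
                          method = "Nelder-Mead")
      }
      o
    }, error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best))
    return(list(params = NULL, mse = NA_real_, mse_baseline = mse_base,
                dmse = NA_real_, ok = FALSE))
  logK <- pmin(pmax(best$par, -20), 20)
  K <- exp(logK)
  mse <- best$value / n
  x <- protein
  i <- 1L
  K_met <- K_kin <- NA_real_
  if (!is.null(met)) {
    K_met <- K[i]
    x <- x * effector_f(met, K_met, met_mode)
    i <- i + 1L
  }
  if (!is.null(kin)) {
    K_kin <- K[i]
    x <- x * effector_f(kin, K_kin, kin_mode)
  }
  ab <- stats::lm.fit(cbind(1, x), activity)$coefficients
  list(params = c(a = unname(ab[1]), b = unname(ab[2]), K_met = K_met,
                  K_kin = K_kin),
       mse = mse, mse_baseline = mse_base, dmse = mse_base - mse,
       ok = TRUE)
}

scan_specs <- function(activity, proteome, met_levels, specs) {
  vapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    act <- activity[s$tr, ]
    prot <- proteome[s$tr, ]
    met <- if (is.na(s$metabolite)) NULL else met_levels[s$metabolite, ]
    kin <- if (is.na(s$kinase)) NULL else proteome[s$kinase, ]
    fit <- fit_effector_model(act, prot, met, kin,
                              met_mode = if (is.na(s$met_mode)) NULL else
                                s$met_mode,
                              kin_mode = if (is.na(s$kin_mode)) NULL else
                                s$kin_mode)
    if (fit$ok) fit$dmse else NA_real_
  }, numeric(1))
}

#' Ensemble effector scan with resampling FDR
#'
#' Fits every candidate model, then builds a null MSE-improvement
#' distribution by refitting all models on activity rows with permuted
#' cell-line labels (`n_null` permutations, pooled across TRs and model
#' families — the bulk-distribution FDR of the reference workflow). A
#' model passes if its improvement exceeds the `1 - fdr` quantile of the
#' pooled null.
#'
#' @param activity TRs x lines matrix (or `activity_matrix`).
#' @param proteome proteins x lines abundance matrix covering the TRs and
#'   kinases referenced by `specs`.
#' @param met_levels metabolites x lines positive abundance matrix.
#' @param specs model specifications from [enumerate_effector_models()].
#' @param fdr resampling false-discovery level.
#' @param n_null label permutations for the null pool.
#' @param seed integer seed.
#' @return list with `results` (specs + dmse, pass), `threshold`,
#'   `null_dmse`.
#' @export
effector_scan <- function(activity, proteome, met_levels, specs,
                          fdr = 0.001, n_null = 5, seed = 1L) {
  act <- if (inherits(activity, "activity_matrix")) activity$activity
         else activity
  shared <- Reduce(intersect, list(colnames(act), colnames(proteome),
                                   colnames(met_levels)))
  act <- act[, shared, drop = FALSE]
  proteome <- proteome[, shared, drop = FALSE]
  met_levels <- met_levels[, shared, drop = FALSE]
  if (n_null * nrow(specs) < ceiling(1 / fdr))
    stop("effector_scan: n_null * n_models (", n_null * nrow(specs),
         ") too small for the ", fdr, " FDR quantile")
  dmse <- scan_specs(act, proteome, met_levels, specs)
  set.seed(seed)
  null_pool <- numeric(0)
  for (b in seq_len(n_null)) {
    perm_act <- act[, sample(ncol(act)), drop = FALSE]
    colnames(perm_act) <- colnames(act)
    null_pool <- c(null_pool, scan_specs(perm_act, proteome, met_levels,
                                         specs))
  }
  null_pool <- null_pool[!is.na(null_pool)]
  threshold <- sort(null_pool)[ceiling((1 - fdr) * length(null_pool))]
  results <- specs
  results$dmse <- dmse
  results$pass <- !is.na(dmse) & dmse > threshold
  list(results = results, threshold = threshold, null_dmse = null_pool)
}

#' Compare kinase-interaction degree distributions of TRs and enzymes
#'
#' Two-sample Kolmogorov-Smirnov test on per-node kinase degrees.
#'
#' @param deg_tr,deg_enzyme per-node kinase-interaction counts.
#' @return list with `statistic` (KS D) and `p`.
#' @export
kinase_degree_compare <- function(deg_tr, deg_enzyme) {
  if (length(deg_tr) == 0 || length(deg_enzyme) == 0)
    stop("kinase_degree_compare: empty degree sample")
  ks <- suppressWarnings(stats::ks.test(deg_tr, deg_enzyme))
  list(statistic = unname(ks$statistic), p = ks$p.value)
}
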