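# Pipeline driver: runs the synthetic study end to end through every
# analysis stage, with per-stage caching, logging and TSV outputs.

#' Pipeline configuration
#'
#' Bundles the simulation config with every stage's parameters. Defaults
#' mirror the reference workflow: 0.003 amu annotation tolerance, volume
#' selection at Pearson r > 0.8, augmented-network cutoff |R| > 0.5, 100
#' bootstrap resamples at 0.1% FDR for association links, 10,000
#' permutations for in-vivo scores and randomized distance nulls, and the
#' more-than-10-missing patient filter.
#'
#' @param sim a [sim_config()].
#' @param mz_tol annotation mass tolerance (amu).
#' @param volume_r_threshold volume-reporter selection threshold.
#' @param aug_r_threshold augmented-network |Spearman| cutoff.
#' @param assoc_resamples,assoc_fdr bootstrap FDR control of the
#'   association network.
#' @param subnetworks_per_tr,k_subnetwork activity bootstrap scheme.
#' @param distance_thresholds,distance_n_random distance-curve sweep.
#' @param invivo_n_perm,invivo_max_missing,n_patients in-vivo scoring.
#' @param effector_fdr,effector_n_null effector scan FDR control.
#' @param seed master seed for analysis-stage randomness (the simulation
#'   has its own seed inside `sim`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            mz_tol = 0.003,
                            volume_r_threshold = 0.8,
                            aug_r_threshold = 0.5,
                            assoc_resamples = 100,
                            assoc_fdr = 0.001,
                            subnetworks_per_tr = 10,
                            k_subnetwork = 48,
                            distance_thresholds = seq(0, 0.6, by = 0.1),
                            distance_n_random = 10000,
                            invivo_n_perm = 10000,
                            invivo_max_missing = 10,
                            n_patients = 20,
                            effector_fdr = 0.001,
                            effector_n_null = 3,
                            seed = 1L) {
  structure(list(sim = sim, mz_tol = mz_tol,
                 volume_r_threshold = volume_r_threshold,
                 aug_r_threshold = aug_r_threshold,
                 assoc_resamples = assoc_resamples, assoc_fdr = assoc_fdr,
                 subnetworks_per_tr = subnetworks_per_tr,
                 k_subnetwork = k_subnetwork,
                 distance_thresholds = distance_thresholds,
                 distance_n_random = distance_n_random,
                 invivo_n_perm = invivo_n_perm,
                 invivo_max_missing = invivo_max_missing,
                 n_patients = n_patients,
                 effector_fdr = effector_fdr,
                 effector_n_null = effector_n_null,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

param_digest <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Run the full synthetic-study pipeline
#'
#' Stages run in dependency order: simulate, quantify, activity,
#' associate, distance, enrich, flux scoring, in-vivo scoring, knockdown
#' ranking, drug regression, effector scan. Each stage logs its
#' parameters and digest, caches its result under `out_dir`, and is
#' skipped on rerun when its own and all upstream parameters are
#' unchanged; changing e.g. a seed invalidates every downstream stage.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output/cache directory.
#' @param force recompute everything.
#' @param verbose log to the console as well as to `pipeline.log`.
#' @return invisible list with every stage's result and `log` (path).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         out_dir = tempfile("trmet_run"),
                         force = FALSE, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (verbose) message(msg)
  }
  prev_digest <- ""
  stage <- function(name, params, compute) {
    dg <- param_digest(list(upstream = prev_digest, params = params))
    prev_digest <<- dg
    marker <- file.path(out_dir, paste0(name, ".digest"))
    cache <- file.path(out_dir, paste0(name, ".rds"))
    if (!force && file.exists(marker) && file.exists(cache) &&
        readLines(marker, n = 1) == dg) {
      log_line("stage ", name, ": up to date (", dg, ")")
      return(readRDS(cache))
    }
    t0 <- proc.time()[["elapsed"]]
    res <- compute()
    saveRDS(res, cache)
    writeLines(dg, marker)
    log_line("stage ", name, ": done in ",
             sprintf("%.1f", proc.time()[["elapsed"]] - t0),
             " s (digest ", dg, ")")
    res
  }

  sim <- stage("simulate", config$sim, function() {
    study <- simulate_study(config$sim)
    write_matrix_tsv(study$intensities$intensity,
                     file.path(out_dir, "intensities.tsv"))
    utils::write.table(study$intensities$sample_meta,
                       file.path(out_dir, "sample_meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_matrix_tsv(study$tr_system$expression,
                     file.path(out_dir, "expression.tsv"))
    write_regulatory_network(study$tr_system$network,
                             file.path(out_dir, "network.tsv"))
    utils::write.table(study$truth$reactions,
                       file.path(out_dir, "reactions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_sim_config(config$sim, file.path(out_dir, "sim_config.yaml"))
    study
  })
  truth <- sim$truth

  quant <- stage("quantify", list(r = config$volume_r_threshold,
                                  mz_tol = config$mz_tol), function() {
    pf <- estimate_plate_factors(sim$intensities)
    ab <- fit_cell_regression(pf$corrected)
    ab <- filter_ions(ab)
    vc <- volume_correct(ab, r_threshold = config$volume_r_threshold)
    z <- zscore_abundance(vc$ab)
    ann <- annotate_ions(truth$ion_mz, truth$reference,
                         tolerance = config$mz_tol)
    # first annotation per ion names the metabolite space
    ann1 <- ann[!duplicated(ann$ion), ]
    ion2cmp <- stats::setNames(ann1$compound_id, ann1$ion)
    zc <- z$z[rownames(z$z) %in% names(ion2cmp), , drop = FALSE]
    cmp <- ion2cmp[rownames(zc)]
    zc <- zc[!duplicated(cmp), , drop = FALSE]
    rownames(zc) <- cmp[!duplicated(cmp)]
    write_matrix_tsv(zc, file.path(out_dir, "z_abundance.tsv"))
    list(plate_factors = pf$gamma, ab = vc$ab,
         volume_factor = vc$volume_factor, z = z, z_annotated = zc,
         annotation = ann)
  })

  act <- stage("activity", list(b = config$subnetworks_per_tr,
                                k = config$k_subnetwork,
                                seed = config$seed), function() {
    k <- min(config$k_subnetwork, config$sim$n_trs - 2L)
    a <- bootstrap_activities(
      sim$tr_system$expression, sim$tr_system$network,
      subnetworks_per_tr = config$subnetworks_per_tr, k = k,
      seed = config$seed)
    write_matrix_tsv(a$activity, file.path(out_dir, "tr_activity.tsv"))
    a
  })

  assoc <- stage("associate", list(n = config$assoc_resamples,
                                   fdr = config$assoc_fdr,
                                   seed = config$seed), function() {
    am <- tr_metabolite_correlation(act, quant$z_annotated)
    thr <- bootstrap_fdr_threshold(act, quant$z_annotated,
                                   n_resamples = config$assoc_resamples,
                                   fdr = config$assoc_fdr,
                                   seed = config$seed)
    links <- which(abs(am$R) >= thr$threshold, arr.ind = TRUE)
    net <- data.frame(tr = rownames(am$R)[links[, 1]],
                      metabolite = colnames(am$R)[links[, 2]],
                      R = am$R[links], p = am$p[links],
                      pass_fdr = TRUE, stringsAsFactors = FALSE)
    utils::write.table(net, file.path(out_dir, "association_network.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(assoc = am, threshold = thr, network = net)
  })

  graph <- metabolic_graph(truth$reactions)
  target_sets <- split(sim$tr_system$network$target,
                       sim$tr_system$network$tr)

  dist <- stage("distance", list(th = config$distance_thresholds,
                                 n = config$distance_n_random,
                                 seed = config$seed), function() {
    R <- assoc$assoc$R
    R <- R[, colnames(R) %in% graph$metabolites, drop = FALSE]
    curve <- distance_correlation_curve(
      R, graph, target_sets, thresholds = config$distance_thresholds,
      n_random = config$distance_n_random, seed = config$seed)
    utils::write.table(curve, file.path(out_dir, "distance_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    curve
  })

  enrich <- stage("enrich", list(seed = config$seed), function() {
    set.seed(config$seed)
    sets <- lapply(split(truth$coupling$metabolite, truth$coupling$tr),
                   unique)
    names(sets) <- paste0("proximal_", names(sets))
    rand <- lapply(seq_len(10), function(i) sample(truth$metabolites, 8))
    names(rand) <- sprintf("random%02d", seq_len(10))
    sets <- c(sets, rand)
    C <- ctr_vectors(assoc$assoc)
    mets <- intersect(colnames(C), truth$metabolites)
    ranked <- mets[order(-abs(C[truth$perturbed_tr, mets]))]
    ire <- iterative_rank_enrichment(ranked, sets, n_perm = 500,
                                     seed = config$seed)
    sel <- assoc$network$metabolite[assoc$network$tr == truth$perturbed_tr]
    hg <- hypergeom_enrichment(intersect(sel, mets), sets, universe = mets)
    list(sets = sets, rank_enrichment = ire, set_enrichment = hg)
  })

  flux <- stage("flux", list(seed = config$seed), function() {
    fx <- simulate_flux(config$sim, truth)
    fc <- metabolite_flux_correlation(quant$z_annotated, fx)
    ts <- tr_flux_score(assoc$assoc, fc)
    # TRs mapped to a pathway when a target enzyme catalyzes a reaction
    # involving one of its metabolites
    rxn_mets <- split(graph$edges$metabolite, graph$edges$reaction)
    gene_rxns <- split(graph$gene_map$reaction, graph$gene_map$gene)
    pathway_trs <- lapply(enrich$sets, function(ms) {
      rx <- names(rxn_mets)[vapply(rxn_mets, function(m)
        any(m %in% ms), logical(1))]
      genes <- unique(graph$gene_map$gene[graph$gene_map$reaction %in% rx])
      unique(sim$tr_system$network$tr[sim$tr_system$network$target %in%
                                        genes])
    })
    pathway_trs <- pathway_trs[lengths(pathway_trs) > 0]
    ps <- if (length(pathway_trs))
      pathway_tr_score(ts, pathway_trs, n_perm = 1000, seed = config$seed)
    else NULL
    list(flux = fx, flux_corr = fc, tr_score = ts, pathway_score = ps)
  })

  invivo <- stage("invivo", list(n = config$invivo_n_perm,
                                 np = config$n_patients,
                                 seed = config$seed), function() {
    C <- ctr_vectors(assoc$assoc)
    cohort <- simulate_cohort(C, config$sim, truth$perturbed_tr,
                              n_patients = config$n_patients)
    sc <- invivo_tr_score(C, cohort$fc, n_perm = config$invivo_n_perm,
                          max_missing = config$invivo_max_missing,
                          seed = config$seed)
    utils::write.table(
      data.frame(tr = names(sc$median_S), median_S = sc$median_S,
                 median_q = sc$median_q),
      file.path(out_dir, "invivo_scores.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    list(cohort = cohort, scores = sc)
  })

  knockdown <- stage("knockdown", list(seed = config$seed), function() {
    set.seed(config$seed + 7L)
    C <- ctr_vectors(assoc$assoc)
    sig <- C[truth$perturbed_tr, ]
    s <- stats::sd(sig)
    if (s > 0) sig <- sig / s
    conc <- c(0.5, 1, 1.5)
    fc <- vapply(conc, function(k)
      -k * sig + stats::rnorm(length(sig), 0, 0.5),
      numeric(length(sig)))
    dimnames(fc) <- list(colnames(C), paste0("conc", seq_along(conc)))
    kd <- knockdown_rank(C, fc)
    list(fc = fc, ranking = kd)
  })

  drugs <- stage("drugs", list(seed = config$seed), function() {
    reg <- drug_tr_regression(sim$proteome_drugs$drug_panel, act,
                              truth$tissue)
    clusters <- stats::setNames(
      paste0("cl", ceiling(seq_along(truth$trs) / 5)), truth$trs)
    moa <- moa_cluster_enrichment(reg$results, clusters,
                                  sim$proteome_drugs$moa)
    utils::write.table(reg$results,
                       file.path(out_dir, "drug_tr_regression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(regression = reg, moa = moa)
  })

  eff <- stage("effectors", list(fdr = config$effector_fdr,
                                 n_null = config$effector_n_null,
                                 seed = config$seed), function() {
    set.seed(config$seed + 8L)
    pe <- truth$planted_effectors
    mets <- unique(c(pe$metabolite,
                     sample(truth$metabolites, 7)))
    kins <- unique(c(pe$kinase, sample(truth$kinases, 5)))
    specs <- enumerate_effector_models(unique(pe$tr), mets, kins)
    met_levels <- sweep(
      truth$alpha_true[match(mets, truth$metabolites), , drop = FALSE],
      2, truth$cell_volume, "/")
    rownames(met_levels) <- mets
    scan <- effector_scan(sim$proteome_drugs$activity,
                          sim$proteome_drugs$proteome, met_levels, specs,
                          fdr = config$effector_fdr,
                          n_null = config$effector_n_null,
                          seed = config$seed)
    utils::write.table(scan$results,
                       file.path(out_dir, "effector_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    scan
  })

  log_line("pipeline complete")
  invisible(list(study = sim, quantify = quant, activity = act,
                 associate = assoc, distance = dist, enrich = enrich,
                 flux = flux, invivo = invivo, knockdown = knockdown,
                 drugs = drugs, effectors = eff, log = log_path,
                 out_dir = out_dir))
}
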