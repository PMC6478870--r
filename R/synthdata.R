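# Synthetic study generator: seeded simulation of the full experimental
# design (logistic growth in 96-well plates, cell-number-linear ion
# intensities with plate scaling, a signed TR->gene system with a growth
# confounder, patient cohorts, proteome and drug panels).

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic study. Defaults
#' emulate the reference design: 54 adherent cell lines from 8 tissue types
#' profiled in triplicate at five daily time points (15 metabolome samples
#' per line), batches of 5 lines per experiment, 12 pooled quality-control
#' extracts per measurement plate, and multiplicative intensity noise with a
#' 13% coefficient of variation.
#'
#' @param n_cell_lines number of cell lines.
#' @param n_tissues number of tissue-of-origin groups.
#' @param n_ions number of measured ions.
#' @param n_true_metabolites number of ions mapped to metabolite nodes of
#'   the toy stoichiometric network.
#' @param n_genes number of genes in the expression matrix.
#' @param n_trs number of transcriptional regulators.
#' @param n_kinases number of kinases in the proteome panel.
#' @param replicates_per_timepoint,n_timepoints sampling design; their
#'   product is the number of metabolome samples per line.
#' @param lines_per_batch cell lines cultivated per experiment (batch).
#' @param pooled_samples_per_plate pooled QC extracts added to each plate.
#' @param blanks_per_plate cell-free extraction-solvent wells per plate.
#' @param noise_cv multiplicative (log-normal) intensity noise, as a CV.
#' @param expression_noise_sd additive noise SD on expression values.
#' @param targets_per_tr regulatory out-degree of each TR.
#' @param shared_target_frac fraction of target slots drawn from a shared
#'   gene pool (the rest are TR-exclusive, keeping the network identifiable).
#' @param activation_frac,unknown_mode_frac edge-mode mixture
#'   (activation / repression / unknown).
#' @param growth_strength scale of the rank-one growth confounder on
#'   expression, relative to a unit single-TR effect.
#' @param coupling_strength scale of planted TR-metabolite couplings on the
#'   log-abundance of metabolites proximal to a planted TR's enzyme targets.
#' @param n_planted_trs number of TRs given proximal metabolite couplings.
#' @param n_reactions reactions in the toy bipartite metabolic network.
#' @param volume_sd between-line SD of log cell volume (drives the rank-one
#'   volume component of per-cell abundances).
#' @param ion_residual_sd per-(ion, line) log-abundance residual SD.
#' @param n_tissue_ions,tissue_effect_sd ions given a tissue-dependent
#'   abundance shift, and its SD.
#' @param plate_sd SD of log plate scaling factors.
#' @param n_drugs drug-sensitivity panel size.
#' @param seed integer seed; identical seed and config give bit-identical
#'   outputs.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_cell_lines = 54,
                       n_tissues = 8,
                       n_ions = 500,
                       n_true_metabolites = 200,
                       n_genes = 800,
                       n_trs = 100,
                       n_kinases = 64,
                       replicates_per_timepoint = 3,
                       n_timepoints = 5,
                       lines_per_batch = 5,
                       pooled_samples_per_plate = 12,
                       blanks_per_plate = 3,
                       noise_cv = 0.13,
                       expression_noise_sd = 0.05,
                       targets_per_tr = 8,
                       shared_target_frac = 0.1,
                       activation_frac = 0.7,
                       unknown_mode_frac = 0.05,
                       growth_strength = 1.5,
                       coupling_strength = 1,
                       n_planted_trs = 8,
                       n_reactions = 220,
                       volume_sd = 0.4,
                       ion_residual_sd = 0.08,
                       n_tissue_ions = 40,
                       tissue_effect_sd = 0.6,
                       plate_sd = 0.15,
                       n_drugs = 40,
                       seed = 1L) {
  cfg <- list(
    n_cell_lines = as.integer(n_cell_lines), n_tissues = as.integer(n_tissues),
    n_ions = as.integer(n_ions),
    n_true_metabolites = as.integer(n_true_metabolites),
    n_genes = as.integer(n_genes), n_trs = as.integer(n_trs),
    n_kinases = as.integer(n_kinases),
    replicates_per_timepoint = as.integer(replicates_per_timepoint),
    n_timepoints = as.integer(n_timepoints),
    lines_per_batch = as.integer(lines_per_batch),
    pooled_samples_per_plate = as.integer(pooled_samples_per_plate),
    blanks_per_plate = as.integer(blanks_per_plate),
    noise_cv = noise_cv, expression_noise_sd = expression_noise_sd,
    targets_per_tr = as.integer(targets_per_tr),
    shared_target_frac = shared_target_frac,
    activation_frac = activation_frac,
    unknown_mode_frac = unknown_mode_frac,
    growth_strength = growth_strength,
    coupling_strength = coupling_strength,
    n_planted_trs = as.integer(n_planted_trs),
    n_reactions = as.integer(n_reactions),
    volume_sd = volume_sd, ion_residual_sd = ion_residual_sd,
    n_tissue_ions = as.integer(n_tissue_ions),
    tissue_effect_sd = tissue_effect_sd,
    plate_sd = plate_sd, n_drugs = as.integer(n_drugs),
    seed = as.integer(seed))
  counts <- c("n_cell_lines", "n_tissues", "n_ions", "n_true_metabolites",
              "n_genes", "n_trs", "n_kinases", "replicates_per_timepoint",
              "n_timepoints", "lines_per_batch", "pooled_samples_per_plate",
              "n_reactions", "n_drugs")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop("sim_config: '", nm, "' must be a count >= 1")
  }
  if (cfg$noise_cv < 0) stop("sim_config: noise_cv must be >= 0")
  if (cfg$n_true_metabolites > cfg$n_ions)
    stop("sim_config: n_true_metabolites cannot exceed n_ions")
  if (cfg$targets_per_tr * cfg$n_trs * (1 - cfg$shared_target_frac) >
      cfg$n_genes)
    stop("sim_config: not enough genes for the requested TR out-degrees")
  class(cfg) <- "sim_config"
  cfg
}

# log-normal multiplier with unit mean and coefficient of variation cv;
# the normal deviate is always drawn so the RNG stream does not depend on cv
ln_noise <- function(n, cv) {
  z <- stats::rnorm(n)
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(s * z - s^2 / 2)
}

pad_ids <- function(prefix, n) sprintf("%s%0*d", prefix, nchar(n), seq_len(n))

#' Generate the ground truth of a synthetic study
#'
#' Draws every latent quantity the pipeline is later asked to recover:
#' per-line cell geometry and doubling times, per-cell abundance slopes
#' `alpha_true` (rank-one in cell volume, plus planted TR couplings and
#' tissue effects), plate scaling factors with per-batch product 1, true TR
#' activities, the signed regulatory network, a toy bipartite metabolic
#' network whose enzymes include targets of planted TRs (so that coupled
#' metabolites sit at distance 1 from those TRs), planted effector triples
#' and the perturbed TR of the patient cohort.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_truth`.
#' @export
simulate_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nl <- config$n_cell_lines
  lines <- pad_ids("line", nl)
  tissues <- paste0("tissue", rep_len(seq_len(config$n_tissues), nl))
  tissues <- sample(tissues)  # shuffle assignment
  names(tissues) <- lines

  cell_area <- stats::setNames(exp(stats::rnorm(nl, log(1800), 0.35)), lines)
  cell_volume <- stats::setNames(
    cell_area^1.5 * exp(stats::rnorm(nl, 0, config$volume_sd)) / 1800^0.5,
    lines)
  doubling_time <- stats::setNames(exp(stats::rnorm(nl, log(30), 0.25)), lines)

  n_batches <- ceiling(nl / config$lines_per_batch)
  batch <- stats::setNames(
    rep(seq_len(n_batches), each = config$lines_per_batch)[seq_len(nl)], lines)
  plate_ids <- as.vector(outer(
    sprintf("b%02d", seq_len(n_batches)),
    sprintf("t%d", seq_len(config$n_timepoints)),
    paste, sep = "_"))
  lg <- stats::rnorm(length(plate_ids), 0, config$plate_sd)
  gamma <- exp(lg)
  names(gamma) <- plate_ids
  # gauge: product 1 within every batch (pooled extracts only tie plates of
  # the same batch together, so only the per-batch scale is identifiable)
  pb <- sub("_t\\d+$", "", plate_ids)
  for (b in unique(pb)) {
    i <- pb == b
    gamma[i] <- gamma[i] / exp(mean(log(gamma[i])))
  }

  # regulatory network: mostly TR-exclusive targets plus a shared pool
  trs <- pad_ids("tr", config$n_trs)
  genes <- pad_ids("g", config$n_genes)
  n_excl <- round(config$targets_per_tr * (1 - config$shared_target_frac))
  n_shared <- config$targets_per_tr - n_excl
  excl_block <- matrix(genes[seq_len(n_excl * config$n_trs)],
                       nrow = n_excl)
  pool <- setdiff(genes, as.vector(excl_block))
  edges <- do.call(rbind, lapply(seq_len(config$n_trs), function(t) {
    tg <- excl_block[, t]
    if (n_shared > 0 && length(pool) > 0)
      tg <- c(tg, sample(pool, min(n_shared, length(pool))))
    data.frame(tr = trs[t], target = tg, stringsAsFactors = FALSE)
  }))
  u <- stats::runif(nrow(edges))
  mode <- ifelse(u < config$unknown_mode_frac, "Unknown",
          ifelse(u < config$unknown_mode_frac +
                   (1 - config$unknown_mode_frac) * config$activation_frac,
                 "Activation", "Repression"))
  edges$mode <- mode
  true_sign <- ifelse(mode == "Activation", 1,
               ifelse(mode == "Repression", -1,
                      sample(c(-1, 1), nrow(edges), replace = TRUE)))
  edges$true_sign <- true_sign
  edges$weight <- exp(stats::rnorm(nrow(edges), 0, 0.3)) * true_sign

  # True activities model growth-independent regulation: the growth
  # confounder carries all growth covariation, so activity rows are drawn
  # orthogonal to the growth-rate vector (which is also the component the
  # growth pseudo-TR gauge removes during inference).
  w0 <- log(2) / doubling_time
  w0 <- (w0 - mean(w0)) / stats::sd(w0)
  tr_activity_true <- matrix(stats::rnorm(config$n_trs * nl), config$n_trs,
                             dimnames = list(trs, lines))
  tr_activity_true <- tr_activity_true -
    (tr_activity_true %*% w0 / sum(w0^2)) %*% t(w0)
  tr_activity_true <- tr_activity_true - rowMeans(tr_activity_true)
  tr_activity_true <- tr_activity_true /
    apply(tr_activity_true, 1, stats::sd)

  # toy bipartite metabolic network
  mets <- pad_ids("met", config$n_true_metabolites)
  rxns <- pad_ids("rx", config$n_reactions)
  subs <- lapply(seq_len(config$n_reactions), function(r)
    sample(mets, sample(1:2, 1)))
  prods <- lapply(seq_len(config$n_reactions), function(r)
    sample(setdiff(mets, subs[[r]]), sample(1:2, 1)))
  rxn_gene <- sample(genes, config$n_reactions, replace = TRUE)

  # planted TR-metabolite proximity: reassign a few reactions to enzymes
  # among a planted TR's targets, and couple the adjacent metabolites to
  # that TR's activity
  planted_trs <- sample(trs, config$n_planted_trs)
  coupling <- data.frame(tr = character(0), metabolite = character(0),
                         strength = numeric(0), stringsAsFactors = FALSE)
  rx_avail <- seq_len(config$n_reactions)
  for (t in planted_trs) {
    tg <- edges$target[edges$tr == t]
    rsel <- sample(rx_avail, 2)
    rx_avail <- setdiff(rx_avail, rsel)
    rxn_gene[rsel] <- sample(tg, 2, replace = length(tg) < 2)
    near <- unique(unlist(c(subs[rsel], prods[rsel])))
    coupling <- rbind(coupling, data.frame(
      tr = t, metabolite = near,
      strength = 0.3 * config$coupling_strength,
      stringsAsFactors = FALSE))
  }
  reactions <- data.frame(
    reaction_id = rxns,
    gene_ids = rxn_gene,
    substrates = vapply(subs, paste, "", collapse = ";"),
    products = vapply(prods, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)

  # per-cell abundance slopes (ions x lines)
  ions <- pad_ids("ion", config$n_ions)
  ion_scale <- exp(stats::rnorm(config$n_ions, log(50), 1))
  lvol <- log(cell_volume) - mean(log(cell_volume))
  lalpha <- outer(rep(1, config$n_ions), lvol) + log(ion_scale)
  dimnames(lalpha) <- list(ions, lines)
  tissue_ions <- sample(ions, min(config$n_tissue_ions, config$n_ions))
  teff <- matrix(stats::rnorm(length(tissue_ions) * config$n_tissues, 0,
                              config$tissue_effect_sd),
                 length(tissue_ions),
                 dimnames = list(tissue_ions, unique(sort(tissues))))
  lalpha[tissue_ions, ] <- lalpha[tissue_ions, ] + teff[, tissues]
  if (nrow(coupling) > 0) {
    for (k in seq_len(nrow(coupling))) {
      ion <- ions[match(coupling$metabolite[k], mets)]
      act <- tr_activity_true[coupling$tr[k], ]
      lalpha[ion, ] <- lalpha[ion, ] +
        coupling$strength[k] * (act - mean(act)) / stats::sd(act)
    }
  }
  lalpha <- lalpha +
    matrix(stats::rnorm(length(lalpha), 0, config$ion_residual_sd),
           nrow(lalpha))
  alpha_true <- exp(lalpha)
  dimnames(alpha_true) <- list(ions, lines)
  beta_true <- stats::setNames(exp(stats::rnorm(config$n_ions, log(2e4), 1)),
                               ions)

  # ion m/z values from a synthetic reference compound list
  ref_mass <- round(stats::runif(config$n_ions, 80, 600), 5)
  is_keto <- rep(FALSE, config$n_ions)
  is_keto[sample(config$n_true_metabolites,
                 max(1, round(0.05 * config$n_true_metabolites)))] <- TRUE
  reference <- data.frame(
    compound_id = c(mets, pad_ids("cmp", config$n_ions - length(mets))),
    formula = "unspecified",
    monoisotopic_mass = ref_mass,
    is_alpha_keto = is_keto,
    stringsAsFactors = FALSE)
  mz <- ref_mass - 1.007276 + stats::runif(config$n_ions, -0.002, 0.002)
  names(mz) <- ions

  # planted effector triples and the cohort's perturbed TR
  kinases <- pad_ids("kin", config$n_kinases)
  eff_tr <- sample(trs, 3)
  planted_effectors <- data.frame(
    tr = eff_tr,
    metabolite = sample(mets, 3),
    kinase = sample(kinases, 3),
    met_mode = sample(c("activating", "inhibiting"), 3, replace = TRUE),
    kin_mode = sample(c("activating", "inhibiting"), 3, replace = TRUE),
    K_met = exp(stats::rnorm(3, 0, 0.4)),
    K_kin = exp(stats::rnorm(3, 0, 0.4)),
    stringsAsFactors = FALSE)
  perturbed_tr <- planted_trs[1]

  out <- list(
    config = config, cell_lines = lines, tissue = tissues,
    cell_area = cell_area, cell_volume = cell_volume,
    doubling_time = doubling_time, batch = batch,
    plate_factor_true = gamma,
    alpha_true = alpha_true, beta_true = beta_true,
    tr_activity_true = tr_activity_true,
    regulatory_edges = edges, reactions = reactions,
    metabolites = mets, ions = ions, genes = genes, trs = trs,
    kinases = kinases, ion_mz = mz, reference = reference,
    tissue_ions = tissue_ions,
    planted_trs = planted_trs, coupling = coupling,
    planted_effectors = planted_effectors, perturbed_tr = perturbed_tr)
  class(out) <- "sim_truth"
  out
}

#' Simulate logistic growth and the metabolome sampling design
#'
#' Each cell line grows logistically from ~25% confluence; replicate wells
#' carry a small deterministic-per-seed spread in starting confluence.
#' Sampling yields `replicates_per_timepoint * n_timepoints` metabolome
#' samples per line; extracted cell number is confluence times well area
#' over the line's characteristic cell area.
#'
#' @param config a [sim_config()].
#' @param truth a [simulate_ground_truth()] result (regenerated from
#'   `config` when omitted).
#' @param well_area well surface area in square micrometres (96-well plate).
#' @return data.frame with one row per cell sample: sample_id, cell_line,
#'   batch, plate, timepoint (h), replicate, confluence (%), cell_count.
#' @export
simulate_growth <- function(config, truth = simulate_ground_truth(config),
                            well_area = 0.32e8) {
  set.seed(config$seed + 1L)
  tps <- (seq_len(config$n_timepoints) - 1L) * 24
  rows <- list()
  for (l in truth$cell_lines) {
    r <- log(2) / truth$doubling_time[l]
    for (rep_i in seq_len(config$replicates_per_timepoint)) {
      c0 <- 25 * exp(stats::rnorm(1, 0, 0.07))
      conf <- 100 / (1 + ((100 - c0) / c0) * exp(-r * tps))
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = l, batch = truth$batch[[l]],
        timepoint = tps, replicate = rep_i,
        confluence = pmin(conf, 100), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$plate <- sprintf("b%02d_t%d", out$batch,
                       match(out$timepoint, tps))
  out$cell_count <- cells_from_confluence(
    out$confluence, truth$cell_area[out$cell_line], well_area)
  out$sample_id <- sprintf("%s_t%d_r%d", out$cell_line,
                           match(out$timepoint, tps), out$replicate)
  rownames(out) <- NULL
  out[, c("sample_id", "cell_line", "batch", "plate", "timepoint",
          "replicate", "confluence", "cell_count")]
}

#' Simulate the raw ion-intensity table
#'
#' Cell samples follow `I = gamma_p * (alpha_true * N + beta_true)` with
#' multiplicative log-normal noise of CV `noise_cv`; pooled QC wells share
#' one pooled composition per batch across that batch's plates; cell-free
#' blanks emit the scaled background only.
#'
#' @param truth a `sim_truth`.
#' @param samples output of [simulate_growth()].
#' @param config the [sim_config()].
#' @param pooled_cell_count nominal cell equivalents in pooled extracts.
#' @return a list of class `intensity_table` with elements `intensity`
#'   (ions x samples) and `sample_meta` (sample_id, sample_type, cell_line,
#'   batch, plate, timepoint, replicate, confluence, cell_count).
#' @export
simulate_intensities <- function(truth, samples, config,
                                 pooled_cell_count = 5000) {
  stopifnot(inherits(truth, "sim_truth"))
  if (any(truth$alpha_true < 0) || any(samples$cell_count < 0))
    stop("simulate_intensities: negative alpha_true or cell counts")
  set.seed(config$seed + 2L)
  plates <- names(truth$plate_factor_true)
  meta_cell <- data.frame(samples, sample_type = "cell",
                          stringsAsFactors = FALSE)
  # pooled and blank wells on every plate
  extra <- list()
  for (p in plates) {
    b <- as.integer(sub("^b(\\d+)_.*$", "\\1", p))
    np <- config$pooled_samples_per_plate
    nb <- config$blanks_per_plate
    extra[[p]] <- data.frame(
      sample_id = c(sprintf("%s_pool%02d", p, seq_len(np)),
                    sprintf("%s_blank%02d", p, seq_len(nb))),
      cell_line = NA_character_, batch = b, plate = p,
      timepoint = NA_real_, replicate = NA_integer_,
      confluence = NA_real_, cell_count = NA_real_,
      sample_type = rep(c("pooled", "blank"), c(np, nb)),
      stringsAsFactors = FALSE)
  }
  meta <- rbind(meta_cell[, names(extra[[1]])], do.call(rbind, extra))
  rownames(meta) <- NULL

  # pre-noise pooled composition, identical across a batch's plates
  batch_lines <- split(truth$cell_lines, truth$batch)
  m_pool <- vapply(batch_lines, function(ls) {
    rowMeans(truth$alpha_true[, ls, drop = FALSE]) * pooled_cell_count +
      truth$beta_true
  }, numeric(length(truth$ions)))

  n_ion <- length(truth$ions)
  inten <- matrix(NA_real_, n_ion, nrow(meta),
                  dimnames = list(truth$ions, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    g <- truth$plate_factor_true[[meta$plate[j]]]
    base <- switch(meta$sample_type[j],
      cell = truth$alpha_true[, meta$cell_line[j]] * meta$cell_count[j] +
        truth$beta_true,
      pooled = m_pool[, meta$batch[j]],
      blank = truth$beta_true)
    inten[, j] <- g * base * ln_noise(n_ion, config$noise_cv)
  }
  structure(list(intensity = inten, sample_meta = meta),
            class = "intensity_table")
}

#' Simulate the TR system: regulatory network and expression matrix
#'
#' Expression is `E = A %*% P + growth_strength * g %*% t(w) + noise`, where
#' `A` respects the signed edges of the regulatory network, `P` is the true
#' TR activity matrix, and the rank-one term (gene loadings `g`, growth
#' rates `w` proportional to 1/doubling time) emulates the pleiotropic
#' effect of proliferation on gene expression — the motivation for the
#' growth pseudo-TR used during activity inference.
#'
#' @param config the [sim_config()].
#' @param truth a `sim_truth`.
#' @return list with `network` (TR, target, mode), `expression`
#'   (genes x lines), `A_true` (genes x TRs), `growth_rate` (per line).
#' @export
simulate_tr_system <- function(config, truth = simulate_ground_truth(config)) {
  set.seed(config$seed + 3L)
  e <- truth$regulatory_edges
  A <- matrix(0, config$n_genes, config$n_trs,
              dimnames = list(truth$genes, truth$trs))
  A[cbind(e$target, e$tr)] <- e$weight
  w <- log(2) / truth$doubling_time
  w <- (w - mean(w)) / stats::sd(w)
  g <- abs(stats::rnorm(config$n_genes, 0, 1))
  E <- A %*% truth$tr_activity_true +
    config$growth_strength * outer(g, w) +
    matrix(stats::rnorm(config$n_genes * config$n_cell_lines, 0,
                        config$expression_noise_sd),
           config$n_genes)
  dimnames(E) <- list(truth$genes, truth$cell_lines)
  list(network = e[, c("tr", "target", "mode")], expression = E,
       A_true = A, growth_rate = stats::setNames(w, truth$cell_lines))
}

#' Simulate a patient cohort of metabolite fold-changes
#'
#' Per patient, log2 fold-changes between tumor and adjacent normal tissue
#' follow `FC = effect * C_perturbed + noise`, where `C_perturbed` is the
#' perturbed TR's standardized in-vitro correlation signature. A fraction of
#' values is missing completely at random, and a small set of poorly
#' detected metabolites has heavy missingness so the more-than-10-missing
#' exclusion filter is exercised.
#'
#' @param ctr C_TR matrix (TRs x metabolites), e.g. from [ctr_vectors()].
#' @param config the [sim_config()].
#' @param perturbed_tr row of `ctr` that drives the cohort signal.
#' @param n_patients cohort size.
#' @param effect_size multiplier on the standardized signature.
#' @param noise_sd additive noise SD on fold-changes.
#' @param missing_frac MCAR missingness fraction.
#' @param dropout_frac fraction of metabolites with heavy (>10 of the
#'   patients) missingness.
#' @return list with `fc` (metabolites x patients, NAs for missing) and
#'   `perturbed_tr`.
#' @export
simulate_cohort <- function(ctr, config, perturbed_tr,
                            n_patients = 20, effect_size = 1.5,
                            noise_sd = 1, missing_frac = 0.05,
                            dropout_frac = 0.05) {
  if (!perturbed_tr %in% rownames(ctr))
    stop("simulate_cohort: unknown perturbed_tr '", perturbed_tr, "'")
  set.seed(config$seed + 4L)
  sig <- ctr[perturbed_tr, ]
  s <- stats::sd(sig)
  if (s > 0) sig <- sig / s
  m <- length(sig)
  fc <- matrix(effect_size * sig, m, n_patients) +
    matrix(stats::rnorm(m * n_patients, 0, noise_sd), m)
  dimnames(fc) <- list(colnames(ctr), sprintf("patient%02d",
                                              seq_len(n_patients)))
  if (missing_frac > 0)
    fc[matrix(stats::runif(length(fc)) < missing_frac, m)] <- NA
  n_drop <- round(dropout_frac * m)
  if (n_drop > 0) {
    drop_rows <- sample(m, n_drop)
    for (i in drop_rows) {
      k <- sample(11:(n_patients - 1), 1)
      fc[i, sample(n_patients, min(k, n_patients))] <- NA
    }
  }
  list(fc = fc, perturbed_tr = perturbed_tr)
}

# saturable modulation used by the effector generator and fitter
effector_f <- function(x, K, mode) {
  if (mode == "activating") x / (K + x) else K / (K + x)
}

#' Simulate proteome abundances, effector-driven TR activities and a drug
#' sensitivity panel
#'
#' TR activity for planted effector TRs follows
#' `a + b * protein * f(metabolite) * f(kinase) + noise` with saturable
#' activation `x/(K+x)` or inhibition `K/(K+x)`; all other TRs keep their
#' ground-truth activity. Drug sensitivity (log GI50 scale) is
#' `lambda * activity_TR + beta_tissue + noise`, with half the panel given
#' `lambda = 0` as negative controls; drugs sharing a target TR share a
#' mechanism-of-action label.
#'
#' @param config the [sim_config()].
#' @param truth a `sim_truth`.
#' @param effector_noise_sd additive noise SD on effector-driven activity.
#' @param drug_noise_sd additive noise SD on sensitivities.
#' @return list with `proteome` (proteins x lines, rows named by TR/kinase
#'   ids), `protein_type`, `activity` (TRs x lines including the
#'   effector-driven rows), `drug_panel` (drugs x lines), `moa` (drug ->
#'   mechanism label), `lambda_true`, `drug_target`.
#' @export
simulate_proteome_drugs <- function(config,
                                    truth = simulate_ground_truth(config),
                                    effector_noise_sd = 0.05,
                                    drug_noise_sd = 0.3) {
  set.seed(config$seed + 5L)
  nl <- config$n_cell_lines
  prot_ids <- c(truth$trs, truth$kinases)
  proteome <- matrix(exp(stats::rnorm(length(prot_ids) * nl, 0, 0.5)),
                     length(prot_ids), dimnames = list(prot_ids,
                                                       truth$cell_lines))
  protein_type <- stats::setNames(
    rep(c("TR", "kinase"), c(length(truth$trs), length(truth$kinases))),
    prot_ids)

  activity <- truth$tr_activity_true
  pe <- truth$planted_effectors
  vol <- truth$cell_volume
  for (k in seq_len(nrow(pe))) {
    met_ion <- truth$ions[match(pe$metabolite[k], truth$metabolites)]
    met <- truth$alpha_true[met_ion, ] / vol  # per-volume level
    met <- met / stats::median(met)
    kin <- proteome[pe$kinase[k], ]
    kin <- kin / stats::median(kin)
    prot <- proteome[pe$tr[k], ]
    raw <- prot * effector_f(met, pe$K_met[k], pe$met_mode[k]) *
      effector_f(kin, pe$K_kin[k], pe$kin_mode[k])
    raw <- (raw - mean(raw)) / stats::sd(raw)
    activity[pe$tr[k], ] <- raw + stats::rnorm(nl, 0, effector_noise_sd)
  }

  nd <- config$n_drugs
  drugs <- pad_ids("drug", nd)
  n_active <- floor(nd / 2)
  target <- c(sample(truth$trs, n_active, replace = n_active >
                       length(truth$trs)),
              rep(NA_character_, nd - n_active))
  lambda <- c(sample(c(-1, 1), n_active, replace = TRUE) *
                stats::runif(n_active, 0.5, 1.5),
              rep(0, nd - n_active))
  tiss <- truth$tissue
  tissue_levels <- sort(unique(tiss))
  beta_t <- matrix(stats::rnorm(nd * length(tissue_levels), 0, 0.5), nd,
                   dimnames = list(drugs, tissue_levels))
  panel <- matrix(0, nd, nl, dimnames = list(drugs, truth$cell_lines))
  for (d in seq_len(nd)) {
    act <- if (is.na(target[d])) 0 else activity[target[d], ]
    panel[d, ] <- lambda[d] * act + beta_t[d, tiss] +
      stats::rnorm(nl, 0, drug_noise_sd)
  }
  # MoA labels: drugs hitting the same TR share a mechanism; controls get
  # assorted labels
  moa <- ifelse(is.na(target), paste0("moa_ctrl",
                                      rep_len(1:4, nd)),
                paste0("moa_", target))
  names(moa) <- drugs
  list(proteome = proteome, protein_type = protein_type,
       activity = activity, drug_panel = panel,
       moa = moa, lambda_true = stats::setNames(lambda, drugs),
       drug_target = stats::setNames(target, drugs))
}

#' Run the complete synthetic study
#'
#' Convenience wrapper drawing ground truth, growth, intensities,
#' expression and the proteome/drug layer in one call.
#'
#' @param config a [sim_config()].
#' @return list with elements `truth`, `samples`, `intensities`,
#'   `tr_system`, `proteome_drugs`.
#' @export
simulate_study <- function(config = sim_config()) {
  truth <- simulate_ground_truth(config)
  samples <- simulate_growth(config, truth)
  intens <- simulate_intensities(truth, samples, config)
  trs <- simulate_tr_system(config, truth)
  pd <- simulate_proteome_drugs(config, truth)
  list(truth = truth, samples = samples, intensities = intens,
       tr_system = trs, proteome_drugs = pd)
}

#' Simulate glucose uptake and lactate secretion rates
#'
#' Glycolytic flux proxies per cell line: glucose uptake scales with
#' growth rate, and lactate secretion is drawn so that on average about
#' 70% of incoming glucose carbon leaves as lactate (a molar
#' lactate/glucose ratio of 1.4).
#'
#' @param config the [sim_config()].
#' @param truth a `sim_truth`.
#' @param carbon_fraction mean fraction of glucose carbon secreted as
#'   lactate.
#' @param rel_sd replicate-level relative SD reported alongside the means.
#' @return data.frame: cell_line, glucose_uptake, uptake_sd,
#'   lactate_secretion, secretion_sd (arbitrary per-cell rate units).
#' @export
simulate_flux <- function(config, truth = simulate_ground_truth(config),
                          carbon_fraction = 0.7, rel_sd = 0.08) {
  set.seed(config$seed + 6L)
  gr <- log(2) / truth$doubling_time
  uptake <- 100 * gr / mean(gr) * exp(stats::rnorm(length(gr), 0, 0.2))
  secretion <- 2 * carbon_fraction * uptake *
    exp(stats::rnorm(length(gr), 0, 0.08))
  data.frame(cell_line = truth$cell_lines,
             glucose_uptake = uptake,
             uptake_sd = rel_sd * uptake,
             lactate_secretion = secretion,
             secretion_sd = rel_sd * secretion,
             stringsAsFactors = FALSE)
}
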